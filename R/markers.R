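# Fiducial marker detection and cross-modal correspondence.

# 26-connected component labelling restricted to the voxels of a binary
# mask. Returns an integer vector of component ids parallel to `idx`
# (linear indices into the grid).
.connected_components <- function(idx, dims) {
  if (length(idx) == 0L) return(integer(0))
  ord <- order(idx)
  idx <- idx[ord]
  coords <- arrayInd(idx, dims)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  comp <- integer(length(idx))
  cur <- 0L
  for (start in seq_along(idx)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier) > 0L) {
      fc <- coords[frontier, , drop = FALSE]
      cand <- fc[rep(seq_len(nrow(fc)), each = nrow(nbr)), , drop = FALSE] +
        nbr[rep(seq_len(nrow(nbr)), times = nrow(fc)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + dims[1] * (cand[, 2] - 1 + dims[2] * (cand[, 3] - 1))
      pos <- findInterval(lin, idx)
      hit <- pos > 0 & idx[pmax(pos, 1)] == lin
      pos <- unique(pos[hit])
      pos <- pos[comp[pos] == 0L]
      comp[pos] <- cur
      frontier <- pos
    }
  }
  out <- integer(length(idx))
  out[ord] <- comp
  out
}

#' Detect fiducial markers by thresholding
#'
#' Binarises the volume at `threshold`, labels 26-connected components,
#' and keeps components whose voxel count falls inside
#' `[min_voxels, max_voxels]` (which removes both noise speckle and the
#' cranial bone shell). The centroid is the unweighted mean of the
#' component's voxel world-centres (binary centroid); an
#' intensity-weighted variant is available via `weighted = TRUE`. Each
#' marker carries an asymmetry index in `[0, 1]`: one minus the overlap
#' fraction of the component with its point reflection about the
#' centroid. Clean cylindrical markers are nearly symmetric (index close
#' to 0); an air bubble in the cavity raises it.
#'
#' @param v a [volume()].
#' @param threshold lower intensity bound for marker voxels.
#' @param min_voxels,max_voxels component size window (voxels).
#' @param weighted use intensity-weighted centroids.
#' @return A `marker_set`: list with `markers` (data.frame: label, x, y,
#'   z, voxels, bounding_size, asymmetry, on_border) and `modality`.
#' @export
detect_markers <- function(v, threshold, min_voxels = 5L,
                           max_voxels = 100000L, weighted = FALSE) {
  stopifnot(is_volume(v))
  dims <- dim(v$data)
  idx <- which(v$data >= threshold)
  empty <- data.frame(label = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), voxels = integer(0),
                      bounding_size = numeric(0), asymmetry = numeric(0),
                      on_border = logical(0))
  if (length(idx) == 0L) {
    warning("detect_markers: no voxels above threshold")
    return(structure(list(markers = empty, modality = v$modality),
                     class = "marker_set"))
  }
  comp <- .connected_components(idx, dims)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_voxels & sizes <= max_voxels)
  if (length(keep) == 0L) {
    warning("detect_markers: no component inside the size window")
    return(structure(list(markers = empty, modality = v$modality),
                     class = "marker_set"))
  }
  vs <- voxel_size(v)
  rows <- lapply(seq_along(keep), function(m) {
    ci <- idx[comp == keep[m]]
    co <- arrayInd(ci, dims)
    cen_vox <- if (weighted) {
      w <- v$data[ci]
      colSums(co * w) / sum(w)
    } else colMeans(co)
    cen <- voxel_to_world(v, cen_vox)
    ext <- apply(co, 2, function(x) diff(range(x)) + 1) * vs
    # point reflection about the (binary) centroid, on the voxel lattice
    bc <- colMeans(co)
    refl <- round(sweep(-co, 2, 2 * bc, "+"))
    ok <- refl[, 1] >= 1 & refl[, 1] <= dims[1] &
      refl[, 2] >= 1 & refl[, 2] <= dims[2] &
      refl[, 3] >= 1 & refl[, 3] <= dims[3]
    rl <- refl[ok, 1] + dims[1] * (refl[ok, 2] - 1 + dims[2] * (refl[ok, 3] - 1))
    overlap <- sum(!is.na(match(rl, ci)))
    border <- any(co == 1) || any(sweep(co, 2, dims, "-") == 0)
    data.frame(label = sprintf("m%02d", m), x = cen[1], y = cen[2],
               z = cen[3], voxels = length(ci), bounding_size = max(ext),
               asymmetry = 1 - overlap / length(ci), on_border = border)
  })
  structure(list(markers = do.call(rbind, rows), modality = v$modality),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set (", x$modality, "): ", nrow(x$markers), " markers\n",
      sep = "")
  if (nrow(x$markers)) print(x$markers, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @rdname detect_markers
#' @param ms a `marker_set`.
#' @export
marker_points <- function(ms) {
  point_set(as.matrix(ms$markers[, c("x", "y", "z")]), ms$markers$label)
}

#' Write / read marker sets as TSV
#' @param ms a `marker_set`.
#' @param path file path.
#' @return `read_markers` returns a `marker_set`.
#' @export
write_markers <- function(ms, path) {
  utils::write.table(cbind(ms$markers, modality = ms$modality), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  modality <- if ("modality" %in% names(d)) d$modality[1] else "CT"
  structure(list(markers = d[setdiff(names(d), "modality")],
                 modality = modality), class = "marker_set")
}

# squared distance matrix
.dmat <- function(p) as.matrix(stats::dist(p))

#' Establish cross-modal marker correspondence
#'
#' Rigid motions preserve pairwise distances, so two views of the same
#' marker constellation must have matching inter-marker distance
#' matrices. The matcher seeds on consistent non-collinear triplets,
#' extends each seed greedily under the distance-consistency tolerance,
#' and returns the largest pairing with the smallest RMS distance-matrix
#' residual. Spurious detections are left unmatched. Exhaustive over
#' triplets, intended for the n <= 8 markers of a head holder.
#'
#' @param a,b `marker_set` or `point_set` objects with >= 3 points each.
#' @param tol distance-consistency tolerance (mm).
#' @return A `correspondence`: list with `pairs` (data.frame label_a,
#'   label_b) and `rms_residual` (mm).
#' @export
match_markers <- function(a, b, tol = 0.5) {
  pa <- if (is_point_set(a)) a else marker_points(a)
  pb <- if (is_point_set(b)) b else marker_points(b)
  na <- nrow(pa$coords); nb <- nrow(pb$coords)
  if (na < 3L || nb < 3L)
    stop("match_markers needs at least 3 markers in each set")
  if (na > 12L || nb > 12L)
    stop("match_markers is exhaustive and limited to 12 markers per set")
  da <- .dmat(pa$coords); db <- .dmat(pb$coords)
  noncollinear <- function(p, i, j, k) {
    v1 <- p[j, ] - p[i, ]; v2 <- p[k, ] - p[i, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    area2 <- sqrt(sum(cr^2))
    base <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)), 1e-9)
    (area2 / base) > 4 * tol   # triangle height must exceed the tolerance
  }
  best <- list()
  tri_a <- utils::combn(na, 3)
  seeded <- FALSE
  for (ta in seq_len(ncol(tri_a))) {
    ia <- tri_a[, ta]
    if (!noncollinear(pa$coords, ia[1], ia[2], ia[3])) next
    seeded <- TRUE
    for (ib1 in seq_len(nb)) for (ib2 in seq_len(nb)) for (ib3 in seq_len(nb)) {
      ib <- c(ib1, ib2, ib3)
      if (anyDuplicated(ib)) next
      if (abs(da[ia[1], ia[2]] - db[ib[1], ib[2]]) > tol) next
      if (abs(da[ia[1], ia[3]] - db[ib[1], ib[3]]) > tol) next
      if (abs(da[ia[2], ia[3]] - db[ib[2], ib[3]]) > tol) next
      map <- integer(na); map[ia] <- ib
      # greedy extension by distance consistency to all mapped markers
      repeat {
        free_a <- which(map == 0L)
        if (!length(free_a)) break
        added <- FALSE
        for (fa in free_a) {
          ma <- which(map != 0L)
          cand <- setdiff(seq_len(nb), map[ma])
          if (!length(cand)) next
          dev <- vapply(cand, function(cb)
            max(abs(da[fa, ma] - db[cb, map[ma]])), numeric(1))
          if (min(dev) <= tol) {
            map[fa] <- cand[which.min(dev)]
            added <- TRUE
          }
        }
        if (!added) break
      }
      ma <- which(map != 0L)
      res <- sqrt(mean((da[ma, ma] - db[map[ma], map[ma]])^2))
      key <- paste(ma, map[ma], sep = ":", collapse = ",")
      best[[key]] <- list(size = length(ma), rms = res, a = ma, b = map[ma])
    }
  }
  if (!seeded)
    stop("match_markers: all marker triplets are (near-)collinear ",
         "(degenerate geometry)")
  if (!length(best))
    stop("match_markers: no distance-consistent pairing of size >= 3 found")
  sizes <- vapply(best, `[[`, numeric(1), "size")
  rmss <- vapply(best, `[[`, numeric(1), "rms")
  top <- which(sizes == max(sizes))
  top <- top[order(rmss[top])]
  winner <- best[[top[1]]]
  # ambiguity: a different pairing of the same size with an equal residual
  if (length(top) > 1L) {
    ties <- top[abs(rmss[top] - rmss[top[1]]) < 1e-6]
    distinct <- unique(names(best)[ties])
    if (length(distinct) > 1L)
      stop("match_markers: ambiguous symmetric configuration; tied pairings: ",
           paste(distinct, collapse = " | "))
  }
  structure(list(
    pairs = data.frame(label_a = pa$labels[winner$a],
                       label_b = pb$labels[winner$b],
                       stringsAsFactors = FALSE),
    rms_residual = winner$rms), class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat("correspondence:", nrow(x$pairs), "pairs, rms distance residual",
      format(x$rms_residual, digits = 4), "mm\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
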