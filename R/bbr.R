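# Boundary-based (BBR-style) fine tuning of a rigid CT-to-MR pose.
#
# This is a self-contained boundary-contrast cost in the spirit of FSL's
# BBR, not a bit-exact clone: the bone boundary is taken from a direct HU
# threshold, and the cost is the mean of a tanh-squashed percent contrast
# sampled across the boundary, with the conventional slope of -0.5.

#' BBR configuration
#'
#' @param ct_threshold HU threshold retaining soft tissue and bone
#'   (excludes air) before bone extraction; default -250. With
#'   `tissue_adjacent_only` it also defines which boundary voxels carry
#'   usable contrast.
#' @param tissue_adjacent_only keep only bone-boundary voxels adjacent
#'   to soft tissue (default). Air-adjacent boundary (the outer skull
#'   surface of a bare phantom) carries the opposite contrast sign and
#'   would let the cost reward drifting the boundary into uniform air;
#'   excluding air mirrors thresholding the CT before segmentation.
#' @param bone_threshold HU threshold isolating bone; default 1000.
#' @param slope contrast slope of the cost (dimensionless, non-zero);
#'   the default -0.5 rewards boundaries whose outward side is brighter.
#' @param normal_offset sampling offset along the boundary normal (mm);
#'   default 0.5 mm, about one MR voxel.
#' @param max_iterations optimizer iteration budget.
#' @param convergence_tol relative cost tolerance for convergence.
#' @param max_boundary_points boundary points are deterministically
#'   subsampled to at most this many (evenly over the surface) to keep
#'   cost evaluation cheap.
#' @param epsilon contrast denominator guard.
#' @param basin_mm,basin_deg documented basin of attraction; a refined
#'   pose further than this from its initialisation is flagged.
#' @return A list of class `bbr_config`.
#' @export
bbr_config <- function(ct_threshold = -250, bone_threshold = 1000,
                       tissue_adjacent_only = TRUE,
                       slope = -0.5, normal_offset = 0.5,
                       max_iterations = 600, convergence_tol = 1e-6,
                       max_boundary_points = 8000, epsilon = 1e-6,
                       basin_mm = 2, basin_deg = 5) {
  if (slope == 0) stop("bbr_config: slope must be non-zero")
  if (normal_offset <= 0) stop("bbr_config: normal_offset must be positive")
  structure(list(ct_threshold = ct_threshold,
                 bone_threshold = bone_threshold,
                 tissue_adjacent_only = tissue_adjacent_only, slope = slope,
                 normal_offset = normal_offset,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 max_boundary_points = max_boundary_points,
                 epsilon = epsilon, basin_mm = basin_mm,
                 basin_deg = basin_deg), class = "bbr_config")
}

#' Extract the bone boundary with outward normals
#'
#' Thresholds the CT at `bone_threshold`, keeps mask voxels with at
#' least one non-mask 6-neighbour, and estimates outward unit normals
#' from the central-difference gradient of the binary mask (pointing
#' away from bone). By default only boundary voxels adjacent to soft
#' tissue (CT above `ct_threshold`) are returned, so the point set is
#' the bone/soft-tissue interface the refinement cost needs; set
#' `tissue_adjacent_only = FALSE` in the config to keep air-facing
#' surfaces too.
#'
#' @param ct CT [volume()] in HU.
#' @param cfg a [bbr_config()].
#' @return A `point_set` of boundary world coordinates with an
#'   `normals` attribute (n x 3 unit vectors, world frame).
#' @export
extract_bone_boundary <- function(ct, cfg = bbr_config()) {
  stopifnot(is_volume(ct))
  mask <- ct$data >= cfg$bone_threshold
  if (!any(mask)) stop("extract_bone_boundary: empty bone mask")
  dims <- dim(mask)
  m <- array(0, dims); m[mask] <- 1
  pad_shift <- function(a, d) {
    # shift array by d (length-3), zero-padded: out[i] = a[i - d]
    out <- array(0, dims)
    src <- lapply(1:3, function(ax) seq_len(dims[ax]) - d[ax])
    ok <- lapply(1:3, function(ax) src[[ax]] >= 1 & src[[ax]] <= dims[ax])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  nb_sum <- pad_shift(m, c(1, 0, 0)) + pad_shift(m, c(-1, 0, 0)) +
    pad_shift(m, c(0, 1, 0)) + pad_shift(m, c(0, -1, 0)) +
    pad_shift(m, c(0, 0, 1)) + pad_shift(m, c(0, 0, -1))
  boundary <- mask & nb_sum < 6
  idx <- which(boundary)
  co <- arrayInd(idx, dims)
  # central-difference gradient of the mask points into the bone;
  # the outward normal is its negation, mapped to world as a covector
  g <- cbind(
    (pad_shift(m, c(-1, 0, 0)) - pad_shift(m, c(1, 0, 0)))[idx],
    (pad_shift(m, c(0, -1, 0)) - pad_shift(m, c(0, 1, 0)))[idx],
    (pad_shift(m, c(0, 0, -1)) - pad_shift(m, c(0, 0, 1)))[idx]) / 2
  A <- ct$affine[1:3, 1:3]
  gw <- g %*% solve(A)         # (A^-T g)^T rowwise
  nrm <- sqrt(rowSums(gw^2))
  keep <- nrm > 1e-9
  if (!any(keep)) stop("extract_bone_boundary: degenerate mask gradient")
  pts <- voxel_to_world(ct, co[keep, , drop = FALSE])
  normals <- -gw[keep, , drop = FALSE] / nrm[keep]
  if (cfg$tissue_adjacent_only) {
    # probe the CT beyond the partial-volume rim: keep boundary points
    # whose outward side is soft tissue (not air, not more bone)
    probe_mm <- 2.5 * max(voxel_size(ct))
    probe <- sample_world(ct, pts + probe_mm * normals, background = -1000)
    tis <- probe >= cfg$ct_threshold & probe < cfg$bone_threshold
    if (!any(tis))
      stop("extract_bone_boundary: no bone/soft-tissue interface found")
    pts <- pts[tis, , drop = FALSE]
    normals <- normals[tis, , drop = FALSE]
  }
  ps <- point_set(pts, sprintf("b%06d", seq_len(nrow(pts))))
  attr(ps, "normals") <- normals
  ps
}

.subsample_boundary <- function(boundary, nmax) {
  n <- nrow(boundary$coords)
  if (n <= nmax) return(boundary)
  keep <- round(seq(1, n, length.out = nmax))
  ps <- point_set(boundary$coords[keep, , drop = FALSE],
                  boundary$labels[keep])
  attr(ps, "normals") <- attr(boundary, "normals")[keep, , drop = FALSE]
  ps
}

#' Boundary-contrast registration cost
#'
#' Maps each boundary point (and its outward normal) through `t`, samples
#' the MR volume at `+/- normal_offset` along the normal, and converts
#' the percent contrast `Q = 100 (g_out - g_in) / (0.5 (g_out + g_in) + eps)`
#' into a cost `mean (1 + tanh(slope * Q / 2)) / 2` in `[0, 1]`. With the
#' default negative slope, a boundary whose outside (away from bone) is
#' brighter than its inside drives the cost toward 0; a uniform image
#' gives exactly 0.5.
#'
#' @param boundary `point_set` with `normals` attribute (from
#'   [extract_bone_boundary()]), in CT world coordinates.
#' @param mr MR [volume()].
#' @param t `rigid_transform` mapping CT world to MR world.
#' @param cfg a [bbr_config()].
#' @return Cost in `[0, 1]`.
#' @export
bbr_cost <- function(boundary, mr, t, cfg = bbr_config()) {
  stopifnot(is_point_set(boundary), is_volume(mr), is_rigid_transform(t))
  normals <- attr(boundary, "normals")
  if (is.null(normals)) stop("boundary has no normals attribute")
  p <- rt_apply(t, boundary$coords)
  n <- normals %*% t(t$rotation)
  g_out <- sample_world(mr, p + cfg$normal_offset * n)
  g_in <- sample_world(mr, p - cfg$normal_offset * n)
  ok <- !is.na(g_out) & !is.na(g_in)
  if (mean(ok) < 0.5)
    stop("bbr_cost: more than half of the boundary samples fall outside ",
         "the MR field of view")
  q <- 100 * (g_out[ok] - g_in[ok]) /
    (0.5 * (g_out[ok] + g_in[ok]) + cfg$epsilon)
  mean((1 + tanh(cfg$slope * q / 2)) / 2)
}

.pose_delta <- function(par) {
  euler_compose(par[4], par[5], par[6], par[1:3])
}

.delta_magnitude <- function(delta) {
  e <- euler_decompose(delta)
  list(trans = sqrt(sum(delta$translation^2)),
       rot = max(abs(c(e$pitch, e$roll, e$yaw))))
}

#' BBR-style refinement of an initial rigid pose
#'
#' Derivative-free (Nelder-Mead) minimisation of [bbr_cost()] over a
#' 6-parameter perturbation (3 translations in mm, 3 rotations in
#' degrees, scaled 1 mm : 1 degree) composed with the initial transform.
#' The initialisation is assumed to lie within the cost's basin of
#' attraction (about 2 mm / 5 degrees, as delivered by MBFR); a result
#' whose perturbation leaves twice that basin is flagged as escaped and
#' reported unconverged.
#'
#' @param init initial `rigid_transform` (CT world to MR world),
#'   typically from [run_mbfr()].
#' @param ct CT [volume()] in HU.
#' @param mr MR [volume()].
#' @param cfg a [bbr_config()].
#' @return A `bbr_result`: `transform`, `min_cost`, `initial_cost`,
#'   `converged`, `escaped_basin`, `iterations`.
#' @export
refine_bbr <- function(init, ct, mr, cfg = bbr_config()) {
  stopifnot(is_rigid_transform(init), is_volume(ct), is_volume(mr))
  boundary <- .subsample_boundary(extract_bone_boundary(ct, cfg),
                                  cfg$max_boundary_points)
  fn <- function(par) {
    t <- rt_compose(.pose_delta(par), init)
    tryCatch(bbr_cost(boundary, mr, t, cfg), error = function(e) 1)
  }
  # the tanh contrast saturates on high-contrast data, driving the cost
  # through many orders of magnitude near the optimum; optimising its
  # logarithm (same minimiser) keeps the relative-tolerance stop rule
  # meaningful there
  obj <- function(par) log(fn(par) + 1e-25)
  c0 <- fn(rep(0, 6))
  opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                      control = list(maxit = cfg$max_iterations,
                                     reltol = cfg$convergence_tol))
  v_opt <- exp(opt$value) - 1e-25
  best <- if (v_opt <= c0) opt$par else rep(0, 6)
  min_cost <- min(v_opt, c0)
  delta <- .pose_delta(best)
  mag <- .delta_magnitude(delta)
  escaped <- mag$trans > 2 * cfg$basin_mm || mag$rot > 2 * cfg$basin_deg
  structure(list(transform = rt_compose(delta, init),
                 min_cost = min_cost, initial_cost = c0,
                 converged = (opt$convergence == 0) && !escaped,
                 escaped_basin = escaped,
                 iterations = opt$counts[["function"]]),
            class = "bbr_result")
}

#' @export
print.bbr_result <- function(x, ...) {
  cat(sprintf(
    "bbr_result: cost %.4f (from %.4f), %s%s, %d evaluations\n",
    x$min_cost, x$initial_cost,
    if (x$converged) "converged" else "not converged",
    if (x$escaped_basin) " [escaped basin]" else "", x$iterations))
  print(x$transform)
  invisible(x)
}
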