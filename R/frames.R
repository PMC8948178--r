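# AC-PC and image-based stereotactic coordinate frames.

#' Cranial and intracerebral landmark sets
#'
#' A `landmark_set` is a named collection of world-mm points. The AC-PC
#' frame needs `AC` and `PC`; the stereotactic frame needs both
#' ear-canal centres and both infra-orbital points. Cranial points
#' (bregma, inion, rhinion, zygions) are optional extras used for
#' variability summaries.
#'
#' @param ... named length-3 numeric points, or a single named list /
#'   3-column matrix with rownames.
#' @return A `landmark_set` (named list of length-3 numeric vectors).
#' @examples
#' lm <- landmark_set(AC = c(0, 0, 0), PC = c(0, -6, 0),
#'                    ear_canal_L = c(-12.5, -4, -10),
#'                    ear_canal_R = c(12.5, -4, -10),
#'                    infraorbital_L = c(-5.5, 6, -10),
#'                    infraorbital_R = c(5.5, 6, -10))
#' @export
landmark_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.matrix(args[[1]])) {
    m <- args[[1]]
    args <- stats::setNames(lapply(seq_len(nrow(m)), function(i)
      as.numeric(m[i, ])), rownames(m))
  } else if (length(args) == 1L && is.list(args[[1]]) &&
             !is.numeric(args[[1]])) {
    args <- args[[1]]
  }
  if (is.null(names(args)) || any(names(args) == ""))
    stop("all landmarks must be named")
  args <- lapply(args, as.numeric)
  if (any(vapply(args, length, integer(1)) != 3L))
    stop("each landmark must be a length-3 point")
  if (any(!is.finite(unlist(args)))) stop("landmarks must be finite")
  structure(args, class = "landmark_set")
}

#' @rdname landmark_set
#' @param x object to test.
#' @export
is_landmark_set <- function(x) inherits(x, "landmark_set")

#' @rdname landmark_set
#' @param lm a `landmark_set`.
#' @export
landmark_points <- function(lm) {
  point_set(do.call(rbind, lm), names(lm))
}

#' Read/write landmark CSV (name,x,y,z with header, world mm)
#' @param lm a `landmark_set`.
#' @param path file path.
#' @export
write_landmarks <- function(lm, path) {
  m <- do.call(rbind, lm)
  utils::write.csv(data.frame(name = names(lm), x = m[, 1], y = m[, 2],
                              z = m[, 3]), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(d)))
    stop("landmark CSV needs a header with columns name,x,y,z")
  landmark_set(stats::setNames(lapply(seq_len(nrow(d)), function(i)
    c(d$x[i], d$y[i], d$z[i])), d$name))
}

.frame_definition <- function(name, to_frame, origin_definition,
                              landmarks = NULL) {
  structure(list(name = name, to_frame = to_frame,
                 origin_definition = origin_definition,
                 landmarks = landmarks), class = "frame_definition")
}

#' @export
print.frame_definition <- function(x, ...) {
  cat("frame_definition [", x$name, "]: ", x$origin_definition, "\n",
      sep = "")
  print(x$to_frame)
  invisible(x)
}

# smallest-eigenvector direction of the scatter of rows of `q` inside the
# plane orthogonal to unit vector `u`; errors when the constraint is
# degenerate (all rows parallel to u)
.min_scatter_normal <- function(q, u, what) {
  P <- diag(3) - tcrossprod(u)           # projector onto u-perp
  qp <- q %*% P
  if (max(sqrt(rowSums(qp^2))) < 1e-9)
    stop(what, ": defining points are collinear with the frame axis ",
         "(degenerate geometry)")
  S <- crossprod(qp) + tcrossprod(u) * (sum(qp^2) + 1)  # push u up-spectrum
  e <- eigen(S, symmetric = TRUE)
  n <- e$vectors[, 3]
  n <- n - sum(n * u) * u                # numerical cleanup: keep n in u-perp
  n / sqrt(sum(n^2))
}

#' Fit the AC-PC native coordinate frame
#'
#' Origin at the AC centre; +Y along the PC-to-AC direction (AC
#' anterior); the midsagittal plane is X = 0, fitted so the supplied
#' midline points have (least squares) zero X; +Z superior completes the
#' right-handed frame. In the returned frame AC maps to the origin and
#' PC to `(0, -|AC - PC|, 0)`.
#'
#' @param lm a [landmark_set()] with `AC` and `PC`.
#' @param midsagittal_points `point_set` (or n x 3 matrix) of midline
#'   points, at least one off the AC-PC line; points with positive Z in
#'   the result are taken as superior (used to orient +Z).
#' @return A `frame_definition` whose `to_frame` maps scanner world to
#'   AC-PC coordinates.
#' @export
fit_acpc_frame <- function(lm, midsagittal_points) {
  stopifnot(is_landmark_set(lm))
  if (is.null(lm$AC) || is.null(lm$PC))
    stop("fit_acpc_frame needs AC and PC landmarks")
  ms <- if (is_point_set(midsagittal_points)) midsagittal_points$coords
        else as.matrix(midsagittal_points)
  if (is.null(dim(ms))) ms <- matrix(ms, ncol = 3)
  ac <- lm$AC; pc <- lm$PC
  ab <- ac - pc
  len <- sqrt(sum(ab^2))
  if (len < 1e-9) stop("fit_acpc_frame: AC and PC coincide (degenerate)")
  y <- ab / len
  q <- sweep(rbind(ms, pc), 2, ac)       # plane through AC containing y
  x <- .min_scatter_normal(q, y, "fit_acpc_frame")
  z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  # orient +Z so the midline points sit superior on average
  zm <- mean(sweep(ms, 2, ac) %*% z)
  if (zm < 0) { z <- -z; x <- -x }
  R <- rbind(x, y, z)
  to_frame <- rigid_transform(R, -as.vector(R %*% ac))
  .frame_definition("ACPC", to_frame,
                    "origin at AC; +Y along PC->AC; midsagittal plane X=0",
                    lm)
}

#' Fit the image-based stereotactic coordinate frame
#'
#' The interaural line (ear-canal centres) defines the X axis, the
#' horizontal zero plane (Z = 0) is the least-squares plane constrained
#' to contain the interaural line and passing through the two
#' infra-orbital points, the origin is the interaural midpoint, and +Y
#' points anteriorly toward the infra-orbital side.
#'
#' @param lm a [landmark_set()] with `ear_canal_L`, `ear_canal_R`,
#'   `infraorbital_L`, `infraorbital_R`.
#' @return A `frame_definition` whose `to_frame` maps scanner world to
#'   stereotactic coordinates.
#' @export
fit_stereotactic_frame <- function(lm) {
  stopifnot(is_landmark_set(lm))
  need <- c("ear_canal_L", "ear_canal_R", "infraorbital_L", "infraorbital_R")
  if (!all(need %in% names(lm)))
    stop("fit_stereotactic_frame needs landmarks: ",
         paste(need, collapse = ", "))
  el <- lm$ear_canal_L; er <- lm$ear_canal_R
  il <- lm$infraorbital_L; ir <- lm$infraorbital_R
  xv <- er - el
  xl <- sqrt(sum(xv^2))
  if (xl < 1e-9) stop("fit_stereotactic_frame: ear canals coincide")
  x <- xv / xl
  origin <- (el + er) / 2
  q <- rbind(il - origin, ir - origin)
  z <- .min_scatter_normal(q, x, "fit_stereotactic_frame")
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  # +Y anterior: toward the infra-orbital points
  if (sum((colMeans(rbind(il, ir)) - origin) * y) < 0) { y <- -y; z <- -z }
  R <- rbind(x, y, z)
  to_frame <- rigid_transform(R, -as.vector(R %*% origin))
  .frame_definition(
    "STEREOTACTIC", to_frame,
    "origin at interaural midpoint; Z=0 through interaural line and infra-orbital ridge",
    lm)
}

#' Rotation and translation bias between two frames
#'
#' `frame_bias(a, b)` returns the transform `a$to_frame o b$to_frame^-1`
#' (mapping b-frame coordinates into a-frame coordinates) decomposed
#' into Euler angles and translation. With `a` the AC-PC frame and `b`
#' the stereotactic frame of the same head, a positive pitch means the
#' stereotactic horizontal plane tips the frontal direction downward
#' relative to AC-PC.
#'
#' @param a,b `frame_definition`s defined in the same scanner world.
#' @return A `frame_bias`: `rotation` ([euler_angles()]), `translation`
#'   (mm), `transform`, `from_frame`, `to_frame`.
#' @export
frame_bias <- function(a, b) {
  stopifnot(inherits(a, "frame_definition"), inherits(b, "frame_definition"))
  t <- rt_compose(a$to_frame, rt_inverse(b$to_frame))
  structure(list(rotation = euler_decompose(t),
                 translation = t$translation, transform = t,
                 from_frame = b$name, to_frame = a$name),
            class = "frame_bias")
}

#' @export
print.frame_bias <- function(x, ...) {
  cat("frame_bias:", x$from_frame, "->", x$to_frame, "\n")
  print(x$rotation)
  cat(sprintf("  translation: %.4f %.4f %.4f mm\n", x$translation[1],
              x$translation[2], x$translation[3]))
  invisible(x)
}

#' Frame bias fitted from paired landmark coordinates
#'
#' When the same labelled landmarks are known in two coordinate frames,
#' the rigid transform taking frame-b coordinates into frame-a
#' coordinates is fitted with [kabsch_fit()] and decomposed. This is the
#' operation behind the worked example shipped with the package: fitting
#' the published marmoset cranial landmark means in stereotactic
#' coordinates to the same landmarks in AC-PC coordinates recovers the
#' ~10 degree frontal-downward pitch of the stereotactic plane.
#'
#' @param pairs_in_frame_a,pairs_in_frame_b `point_set`s of the same
#'   (>= 3) labelled landmarks expressed in frames a and b.
#' @return A `frame_bias` (b -> a), including the fitted `transform`.
#' @export
landmark_fit_bias <- function(pairs_in_frame_a, pairs_in_frame_b) {
  t <- kabsch_fit(pairs_in_frame_b, pairs_in_frame_a)
  structure(list(rotation = euler_decompose(t),
                 translation = t$translation, transform = t,
                 from_frame = "b", to_frame = "a"),
            class = "frame_bias")
}

#' Published marmoset cranial landmark mean positions
#'
#' Cohort mean coordinates (mm) of five cranial landmarks (bregma,
#' inion, rhinion, left/right zygion) of the common marmoset in AC-PC
#' native and image-based stereotactic coordinates, shipped as the
#' package's worked example for [landmark_fit_bias()].
#'
#' @return List with `acpc` and `stereotactic` `point_set`s.
#' @export
cranial_landmark_means <- function() {
  path <- system.file("extdata", "cranial_landmark_means.csv",
                      package = "marmoreg", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  mk <- function(frame) {
    dd <- d[d$frame == frame, ]
    point_set(as.matrix(dd[, c("x", "y", "z")]), dd$name)
  }
  list(acpc = mk("acpc"), stereotactic = mk("stereotactic"))
}
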