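#' Rigid-body transforms
#'
#' A `rigid_transform` is a 6-degree-of-freedom world-to-world mapping
#' `x -> R x + t` with `R` a proper rotation (orthonormal, det = +1) and
#' `t` a translation in millimetres. It is the common currency of every
#' registration and coordinate-frame operation in the package.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation (mm).
#' @param tol orthonormality tolerance.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t <- rigid_transform(diag(3), c(1, 2, 3))
#' rt_apply(t, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (anyNA(rotation) || anyNA(translation) ||
      any(!is.finite(rotation)) || any(!is.finite(translation)))
    stop("rigid_transform entries must be finite")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > sqrt(tol))
    stop("rotation is not orthonormal (max |R'R - I| = ",
         format(err), ")")
  if (det(rotation) < 0)
    stop("rotation has negative determinant (reflection, not rotation)")
  # re-orthonormalize via polar decomposition so numerical drift never
  # accumulates through long composition chains
  s <- svd(rotation)
  rotation <- s$u %*% t(s$v)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @rdname rigid_transform
#' @param x object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  e <- euler_decompose(x)
  cat("rigid_transform (world mm)\n")
  cat(sprintf("  pitch/roll/yaw: %.4f / %.4f / %.4f deg\n",
              e$pitch, e$roll, e$yaw))
  cat(sprintf("  translation:    %.4f %.4f %.4f mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose, invert and apply rigid transforms
#'
#' `rt_compose(a, b)` returns the transform that applies `b` first and then
#' `a` (matrix convention `a %*% b`). `rt_inverse` returns the inverse
#' mapping, and `rt_apply` maps an `n x 3` coordinate matrix (or a single
#' point) through the transform.
#'
#' @param a,b,t `rigid_transform` objects.
#' @param pts numeric length-3 vector, `n x 3` matrix, or `point_set`.
#' @return `rt_compose`/`rt_inverse`: a `rigid_transform`; `rt_apply`: the
#'   transformed coordinates in the same shape as the input.
#' @export
rt_compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rt_compose
#' @export
rt_inverse <- function(t) {
  stopifnot(is_rigid_transform(t))
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' @rdname rt_compose
#' @export
rt_apply <- function(t, pts) {
  stopifnot(is_rigid_transform(t))
  if (is_point_set(pts)) {
    out <- pts
    out$coords <- rt_apply(t, pts$coords)
    return(out)
  }
  vec <- is.null(dim(pts))
  m <- if (vec) matrix(pts, ncol = 3) else as.matrix(pts)
  if (ncol(m) != 3L) stop("points must be n x 3")
  out <- m %*% t(t$rotation)
  out <- sweep(out, 2, t$translation, "+")
  if (vec) as.vector(out) else out
}

#' @rdname rt_compose
#' @export
rt_matrix <- function(t) {
  stopifnot(is_rigid_transform(t))
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' Labelled point sets
#'
#' Holds `n` labelled world coordinates (mm). Used for fiducial centroids,
#' cranial landmarks and bone-boundary samples.
#'
#' @param coords `n x 3` numeric matrix of world coordinates (mm).
#' @param labels character vector of unique identifiers (default
#'   `p1 ... pn`).
#' @return An object of class `point_set` with fields `labels`, `coords`.
#' @export
point_set <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  if (nrow(coords) < 1L) stop("point_set needs at least one point")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(coords)))
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) stop("one label per point required")
  if (anyDuplicated(labels)) stop("labels must be unique")
  rownames(coords) <- labels
  structure(list(labels = labels, coords = coords), class = "point_set")
}

#' @rdname point_set
#' @param x object to test.
#' @export
is_point_set <- function(x) inherits(x, "point_set")

#' @export
print.point_set <- function(x, ...) {
  cat("point_set with", nrow(x$coords), "points\n")
  print(round(x$coords, 4))
  invisible(x)
}

#' Euler angles (fixed-axis X, then Y, then Z)
#'
#' The package-wide rotation convention is extrinsic (fixed) axes applied
#' X then Y then Z in a right-handed RAS world (+X right, +Y anterior,
#' +Z superior), i.e. `R = Rz(yaw) Ry(roll) Rx(pitch)`. All angles are
#' right-handed and in degrees. Under this convention a *positive* pitch
#' of the stereotactic frame relative to the AC-PC frame (as returned by
#' [frame_bias()] with the AC-PC frame first) tips the frontal (+Y)
#' direction downward.
#'
#' @param pitch,roll,yaw rotation about the X, Y and Z axis (degrees).
#' @param gimbal_warning logical flag set by [euler_decompose()] when the
#'   middle (Y) angle is within 1 degree of +/-90 and the X/Z split is
#'   ill-conditioned.
#' @return An object of class `euler_angles`.
#' @export
euler_angles <- function(pitch, roll, yaw, gimbal_warning = FALSE) {
  structure(list(pitch = as.numeric(pitch), roll = as.numeric(roll),
                 yaw = as.numeric(yaw),
                 gimbal_warning = isTRUE(gimbal_warning)),
            class = "euler_angles")
}

#' @export
print.euler_angles <- function(x, ...) {
  cat(sprintf("euler_angles: pitch %.4f, roll %.4f, yaw %.4f deg%s\n",
              x$pitch, x$roll, x$yaw,
              if (x$gimbal_warning) "  [near gimbal lock]" else ""))
  invisible(x)
}

.rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
.rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Compose a rigid transform from Euler angles
#'
#' @param e an `euler_angles` object, or the pitch angle in degrees when
#'   `roll`/`yaw` are given separately.
#' @param roll,yaw angles in degrees (ignored when `e` is `euler_angles`).
#' @param translation translation (mm).
#' @return A `rigid_transform` with rotation
#'   `Rz(yaw) %*% Ry(roll) %*% Rx(pitch)`.
#' @seealso [euler_decompose()]
#' @export
euler_compose <- function(e, roll = 0, yaw = 0, translation = c(0, 0, 0)) {
  if (inherits(e, "euler_angles")) {
    pitch <- e$pitch; roll <- e$roll; yaw <- e$yaw
  } else pitch <- e
  d <- pi / 180
  rigid_transform(.rot_z(yaw * d) %*% .rot_y(roll * d) %*% .rot_x(pitch * d),
                  translation)
}

#' Decompose a rotation into fixed-axis Euler angles
#'
#' Inverts the convention of [euler_compose()]. Near gimbal lock
#' (|roll| close to 90 degrees the X and Z rotations become degenerate);
#' the result then carries `gimbal_warning = TRUE` and yaw is set to 0.
#'
#' @param t a `rigid_transform` (or bare 3x3 rotation matrix).
#' @return An `euler_angles` object (degrees).
#' @export
euler_decompose <- function(t) {
  R <- if (is_rigid_transform(t)) t$rotation else as.matrix(t)
  d <- 180 / pi
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  roll <- asin(sy)
  gimbal <- abs(abs(roll) - pi / 2) < (1 * pi / 180)
  if (!gimbal) {
    pitch <- atan2(R[3, 2], R[3, 3])
    yaw <- atan2(R[2, 1], R[1, 1])
  } else {
    # X and Z axes align: attribute the whole remaining rotation to X
    pitch <- atan2(-R[2, 3], R[2, 2])
    yaw <- 0
    warning("euler_decompose: |roll| within 1 degree of 90, ",
            "pitch/yaw split is ill-conditioned")
  }
  euler_angles(pitch * d, roll * d, yaw * d, gimbal_warning = gimbal)
}

#' Least-squares rigid point-set alignment (Kabsch)
#'
#' Fits the rigid transform `T` minimising `sum ||T(s_i) - t_i||^2` over
#' label-matched points, via SVD of the cross-covariance with the usual
#' determinant correction. No scaling or shear is fitted.
#'
#' @param source,target `point_set` objects sharing the same labels
#'   (order-insensitive), n >= 3, source not collinear.
#' @return A `rigid_transform` mapping source coordinates onto target
#'   coordinates.
#' @examples
#' p <- point_set(rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10)))
#' t <- euler_compose(10, 0, 0, c(1, 2, 3))
#' fit <- kabsch_fit(p, rt_apply(t, p))
#' euler_decompose(fit)
#' @export
kabsch_fit <- function(source, target) {
  stopifnot(is_point_set(source), is_point_set(target))
  if (!setequal(source$labels, target$labels) ||
      length(source$labels) != length(target$labels))
    stop("source and target must carry the same labels")
  A <- source$coords
  B <- target$coords[source$labels, , drop = FALSE]
  n <- nrow(A)
  if (n < 3L) stop("kabsch_fit needs at least 3 points (degenerate geometry)")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  # collinearity check: rank of the centred source must exceed 1
  sv <- svd(Ac)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("kabsch_fit: source points are collinear (degenerate geometry)")
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cb - as.vector(R %*% ca))
}

.rot_log <- function(R) {
  # rotation matrix -> rotation vector (axis * angle, radians)
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (theta > pi - 1e-6) {
    # near-pi: extract axis from the symmetric part
    S <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(S), 0))
    i <- which.max(ax)
    v <- S[, i] / ax[i]
    v <- v / sqrt(sum(v^2))
    if (sum(v * w) < 0) v <- -v
    return(v * theta)
  }
  w / (2 * sin(theta)) * theta
}

.rot_exp <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-12) return(diag(3))
  k <- w / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Average a set of rigid transforms
#'
#' Translation is averaged arithmetically; rotation is the Fréchet
#' (Karcher) mean in rotation-vector space, iterated until the mean of
#' `log(M^-1 R_i)` vanishes. The iteration converges in a couple of steps
#' for the small (< 30 degree) rotations this tool handles, and makes the
#' mean an exact fixed point: de-drifted sets re-average to the identity
#' to machine precision.
#'
#' @param ts non-empty list of `rigid_transform`s.
#' @param tol convergence tolerance on the mean rotation vector (radians).
#' @return The mean `rigid_transform`.
#' @seealso [dedrift()]
#' @export
mean_transform <- function(ts, tol = 1e-14) {
  if (!is.list(ts) || length(ts) == 0L)
    stop("mean_transform needs a non-empty list of transforms")
  stopifnot(all(vapply(ts, is_rigid_transform, logical(1))))
  tm <- colMeans(do.call(rbind, lapply(ts, `[[`, "translation")))
  Rm <- ts[[1]]$rotation
  for (iter in 1:100) {
    ws <- vapply(ts, function(t) .rot_log(crossprod(Rm, t$rotation)),
                 numeric(3))
    wbar <- rowMeans(matrix(ws, nrow = 3))
    Rm <- Rm %*% .rot_exp(wbar)
    if (sqrt(sum(wbar^2)) < tol) break
  }
  rigid_transform(Rm, tm)
}

#' Remove the mean transform (de-drifting)
#'
#' Composes each transform with the inverse of the set mean so the
#' population stays put on average: the mean of the returned list is the
#' identity. Used to stop iterated registrations drifting away from the
#' original mean spatial location.
#'
#' @param ts non-empty list of `rigid_transform`s.
#' @return List of `rigid_transform`s, `M^-1 o T_i`.
#' @export
dedrift <- function(ts) {
  m_inv <- rt_inverse(mean_transform(ts))
  lapply(ts, function(t) rt_compose(m_inv, t))
}

#' Orthogonal distance from a point to a line
#'
#' Perpendicular Euclidean distance between a point and the infinite line
#' through `line_point` with direction `line_dir` (used for the distance
#' between a planned target and an actual instrument trajectory).
#'
#' @param p point (mm).
#' @param line_point any point on the line (mm).
#' @param line_dir direction vector (need not be unit, must be non-zero).
#' @return Distance in mm.
#' @export
point_to_line_distance <- function(p, line_point, line_dir) {
  p <- as.numeric(p); a <- as.numeric(line_point); v <- as.numeric(line_dir)
  stopifnot(length(p) == 3L, length(a) == 3L, length(v) == 3L)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("line direction must be non-zero")
  v <- v / nv
  w <- p - a
  w_perp <- w - sum(w * v) * v
  sqrt(sum(w_perp^2))
}

#' Read and write rigid transforms
#'
#' The plain-text format is a 4x4 row-major world-mm matrix (FSL-style
#' layout, whitespace separated). The JSON format additionally carries the
#' Euler angles and the convention string.
#'
#' @param t a `rigid_transform`.
#' @param path file path; `.json` selects the JSON representation.
#' @return `read_transform` returns a `rigid_transform`;
#'   `write_transform` returns `path` invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(is_rigid_transform(t))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    e <- euler_decompose(t)
    jsonlite::write_json(
      list(rotation = t$rotation, translation = t$translation,
           euler_deg = list(pitch = e$pitch, roll = e$roll, yaw = e$yaw),
           convention = "extrinsic X-then-Y-then-Z, right-handed RAS, degrees"),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    m <- rt_matrix(t)
    writeLines(apply(m, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), path)
  }
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(rigid_transform(matrix(unlist(j$rotation), 3, 3),
                           as.numeric(unlist(j$translation))))
  }
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4L, 4L))) stop("transform file must hold a 4x4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}
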