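# Interpolated sampling and rigid resampling.

# Continuous-voxel sampling core. `vox` is n x 3 of 0-based continuous
# voxel coordinates. Returns NA outside the field of view (trilinear and
# nearest need the full support inside the grid; cubic clamps its outer
# ring so its support shrinks gracefully near borders).
.sample_voxels <- function(data, vox, interp) {
  dims <- dim(data)
  n <- nrow(vox)
  out <- rep(NA_real_, n)
  # snap almost-integer coordinates so grid-aligned sampling is exact
  snap <- abs(vox - round(vox)) < 1e-7
  vox[snap] <- round(vox[snap])
  if (interp == "nearest") {
    idx <- round(vox)
    ok <- idx[, 1] >= 0 & idx[, 1] <= dims[1] - 1 &
      idx[, 2] >= 0 & idx[, 2] <= dims[2] - 1 &
      idx[, 3] >= 0 & idx[, 3] <= dims[3] - 1
    lin <- idx[ok, 1] + dims[1] * (idx[ok, 2] + dims[2] * idx[ok, 3]) + 1
    out[ok] <- data[lin]
    return(out)
  }
  i0 <- floor(vox)
  f <- vox - i0
  if (interp == "trilinear") {
    ok <- i0[, 1] >= 0 & i0[, 1] + 1 <= dims[1] - 1 + (f[, 1] == 0) &
      i0[, 2] >= 0 & i0[, 2] + 1 <= dims[2] - 1 + (f[, 2] == 0) &
      i0[, 3] >= 0 & i0[, 3] + 1 <= dims[3] - 1 + (f[, 3] == 0)
    if (!any(ok)) return(out)
    i <- i0[ok, , drop = FALSE]
    g <- f[ok, , drop = FALSE]
    # clamp the +1 neighbour when sitting exactly on the last plane
    up <- function(ax) pmin(i[, ax] + 1, dims[ax] - 1)
    acc <- numeric(sum(ok))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) g[, 1] else 1 - g[, 1]) *
        (if (dy) g[, 2] else 1 - g[, 2]) *
        (if (dz) g[, 3] else 1 - g[, 3])
      ix <- if (dx) up(1) else i[, 1]
      iy <- if (dy) up(2) else i[, 2]
      iz <- if (dz) up(3) else i[, 3]
      lin <- ix + dims[1] * (iy + dims[2] * iz) + 1
      acc <- acc + w * data[lin]
    }
    out[ok] <- acc
    return(out)
  }
  if (interp != "spline") stop("unknown interpolation: ", interp)
  # tricubic convolution (Keys kernel, a = -0.5), outer support clamped
  ok <- vox[, 1] >= 0 & vox[, 1] <= dims[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= dims[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= dims[3] - 1
  if (!any(ok)) return(out)
  i <- i0[ok, , drop = FALSE]
  g <- f[ok, , drop = FALSE]
  a <- -0.5
  keys <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  wts <- lapply(1:3, function(ax)
    lapply(-1:2, function(m) keys(g[, ax] - m)))
  clamp <- function(idx, ax) pmin(pmax(idx, 0), dims[ax] - 1)
  acc <- numeric(sum(ok))
  for (mz in -1:2) for (my in -1:2) for (mx in -1:2) {
    w <- wts[[1]][[mx + 2]] * wts[[2]][[my + 2]] * wts[[3]][[mz + 2]]
    lin <- clamp(i[, 1] + mx, 1) +
      dims[1] * (clamp(i[, 2] + my, 2) + dims[2] * clamp(i[, 3] + mz, 3)) + 1
    acc <- acc + w * data[lin]
  }
  out[ok] <- acc
  out
}

#' Sample a volume at world coordinates
#'
#' @param v a [volume()].
#' @param xyz `n x 3` world coordinates (mm).
#' @param interp `"trilinear"`, `"spline"` (tricubic convolution) or
#'   `"nearest"`.
#' @param background value returned outside the field of view; `NA` keeps
#'   missing values distinguishable (used by the BBR cost to track
#'   coverage).
#' @return Numeric vector of sampled intensities.
#' @export
sample_world <- function(v, xyz, interp = "trilinear", background = NA) {
  stopifnot(is_volume(v))
  vox <- world_to_voxel(v, xyz) - 1
  if (is.null(dim(vox))) vox <- matrix(vox, ncol = 3)
  out <- .sample_voxels(v$data, vox, interp)
  if (!is.na(background)) out[is.na(out)] <- background
  out
}

.background_value <- function(v) {
  switch(v$modality, CT = -1000, LABEL = 0, 0)
}

#' Rigidly resample a volume onto a reference grid
#'
#' `t` maps world coordinates of `v` to world coordinates of `reference`
#' (i.e. it is the forward transform fitted by registration). Each output
#' voxel centre is pulled back through `t^-1` and `v` is interpolated
#' there. Voxels that fall outside `v`'s field of view are filled with
#' the modality background (-1000 HU for CT, 0 otherwise). `LABEL`
#' volumes default to nearest-neighbour interpolation.
#'
#' @param v source [volume()].
#' @param t a `rigid_transform` mapping `v` world to `reference` world.
#' @param reference [volume()] defining the output grid.
#' @param interp `"trilinear"`, `"spline"` or `"nearest"`; default
#'   trilinear (nearest for LABEL).
#' @return A [volume()] on the reference grid, keeping `v`'s modality.
#' @export
resample_rigid <- function(v, t, reference, interp = NULL) {
  stopifnot(is_volume(v), is_volume(reference), is_rigid_transform(t))
  if (is.null(interp))
    interp <- if (v$modality == "LABEL") "nearest" else "trilinear"
  dims <- dim(reference$data)
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  world_ref <- cbind(ijk, 1) %*% t(reference$affine)
  world_src <- rt_apply(rt_inverse(t), world_ref[, 1:3, drop = FALSE])
  vox_src <- cbind(world_src, 1) %*% t(solve(v$affine))
  vals <- .sample_voxels(v$data, vox_src[, 1:3, drop = FALSE], interp)
  vals[is.na(vals)] <- .background_value(v)
  volume(array(vals, dims), reference$affine, modality = v$modality,
         units = v$units)
}
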