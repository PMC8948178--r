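# Digital head phantom: paired CT/MR volumes with exact ground truth.
#
# The phantom emulates the acquisition geometry the registration code
# targets: an ellipsoidal cranial shell of bone density around a
# soft-tissue brain compartment, >= 6 cylindrical fiducial markers on a
# holder surface outside the shell (inner cavity 2.0 mm diameter x
# 2.0 mm, density near cortical bone in CT and bright in T2w), cranial
# landmarks and AC/PC points, and an MR volume posed by a known rigid
# CT-to-MR transform. Shapes are rendered with a signed-distance
# partial-volume ramp so ground-truth centroids are sub-voxel accurate.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

# fixed bony ridge sites (unit directions) and geometry for the inner
# surface: spheres of bone centred 1.5 mm outside the inner surface,
# radius 4 mm, protruding ~2.5 mm into the brain compartment
.bump_dirs <- function() {
  d <- rbind(c(0.30, 0.80, -0.50), c(-0.70, 0.20, -0.60),
             c(0.60, -0.60, -0.40), c(-0.30, -0.90, 0.20),
             c(0.20, 0.40, 0.90), c(-0.80, -0.10, 0.55),
             c(0.85, 0.40, 0.30), c(-0.25, 0.60, 0.75))
  d / sqrt(rowSums(d^2))
}

.bump_geometry <- function(spec) {
  ax_in <- spec$head_semiaxes - spec$shell_thickness
  dirs <- .bump_dirs()
  centers <- t(apply(dirs, 1, function(d) {
    s <- 1 / sqrt(sum((d / ax_in)^2))
    p <- s * d
    p * (1 + 1.5 / sqrt(sum(p^2)))
  }))
  list(centers = centers, radius = 4.0)
}

.default_marker_dirs <- function() {
  d <- rbind(c(0.90, 0.20, 0.80), c(-0.80, 0.50, 0.70),
             c(0.60, -0.90, 0.50), c(-0.50, -0.80, 0.90),
             c(0.10, 0.95, 0.40), c(-0.15, -0.20, 1.00))
  d / sqrt(rowSums(d^2))
}

#' Phantom specification
#'
#' Defaults state the world the phantom emulates: a marmoset-sized head
#' (ellipsoid semi-axes 25 x 20 x 18 mm) with a 1 mm bone shell, six
#' non-degenerate cylindrical markers (2.0 mm diameter x 2.0 mm cavity)
#' on a holder surface just outside the shell, CT/MR voxels of
#' 0.24/0.48 mm (half the acquisition resolution of 0.12/0.36 mm, which
#' `acquisition_resolution = TRUE` restores at ~8x the memory/time), mild
#' additive Gaussian noise, and a known true CT-to-MR rigid transform.
#'
#' @param head_semiaxes outer ellipsoid semi-axes (mm).
#' @param shell_thickness bone shell thickness (mm).
#' @param ct_voxel,mr_voxel isotropic voxel sizes (mm).
#' @param acquisition_resolution use the full acquisition resolution
#'   (0.12 / 0.36 mm) instead of the desk-scale default.
#' @param marker_dirs n x 3 unit directions (head-centred) of the
#'   marker sites; >= 3 non-collinear, default 6 asymmetric sites.
#' @param marker_inner cavity `c(diameter, length)` in mm.
#' @param marker_gap clearance between shell and cavity centre line (mm).
#' @param inner_bumps render a set of fixed bony ridges protruding from
#'   the inner shell surface (cranial-base asphericity analog). A
#'   purely ellipsoidal inner surface leaves rotations about the head
#'   centre invisible to any boundary-contrast cost; the ridges give
#'   boundary refinement the same rotational anchoring a real cranium
#'   provides.
#' @param bubble_fraction per-marker air-bubble volume fraction in
#'   `[0, 1)` (recycled). A bubble is a spherical air pocket seated at
#'   the radially outer end of the cavity (a slab-shaped void would
#'   leave a shorter but still point-symmetric solid and defeat the
#'   asymmetry QC it is meant to exercise); its radius is chosen so the
#'   displaced volume matches the requested fraction (exact while the
#'   pocket is narrower than the cavity, i.e. fraction <= radius /
#'   (1.5 length) ~ 0.33 at the default dimensions). The ground-truth
#'   centroid shifts inward accordingly.
#' @param noise_sd additive Gaussian noise `c(ct = ..., mr = ...)`
#'   (HU; MR arbitrary units on a 0-1 scale).
#' @param true_ct_to_mr `rigid_transform` from CT world to MR world.
#' @param head_pose `rigid_transform` posing the canonical
#'   (stereotactic) head frame in CT scanner world.
#' @param acpc_pitch pitch (degrees, frontal-downward positive) of the
#'   stereotactic frame relative to the AC-PC frame built into the
#'   landmark truth.
#' @param acpc_length AC-PC distance (mm).
#' @param seed RNG seed making generation deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(head_semiaxes = c(25, 20, 18),
                         shell_thickness = 1.0,
                         ct_voxel = 0.24, mr_voxel = 0.48,
                         acquisition_resolution = FALSE,
                         marker_dirs = .default_marker_dirs(),
                         marker_inner = c(2.0, 2.0),
                         marker_gap = 1.5,
                         inner_bumps = TRUE,
                         bubble_fraction = 0,
                         noise_sd = c(ct = 15, mr = 0.02),
                         true_ct_to_mr = euler_compose(10, 0, 0, c(2, -3, 1)),
                         head_pose = rt_identity(),
                         acpc_pitch = 10, acpc_length = 6.5,
                         seed = 1L) {
  if (acquisition_resolution) { ct_voxel <- 0.12; mr_voxel <- 0.36 }
  marker_dirs <- as.matrix(marker_dirs)
  if (nrow(marker_dirs) < 3L) stop("need at least 3 marker sites")
  if (any(c(ct_voxel, mr_voxel) <= 0)) stop("voxel sizes must be positive")
  sv <- svd(scale(marker_dirs, scale = FALSE))$d
  if (sv[2] < 1e-6) stop("marker sites are collinear")
  bubble_fraction <- rep_len(bubble_fraction, nrow(marker_dirs))
  if (any(bubble_fraction < 0 | bubble_fraction >= 1))
    stop("bubble_fraction must be in [0, 1)")
  structure(list(head_semiaxes = head_semiaxes,
                 shell_thickness = shell_thickness,
                 ct_voxel = ct_voxel, mr_voxel = mr_voxel,
                 marker_dirs = marker_dirs, marker_inner = marker_inner,
                 marker_gap = marker_gap, inner_bumps = inner_bumps,
                 bubble_fraction = bubble_fraction,
                 noise_sd = noise_sd, true_ct_to_mr = true_ct_to_mr,
                 head_pose = head_pose, acpc_pitch = acpc_pitch,
                 acpc_length = acpc_length, seed = seed),
            class = "phantom_spec")
}

# intensity models (ordering/contrast is what matters, not realism).
# T2w "bone" is intermediate rather than near-zero: a ~1 mm cranial
# shell is heavily partial-volumed at 0.36-0.48 mm MR voxels, and a
# hard-saturated bone/brain contrast would also leave the tanh-squashed
# BBR cost without usable tails.
.phantom_intensity <- list(
  CT = c(air = -1000, tissue = 40, bone = 1500, marker = 1200),
  T1w = c(air = 0.05, tissue = 0.70, bone = 0.30, marker = 0.40),
  T2w = c(air = 0.05, tissue = 0.60, bone = 0.35, marker = 0.95))

# marker cavity centres (canonical frame): radial sites on the holder
# surface outside the shell, cylinder axis along the radial direction
.marker_geometry <- function(spec) {
  ax <- spec$head_semiaxes + spec$shell_thickness + spec$marker_gap +
    spec$marker_inner[2] / 2
  centers <- t(apply(spec$marker_dirs, 1, function(d) {
    s <- 1 / sqrt(sum((d / ax)^2))
    s * d
  }))
  list(centers = centers, axes = spec$marker_dirs,
       radius = spec$marker_inner[1] / 2,
       half_len = spec$marker_inner[2] / 2)
}

# spherical bubble seated at the outer end face: radius matching the
# requested volume fraction (half-ball model), and the resulting
# centroid shift of the remaining solid along the cylinder axis
.bubble_geometry <- function(frac, radius, half_len) {
  if (frac <= 0) return(list(r = 0, shift = 0))
  v_cav <- pi * radius^2 * 2 * half_len
  r <- (3 * frac * v_cav / (2 * pi))^(1 / 3)
  z_hb <- half_len - 3 * r / 8             # half-ball centroid (on-axis)
  shift <- frac * z_hb / (1 - frac)        # solid centroid moves inward
  list(r = r, shift = shift)
}

# canonical-frame landmark truth; canonical frame == stereotactic frame
.landmark_truth <- function(spec) {
  Ra <- .rot_x(spec$acpc_pitch * pi / 180)   # stereo -> acpc rotation
  ac <- c(0, 4.4, 10.2)
  from_acpc <- function(p) ac + as.vector(t(Ra) %*% p)
  landmark_set(
    AC = ac,
    PC = from_acpc(c(0, -spec$acpc_length, 0)),
    ear_canal_L = c(-12.5, 0, 0), ear_canal_R = c(12.5, 0, 0),
    infraorbital_L = c(-5.5, 9.5, 0), infraorbital_R = c(5.5, 9.5, 0),
    bregma = from_acpc(c(-0.1, -7.0, 10.0)),
    inion = from_acpc(c(0.1, -23.0, -3.0)),
    rhinion = from_acpc(c(-0.1, 19.6, -3.2)),
    zygion_L = from_acpc(c(-15.1, -0.2, -10.0)),
    zygion_R = from_acpc(c(14.9, -0.1, -10.0)))
}

# approximate signed distance to an ellipsoid with semi-axes `ax`
.ellipsoid_sdf <- function(cx, cy, cz, ax) {
  m <- sqrt((cx / ax[1])^2 + (cy / ax[2])^2 + (cz / ax[3])^2)
  g <- sqrt((cx / ax[1]^2)^2 + (cy / ax[2]^2)^2 + (cz / ax[3]^2)^2)
  d <- (m - 1) * m / pmax(g, 1e-9)
  d[g < 1e-9] <- -min(ax)
  d
}

# partial-volume fraction from a signed distance (linear ramp over one
# voxel width)
.pv <- function(d, w) pmin(pmax(0.5 - d / w, 0), 1)

# centred axis-aligned grid of `dims` voxels with isotropic size `vox`
# whose world centre sits at `center`
.centered_affine <- function(dims, vox, center) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- center - vox * (dims - 1) / 2
  aff
}

# canonical coordinates of every voxel of a grid: separable evaluation
# of Q = world_to_canonical %*% affine
.canonical_coords <- function(dims, affine, world_to_canonical) {
  q <- rt_matrix(world_to_canonical) %*% affine
  iv <- seq_len(dims[1]) - 1; jv <- seq_len(dims[2]) - 1
  kv <- seq_len(dims[3]) - 1
  coord <- function(r) outer(outer(q[r, 1] * iv, q[r, 2] * jv, "+"),
                             q[r, 3] * kv, "+") + q[r, 4]
  list(x = coord(1), y = coord(2), z = coord(3))
}

# render one modality on a grid; `world_to_canonical` maps that
# modality's scanner world into the canonical head frame
.render_phantom <- function(spec, dims, affine, world_to_canonical,
                            modality) {
  inten <- .phantom_intensity[[modality]]
  vox <- sqrt(sum(affine[1:3, 1]^2))
  cc <- .canonical_coords(dims, affine, world_to_canonical)
  ax_out <- spec$head_semiaxes
  ax_in <- spec$head_semiaxes - spec$shell_thickness
  f_out <- .pv(.ellipsoid_sdf(cc$x, cc$y, cc$z, ax_out), vox)
  f_in <- .pv(.ellipsoid_sdf(cc$x, cc$y, cc$z, ax_in), vox)
  data <- inten["air"] + (inten["bone"] - inten["air"]) * f_out +
    (inten["tissue"] - inten["bone"]) * f_in
  label <- (f_out > 0.5) + (f_in > 0.5)    # 0 air, 1 bone, 2 tissue
  rm(f_out)
  geo <- .marker_geometry(spec)
  can_to_grid <- solve(rt_matrix(world_to_canonical) %*% affine)
  subbox <- function(cen, rad) {
    corners <- as.matrix(expand.grid(c(-rad, rad), c(-rad, rad),
                                     c(-rad, rad)))
    gi <- cbind(sweep(corners, 2, cen, "+"), 1) %*% t(can_to_grid)
    lo <- pmax(floor(apply(gi[, 1:3], 2, min)) + 1, 1)
    hi <- pmin(ceiling(apply(gi[, 1:3], 2, max)) + 1, dims)
    if (any(lo > hi)) return(NULL)
    list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  }
  if (isTRUE(spec$inner_bumps)) {
    bg <- .bump_geometry(spec)
    for (b in seq_len(nrow(bg$centers))) {
      cen <- bg$centers[b, ]
      sb <- subbox(cen, bg$radius + 2 * vox)
      if (is.null(sb)) next
      px <- cc$x[sb$x, sb$y, sb$z] - cen[1]
      py <- cc$y[sb$x, sb$y, sb$z] - cen[2]
      pz <- cc$z[sb$x, sb$y, sb$z] - cen[3]
      d_sph <- sqrt(px^2 + py^2 + pz^2) - bg$radius
      # the sphere converts brain tissue to bone where it overlaps the
      # brain compartment
      f_b <- .pv(d_sph, vox) * f_in[sb$x, sb$y, sb$z]
      blk <- data[sb$x, sb$y, sb$z]
      data[sb$x, sb$y, sb$z] <- blk + (inten["bone"] - inten["tissue"]) * f_b
      lb <- label[sb$x, sb$y, sb$z]
      lb[f_b > 0.5 & lb == 2] <- 1
      label[sb$x, sb$y, sb$z] <- lb
    }
  }
  rm(f_in)
  for (m in seq_len(nrow(geo$centers))) {
    cen <- geo$centers[m, ]
    # sub-box of the grid covering the cavity
    rad <- sqrt(geo$radius^2 + geo$half_len^2) + 2 * vox
    corners <- as.matrix(expand.grid(c(-rad, rad), c(-rad, rad),
                                     c(-rad, rad)))
    gi <- cbind(sweep(corners, 2, cen, "+"), 1) %*% t(can_to_grid)
    lo <- pmax(floor(apply(gi[, 1:3], 2, min)) + 1, 1)
    hi <- pmin(ceiling(apply(gi[, 1:3], 2, max)) + 1, dims)
    if (any(lo > hi)) next                 # marker outside this FOV
    sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
    px <- cc$x[sx, sy, sz] - cen[1]
    py <- cc$y[sx, sy, sz] - cen[2]
    pz <- cc$z[sx, sy, sz] - cen[3]
    axis <- geo$axes[m, ]
    t_ax <- px * axis[1] + py * axis[2] + pz * axis[3]
    r2 <- pmax(px^2 + py^2 + pz^2 - t_ax^2, 0)
    dr <- sqrt(r2) - geo$radius
    dz <- abs(t_ax) - geo$half_len
    outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
    inside <- pmin(pmax(dr, dz), 0)
    f_cyl <- .pv(outside + inside, vox)
    b <- spec$bubble_fraction[m]
    if (b > 0) {
      bub <- .bubble_geometry(b, geo$radius, geo$half_len)
      # air sphere centred on the axis at the outer end face:
      # |p - half_len * axis|^2 = |p|^2 - 2 half_len (p.axis) + half_len^2
      d_bub <- sqrt(pmax(px^2 + py^2 + pz^2 -
                           2 * geo$half_len * t_ax + geo$half_len^2, 0)) -
        bub$r
      f_cyl <- f_cyl * (1 - .pv(d_bub, vox))
    }
    blk <- data[sx, sy, sz]
    data[sx, sy, sz] <- blk + (inten["marker"] - blk) * f_cyl
    lb <- label[sx, sy, sz]
    lb[f_cyl > 0.5] <- 3L
    label[sx, sy, sz] <- lb
  }
  if (modality == "CT") {
    # remap label codes to 0 air, 1 tissue, 2 bone, 3 marker
    lab <- label
    lab[label == 1] <- 2L
    lab[label == 2] <- 1L
    label <- lab
  }
  sd <- if (modality == "CT") spec$noise_sd[["ct"]] else spec$noise_sd[["mr"]]
  if (sd > 0) data <- data + stats::rnorm(length(data), sd = sd)
  list(data = array(data, dims), label = array(as.integer(label), dims))
}

#' Generate a paired CT/MR head phantom with ground truth
#'
#' Renders CT, T1w and T2w volumes of the phantom described by `spec`,
#' together with a `ground_truth` list that is exact by construction:
#' the true CT-to-MR transform, scanner-to-AC-PC and
#' scanner-to-stereotactic transforms, marker cavity centroids in both
#' scanner worlds (bubble displacement included), the full landmark set
#' in CT world, and a CT-grid label volume (0 air, 1 soft tissue,
#' 2 bone, 3 marker).
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `ct`, `t1w`, `t2w` ([volume()]s) and
#'   `truth`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    geo <- .marker_geometry(spec)
    margin <- 2
    half_fov <- spec$head_semiaxes + spec$shell_thickness +
      spec$marker_gap + spec$marker_inner[2] + margin
    pose <- spec$head_pose                  # canonical -> CT world
    t_cm <- spec$true_ct_to_mr
    center_ct <- rt_apply(pose, c(0, 0, 0))
    center_mr <- rt_apply(t_cm, center_ct)
    dims_ct <- pmax(as.integer(ceiling(2 * half_fov / spec$ct_voxel)), 8L)
    dims_mr <- pmax(as.integer(ceiling(2 * half_fov / spec$mr_voxel)), 8L)
    aff_ct <- .centered_affine(dims_ct, spec$ct_voxel, center_ct)
    aff_mr <- .centered_affine(dims_mr, spec$mr_voxel, center_mr)
    w2c_ct <- rt_inverse(pose)
    w2c_mr <- rt_inverse(rt_compose(t_cm, pose))
    ct_r <- .render_phantom(spec, dims_ct, aff_ct, w2c_ct, "CT")
    t1_r <- .render_phantom(spec, dims_mr, aff_mr, w2c_mr, "T1w")
    t2_r <- .render_phantom(spec, dims_mr, aff_mr, w2c_mr, "T2w")
    # marker centroid truth: the bubble shifts the centroid inward
    shifts <- vapply(spec$bubble_fraction, function(b)
      .bubble_geometry(b, geo$radius, geo$half_len)$shift, numeric(1))
    cen_can <- geo$centers - geo$axes * shifts
    markers_ct <- point_set(rt_apply(pose, cen_can),
                            sprintf("M%d", seq_len(nrow(cen_can))))
    markers_mr <- rt_apply(t_cm, markers_ct)
    lm_can <- .landmark_truth(spec)
    lm_ct <- landmark_set(stats::setNames(
      lapply(lm_can, function(p) rt_apply(pose, p)), names(lm_can)))
    Ra <- .rot_x(spec$acpc_pitch * pi / 180)
    scanner_to_stereo <- rt_inverse(pose)
    acpc_from_can <- rigid_transform(Ra, -as.vector(Ra %*% lm_can$AC))
    scanner_to_acpc <- rt_compose(acpc_from_can, rt_inverse(pose))
    truth <- list(ct_to_mr = t_cm,
                  scanner_to_acpc = scanner_to_acpc,
                  scanner_to_stereo = scanner_to_stereo,
                  markers_ct = markers_ct, markers_mr = markers_mr,
                  landmarks_ct = lm_ct,
                  label = volume(ct_r$label, aff_ct, modality = "LABEL"))
    list(ct = volume(ct_r$data, aff_ct, modality = "CT"),
         t1w = volume(t1_r$data, aff_mr, modality = "T1w"),
         t2w = volume(t2_r$data, aff_mr, modality = "T2w"),
         truth = truth)
  })
}

#' Simulate repeated stereotactic positionings
#'
#' Draws, for each of 6 pose parameters (pitch/roll/yaw in degrees and
#' X/Y/Z translation in mm), mounting errors
#' `value = bias + subject_effect + repetition_noise` with Gaussian
#' subject effects (SD `between_sd`) and repetition noise (SD
#' `within_sd`). The default SDs qualitatively mirror an observed
#' reproducibility pattern: poor for pitch, excellent for roll/yaw,
#' moderate for X/Y translation.
#'
#' @param n_subjects,n_reps design size (default 5 x 5).
#' @param bias length-6 systematic bias (pitch, roll, yaw, tx, ty, tz);
#'   default `c(1.6, 1.1, -0.2, 0, 0, 0)`.
#' @param within_sd,between_sd length-6 repetition / subject SDs.
#' @param seed RNG seed.
#' @return List with `tables` (one [repeated_measures()] per parameter)
#'   and `truth` (bias, SDs, and the population ICC
#'   `between^2 / (between^2 + within^2)` per parameter).
#' @export
simulate_positionings <- function(n_subjects = 5, n_reps = 5,
                                  bias = c(1.6, 1.1, -0.2, 0, 0, 0),
                                  within_sd = c(1.0, 0.3, 0.2,
                                                0.4, 0.4, 0.7),
                                  between_sd = c(0.3, 1.0, 1.5,
                                                 0.8, 0.9, 0.5),
                                  seed = NULL) {
  pars <- c("pitch", "roll", "yaw", "tx", "ty", "tz")
  units <- c(rep("deg", 3), rep("mm", 3))
  stopifnot(length(bias) == 6, length(within_sd) == 6,
            length(between_sd) == 6, all(within_sd >= 0),
            all(between_sd >= 0))
  .with_seed(seed, {
    tables <- lapply(seq_along(pars), function(p) {
      subj <- stats::rnorm(n_subjects, 0, between_sd[p])
      vals <- matrix(stats::rnorm(n_subjects * n_reps, 0, within_sd[p]),
                     n_subjects, n_reps) + subj + bias[p]
      repeated_measures(vals, parameter = pars[p], units = units[p])
    })
    names(tables) <- pars
    pop_icc <- ifelse(between_sd^2 + within_sd^2 > 0,
                      between_sd^2 / (between_sd^2 + within_sd^2), NA)
    list(tables = tables,
         truth = list(bias = stats::setNames(bias, pars),
                      within_sd = stats::setNames(within_sd, pars),
                      between_sd = stats::setNames(between_sd, pars),
                      population_icc = stats::setNames(pop_icc, pars)))
  })
}

#' Simulate a cohort of landmark sets
#'
#' Gaussian per-axis scatter about true landmark positions, with an
#' optional per-landmark presence probability (emulating landmarks that
#' are only identifiable in a subset of subjects).
#'
#' @param n number of subjects.
#' @param landmarks true [landmark_set()] (default: the phantom's
#'   canonical landmark truth).
#' @param per_axis_sd length-3 per-axis SD (mm), or a named list of
#'   per-landmark length-3 SDs.
#' @param presence named per-landmark presence probabilities (default
#'   1 for all).
#' @param seed RNG seed.
#' @return List with `cohort` (list of [landmark_set()]s) and
#'   `n_present` (named counts actually drawn).
#' @export
simulate_cohort_landmarks <- function(n, landmarks = NULL,
                                      per_axis_sd = c(0.2, 1.0, 0.3),
                                      presence = NULL, seed = NULL) {
  if (n < 1) stop("n must be positive")
  if (is.null(landmarks)) landmarks <- .landmark_truth(phantom_spec())
  nm <- names(landmarks)
  sd_of <- function(l) {
    if (is.list(per_axis_sd)) as.numeric(per_axis_sd[[l]])
    else as.numeric(per_axis_sd)
  }
  pres <- stats::setNames(rep(1, length(nm)), nm)
  if (!is.null(presence)) pres[names(presence)] <- presence
  .with_seed(seed, {
    cohort <- lapply(seq_len(n), function(i) {
      pts <- list()
      for (l in nm) {
        if (stats::runif(1) <= pres[l]) {
          pts[[l]] <- landmarks[[l]] + stats::rnorm(3, 0, sd_of(l))
        }
      }
      landmark_set(pts)
    })
    counts <- stats::setNames(vapply(nm, function(l)
      sum(vapply(cohort, function(s) !is.null(s[[l]]), logical(1))),
      integer(1)), nm)
    list(cohort = cohort, n_present = counts)
  })
}
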