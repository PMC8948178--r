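# Volume container, NIfTI-1 serialisation, thresholding, resampling.

test_that("NIfTI round-trip preserves data and affine", {
  set.seed(10)
  data <- array(round(rnorm(32^3, sd = 100)), c(32, 32, 32))
  aff <- diag(c(0.5, 0.5, 0.5, 1)); aff[1:3, 4] <- c(-8, -8, -8)
  v <- volume(data, aff, modality = "T2w")
  f <- tempfile(fileext = ".nii")
  write_volume(v, f)
  v2 <- read_volume(f, modality = "T2w")
  expect_identical(dim(v2$data), dim(v$data))
  expect_identical(v2$data, v$data)          # integers are float32-exact
  expect_lt(max(abs(v2$affine - v$affine)), 1e-5)
  fgz <- tempfile(fileext = ".nii.gz")
  write_volume(v, fgz)
  expect_identical(read_volume(fgz, modality = "T2w")$data, v$data)
})

test_that("anisotropic oblique affines survive the round-trip", {
  R <- euler_compose(7, -4, 11)$rotation
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% diag(c(0.3, 0.7, 1.1))
  aff[1:3, 4] <- c(5, -12.5, 3)
  v <- volume(array(seq_len(4 * 5 * 6), c(4, 5, 6)), aff, modality = "CT")
  f <- tempfile(fileext = ".nii")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(voxel_size(v2), voxel_size(v), tolerance = 1e-6)
  expect_equal(voxel_to_world(v2, c(1, 1, 1)), aff[1:3, 4],
               tolerance = 1e-5)
})

test_that("read_volume agrees with nibabel on files written both ways", {
  set.seed(11)
  data <- array(round(rnorm(8 * 9 * 10, sd = 50)), c(8, 9, 10))
  aff <- diag(c(0.4, 0.5, 0.6, 1)); aff[1:3, 4] <- c(1, 2, 3)
  f1 <- tempfile(fileext = ".nii")
  write_volume(volume(data, aff, modality = "CT"), f1)
  f2 <- tempfile(fileext = ".nii")       # qform-only file from nibabel
  csv <- tempfile(fileext = ".csv")
  script <- sprintf("
import nibabel as nib, numpy as np
img = nib.load(%s)
np.savetxt(%s, np.concatenate([img.affine.ravel(),
           np.asarray(img.dataobj, dtype=np.float64).ravel(order='F')]))
img2 = nib.Nifti1Image(np.arange(24.0).reshape(2,3,4,order='F'), None)
img2.header.set_qform(np.diag([0.7,0.8,0.9,1.0]), code=1)
img2.header['sform_code'] = 0
nib.save(img2, %s)
", deparse(f1), deparse(csv), deparse(f2))
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  expect_true(file.exists(csv), info = paste(res, collapse = "\n"))
  ref <- scan(csv, quiet = TRUE)
  expect_lt(max(abs(matrix(ref[1:16], 4, 4, byrow = TRUE) - aff)), 1e-5)
  expect_equal(array(ref[-(1:16)], dim(data)), data, ignore_attr = TRUE)
  vq <- read_volume(f2, modality = "T1w")
  expect_equal(unname(voxel_size(vq)), c(0.7, 0.8, 0.9), tolerance = 1e-6)
  expect_equal(as.vector(vq$data), 0:23, ignore_attr = TRUE)
})

test_that("threshold_mask follows the HU conventions", {
  ph <- test_phantom("noiseless")
  ct <- ph$ct
  expect_error(threshold_mask(ct, 10, 10), "lo must be")
  m <- threshold_mask(ct, -250)
  air_frac <- mean(m$data[ct$data < -900])
  expect_lt(air_frac, 0.001)               # air excluded
  expect_gt(sum(m$data), 0)
  # monotone non-increasing voxel count in lo
  counts <- vapply(c(-500, -250, 0, 500, 1000), function(lo)
    sum(threshold_mask(ct, lo)$data), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(sum(threshold_mask(ct, max(ct$data) + 1)$data), 0)
  # bone threshold reproduces the generator's shell label up to
  # partial-volume voxelization: every disagreeing voxel must lie on
  # the shell's rim (within ~1 voxel of an analytic surface)
  bone <- threshold_mask(ct, 1000)$data
  lab_bone <- ph$truth$label$data %in% c(2, 3)
  agree <- sum(bone == 1 & lab_bone) / sum(bone == 1 | lab_bone)
  expect_gt(agree, 0.75)
  dis <- which((bone == 1) != lab_bone)
  co <- voxel_to_world(ct, arrayInd(dis, dim(ct$data)))
  # canonical frame == CT world for the default head pose
  sp <- phantom_spec(ct_voxel = 0.4, mr_voxel = 0.7, seed = 11)
  geo_m <- marmoreg:::.marker_geometry(sp)
  geo_b <- marmoreg:::.bump_geometry(sp)
  d_out <- abs(marmoreg:::.ellipsoid_sdf(co[, 1], co[, 2], co[, 3],
                                         c(25, 20, 18)))
  d_in <- abs(marmoreg:::.ellipsoid_sdf(co[, 1], co[, 2], co[, 3],
                                        c(24, 19, 17)))
  d_mark <- apply(geo_m$centers, 1, function(cen)
    pmax(sqrt(rowSums(sweep(co, 2, cen)^2)) - 1.5, 0))  # cavity envelope
  d_bump <- apply(geo_b$centers, 1, function(cen)
    abs(sqrt(rowSums(sweep(co, 2, cen)^2)) - geo_b$radius))
  near_feature <- pmin(d_out, d_in, apply(d_mark, 1, min),
                       apply(d_bump, 1, min))
  expect_gt(mean(near_feature < 1.2 * max(voxel_size(ct))), 0.995)
})

test_that("resample_rigid honours exactness and inversion contracts", {
  ph <- test_phantom("noiseless")
  ct <- ph$ct
  same <- resample_rigid(ct, rt_identity(), ct)
  expect_lt(max(abs(same$data - ct$data)), 1e-9)
  # one-voxel integer shift equals an index shift away from borders
  vs <- voxel_size(ct)
  shift <- rigid_transform(diag(3), c(vs[1], 0, 0))
  sh <- resample_rigid(ct, shift, ct)
  dims <- dim(ct$data)
  expect_lt(max(abs(sh$data[2:dims[1], , ] -
                    ct$data[1:(dims[1] - 1), , ])), 1e-6)
  # T then T^-1 with spline interpolation: interior error near the
  # constant-image floor
  t <- euler_compose(3, -2, 1, c(1.3, -0.7, 0.4))
  fwd <- resample_rigid(ct, t, ct, interp = "spline")
  back <- resample_rigid(fwd, rt_inverse(t), ct, interp = "spline")
  const <- volume(array(100, dim(ct$data)), ct$affine, "CT")
  cfwd <- resample_rigid(const, t, ct, interp = "spline")
  cback <- resample_rigid(cfwd, rt_inverse(t), ct, interp = "spline")
  core <- lapply(dims, function(n) 12:(n - 12))
  err <- mean(abs((back$data - ct$data)[core[[1]], core[[2]], core[[3]]]))
  floor_err <- mean(abs((cback$data - 100)[core[[1]], core[[2]],
                                           core[[3]]]))
  expect_lt(floor_err, 1e-9)                 # spline reproduces constants
  expect_lt(err, 0.02 * diff(range(ct$data)))
})

test_that("marker centroids transform covariantly under resampling", {
  ph <- test_phantom("noiseless")
  ct <- ph$ct
  t <- euler_compose(2, 0, -1, c(1.1, -0.9, 0.6))
  moved <- resample_rigid(ct, t, ct)
  vox <- prod(voxel_size(ct))
  det0 <- detect_markers(ct, 800, floor(2 / vox), ceiling(20 / vox))
  det1 <- detect_markers(moved, 800, floor(2 / vox), ceiling(20 / vox))
  expect_equal(nrow(det1$markers), nrow(det0$markers))
  p0 <- rt_apply(t, marker_points(det0)$coords)
  p1 <- marker_points(det1)$coords
  # order-free comparison via nearest neighbours
  for (i in seq_len(nrow(p0))) {
    d <- sqrt(rowSums(sweep(p1, 2, p0[i, ])^2))
    expect_lt(min(d), max(voxel_size(ct)) / 2)
  }
})
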