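# Boundary extraction, boundary-contrast cost, pose refinement.

analytic_sdf <- function(pts, ax)
  marmoreg:::.ellipsoid_sdf(pts[, 1], pts[, 2], pts[, 3], ax)

test_that("extract_bone_boundary tracks the analytic shell surfaces", {
  ph <- test_phantom("nobumps")
  vox <- max(voxel_size(ph$ct))
  ax_out <- c(25, 20, 18)
  ax_in <- ax_out - 1
  # tissue-adjacent boundary: the inner surface, within ~1 voxel
  bt <- extract_bone_boundary(ph$ct, bbr_config())
  expect_gt(nrow(bt$coords), 1000)
  expect_lt(max(abs(analytic_sdf(bt$coords, ax_in))), 1.25 * vox)
  # normals are unit and roughly inward radial (toward the brain)
  nr <- attr(bt, "normals")
  expect_equal(sqrt(rowSums(nr^2)), rep(1, nrow(nr)), tolerance = 1e-9)
  inward <- rowSums(nr * bt$coords) / sqrt(rowSums(bt$coords^2))
  expect_gt(mean(inward < 0), 0.99)
  # raw boundary holds both surfaces
  braw <- extract_bone_boundary(ph$ct, bbr_config(
    tissue_adjacent_only = FALSE))
  near_out <- mean(abs(analytic_sdf(braw$coords, ax_out)) < 1.25 * vox)
  near_in <- mean(abs(analytic_sdf(braw$coords, ax_in)) < 1.25 * vox)
  expect_gt(near_out, 0.4)
  expect_gt(near_in, 0.3)
  expect_gt(near_out + near_in, 0.95)
  expect_error(extract_bone_boundary(
    volume(array(-1000, c(10, 10, 10)), diag(4), "CT")), "empty bone mask")
})

test_that("a sub-voxel shell resolves into more boundary as it thickens", {
  thick <- test_phantom("thickshell")
  thin <- generate_phantom(phantom_spec(
    ct_voxel = 0.4, mr_voxel = 0.7, seed = 11, inner_bumps = FALSE,
    noise_sd = c(ct = 0, mr = 0), shell_thickness = 0.3))
  cfg <- bbr_config(tissue_adjacent_only = FALSE)
  n_thin <- nrow(extract_bone_boundary(thin$ct, cfg)$coords)
  n_thick <- nrow(extract_bone_boundary(thick$ct, cfg)$coords)
  expect_gt(n_thick, 5 * n_thin)
  # resolved thick shell: both surfaces present
  ax_out <- c(25, 20, 18)
  b2 <- extract_bone_boundary(thick$ct, cfg)
  expect_gt(mean(abs(analytic_sdf(b2$coords, ax_out)) < 0.5), 0.4)
  expect_gt(mean(abs(analytic_sdf(b2$coords, ax_out - 2)) < 0.5), 0.3)
})

test_that("bbr_cost obeys its algebraic identities", {
  ph <- test_phantom("noiseless")
  cfg <- bbr_config()
  bd <- marmoreg:::.subsample_boundary(
    extract_bone_boundary(ph$ct, cfg), 2000)
  uniform <- volume(array(0.5, dim(ph$t2w$data)), ph$t2w$affine, "T2w")
  expect_equal(bbr_cost(bd, uniform, ph$truth$ct_to_mr, cfg), 0.5,
               tolerance = 1e-12)
  cfg_flip <- bbr_config(slope = 0.5)
  c1 <- bbr_cost(bd, ph$t2w, ph$truth$ct_to_mr, cfg)
  c2 <- bbr_cost(bd, ph$t2w, ph$truth$ct_to_mr, cfg_flip)
  expect_equal(c1 + c2, 1, tolerance = 1e-12)
  expect_error(bbr_config(slope = 0), "non-zero")
  # far-off pose: samples leave the MR field of view
  far <- rigid_transform(diag(3), c(500, 0, 0))
  expect_error(bbr_cost(bd, ph$t2w, far, cfg), "outside")
})

test_that("the cost has a strict local minimum at the true pose", {
  ph <- test_phantom("default")
  cfg <- bbr_config()
  bd <- marmoreg:::.subsample_boundary(
    extract_bone_boundary(ph$ct, cfg), cfg$max_boundary_points)
  truth <- ph$truth$ct_to_mr
  c0 <- bbr_cost(bd, ph$t2w, truth, cfg)
  for (axis in 1:3) {
    for (s in c(-1, 1)) {
      dt <- numeric(3); dt[axis] <- s
      ct_t <- bbr_cost(bd, ph$t2w,
                       rt_compose(rigid_transform(diag(3), dt), truth), cfg)
      ang <- numeric(3); ang[axis] <- 2 * s
      ct_r <- bbr_cost(bd, ph$t2w,
                       rt_compose(euler_compose(ang[1], ang[2], ang[3]),
                                  truth), cfg)
      expect_gt(ct_t, c0)
      expect_gt(ct_r, c0)
    }
    # monotone growth along each translation axis
    mags <- vapply(c(0.25, 0.5, 1, 2), function(mm) {
      dt <- numeric(3); dt[axis] <- mm
      bbr_cost(bd, ph$t2w, rt_compose(rigid_transform(diag(3), dt), truth),
               cfg)
    }, numeric(1))
    expect_true(all(diff(mags) > 0))
    expect_gt(mags[1], c0)
  }
})

test_that("refine_bbr recovers pose from a perturbed initialisation", {
  ph <- test_phantom("default")
  truth <- ph$truth$ct_to_mr
  init <- rt_compose(euler_compose(1.5, 0, 0, c(0.8, 0, 0)), truth)
  res <- refine_bbr(init, ph$ct, ph$t2w)
  err <- pose_error(truth, res$transform)
  expect_lt(err$trans, 0.2)
  expect_lt(err$rot, 0.5)
  expect_lte(res$min_cost, res$initial_cost)
  expect_false(res$escaped_basin)
  # fixed point: starting at the truth stays at the truth
  res0 <- refine_bbr(truth, ph$ct, ph$t2w)
  err0 <- pose_error(truth, res0$transform)
  expect_lt(err0$trans, 0.2)
  expect_lt(err0$rot, 0.5)
})

test_that("refine_bbr flags initialisations outside the basin", {
  ph <- test_phantom("default")
  init <- rt_compose(rigid_transform(diag(3), c(10, 0, 0)),
                     ph$truth$ct_to_mr)
  res <- refine_bbr(init, ph$ct, ph$t2w,
                    bbr_config(max_iterations = 150))
  err <- pose_error(ph$truth$ct_to_mr, res$transform)
  expect_true(!res$converged || res$escaped_basin || err$trans > 2)
})

test_that("BBR after noisy MBFR does not degrade the pose", {
  ph <- test_phantom("default")
  truth <- ph$truth$ct_to_mr
  src <- ph$truth$markers_ct
  dst <- ph$truth$markers_mr
  set.seed(41)
  for (rep in 1:2) {
    noisy <- dst
    noisy$coords <- noisy$coords + matrix(rnorm(length(dst$coords),
                                                sd = 0.2), ncol = 3)
    mbfr_t <- kabsch_fit(src, noisy)
    e_mbfr <- pose_error(truth, mbfr_t)
    res <- refine_bbr(mbfr_t, ph$ct, ph$t2w)
    e_bbr <- pose_error(truth, res$transform)
    score <- function(e) e$trans + 0.5 * e$rot   # 1 mm ~ 2 deg
    expect_lte(score(e_bbr), score(e_mbfr) + 0.05)
  }
})
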