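# AC-PC and stereotactic frame construction and frame bias.

test_that("fit_acpc_frame satisfies its geometric contract", {
  lm <- landmark_set(AC = c(0, 0, 0), PC = c(0, -6, 0))
  ms <- rbind(c(0, -3, 5))
  f <- fit_acpc_frame(lm, ms)
  expect_lt(max(abs(rt_matrix(f$to_frame) - diag(4))), 1e-9)
  # a rotated world is undone: to_frame composes with the inverse motion
  g <- euler_compose(10, 0, 0)
  lm_r <- landmark_set(AC = rt_apply(g, c(0, 0, 0)),
                       PC = rt_apply(g, c(0, -6, 0)))
  f_r <- fit_acpc_frame(lm_r, rt_apply(g, ms))
  expect_equal(euler_decompose(f_r$to_frame)$pitch, -10, tolerance = 1e-6)
  # frame invariants: AC at origin, PC at (0, -|AC-PC|, 0)
  expect_equal(rt_apply(f_r$to_frame, lm_r$AC), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(rt_apply(f_r$to_frame, lm_r$PC), c(0, -6, 0),
               tolerance = 1e-9)
  expect_error(fit_acpc_frame(landmark_set(AC = c(0, 0, 0),
                                           PC = c(0, 0, 0)), ms),
               "coincide")
  expect_error(fit_acpc_frame(lm, rbind(c(0, -3, 0))), "collinear")
})

test_that("fit_stereotactic_frame satisfies its geometric contract", {
  lm <- landmark_set(ear_canal_L = c(-15, 0, 0), ear_canal_R = c(15, 0, 0),
                     infraorbital_L = c(-8, 20, 0),
                     infraorbital_R = c(8, 20, 0))
  f <- fit_stereotactic_frame(lm)
  expect_lt(max(abs(rt_matrix(f$to_frame) - diag(4))), 1e-9)
  set.seed(51)
  g <- random_rigid()
  lm_r <- landmark_set(lapply(unclass(lm), function(p) rt_apply(g, p)))
  f_r <- fit_stereotactic_frame(lm_r)
  expect_lt(max(abs(rt_matrix(rt_compose(f_r$to_frame, g)) - diag(4))),
            1e-9)
  # raising the infra-orbital points pitches the zero plane by
  # atan(rise / horizontal distance)
  h <- 3
  lm_h <- landmark_set(ear_canal_L = c(-15, 0, 0),
                       ear_canal_R = c(15, 0, 0),
                       infraorbital_L = c(-8, 20, h),
                       infraorbital_R = c(8, 20, h))
  f_h <- fit_stereotactic_frame(lm_h)
  e <- euler_decompose(f_h$to_frame)
  expect_equal(abs(e$pitch), atan(h / 20) * 180 / pi, tolerance = 1e-9)
  expect_equal(abs(e$roll), 0, tolerance = 1e-9)
  # ear canals still span the X axis, infra-orbitals sit on Z = 0
  expect_equal(rt_apply(f_h$to_frame, lm_h$ear_canal_R), c(15, 0, 0),
               tolerance = 1e-9)
  expect_equal(rt_apply(f_h$to_frame, lm_h$infraorbital_L)[3], 0,
               tolerance = 1e-9)
  expect_error(fit_stereotactic_frame(landmark_set(
    ear_canal_L = c(0, 0, 0), ear_canal_R = c(0, 0, 0),
    infraorbital_L = c(-8, 20, 0), infraorbital_R = c(8, 20, 0))),
    "coincide")
  expect_error(fit_stereotactic_frame(landmark_set(
    ear_canal_L = c(-15, 0, 0), ear_canal_R = c(15, 0, 0),
    infraorbital_L = c(5, 0, 0), infraorbital_R = c(-5, 0, 0))),
    "collinear")
})

test_that("frame_bias decomposes and inverts correctly", {
  a <- marmoreg:::.frame_definition("ACPC",
                                    euler_compose(10, 0.6, 0.2, c(1, 2, 3)),
                                    "test")
  b <- marmoreg:::.frame_definition("STEREOTACTIC", rt_identity(), "test")
  expect_equal(frame_bias(a, a)$translation, c(0, 0, 0), tolerance = 1e-12)
  bias <- frame_bias(a, b)
  expect_equal(c(bias$rotation$pitch, bias$rotation$roll,
                 bias$rotation$yaw), c(10, 0.6, 0.2), tolerance = 1e-6)
  round_trip <- rt_compose(frame_bias(a, b)$transform,
                           frame_bias(b, a)$transform)
  expect_lt(max(abs(rt_matrix(round_trip) - diag(4))), 1e-9)
})

test_that("landmark_fit_bias recovers pure motions", {
  set.seed(52)
  pts <- point_set(matrix(rnorm(15, sd = 12), 5, 3), paste0("L", 1:5))
  same <- landmark_fit_bias(pts, pts)
  expect_equal(c(same$rotation$pitch, same$rotation$roll,
                 same$rotation$yaw), c(0, 0, 0), tolerance = 1e-9)
  shifted <- pts
  shifted$coords <- sweep(pts$coords, 2, c(-3, 2, 7), "+")
  # frame-b coordinates are the shifted ones; bias maps b -> a
  bias <- landmark_fit_bias(pts, shifted)
  expect_equal(c(bias$rotation$pitch, bias$rotation$roll,
                 bias$rotation$yaw), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(bias$translation, c(3, -2, -7), tolerance = 1e-9)
})

test_that("published cranial landmark means give the ~10 degree pitch", {
  cl <- cranial_landmark_means()
  bias <- landmark_fit_bias(cl$acpc, cl$stereotactic)
  expect_equal(abs(bias$rotation$pitch), 10.0, tolerance = 0.5 / 10.0)
  # frontal-downward positive under the package convention
  expect_gt(bias$rotation$pitch, 0)
  expect_lt(abs(bias$rotation$roll), 1)
  expect_lt(abs(bias$rotation$yaw), 1)
})

test_that("phantom landmark truth reproduces the constructed frames", {
  ph <- test_phantom("noiseless")
  lm <- ph$truth$landmarks_ct
  stereo <- fit_stereotactic_frame(lm)
  expect_lt(max(abs(rt_matrix(stereo$to_frame) -
                    rt_matrix(ph$truth$scanner_to_stereo))), 1e-6)
  ms <- rbind(rt_apply(rt_inverse(ph$truth$scanner_to_acpc), c(0, -3, 5)),
              rt_apply(rt_inverse(ph$truth$scanner_to_acpc), c(0, 3, 4)))
  acpc <- fit_acpc_frame(lm, ms)
  expect_lt(max(abs(rt_matrix(acpc$to_frame) -
                    rt_matrix(ph$truth$scanner_to_acpc))), 1e-6)
  bias <- frame_bias(acpc, stereo)
  expect_equal(bias$rotation$pitch, 10, tolerance = 1e-6)
})

test_that("landmarks round-trip through CSV", {
  lm <- landmark_set(AC = c(0.25, -1.5, 3), PC = c(0, -7.75, 2.5),
                     bregma = c(-0.1, -7, 10))
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(names(back), names(lm))
  expect_equal(back$bregma, lm$bregma, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_landmarks(bad), "name,x,y,z")
})
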