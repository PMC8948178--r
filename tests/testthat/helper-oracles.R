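# Independent oracles and shared fixtures.
#
# Oracles deliberately avoid the code paths they check: the rigid fit is
# verified against Horn's quaternion method (eigen decomposition, no
# SVD), ICC(1,1) against R's aov() machinery, and the signed-rank test
# against a literal enumeration of all sign assignments.

# Horn (1987) closed-form absolute orientation, rotation via the largest
# eigenvector of the 4x4 quaternion matrix
horn_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- crossprod(Ac, Bc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), w^2 - x^2 - y^2 + z^2),
    3, 3)
  list(R = R, t = cb - as.vector(R %*% ca))
}

# one-way ANOVA mean squares through stats::aov
aov_icc_oracle <- function(x) {
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(nrow(x)), ncol(x))))
  tab <- summary(stats::aov(y ~ subj, data = d))[[1]]
  msb <- tab["subj", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(x)
  (msb - msw) / (msb + (k - 1) * msw)
}

# literal 2^m enumeration of the signed-rank null (Pratt zeros,
# midranks), two-sided
wsr_enum_oracle <- function(values, null = 0) {
  d <- values - null
  r <- rank(abs(d))
  nz <- which(d != 0)
  m <- length(nz)
  stopifnot(m <= 14)
  w_obs <- sum(r[nz][d[nz] > 0])
  ws <- vapply(0:(2^m - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(seq_len(m) - 1)) > 0
    sum(r[nz][signs])
  }, numeric(1))
  p <- min(1, 2 * min(mean(ws <= w_obs + 1e-12),
                      mean(ws >= w_obs - 1e-12)))
  list(statistic = w_obs, p_value = p)
}

random_rigid <- function(max_deg = 20, max_mm = 10) {
  euler_compose(stats::runif(1, -max_deg, max_deg),
                stats::runif(1, -max_deg, max_deg),
                stats::runif(1, -max_deg, max_deg),
                stats::runif(3, -max_mm, max_mm))
}

pose_error <- function(truth, estimate) {
  err <- rt_compose(rt_inverse(truth), estimate)
  e <- euler_decompose(err)
  list(trans = sqrt(sum(err$translation^2)),
       rot = max(abs(c(e$pitch, e$roll, e$yaw))))
}

# Phantoms are expensive; build each named variant once per test run.
# Test-scale resolution (0.4 / 0.7 mm) keeps the suite fast; the
# geometry, noise model and all thresholds are the package defaults.
.phantom_cache <- new.env(parent = emptyenv())

test_phantom <- function(variant = "default") {
  if (!is.null(.phantom_cache[[variant]])) return(.phantom_cache[[variant]])
  args <- list(ct_voxel = 0.4, mr_voxel = 0.7, seed = 11L)
  extra <- switch(variant,
    default = list(),
    noiseless = list(noise_sd = c(ct = 0, mr = 0)),
    bubble = list(bubble_fraction = c(0.3, 0, 0, 0, 0, 0)),
    nobumps = list(inner_bumps = FALSE, noise_sd = c(ct = 0, mr = 0)),
    thickshell = list(inner_bumps = FALSE, noise_sd = c(ct = 0, mr = 0),
                      shell_thickness = 2.0),
    noisy4x = list(noise_sd = c(ct = 60, mr = 0.08)),
    stop("unknown phantom variant: ", variant))
  ph <- do.call(generate_phantom, list(do.call(phantom_spec,
                                               c(args, extra))))
  .phantom_cache[[variant]] <- ph
  ph
}

mbfr_test_config <- function(...) mbfr_config(...)
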