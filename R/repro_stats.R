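# Bias, reproducibility and variability statistics.

#' Repeated-measures table
#'
#' Subjects x repetitions matrix of one scalar positioning parameter
#' (e.g. pitch in degrees). Rows with missing cells are dropped listwise
#' with a warning.
#'
#' @param values numeric matrix, subjects in rows, repetitions in
#'   columns.
#' @param parameter parameter name.
#' @param units parameter units.
#' @return An object of class `repeated_measures`.
#' @export
repeated_measures <- function(values, parameter = "parameter",
                              units = "") {
  values <- as.matrix(values)
  if (anyNA(values)) {
    keep <- stats::complete.cases(values)
    warning("repeated_measures: dropping ", sum(!keep),
            " subject(s) with missing cells")
    values <- values[keep, , drop = FALSE]
  }
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("repeated_measures needs >= 2 subjects and >= 2 repetitions")
  structure(list(values = values, parameter = parameter, units = units),
            class = "repeated_measures")
}

#' Intraclass correlation ICC(1,1)
#'
#' One-way random-effects intraclass correlation
#' `ICC(1,1) = (MSB - MSW) / (MSB + (k - 1) MSW)` with the F-based 95%
#' confidence interval of Shrout & Fleiss. A table with zero total
#' variance yields `icc = 0` with a warning.
#'
#' @param rm a [repeated_measures()] (or bare subjects x reps matrix).
#' @param conf_level confidence level for the interval.
#' @return An `icc_result`: `icc`, `ci_low`, `ci_high`, `ms_between`,
#'   `ms_within`, `n_subjects`, `n_reps`.
#' @export
icc_1_1 <- function(rm, conf_level = 0.95) {
  if (!inherits(rm, "repeated_measures")) rm <- repeated_measures(rm)
  x <- rm$values
  n <- nrow(x); k <- ncol(x)
  row_means <- rowMeans(x)
  grand <- mean(x)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((x - row_means)^2) / (n * (k - 1))
  if (msb + msw < .Machine$double.eps) {
    warning("icc_1_1: zero total variance; ICC undefined, returning 0")
    return(structure(list(icc = 0, ci_low = NA_real_, ci_high = NA_real_,
                          ms_between = msb, ms_within = msw,
                          n_subjects = n, n_reps = k),
                     class = "icc_result"))
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf_level
  fobs <- msb / max(msw, .Machine$double.xmin)
  fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  structure(list(icc = icc,
                 ci_low = (fl - 1) / (fl + k - 1),
                 ci_high = (fu - 1) / (fu + k - 1),
                 ms_between = msb, ms_within = msw,
                 n_subjects = n, n_reps = k), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.4f [%.4f, %.4f], %d subjects x %d reps\n",
              x$icc, x$ci_low, x$ci_high, x$n_subjects, x$n_reps))
  invisible(x)
}

# exact null distribution of the positive-rank sum over doubled ranks
# (doubling makes midranks integral), by dynamic programming over the
# 2^m sign assignments
.wsr_exact_dist <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)          # counts[w + 1] = #assignments
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts / 2^length(ranks2)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided one-sample Wilcoxon signed-rank test of symmetry about
#' `null`. Zeros are handled by the Pratt method (ranked with the rest,
#' then discarded from the statistic) and ties by midranks. The p-value
#' is exact (full enumeration of sign assignments via dynamic
#' programming) for up to 25 informative observations, and uses the
#' normal approximation with tie/zero corrections above that.
#'
#' @param values numeric observations.
#' @param null hypothesised centre of symmetry.
#' @return A list: `statistic` (positive-rank sum W+), `p_value`,
#'   `n_informative`, `method`.
#' @export
wilcoxon_signed_rank <- function(values, null = 0) {
  d <- as.numeric(values) - null
  if (length(d) < 1L) stop("no observations")
  if (all(d == 0)) {
    warning("wilcoxon_signed_rank: all values equal the null; p = 1")
    return(list(statistic = 0, p_value = 1, n_informative = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))                      # Pratt: zeros ranked too
  nz <- d != 0
  w <- sum(r[nz & d > 0])
  m <- sum(nz)
  if (m <= 25L) {
    dist <- .wsr_exact_dist(round(2 * r[nz]))
    w2 <- round(2 * w)
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    # normal approximation, Pratt zero correction and tie correction
    n <- length(d)
    n0 <- n - m
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    tie_tab <- table(r[nz])
    sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n_informative = m, method = method)
}

#' Coefficient-of-variation summary
#'
#' `cov_percent = 100 * sd / mean`, defined only for positive means.
#' Either supply `mean` and `sd` directly, or raw `values`.
#'
#' @param mean,sd summary statistics of a positive-valued quantity.
#' @param values raw observations (used when `mean` is missing).
#' @return A `variability_summary`: `mean`, `sd`, `cov_percent`, `n`.
#' @examples
#' cov_summary(6180, 524)$cov_percent   # 8.5 (to 0.1% precision)
#' @export
cov_summary <- function(mean = NULL, sd = NULL, values = NULL) {
  if (is.null(mean)) {
    if (is.null(values)) stop("supply mean/sd or raw values")
    n <- length(values)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  } else {
    if (is.null(sd)) stop("sd is required with mean")
    n <- NA_integer_
  }
  if (!is.finite(mean) || mean <= 0)
    stop("cov_summary: mean must be positive")
  if (sd < 0) stop("cov_summary: sd must be non-negative")
  structure(list(mean = mean, sd = sd, cov_percent = 100 * sd / mean,
                 n = n), class = "variability_summary")
}

#' @export
print.variability_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (COV %.1f%%)\n", x$mean, x$sd, x$cov_percent))
  invisible(x)
}

#' Isometric scale ratio
#'
#' Cross-species normalisation: a linear measure is compared directly
#' (`a / b`); a volume is compared through its cube root
#' (`(a / b)^(1/3)`), so that both are on an isometric (linear) scale.
#'
#' @param value_a,value_b positive measurements (e.g. one species'
#'   bregma variability vs the reference species').
#' @param kind `"linear"` or `"volume"`.
#' @return Dimensionless ratio.
#' @examples
#' isometric_ratio(2.0, 0.5, "linear")   # 4
#' @export
isometric_ratio <- function(value_a, value_b, kind = c("linear", "volume")) {
  kind <- match.arg(kind)
  if (!is.finite(value_a) || !is.finite(value_b) ||
      value_a <= 0 || value_b <= 0)
    stop("isometric_ratio: inputs must be positive")
  r <- value_a / value_b
  if (kind == "volume") r^(1 / 3) else r
}

#' Per-landmark per-axis cohort variability
#'
#' Transforms each subject's landmarks into a common frame and reports
#' per-landmark, per-axis mean and SD, with the number of subjects in
#' which the landmark was present.
#'
#' @param cohort list of [landmark_set()]s (one per subject).
#' @param frame optional `frame_definition` (or `rigid_transform`)
#'   mapping scanner world to the reporting frame; identity if omitted.
#' @return data.frame: landmark, n, mean_x/y/z, sd_x/y/z.
#' @export
landmark_variability <- function(cohort, frame = NULL) {
  if (length(cohort) < 2L) stop("landmark_variability needs >= 2 subjects")
  t <- if (is.null(frame)) rt_identity()
       else if (is_rigid_transform(frame)) frame
       else frame$to_frame
  all_names <- unique(unlist(lapply(cohort, names)))
  rows <- lapply(all_names, function(nm) {
    pts <- do.call(rbind, lapply(cohort, function(s)
      if (!is.null(s[[nm]])) rt_apply(t, s[[nm]])))
    n <- nrow(pts)
    data.frame(landmark = nm, n = n,
               mean_x = mean(pts[, 1]), mean_y = mean(pts[, 2]),
               mean_z = mean(pts[, 3]),
               sd_x = stats::sd(pts[, 1]), sd_y = stats::sd(pts[, 2]),
               sd_z = stats::sd(pts[, 3]))
  })
  do.call(rbind, rows)
}
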