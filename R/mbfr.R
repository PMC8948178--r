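# Marker-based fiducial registration (MBFR) and its accuracy metric.

#' MBFR configuration
#'
#' @param ct_threshold HU threshold for marker detection in CT. The
#'   tungsten-solution markers sit near cortical-bone density, so 800 HU
#'   captures them; the bone shell itself is removed by the component
#'   size window, not the threshold.
#' @param mr_quantile intensity quantile defining the MR marker
#'   threshold (markers are the brightest structures in T2w). The
#'   default 0.9995 keeps the threshold above the soft-tissue noise
#'   tail for any marker payload below 0.05% of the field of view.
#' @param min_volume,max_volume accepted marker volume (mm^3), converted
#'   to voxels per modality. Defaults bracket the ~6.3 mm^3 cylindrical
#'   marker cavity (2.0 mm diameter x 2.0 mm).
#' @param match_tol pairwise-distance consistency tolerance for marker
#'   correspondence (mm).
#' @param failure_threshold MRE above which a registration is reported
#'   as failed (mm).
#' @param asymmetry_threshold markers with a higher asymmetry index are
#'   flagged (air-bubble proxy); flagged markers are still used unless
#'   `drop_asymmetric = TRUE`.
#' @param drop_asymmetric drop flagged markers before fitting.
#' @param direction `"ct_to_mr"` (default, CT is aligned onto MR) or
#'   `"mr_to_ct"`.
#' @return A list of class `mbfr_config`.
#' @export
mbfr_config <- function(ct_threshold = 800, mr_quantile = 0.9995,
                        min_volume = 2, max_volume = 20,
                        match_tol = 0.5, failure_threshold = 1.0,
                        asymmetry_threshold = 0.15,
                        drop_asymmetric = FALSE,
                        direction = c("ct_to_mr", "mr_to_ct")) {
  structure(list(ct_threshold = ct_threshold, mr_quantile = mr_quantile,
                 min_volume = min_volume, max_volume = max_volume,
                 match_tol = match_tol, failure_threshold = failure_threshold,
                 asymmetry_threshold = asymmetry_threshold,
                 drop_asymmetric = drop_asymmetric,
                 direction = match.arg(direction)),
            class = "mbfr_config")
}

#' Marker registration error (MRE)
#'
#' Root-mean-square of the Euclidean distances between corresponding
#' marker centroids, `MRE = sqrt((d_1^2 + ... + d_n^2) / n)`.
#'
#' @param registered,reference label-matched `point_set`s: marker
#'   centroids after registration and in the reference modality.
#' @return List with `mre` (mm) and `per_marker` (named distances, mm).
#' @examples
#' a <- point_set(rbind(c(0,0,0), c(10,0,0)))
#' b <- point_set(rbind(c(3,0,0), c(10,4,0)))
#' compute_mre(a, b)$mre   # sqrt((9 + 16) / 2)
#' @export
compute_mre <- function(registered, reference) {
  stopifnot(is_point_set(registered), is_point_set(reference))
  if (!setequal(registered$labels, reference$labels) ||
      length(registered$labels) != length(reference$labels))
    stop("compute_mre: point sets must carry the same labels")
  A <- registered$coords
  B <- reference$coords[registered$labels, , drop = FALSE]
  d <- sqrt(rowSums((A - B)^2))
  names(d) <- registered$labels
  list(mre = sqrt(mean(d^2)), per_marker = d)
}

.registration_result <- function(transform, per_marker, mre, method,
                                 failure_threshold, correspondence = NULL) {
  structure(list(transform = transform,
                 per_marker_distance = per_marker,
                 mre = mre, n_markers = length(per_marker),
                 status = if (mre > failure_threshold) "failed" else "ok",
                 failure_threshold = failure_threshold,
                 method = method, correspondence = correspondence),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s]: %s, MRE %.4f mm over %d markers\n",
              x$method, x$status, x$mre, x$n_markers))
  print(x$transform)
  invisible(x)
}

#' Run marker-based fiducial registration
#'
#' Pipeline: detect markers in CT and MR, establish correspondence by
#' pairwise-distance consistency, fit the rigid transform with the
#' Kabsch algorithm, and score the fit with the MRE on the markers used.
#' The result is flagged `failed` when the MRE exceeds the failure
#' threshold (default 1 mm).
#'
#' @param ct CT [volume()] (HU).
#' @param mr MR [volume()] (T2w recommended: markers bright).
#' @param cfg an [mbfr_config()].
#' @return A `registration_result`; its `transform` maps CT world to MR
#'   world (or the reverse under `direction = "mr_to_ct"`).
#' @export
run_mbfr <- function(ct, mr, cfg = mbfr_config()) {
  stopifnot(is_volume(ct), is_volume(mr))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("MBFR stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  vox_ct <- prod(voxel_size(ct)); vox_mr <- prod(voxel_size(mr))
  ms_ct <- stage("detect CT markers", {
    m <- detect_markers(ct, cfg$ct_threshold,
                        min_voxels = max(1L, floor(cfg$min_volume / vox_ct)),
                        max_voxels = ceiling(cfg$max_volume / vox_ct))
    if (nrow(m$markers) < 3L)
      stop("fewer than 3 markers detected (found ", nrow(m$markers), ")")
    m
  })
  thr_mr <- stats::quantile(mr$data, cfg$mr_quantile, names = FALSE)
  ms_mr <- stage("detect MR markers", {
    m <- detect_markers(mr, thr_mr,
                        min_voxels = max(1L, floor(cfg$min_volume / vox_mr)),
                        max_voxels = ceiling(cfg$max_volume / vox_mr))
    if (nrow(m$markers) < 3L)
      stop("fewer than 3 markers detected (found ", nrow(m$markers), ")")
    m
  })
  # correspondence search is exhaustive; if noise speckle slipped through
  # the size window, keep only the 12 largest candidates per modality
  for (nm in c("ms_ct", "ms_mr")) {
    m <- get(nm)
    if (nrow(m$markers) > 12L) {
      m$markers <- m$markers[order(-m$markers$voxels)[1:12], ]
      assign(nm, m)
    }
  }
  if (cfg$drop_asymmetric) {
    for (nm in c("ms_ct", "ms_mr")) {
      m <- get(nm)
      m$markers <- m$markers[m$markers$asymmetry <= cfg$asymmetry_threshold, ]
      assign(nm, m)
    }
  }
  corr <- stage("match markers", match_markers(ms_ct, ms_mr, cfg$match_tol))
  pc <- marker_points(ms_ct)
  pm <- marker_points(ms_mr)
  src <- point_set(pc$coords[corr$pairs$label_a, , drop = FALSE],
                   corr$pairs$label_a)
  dst <- point_set(pm$coords[corr$pairs$label_b, , drop = FALSE],
                   corr$pairs$label_a)   # relabel to shared labels
  if (cfg$direction == "mr_to_ct") { tmp <- src; src <- dst; dst <- tmp }
  fit <- stage("kabsch fit", kabsch_fit(src, dst))
  mre <- compute_mre(rt_apply(fit, src), dst)
  if (nrow(corr$pairs) == 3L)
    warning("run_mbfr: only 3 markers used; the fit is valid but has no ",
            "redundancy (MRE is optimistic)")
  .registration_result(fit, mre$per_marker, mre$mre, "MBFR",
                       cfg$failure_threshold, corr)
}

#' Cohort summary of registration results
#'
#' @param results non-empty list of `registration_result`s.
#' @return A `cohort_summary`: counts, failure probability
#'   (`n_failed / n_total`), and MRE mean/sd over all results and over
#'   the non-failed subset.
#' @export
summarize_cohort <- function(results) {
  if (!is.list(results) || length(results) == 0L)
    stop("summarize_cohort needs a non-empty list")
  stopifnot(all(vapply(results, inherits, logical(1), "registration_result")))
  mre <- vapply(results, `[[`, numeric(1), "mre")
  failed <- vapply(results, function(r) r$status == "failed", logical(1))
  ok <- mre[!failed]
  structure(list(
    n_total = length(results), n_failed = sum(failed),
    failure_probability = mean(failed),
    mre_mean = mean(mre), mre_sd = stats::sd(mre),
    mre_mean_ok = if (length(ok)) mean(ok) else NA_real_,
    mre_sd_ok = if (length(ok) > 1) stats::sd(ok) else NA_real_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "cohort_summary: %d registrations, %d failed (probability %.2f)\n",
    x$n_total, x$n_failed, x$failure_probability))
  cat(sprintf("  MRE %.4f +/- %.4f mm (all), %.4f +/- %.4f mm (ok only)\n",
              x$mre_mean, x$mre_sd, x$mre_mean_ok, x$mre_sd_ok))
  invisible(x)
}
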