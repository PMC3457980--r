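#' Quantile-normalize an intensity table
#'
#' Forces every sample's intensity distribution onto the across-sample mean
#' of sorted intensity vectors while preserving within-sample rank order;
#' ties receive the mean of the tied target values. This is the standard
#' between-array normalization for single-channel BeadChip data.
#'
#' @param signals A tibble with a `probe_id` column followed by one numeric
#'   column per sample, or a plain numeric matrix.
#'
#' @return An object of the same shape with normalized intensities. With one
#'   sample the input is returned unchanged (nothing to equalize).
#' @export
quantile_normalize <- function(signals) {
  if (is.matrix(signals)) {
    check_intensities(signals)
    return(qn_core(signals))
  }
  stopifnot(is.data.frame(signals), names(signals)[1] == "probe_id")
  m <- as.matrix(signals[, -1, drop = FALSE])
  check_intensities(m)
  out <- signals
  out[, -1] <- as.data.frame(qn_core(m))
  tibble::as_tibble(out)
}

# Single-probe matrices short-circuit the interpolation path: the common
# target distribution of one value per column is the across-column mean.
qn_core <- function(m) {
  if (nrow(m) == 1) {
    out <- m
    out[1, ] <- mean(m[1, ])
    return(out)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

check_intensities <- function(m) {
  if (!is.numeric(m)) abort("intensity values must be numeric")
  if (anyNA(m)) abort("intensity matrix contains missing values")
  if (any(m < 0)) abort("intensity matrix contains negative values")
  if (nrow(m) < 1 || ncol(m) < 1) abort("need at least one probe and one sample")
  invisible(m)
}

#' Rank-based detection p-value against negative-control probes
#'
#' Empirical upper-tail p-value of an intensity within the negative-control
#' distribution: `(1 + #\{controls >= intensity\}) / (N + 1)`, always in
#' (0, 1\]. Small values mean the probe is expressed above background. Used
#' to equip synthetic data with detection calls; real arrays carry
#' vendor-computed detection p-values which are used as-is.
#'
#' @param intensity Numeric vector of probe intensities.
#' @param negctrl_intensities Numeric vector of negative-control intensities
#'   from the same array.
#'
#' @return Numeric vector of p-values, one per intensity.
#' @export
compute_detection_p <- function(intensity, negctrl_intensities) {
  if (length(negctrl_intensities) < 1) {
    abort("compute_detection_p() needs at least one negative-control intensity")
  }
  n <- length(negctrl_intensities)
  sorted <- sort(negctrl_intensities)
  # #{controls >= x} = n - #{controls < x}
  below <- findInterval(intensity, sorted, left.open = TRUE)
  (1 + (n - below)) / (n + 1)
}

#' Filter to probes expressed in at least one array
#'
#' A regular probe is retained iff its detection p-value is below `alpha` in
#' at least one sample; probes undetected everywhere are removed.
#' Negative-control probes never enter the expression matrix (they are kept
#' aside for background estimation).
#'
#' @param profile A probe-profile tibble.
#' @param alpha Detection threshold (default 0.05).
#' @param normalize Quantile-normalize the retained regular-probe signals
#'   (default `TRUE`). Normalization is computed on all regular probes before
#'   filtering so the target distribution is the whole-array one.
#'
#' @return A list with `signals` (tibble, retained probes x samples,
#'   normalized unless `normalize = FALSE`), `raw_signals` (same probes,
#'   unnormalized), `detection_p` (same probes), `removed_count` and
#'   `retained_count` (regular probes only).
#' @export
filter_expressed <- function(profile, alpha = 0.05, normalize = TRUE) {
  validate_probe_profile(profile)
  regular <- profile[profile$PROBE_CLASS == "regular", , drop = FALSE]
  sig <- profile_signals(regular)
  det <- profile_detection(regular)
  norm <- if (normalize) quantile_normalize(sig) else sig
  detected <- apply(as.matrix(det[, -1, drop = FALSE]) < alpha, 1, any)
  list(
    signals = norm[detected, , drop = FALSE],
    raw_signals = sig[detected, , drop = FALSE],
    detection_p = det[detected, , drop = FALSE],
    removed_count = sum(!detected),
    retained_count = sum(detected)
  )
}

#' Estimate array background from negative-control probes
#'
#' The background is the arithmetic mean of all negative-control intensities
#' pooled across every array; it is reported rounded to the nearest integer
#' with full precision retained in `value`.
#'
#' @param profile A probe-profile tibble containing `negative_control` probes.
#'
#' @return A `background_estimate` list: `value` (full precision), `reported`
#'   (rounded), `n_control_probes_used`, `method`.
#' @export
estimate_background <- function(profile) {
  validate_probe_profile(profile)
  nc <- profile[profile$PROBE_CLASS == "negative_control", , drop = FALSE]
  if (nrow(nc) == 0) {
    abort(paste("no negative-control probes in the profile;",
                "supply a background constant explicitly"))
  }
  vals <- as.matrix(profile_signals(nc)[, -1, drop = FALSE])
  est <- structure(
    list(
      value = mean(vals),
      reported = round(mean(vals)),
      n_control_probes_used = nrow(nc),
      method = "mean of negative-control intensities pooled over all arrays"
    ),
    class = "background_estimate"
  )
  est
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("Background estimate: %d (exact %.6g) from %d negative-control probes\n",
              x$reported, x$value, x$n_control_probes_used))
  invisible(x)
}

#' Run the full preprocessing stage
#'
#' Convenience composition: quantile normalization of regular probes,
#' detection-based filtering, and background estimation from raw
#' negative-control intensities.
#'
#' @inheritParams filter_expressed
#' @return The [filter_expressed()] list with an additional `background`
#'   element (a `background_estimate`) and the `alpha` used.
#' @export
preprocess_profile <- function(profile, alpha = 0.05, normalize = TRUE) {
  out <- filter_expressed(profile, alpha = alpha, normalize = normalize)
  out$background <- estimate_background(profile)
  out$alpha <- alpha
  class(out) <- "bead_prep"
  out
}

#' @export
print.bead_prep <- function(x, ...) {
  cat(sprintf("BeadChip preprocessing: %d probes retained, %d removed (alpha = %g)\n",
              x$retained_count, x$removed_count, x$alpha))
  print(x$background)
  invisible(x)
}
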