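#' Construct a FRAP trace
#'
#' Time-stamped fluorescence of a bleached region and an unbleached
#' reference region from the same cell, plus the bleach time. Samples at
#' `time_s < bleach_time_s` are pre-bleach; the first sample at or after
#' `bleach_time_s` is the first post-bleach point.
#'
#' @param time_s numeric vector of times (s), strictly increasing.
#' @param bleach_intensity fluorescence of the bleached region (a.u.).
#' @param reference_intensity fluorescence of the unbleached reference
#'   region (a.u., must stay positive).
#' @param bleach_time_s time of the bleach event (s), within the time range.
#' @return list of class `frap_trace`; `normalized_recovery` is `NULL`
#'   until [normalize_frap()] is applied.
#' @export
frap_trace <- function(time_s, bleach_intensity, reference_intensity,
                       bleach_time_s) {
  stopifnot(is.numeric(time_s), is.numeric(bleach_intensity),
            is.numeric(reference_intensity),
            length(time_s) == length(bleach_intensity),
            length(time_s) == length(reference_intensity))
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (!is.numeric(bleach_time_s) || length(bleach_time_s) != 1L ||
      bleach_time_s <= min(time_s) || bleach_time_s > max(time_s))
    stop("bleach_time_s must lie within the time range", call. = FALSE)
  out <- list(time_s = time_s, bleach_intensity = bleach_intensity,
              reference_intensity = reference_intensity,
              bleach_time_s = bleach_time_s, normalized_recovery = NULL)
  class(out) <- "frap_trace"
  out
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("FRAP trace: %d samples over %.1f-%.1f s, bleach at %.1f s%s\n",
              length(x$time_s), min(x$time_s), max(x$time_s),
              x$bleach_time_s,
              if (is.null(x$normalized_recovery)) " (not normalized)" else
                " (normalized)"))
  invisible(x)
}

#' Double-normalize a FRAP trace to percent recovery
#'
#' Corrects for whole-cell photobleaching during imaging by dividing the
#' bleached-region intensity by the unbleached reference region, then
#' divides that ratio by its mean over the pre-bleach samples:
#' `r(t) = (B(t)/R(t)) / mean_prebleach(B/R)`. The corrected ratio is then
#' scaled to percent recovery,
#' `100 * (r(t) - r(t0+)) / (1 - r(t0+))`, where `t0+` is the first
#' post-bleach sample, so the pre-bleach level maps to 100% and the first
#' post-bleach point to 0%.
#'
#' @param trace a [frap_trace()] with at least 2 pre-bleach and 1
#'   post-bleach samples.
#' @param median_filter optional width-3 running median applied to the
#'   corrected ratio before scaling, to suppress transient blips from
#'   trafficking vesicles; off by default.
#' @return the trace with `normalized_recovery` (%) filled in (pre-bleach
#'   samples are reported at their normalized level, near 100%).
#' @export
normalize_frap <- function(trace, median_filter = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  if (any(trace$reference_intensity <= 0))
    stop("reference intensity must be positive at all samples",
         call. = FALSE)
  pre <- trace$time_s < trace$bleach_time_s
  if (sum(pre) < 2L)
    stop("need at least 2 pre-bleach samples", call. = FALSE)
  if (!any(!pre))
    stop("need at least 1 post-bleach sample", call. = FALSE)
  ratio <- trace$bleach_intensity / trace$reference_intensity
  r <- ratio / mean(ratio[pre])
  if (median_filter) r <- stats::runmed(r, 3)
  r0 <- r[which(!pre)[1L]]
  if (abs(1 - r0) < 1e-9)
    stop("no bleach depth: first post-bleach ratio equals the pre-bleach level",
         call. = FALSE)
  trace$normalized_recovery <- 100 * (r - r0) / (1 - r0)
  trace
}

#' Recovery plateau over a late time window
#'
#' Mean normalized recovery over a time window (default 110-120 s, the
#' window used to quantify the recovery plateau); on a trace whose recovery
#' has leveled off this estimates the mobile fraction in percent.
#'
#' @param trace a normalized `frap_trace` (see [normalize_frap()]).
#' @param window_s numeric length-2 window in seconds, inclusive.
#' @return mean normalized recovery (%) over samples in the window.
#' @export
recovery_plateau <- function(trace, window_s = c(110, 120)) {
  stopifnot(inherits(trace, "frap_trace"))
  if (is.null(trace$normalized_recovery))
    stop("trace must be normalized first (see normalize_frap)",
         call. = FALSE)
  stopifnot(length(window_s) == 2L, window_s[2] >= window_s[1])
  sel <- trace$time_s >= window_s[1] & trace$time_s <= window_s[2]
  if (!any(sel))
    stop("no samples in the plateau window", call. = FALSE)
  mean(trace$normalized_recovery[sel])
}

#' Compare recovery plateaus between two groups of cells
#'
#' Two-sided two-sample t-test on per-cell plateau values (e.g. dendrite
#' vs axon bleach sites). Zero-variance groups are reported (p = 1 when the
#' means agree, 0 otherwise) rather than raising an error.
#'
#' @param group_a,group_b numeric vectors of per-cell plateau percentages
#'   (each n >= 2).
#' @return list of class `plateau_comparison`: `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `p_value`, `n_a`, `n_b`.
#' @export
compare_plateaus <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 2L, length(group_b) >= 2L)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  p <- tryCatch(stats::t.test(group_a, group_b)$p.value,
                error = function(e) {
                  if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1
                  else 0
                })
  out <- list(mean_a = mean(group_a), mean_b = mean(group_b),
              sem_a = sem(group_a), sem_b = sem(group_b),
              p_value = p, n_a = length(group_a), n_b = length(group_b))
  class(out) <- "plateau_comparison"
  out
}

#' @export
print.plateau_comparison <- function(x, ...) {
  cat(sprintf(
    "recovery plateau: %.1f +/- %.1f%% (n=%d) vs %.1f +/- %.1f%% (n=%d), t-test p = %.3g\n",
    x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b, x$p_value))
  invisible(x)
}

#' Top-and-bottom normalization of an axon intensity profile
#'
#' Normalizes a fluorescence line profile drawn from the cell body along the
#' axon in two steps: each value is first divided by the mean of the lowest
#' 25% of values, then the result is divided by the mean of its highest 5%
#' of values, anchoring the profile floor and ceiling. Window sizes are
#' computed over sample counts with a ceiling of at least one sample. The
#' transform is monotone, so peak positions and sample ordering are
#' preserved.
#'
#' @param distance_um distances from the cell body (microns), monotone
#'   increasing.
#' @param intensity fluorescence (a.u.), same length, at least 8 samples.
#' @return list of class `intensity_profile`: `distance_um`, `intensity`,
#'   `normalized`.
#' @export
normalize_profile <- function(distance_um, intensity) {
  stopifnot(is.numeric(distance_um), is.numeric(intensity),
            length(distance_um) == length(intensity))
  if (length(intensity) < 8L)
    stop("need at least 8 samples for the 25%/5% windows", call. = FALSE)
  if (any(diff(distance_um) <= 0))
    stop("distance_um must be strictly increasing", call. = FALSE)
  n <- length(intensity)
  k_low <- max(1L, ceiling(0.25 * n))
  k_high <- max(1L, ceiling(0.05 * n))
  bottom <- mean(sort(intensity)[seq_len(k_low)])
  if (abs(bottom) < .Machine$double.eps)
    stop("bottom-quartile mean is zero; profile cannot be normalized",
         call. = FALSE)
  v1 <- intensity / bottom
  top <- mean(sort(v1, decreasing = TRUE)[seq_len(k_high)])
  out <- list(distance_um = distance_um, intensity = intensity,
              normalized = v1 / top)
  class(out) <- "intensity_profile"
  out
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "axon intensity profile: %d samples over %.1f-%.1f um, peak at %.1f um\n",
    length(x$distance_um), min(x$distance_um), max(x$distance_um),
    x$distance_um[which.max(x$normalized)]))
  invisible(x)
}
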