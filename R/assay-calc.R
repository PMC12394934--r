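# Arithmetic layer for the plate-based assays: chelation percent,
# luminescence AUC over a kinetic window, and signal normalization.

#' Construct a kinetic trace
#'
#' Time-ordered plate-reader readings for one well/replicate.
#'
#' @param time_min Time points in minutes, strictly increasing.
#' @param signal Signal values (instrument units, >= 0), same length.
#' @param replicate Replicate identifier.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_min, signal, replicate = 1L) {
  stopifnot(length(time_min) == length(signal))
  if (length(time_min) < 2L)
    stop("a kinetic trace needs at least 2 points", call. = FALSE)
  if (any(diff(time_min) <= 0))
    stop("time points must be strictly increasing", call. = FALSE)
  if (any(signal < 0))
    stop("signal values must be non-negative", call. = FALSE)
  structure(list(time_min = as.numeric(time_min),
                 signal = as.numeric(signal),
                 replicate = replicate),
            class = "kinetic_trace")
}

#' Copper-chelation percent from endpoint absorbances
#'
#' The sample absorbance entering the chelation formula is the
#' chelator-dependent signal: `A_sample = A_full - A_sample_background`
#' (the sample+copper+chelator reading minus the sample+copper reading
#' without chelator). The chelation percent is then
#' `(A_control - A_sample) / A_control * 100`. Negative percents (a
#' sample raising apparent free copper) are reported with a warning,
#' never clipped.
#'
#' @param a_control Absorbance of the chelator + copper control (> 0).
#' @param a_full Absorbance of sample + copper + chelator.
#' @param a_sample_background Absorbance of sample + copper without
#'   chelator; default 0 when `a_full` is already background-corrected.
#' @return Chelation percent (at most 100).
#' @export
chelation_percent <- function(a_control, a_full, a_sample_background = 0) {
  if (any(a_control <= 0))
    stop("a_control must be positive", call. = FALSE)
  if (any(c(a_full, a_sample_background) < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  a_sample <- a_full - a_sample_background
  pct <- (a_control - a_sample) / a_control * 100
  if (any(pct < 0))
    warning("negative chelation percent: sample raises apparent free ",
            "copper; value reported unclipped", call. = FALSE)
  pct
}

#' Luminescence area under the curve
#'
#' Trapezoidal integral of the signal over `[0, window_minutes]`. If the
#' window edge falls inside a sampling interval the signal there is
#' obtained by linear interpolation, so the integral is exact for
#' piecewise-linear signals. The trace must start at (or before) time 0
#' and cover the full window.
#'
#' @param trace A [kinetic_trace()].
#' @param window_minutes Integration window; default 20.
#' @return AUC in signal x minutes.
#' @export
luminescence_auc <- function(trace, window_minutes = 20) {
  stopifnot(inherits(trace, "kinetic_trace"), window_minutes > 0)
  t <- trace$time_min; s <- trace$signal
  if (t[1L] > 0)
    stop("trace starts after time 0; cannot integrate from 0",
         call. = FALSE)
  if (max(t) < window_minutes)
    stop("trace ends at ", max(t), " min; window is ", window_minutes,
         " min", call. = FALSE)
  grid <- sort(unique(c(t, 0, window_minutes)))
  grid <- grid[grid >= 0 & grid <= window_minutes]
  sg <- stats::approx(t, s, xout = grid)$y
  sum(diff(grid) * (utils::head(sg, -1L) + utils::tail(sg, -1L)) / 2)
}

#' Normalize a signal to its no-metal baseline
#'
#' Ratio of the reading in the presence of metal to the same sample's
#' reading without metal (e.g. ROS-probe fluorescence with Cu(II)
#' relative to the peptide alone).
#'
#' @param signal_with_metal Reading with metal.
#' @param signal_without_metal Baseline reading (> 0).
#' @return Ratio.
#' @export
normalize_to_no_metal <- function(signal_with_metal, signal_without_metal) {
  if (any(signal_without_metal <= 0))
    stop("baseline signal must be positive", call. = FALSE)
  signal_with_metal / signal_without_metal
}

#' Replicate summary: mean, SEM, n
#'
#' Aggregates replicate measurements the way plate assays are reported
#' (mean with standard error of the mean).
#'
#' @param values Numeric vector of replicate measurements.
#' @return One-row data frame with `mean`, `sem`, `n`.
#' @export
replicate_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (!n) stop("no values to summarize", call. = FALSE)
  data.frame(mean = mean(values),
             sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
             n = n)
}
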