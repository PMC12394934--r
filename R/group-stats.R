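# Between-condition distribution comparisons: Mann-Whitney U and
# two-sample Kolmogorov-Smirnov.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples with midrank tie handling. The
#' exact two-sided p-value is used when the combined sample size is at
#' most 16 and no ties are present; otherwise the normal approximation
#' with tie correction and continuity correction is used. The switch is
#' recorded in the `method` field so reported p-values are reproducible.
#'
#' @param x,y Nonempty numeric samples.
#' @param property Optional property name carried into the result.
#' @return One-row data frame of class `group_comparison`: `property`,
#'   `test`, `statistic` (U for the first sample), `p_value`, `n_A`,
#'   `n_B`, `method`.
#' @export
mann_whitney_u <- function(x, y, property = NA_character_) {
  if (!length(x) || !length(y))
    stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 16L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(data.frame(property = property, test = "mann_whitney_u",
                       statistic = unname(ht$statistic),
                       p_value = min(1, unname(ht$p.value)),
                       n_A = length(x), n_B = length(y),
                       method = if (exact) "exact"
                                else "normal_approx_tie_corrected",
                       stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' Two-sample Kolmogorov-Smirnov test (two-sided)
#'
#' `D` is the supremum absolute difference between the two empirical
#' CDFs; the p-value is the asymptotic two-sided value.
#'
#' @param x,y Nonempty numeric samples.
#' @param property Optional property name carried into the result.
#' @return One-row `group_comparison` data frame.
#' @export
ks_two_sample <- function(x, y, property = NA_character_) {
  if (!length(x) || !length(y))
    stop("both samples must be nonempty", call. = FALSE)
  ht <- suppressWarnings(
    stats::ks.test(x, y, alternative = "two.sided", exact = FALSE))
  structure(data.frame(property = property, test = "kolmogorov_smirnov",
                       statistic = unname(ht$statistic),
                       p_value = min(1, max(0, unname(ht$p.value))),
                       n_A = length(x), n_B = length(y),
                       method = "asymptotic",
                       stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' Compare peptide properties between two populations
#'
#' Runs both tests on each requested property of the two populations'
#' property tables. Raw p-values are reported with a significance flag
#' at `alpha`; no multiplicity correction is applied by default (a
#' Bonferroni flag is available).
#'
#' @param popA,popB [peptide_population()]s (or character vectors).
#' @param properties Property columns to compare; any of `"length"`,
#'   `"gravy"`, `"pI"`, `"net_charge"`, `"mono_mass"`.
#' @param alpha Significance level; default 0.05.
#' @param bonferroni Apply Bonferroni correction across the comparisons
#'   before flagging significance (default `FALSE`, matching reporting
#'   of raw per-property p-values).
#' @param ... Passed to [peptide_properties()].
#' @return `group_comparison` data frame, one row per property x test,
#'   with a logical `significant` column.
#' @export
compare_all_properties <- function(popA, popB,
                                   properties = c("length", "pI", "gravy",
                                                  "net_charge"),
                                   alpha = 0.05, bonferroni = FALSE, ...) {
  pa <- peptide_properties(popA, ...)
  pb <- peptide_properties(popB, ...)
  bad <- setdiff(properties, names(pa))
  if (length(bad))
    stop("unknown propert(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rows <- lapply(properties, function(p)
    rbind(mann_whitney_u(pa[[p]], pb[[p]], property = p),
          ks_two_sample(pa[[p]], pb[[p]], property = p)))
  out <- do.call(rbind, rows)
  thr <- if (bonferroni) alpha / nrow(out) else alpha
  out$significant <- out$p_value < thr
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}
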