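#' Compare response-polarity counts between two populations
#'
#' Pearson chi-squared test (uncorrected) on the 2x2 table of excitatory
#' vs inhibitory first-response counts in two groups of cells; calls with
#' no significant response are excluded before tabulation.
#'
#' @param callsA,callsB Data frames of response calls with a `polarity`
#'   column (or character vectors of polarities).
#' @return A one-row tibble `test, statistic, p, n`.
#' @export
polarity_table_test <- function(callsA, callsB) {
  count_pol <- function(x) {
    pol <- if (is.data.frame(x)) x$polarity else as.character(x)
    c(exc = sum(pol == "excitatory"), inh = sum(pol == "inhibitory"))
  }
  tab <- rbind(A = count_pol(callsA), B = count_pol(callsB))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("polarity table has an empty margin")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(test = "pearson_chisq",
                 statistic = unname(res$statistic),
                 p = res$p.value, n = sum(tab))
}

#' Compare response-latency distributions between two populations
#'
#' Two-sample Kolmogorov-Smirnov test on first-significant-response
#' latencies; cells without a significant response are dropped before the
#' test (their latency is undefined).
#'
#' @param latA,latB Numeric latency samples (`NA` entries dropped).
#' @return A one-row tibble `test, statistic, p, n`.
#' @export
latency_cdf_test <- function(latA, latB) {
  latA <- latA[!is.na(latA)]
  latB <- latB[!is.na(latB)]
  if (length(latA) == 0 || length(latB) == 0) {
    rlang::abort("latency samples must be nonempty")
  }
  res <- suppressWarnings(stats::ks.test(latA, latB))
  tibble::tibble(test = "ks_two_sample",
                 statistic = unname(res$statistic),
                 p = res$p.value, n = length(latA) + length(latB))
}

#' Compare spike-count rate profiles between two populations, per odor
#'
#' Wilcoxon signed-rank test on the paired difference of normalized
#' response profiles between two cell groups, run separately for each
#' odor. With `paired = FALSE` the rank-sum (Mann-Whitney) variant is
#' used instead.
#'
#' @param profilesA,profilesB Data frames with columns `odor` and
#'   `response` (e.g. [rate_profile()] output stacked over cells).
#' @param paired Treat samples as odor-matched pairs (default `TRUE`).
#' @return A tibble with one row per odor: `odor, statistic, p, n`.
#' @export
compare_rate_profiles <- function(profilesA, profilesB, paired = TRUE) {
  odors <- intersect(unique(profilesA$odor), unique(profilesB$odor))
  purrr::map_dfr(odors, function(od) {
    a <- profilesA$response[profilesA$odor == od]
    b <- profilesB$response[profilesB$odor == od]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      rlang::abort(sprintf("need >= 2 responses per group for odor %s", od))
    }
    if (paired && all(a == b)) {
      ## all paired differences are zero: no evidence of a shift
      return(tibble::tibble(odor = od, statistic = 0, p = 1,
                            n = length(a) + length(b)))
    }
    res <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
    tibble::tibble(odor = od, statistic = unname(res$statistic),
                   p = res$p.value, n = length(a) + length(b))
  })
}
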