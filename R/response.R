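#' First significant deviation of an odor snifflet from baseline
#'
#' Scans the snifflet bins in temporal order and reports the first bin at
#' which the odor-evoked and baseline snifflets differ by more than
#' `k` combined posterior standard deviations, in log firing-rate space:
#' `|psi_odor - psi_base| > k * sigma` with
#' `sigma = sqrt(var_odor + var_base + 1/N_odor + 1/N_base)`: the
#' marginal posterior variances at the bin plus the sampling variance of
#' each fit's estimated prior-mean level (the level is a plug-in
#' estimate, `log(spikes/time)`, whose `1/N` variance the Laplace
#' posterior does not see). The sign of the difference at that bin gives
#' the response polarity (positive = excitatory). No multiplicity
#' correction is applied across bins.
#'
#' @param odor_fit,base_fit `snifflet_fit` objects sharing `D` and `K`.
#' @param k Significance threshold in combined SDs (default 3).
#' @return A one-row tibble (`response_call`): `polarity` (`"excitatory"`,
#'   `"inhibitory"` or `"none"`), `latency_bin` (snifflet bin index or
#'   `NA`), `latency_u` (dilated phase of the bin's lower edge or `NA`).
#' @export
first_significant_deviation <- function(odor_fit, base_fit, k = 3) {
  if (odor_fit$D != base_fit$D || odor_fit$K != base_fit$K) {
    rlang::abort("odor and baseline fits must share D and K")
  }
  level_var <- function(f) {
    n <- f$n_spikes
    if (is.null(n) || !is.finite(n) || n <= 0) 0 else 1 / n
  }
  d <- odor_fit$psi - base_fit$psi
  sigma <- sqrt(odor_fit$var + base_fit$var +
                  level_var(odor_fit) + level_var(base_fit))
  hit <- which(abs(d) > k * sigma)
  if (length(hit) == 0) {
    return(tibble::tibble(polarity = "none",
                          latency_bin = NA_integer_,
                          latency_u = NA_real_))
  }
  b <- hit[1]
  tibble::tibble(
    polarity = if (d[b] > 0) "excitatory" else "inhibitory",
    latency_bin = as.integer(b),
    latency_u = (b - 1) / odor_fit$D
  )
}

#' Preferred sniff phase of baseline firing
#'
#' The dilated phase at which the baseline (no-odor) snifflet rate is
#' maximal; ties resolve to the earliest bin. Reported as the midpoint of
#' the winning bin in units of inhalation durations.
#'
#' @param base_fit A `snifflet_fit` for the baseline condition.
#' @return Scalar phase `u`.
#' @export
preferred_phase <- function(base_fit) {
  j <- which.max(base_fit$psi)
  (j - 0.5) / base_fit$D
}

#' Categorize a cell-odor response across three concentrations
#'
#' Given the response calls at three concentrations of the same odor:
#' `"consistent"` if the first significant response has the same polarity
#' at all three; `"dropped"` if at least one concentration shows no
#' significant response (but not all); `"flipped"` if opposite polarities
#' occur at different concentrations; `"omitted"` if no concentration
#' shows a significant response. When a triple satisfies both the flipped
#' and the dropped condition (e.g. excitatory / none / inhibitory), the
#' polarity reversal is the stronger event and `flipped` wins; set
#' `precedence = "dropped"` to invert that.
#'
#' @param calls A data frame of exactly three response calls (rows) with a
#'   `polarity` column, ordered by concentration, or a character vector of
#'   three polarities.
#' @param precedence Which label wins when both apply (default
#'   `"flipped"`).
#' @return A single string.
#' @export
categorize_concentration <- function(calls, precedence = c("flipped",
                                                           "dropped")) {
  precedence <- match.arg(precedence)
  pol <- if (is.data.frame(calls)) calls$polarity else as.character(calls)
  if (length(pol) != 3) {
    rlang::abort("categorize_concentration() needs exactly 3 calls")
  }
  if (!all(pol %in% c("excitatory", "inhibitory", "none"))) {
    rlang::abort("polarities must be excitatory/inhibitory/none")
  }
  has_exc <- "excitatory" %in% pol
  has_inh <- "inhibitory" %in% pol
  has_none <- "none" %in% pol
  if (!has_exc && !has_inh) return("omitted")
  if (has_exc && has_inh) {
    if (has_none && precedence == "dropped") return("dropped")
    return("flipped")
  }
  if (has_none) return("dropped")
  "consistent"
}

#' Normalized spike-count response profile across odors
#'
#' Summarizes a cell's odor tuning from first-sniff spike counts: the
#' response to each odor is the change in mean count relative to baseline
#' (air), scaled so baseline maps to 0 and the strongest odor to 1:
#' `(count_odor - count_base) / (max_odor - count_base)`.
#'
#' @param counts A data frame with columns `odor` and `count` (mean spike
#'   count over the first sniff), or a named numeric vector.
#' @param baseline_count Mean baseline spike count.
#' @return A tibble `odor, response, degenerate`; `degenerate` is `TRUE`
#'   when the maximum odor count equals baseline (no scale).
#' @export
rate_profile <- function(counts, baseline_count) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(odor = names(counts),
                             count = as.numeric(counts))
  }
  if (nrow(counts) == 0) rlang::abort("rate_profile() needs >= 1 odor")
  top <- max(counts$count)
  degenerate <- isTRUE(all.equal(top, baseline_count)) || top == baseline_count
  resp <- if (degenerate) rep(NA_real_, nrow(counts)) else {
    (counts$count - baseline_count) / (top - baseline_count)
  }
  tibble::tibble(odor = counts$odor, response = resp,
                 degenerate = degenerate)
}
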