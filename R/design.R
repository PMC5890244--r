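#' Map a dilated phase to a snifflet bin
#'
#' The snifflet is a length `K*D` vector over normalized sniff time: phase
#' `u` in `[0, 1)` is the inhalation, covered by the first `D` bins of
#' width `1/D`, and `u` in `[1, K)` is the remainder of the sniff, covered
#' by the remaining `(K-1)*D` bins. Phases at or beyond `K` clamp to the
#' last bin, so the rate stays defined up to the next sniff onset.
#'
#' @param u Dilated phase(s), `u >= 0`.
#' @param D Bins per inhalation.
#' @param K Relative duration multiple.
#' @return Integer bin indices in `1..K*D`.
#' @examples
#' snifflet_bin_index(c(0, 0.5, 1, 3.99, 7.3), D = 30, K = 4)
#' @export
snifflet_bin_index <- function(u, D, K) {
  stopifnot(D >= 1, K >= 1)
  if (any(u < 0)) {
    rlang::abort("negative dilated phase: time before sniff onset was mapped to a sniff")
  }
  pmin(as.integer(floor(u * D)) + 1L, as.integer(K * D))
}

dilated_phase <- function(t, sniff, scheme, K, d_ref) {
  dt <- t - sniff$t_onset
  switch(
    scheme,
    inhalation = dt / sniff$d_inh,
    full_sniff = K * dt / sniff$d_sniff,
    two_piece = {
      rest <- sniff$d_sniff - sniff$d_inh
      ifelse(dt < sniff$d_inh,
             dt / sniff$d_inh,
             if (rest > 0) 1 + (K - 1) * (dt - sniff$d_inh) / rest else K)
    },
    none = dt / d_ref,
    rlang::abort(paste0("unknown dilation scheme: ", scheme))
  )
}

#' Bin spikes over sniff cycles and map bins to snifflet bins
#'
#' Tiles each sniff interval `[t_onset, t_end)` with bins of width `delta`
#' (a final truncated bin closes the interval), counts spikes per bin, and
#' maps each bin center to a snifflet bin under the chosen dilation scheme:
#' `"inhalation"` rescales time by the reciprocal of the inhalation
#' duration (the best-fitting choice), `"full_sniff"` by the reciprocal of
#' the whole sniff duration, `"two_piece"` dilates the inhalation and the
#' rest of the sniff separately, and `"none"` applies a fixed reference
#' duration `d_ref` (no per-sniff dilation).
#'
#' @param spikes Numeric vector of spike times (seconds), or a data frame
#'   with a column `t`.
#' @param sniffs A [sniff_train()].
#' @param delta Bin width in seconds (default 0.005).
#' @param D,K Snifflet resolution parameters (defaults 30 and 4).
#' @param scheme One of `"inhalation"`, `"full_sniff"`, `"two_piece"`,
#'   `"none"`.
#' @param d_ref Reference duration (s) for `scheme = "none"`; defaults to
#'   the median inhalation duration of `sniffs`.
#' @return A tibble of class `binned_obs` with one row per time bin
#'   (`sniff_id, t_lo, t_hi, width, u, bin, y`), carrying `delta`, `D`,
#'   `K`, `scheme`, `d_ref` and the number of spikes outside all sniffs
#'   (`n_dropped`) as attributes.
#' @export
build_design <- function(spikes, sniffs, delta = 0.005, D = 30, K = 4,
                         scheme = c("inhalation", "full_sniff",
                                    "two_piece", "none"),
                         d_ref = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(delta > 0, D >= 1, K >= 1)
  if (is.data.frame(spikes)) spikes <- spikes$t
  spikes <- sort(as.numeric(spikes))
  if (is.null(d_ref)) {
    d_ref <- if (nrow(sniffs) > 0) stats::median(sniffs$d_inh) else 0.1
  }

  rows <- purrr::map(seq_len(nrow(sniffs)), function(i) {
    sn <- sniffs[i, ]
    dur <- sn$t_end - sn$t_onset
    n_full <- floor(dur / delta + 1e-9)
    edges <- sn$t_onset + delta * seq(0, n_full)
    if (sn$t_end - edges[length(edges)] > 1e-9) {
      edges <- c(edges, sn$t_end)
    }
    if (length(edges) < 2) return(NULL)
    t_lo <- edges[-length(edges)]
    t_hi <- edges[-1]
    mid <- (t_lo + t_hi) / 2
    y <- if (length(spikes) > 0) {
      as.integer(tabulate(findInterval(spikes, edges,
                                       rightmost.closed = FALSE,
                                       left.open = FALSE),
                          nbins = length(edges))[seq_along(t_lo)])
    } else {
      integer(length(t_lo))
    }
    ## findInterval bins spikes < edges[1] into bin 0 and >= last edge into
    ## length(edges); both fall outside seq_along(t_lo) except the final
    ## slot, which we zero below by construction of nbins
    inside <- spikes >= edges[1] & spikes < edges[length(edges)]
    y <- y[seq_along(t_lo)]
    tibble::tibble(
      sniff_id = sn$sniff_id,
      t_lo = t_lo, t_hi = t_hi,
      width = t_hi - t_lo,
      u = dilated_phase(mid, sn, scheme, K, d_ref),
      y = y
    )
  })
  bins <- dplyr::bind_rows(rows)
  if (nrow(bins) == 0) {
    bins <- tibble::tibble(sniff_id = integer(), t_lo = double(),
                           t_hi = double(), width = double(), u = double(),
                           bin = integer(), y = integer())
  } else {
    bins$bin <- snifflet_bin_index(bins$u, D, K)
    bins <- dplyr::select(bins, "sniff_id", "t_lo", "t_hi", "width", "u",
                          "bin", "y")
  }
  n_inside <- sum(bins$y)
  n_dropped <- length(spikes) - n_inside
  structure(bins,
            class = c("binned_obs", class(tibble::tibble())),
            delta = delta, D = D, K = K, scheme = scheme, d_ref = d_ref,
            n_dropped = n_dropped)
}

## sufficient statistics of the Poisson likelihood: spike count and time
## exposure per snifflet bin
obs_suffstats <- function(obs) {
  m <- attr(obs, "D") * attr(obs, "K")
  n_j <- rep(0, m)
  T_j <- rep(0, m)
  if (nrow(obs) > 0) {
    agg_n <- tapply(obs$y, obs$bin, sum)
    agg_T <- tapply(obs$width, obs$bin, sum)
    idx <- as.integer(names(agg_n))
    n_j[idx] <- as.numeric(agg_n)
    T_j[idx] <- as.numeric(agg_T)
  }
  list(n = n_j, T = T_j)
}
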