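#' Construct a sniff train
#'
#' A sniff train is an ordered table of respiration cycles. Each cycle runs
#' from inhalation onset to the onset of the next cycle, and carries the
#' inhalation offset so that the inhalation duration `d_inh` (the model's
#' dilation timescale) and the dilation factor `alpha = 1/d_inh` can be
#' derived. All times are in seconds and intervals are half-open
#' `[t_onset, t_end)`.
#'
#' @param x A data frame with columns `t_onset`, `t_inh_end`, `t_end`
#'   (seconds). An optional `sniff_id` column is kept; otherwise row order
#'   is used.
#' @return A tibble of class `sniff_train` with derived columns `d_inh`,
#'   `d_sniff` and `alpha`, sorted by `t_onset`.
#' @examples
#' sniff_train(data.frame(t_onset = c(0, 0.4), t_inh_end = c(0.12, 0.55),
#'                        t_end = c(0.4, 0.8)))
#' @export
sniff_train <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("t_onset", "t_inh_end", "t_end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("sniff_train() needs columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"sniff_id" %in% names(x)) {
    x$sniff_id <- seq_len(nrow(x))
  }
  x <- dplyr::arrange(x, .data$t_onset)
  x <- dplyr::mutate(
    x,
    d_inh = .data$t_inh_end - .data$t_onset,
    d_sniff = .data$t_end - .data$t_onset,
    alpha = 1 / .data$d_inh
  )
  x <- dplyr::select(x, "sniff_id", "t_onset", "t_inh_end", "t_end",
                     "d_inh", "d_sniff", "alpha")
  validate_sniff_train(x)
  class(x) <- c("sniff_train", class(tibble::tibble()))
  x
}

validate_sniff_train <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$t_onset)) || any(!is.finite(x$t_inh_end)) ||
      any(!is.finite(x$t_end))) {
    rlang::abort("sniff times must be finite")
  }
  if (any(x$d_inh <= 0)) {
    rlang::abort("each sniff needs t_onset < t_inh_end (d_inh > 0)")
  }
  if (any(x$t_inh_end > x$t_end)) {
    rlang::abort("each sniff needs t_inh_end <= t_end")
  }
  if (is.unsorted(x$t_onset, strictly = TRUE)) {
    rlang::abort("sniff onsets must be strictly increasing")
  }
  if (nrow(x) > 1 && any(x$t_end[-nrow(x)] > x$t_onset[-1] + 1e-9)) {
    rlang::abort("sniff intervals [t_onset, t_end) must not overlap")
  }
  invisible(x)
}

empty_sniff_train <- function() {
  sniff_train(tibble::tibble(t_onset = double(), t_inh_end = double(),
                             t_end = double()))
}

#' Detect sniff cycles from a nasal pressure trace
#'
#' Inhalation is taken as a contiguous negative-pressure epoch (the usual
#' sign convention for intranasal cannula recordings; set `invert = TRUE`
#' for sensors wired the other way). The trace is low-pass smoothed and a
#' slow baseline (running median) is subtracted; an inhalation is triggered
#' wherever the cleaned signal drops below `-k_mad * mad(signal)` and the
#' epoch is then extended outward to the surrounding zero crossings, so
#' that onset and offset sit at the baseline crossings rather than at the
#' trigger threshold. Each cycle's `t_end` is the next cycle's onset; the
#' last cycle is closed at onset + median cycle duration.
#'
#' @param pressure Numeric vector, uniformly sampled pressure signal.
#' @param sample_rate Sampling rate in Hz.
#' @param lowpass_hz Smoothing cutoff in Hz (moving-average cascade with an
#'   equivalent cutoff; default 25).
#' @param baseline_window_s Width of the running-median baseline window in
#'   seconds (default 2).
#' @param k_mad Trigger threshold in units of the scaled median absolute
#'   deviation of the cleaned signal (default 0.5).
#' @param invert If `TRUE`, flip the signal before detection.
#' @param min_epoch_s Discard candidate inhalations shorter than this
#'   (default 0.01 s), guarding against residual noise crossings.
#' @return A [sniff_train()].
#' @export
detect_sniffs <- function(pressure, sample_rate,
                          lowpass_hz = 25,
                          baseline_window_s = 2,
                          k_mad = 0.5,
                          invert = FALSE,
                          min_epoch_s = 0.01) {
  if (!is.numeric(pressure)) rlang::abort("pressure must be numeric")
  if (any(!is.finite(pressure))) {
    rlang::abort("pressure trace contains non-finite samples")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate <= 0) {
    rlang::abort("sample_rate must be a single positive number")
  }
  x <- as.numeric(pressure)
  if (invert) x <- -x
  x <- lowpass_ma(x, sample_rate, lowpass_hz)

  ## slow baseline via running median over ~baseline_window_s
  k <- max(3L, round(baseline_window_s * sample_rate))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (length(x) %% 2 == 1) length(x) else length(x) - 1L)
  base <- if (k >= 3 && length(x) >= 3) {
    ## odd (point-symmetric) reflection padding keeps the running median
    ## unbiased near the edges
    h <- (k - 1L) %/% 2L
    h <- min(h, length(x) - 1L)
    n_x <- length(x)
    xp <- c(2 * x[1] - rev(x[seq_len(h) + 1L]), x,
            2 * x[n_x] - rev(x[n_x - seq_len(h)]))
    kk <- min(k, if (length(xp) %% 2 == 1) length(xp) else length(xp) - 1L)
    bm <- stats::runmed(xp, kk, endrule = "median")
    bm[(h + 1L):(h + length(x))]
  } else {
    rep(stats::median(x), length(x))
  }
  z <- x - base

  s <- stats::mad(z)
  if (s == 0) return(empty_sniff_train())
  thr <- -k_mad * s

  below <- z < thr
  if (!any(below)) return(empty_sniff_train())
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  trig_start <- starts[runs$values]
  trig_end <- ends[runs$values]

  neg <- z < 0
  n <- length(z)
  onset_idx <- integer(0)
  offset_idx <- integer(0)
  for (i in seq_along(trig_start)) {
    a <- trig_start[i]
    b <- trig_end[i]
    while (a > 1 && neg[a - 1]) a <- a - 1L
    while (b < n && neg[b + 1]) b <- b + 1L
    onset_idx <- c(onset_idx, a)
    offset_idx <- c(offset_idx, b)
  }
  keep <- !duplicated(onset_idx)
  onset_idx <- onset_idx[keep]
  offset_idx <- offset_idx[keep]
  dur <- (offset_idx - onset_idx + 1L) / sample_rate
  keep <- dur >= min_epoch_s
  onset_idx <- onset_idx[keep]
  offset_idx <- offset_idx[keep]
  if (length(onset_idx) == 0) return(empty_sniff_train())

  t_onset <- (onset_idx - 1L) / sample_rate
  t_inh_end <- offset_idx / sample_rate
  if (length(t_onset) > 1) {
    cycle <- stats::median(diff(t_onset))
    t_end <- c(t_onset[-1], t_onset[length(t_onset)] + cycle)
  } else {
    t_end <- max(t_inh_end, n / sample_rate)
  }
  ## closing duration may not reach past the inhalation it closes
  t_end <- pmax(t_end, t_inh_end + 1 / sample_rate)
  sniff_train(tibble::tibble(t_onset = t_onset, t_inh_end = t_inh_end,
                             t_end = t_end))
}

## zero-phase smoothing: two passes of a centered moving average whose
## length approximates a first-order low-pass at `cutoff_hz`
lowpass_ma <- function(x, sample_rate, cutoff_hz) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= sample_rate / 2) {
    return(x)
  }
  w <- max(1L, round(sample_rate / (2 * cutoff_hz)))
  if (w <= 1) return(x)
  kern <- rep(1 / w, w)
  pad <- function(v) c(rep(v[1], w), v, rep(v[length(v)], w))
  for (pass in 1:2) {
    xp <- pad(x)
    sm <- stats::filter(xp, kern, sides = 2)
    x <- as.numeric(sm[(w + 1):(w + length(x))])
  }
  x
}

#' Keep sniffs with inhalation longer than a threshold
#'
#' Analyses are typically restricted to slower sniffs; the conventional
#' split is an inhalation duration above 100 ms, which covers about three
#' quarters of sniffs in awake freely breathing mice.
#'
#' @param train A [sniff_train()].
#' @param min_d_inh Threshold in seconds; sniffs with `d_inh > min_d_inh`
#'   are kept (strict). Default 0.1.
#' @return A filtered `sniff_train`, order preserved.
#' @export
filter_by_inhalation <- function(train, min_d_inh = 0.1) {
  stopifnot(min_d_inh >= 0)
  out <- dplyr::filter(train, .data$d_inh > min_d_inh)
  class(out) <- class(train)
  out
}

#' First sniff at or after an event
#'
#' @param train A [sniff_train()].
#' @param t_event Event time in seconds.
#' @return A one-row `sniff_train` (the sniff with the smallest
#'   `t_onset >= t_event`), or a zero-row one if no sniff follows the event.
#' @export
first_sniff_after <- function(train, t_event) {
  stopifnot(is.finite(t_event))
  idx <- which(train$t_onset >= t_event)
  out <- if (length(idx) == 0) train[0, ] else train[min(idx), ]
  class(out) <- class(train)
  out
}

#' Sniffs inside pre-odor baseline windows
#'
#' Baseline activity is estimated from the window preceding each odor
#' onset; the default window is the three seconds before onset.
#'
#' @param train A [sniff_train()].
#' @param odor_onsets Numeric vector of odor-onset times (seconds).
#' @param window Window length in seconds (default 3).
#' @return A `sniff_train` of sniffs whose onset lies in
#'   `[t_odor - window, t_odor)` for at least one odor onset; each sniff
#'   appears once even if windows overlap.
#' @export
baseline_sniffs <- function(train, odor_onsets, window = 3) {
  stopifnot(window > 0)
  if (length(odor_onsets) == 0 || nrow(train) == 0) {
    out <- train[0, ]
    class(out) <- class(train)
    return(out)
  }
  keep <- vapply(train$t_onset, function(t0) {
    any(t0 >= odor_onsets - window & t0 < odor_onsets)
  }, logical(1))
  out <- train[keep, ]
  class(out) <- class(train)
  out
}
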