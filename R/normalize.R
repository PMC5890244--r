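curves_from_fits <- function(fits, scale = c("rate", "log")) {
  scale <- match.arg(scale)
  if (inherits(fits, "snifflet_fit")) fits <- list(fits)
  if (is.data.frame(fits)) {
    rlang::abort("expected a (named) list of snifflet_fit objects or a numeric matrix")
  }
  if (is.matrix(fits)) return(fits)
  stopifnot(length(fits) >= 1)
  mat <- do.call(rbind, lapply(fits, function(f) {
    if (inherits(f, "snifflet_fit")) {
      if (scale == "rate") exp(f$psi) else f$psi
    } else {
      as.numeric(f)
    }
  }))
  rownames(mat) <- names(fits)
  mat
}

#' Normalize a cell's snifflets for population display
#'
#' One affine transform per cell, applied identically to all of that
#' cell's odor curves: subtract the across-odor mean of the value at
#' inhalation onset (bin 1), then divide by the across-odor maximum of
#' the centered curves. Afterwards the mean onset value across odors is 0
#' and the global peak is 1, so curves from different cells are
#' comparable. Degenerate cells (zero maximum after centering) are
#' flagged and their curves dropped, mirroring the convention of omitting
#' cells whose responses are best described as constant.
#'
#' @param fits Named list of `snifflet_fit` objects (one per odor), a
#'   numeric matrix (odors x bins), or a list of numeric vectors.
#' @param scale Work on the exponentiated rate scale (default) or log.
#' @return A tibble `odor, bin, value`; zero rows with attribute
#'   `degenerate = TRUE` if the cell is degenerate.
#' @export
normalize_cell_set <- function(fits, scale = c("rate", "log")) {
  mat <- curves_from_fits(fits, scale)
  onset_mean <- mean(mat[, 1])
  centered <- mat - onset_mean
  peak <- max(centered)
  if (peak <= 0) {
    out <- tibble::tibble(odor = character(), bin = integer(),
                          value = double())
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  norm <- centered / peak
  odors <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  out <- tibble::tibble(
    odor = rep(odors, each = ncol(norm)),
    bin = rep(seq_len(ncol(norm)), times = nrow(norm)),
    value = as.numeric(t(norm))
  )
  attr(out, "degenerate") <- FALSE
  out
}

#' Normalize a cell's snifflets by its largest response amplitude
#'
#' Divides each odor curve's deviation from the cell's constant (prior
#' mean) rate by the cell's largest across-odor amplitude, where the
#' amplitude of a curve is its maximum absolute deviation from that
#' constant rate on the exponentiated scale. The odor with the largest
#' amplitude attains |value| = 1; an excitatory peak reaches exactly 1.
#'
#' @param fits Named list of `snifflet_fit` objects (one per odor).
#' @param ref_rate Reference rate to measure deviations from; defaults to
#'   the exponentiated prior mean of the first fit.
#' @return A tibble `odor, bin, value`; attribute `degenerate = TRUE` when
#'   the largest amplitude is zero.
#' @export
normalize_by_peak <- function(fits, ref_rate = NULL) {
  if (inherits(fits, "snifflet_fit")) fits <- list(fits)
  if (is.null(ref_rate)) {
    f1 <- fits[[1]]
    ref_rate <- if (inherits(f1, "snifflet_fit")) exp(f1$prior_mean) else 0
  }
  mat <- curves_from_fits(fits, "rate")
  dev <- mat - ref_rate
  amp <- max(abs(dev))
  if (amp == 0) {
    out <- tibble::tibble(odor = character(), bin = integer(),
                          value = double())
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  norm <- dev / amp
  odors <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  out <- tibble::tibble(
    odor = rep(odors, each = ncol(norm)),
    bin = rep(seq_len(ncol(norm)), times = nrow(norm)),
    value = as.numeric(t(norm))
  )
  attr(out, "degenerate") <- FALSE
  out
}

#' Across-cell mean curve with standard error
#'
#' @param curves A list of equal-length numeric vectors (one per cell), or
#'   a numeric matrix (cells x bins).
#' @return A tibble `bin, mean, sem, n_cells`; with a single cell the SEM
#'   is 0.
#' @export
population_mean <- function(curves) {
  if (is.list(curves) && !is.data.frame(curves)) {
    lens <- lengths(curves)
    if (length(curves) == 0) rlang::abort("population_mean() needs >= 1 cell")
    if (length(unique(lens)) != 1) rlang::abort("curves must have equal length")
    curves <- do.call(rbind, curves)
  }
  if (!is.matrix(curves)) rlang::abort("curves must be a matrix or list of vectors")
  n <- nrow(curves)
  if (n == 0) rlang::abort("population_mean() needs >= 1 cell")
  mu <- colMeans(curves)
  sem <- if (n > 1) apply(curves, 2, stats::sd) / sqrt(n) else rep(0, ncol(curves))
  tibble::tibble(bin = seq_len(ncol(curves)), mean = mu, sem = sem,
                 n_cells = n)
}
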