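#' Specification for a synthetic population dataset
#'
#' Collects every parameter of the generator in one object. Defaults
#' describe the study conditions the generator emulates: a bimodal
#' slow/fast inhalation-duration mixture dominated by slow sniffs,
#' first-sniff odor responses riding on a mildly phase-tuned baseline of
#' 8 spikes/s, and short-latency light responses for tagged cells.
#'
#' @param n_cells Number of cells.
#' @param n_trials Trials per cell and condition.
#' @param odors Data frame with columns `odor`, `mode` (one of
#'   `"stereotyped"`, `"diverse"`, `"inhibitory"`, `"null"`) and
#'   optionally `conc_pattern` (`"consistent"`, `"dropped"`, `"flipped"`,
#'   or `"none"`; how the response deviation transforms across
#'   concentrations).
#' @param concentrations Character vector of concentration labels, ordered
#'   low to high (default a single `"C0"`).
#' @param sniff_params List: log-normal medians (s) and common `sdlog`
#'   for fast and slow inhalations, fast-component weight, exhalation
#'   median.
#' @param baseline_rate Baseline firing rate, spikes/s (default 8).
#' @param baseline_mod_sd SD of the smooth log-rate modulation of the
#'   baseline snifflet (default 0.2).
#' @param light List: `tag_fraction` of cells carrying a light response,
#'   `latency` (s), `gain` (response rate as a multiple of baseline),
#'   `duration` (s), `n_trials` light and control trials each.
#' @param n_baseline_sniffs Sniffs preceding each odor onset (default 10,
#'   enough to tile a 3 s pre-odor window).
#' @param D,K Snifflet parameterization of the ground-truth templates.
#' @param seed Master seed; every cell and condition derives its own
#'   stream from it, so the dataset is reproducible piecewise.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 30,
                           n_trials = 60,
                           odors = tibble::tibble(
                             odor = c("strong", "weak"),
                             mode = c("stereotyped", "diverse"),
                             conc_pattern = c("consistent", "none")),
                           concentrations = "C0",
                           sniff_params = list(median_fast = 0.060,
                                               median_slow = 0.150,
                                               sdlog = 0.40,
                                               weight_fast = 0.15,
                                               median_exh = 0.200),
                           baseline_rate = 8,
                           baseline_mod_sd = 0.2,
                           light = list(tag_fraction = 0.5,
                                        latency = 0.006,
                                        gain = 15,
                                        duration = 0.010,
                                        n_trials = 50),
                           n_baseline_sniffs = 10,
                           D = 30, K = 4,
                           seed = 1) {
  odors <- tibble::as_tibble(odors)
  if (!"conc_pattern" %in% names(odors)) odors$conc_pattern <- "none"
  stopifnot(n_cells >= 0, n_trials >= 0,
            sniff_params$weight_fast >= 0, sniff_params$weight_fast <= 1)
  structure(list(n_cells = n_cells, n_trials = n_trials, odors = odors,
                 concentrations = concentrations,
                 sniff_params = sniff_params,
                 baseline_rate = baseline_rate,
                 baseline_mod_sd = baseline_mod_sd,
                 light = light, n_baseline_sniffs = n_baseline_sniffs,
                 D = D, K = K, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample a sniff train
#'
#' Inhalation durations come from a two-component log-normal mixture
#' (fast and slow modes), exhalation durations from a single log-normal;
#' cycles are consecutive and non-overlapping, starting at `t0`.
#'
#' @param n Number of sniffs.
#' @param sniff_params See [synthetic_spec()].
#' @param seed Integer seed.
#' @param t0 Start time of the first cycle (default 0).
#' @return A [sniff_train()].
#' @export
sample_sniff_train <- function(n,
                               sniff_params = synthetic_spec()$sniff_params,
                               seed = 1, t0 = 0) {
  p <- sniff_params
  if (is.null(p$median_fast) || p$median_fast <= 0 ||
      is.null(p$median_slow) || p$median_slow <= 0 ||
      is.null(p$sdlog) || p$sdlog < 0 ||
      is.null(p$weight_fast) || p$weight_fast < 0 || p$weight_fast > 1 ||
      is.null(p$median_exh) || p$median_exh <= 0) {
    rlang::abort("invalid sniff_params")
  }
  if (n == 0) return(empty_sniff_train())
  with_seed_local(seed, {
    fast <- stats::runif(n) < p$weight_fast
    med <- ifelse(fast, p$median_fast, p$median_slow)
    d_inh <- stats::rlnorm(n, meanlog = log(med), sdlog = p$sdlog)
    d_exh <- stats::rlnorm(n, meanlog = log(p$median_exh), sdlog = p$sdlog)
    t_onset <- t0 + cumsum(c(0, (d_inh + d_exh)[-n]))
    sniff_train(tibble::tibble(
      t_onset = t_onset,
      t_inh_end = t_onset + d_inh,
      t_end = t_onset + d_inh + d_exh
    ))
  })
}

## smooth zero-mean curve over m bins: squared-exponential Gaussian
## process with length-scale `len`, marginal sd `sd`
gp_curve <- function(m, len, sd) {
  if (sd == 0) return(rep(0, m))
  C <- asd_covariance(m, 2 * log(sd), len)
  as.numeric(t(chol(C)) %*% stats::rnorm(m))
}

## taper weights pulling late-sniff deviations toward baseline, so the
## sparsely sampled tail of the sniff stays identifiable
tail_taper <- function(m) {
  j <- seq_len(m)
  knee <- 0.6 * m
  w <- rep(1, m)
  late <- j > knee
  w[late] <- 1 - 0.7 * (j[late] - knee) / (m - knee)
  w
}

#' Ground-truth snifflet template
#'
#' Builds a log-rate deviation profile over `K*D` snifflet bins for one
#' response mode, added to a baseline log rate: `"stereotyped"` is an
#' early excitatory transient (Gaussian bump centered in the first third
#' of inhalation, gain at least `log 3`) followed by a small smooth tail;
#' `"diverse"` is a smooth random curve (Gaussian-process draw,
#' length-scale about `D/3`) whose first excursion is positive or
#' negative at random; `"inhibitory"` is an early rate suppression;
#' `"constant"`/`"null"` are flat. Deviations are tapered toward zero in
#' the late part of the sniff.
#'
#' @param mode One of `"stereotyped"`, `"diverse"`, `"inhibitory"`,
#'   `"constant"`, `"null"`.
#' @param D,K Snifflet parameterization.
#' @param baseline_log_rate Flat log firing rate the deviation rides on
#'   (default `log(8)`).
#' @param seed Integer seed.
#' @return Numeric length-`K*D` log-rate vector with attribute
#'   `deviation` (the mode-specific part, before adding the baseline).
#' @export
make_truth_snifflet <- function(mode, D = 30, K = 4,
                                baseline_log_rate = log(8), seed = 1) {
  mode <- match.arg(mode, c("stereotyped", "diverse", "inhibitory",
                            "constant", "null"))
  m <- D * K
  dev <- with_seed_local(seed, {
    switch(
      mode,
      constant = ,
      null = rep(0, m),
      stereotyped = {
        center <- stats::runif(1, 0.1 * D, D / 3)
        width <- stats::runif(1, D / 10, D / 6)
        gain <- log(3) * stats::runif(1, 1.15, 1.6)
        bump <- gain * exp(-(seq_len(m) - center)^2 / (2 * width^2))
        tail_mod <- gp_curve(m, D / 3, 0.4)
        tail_w <- pmin(pmax((seq_len(m) - D) / D, 0), 1)
        bump + tail_mod * tail_w
      },
      inhibitory = {
        center <- stats::runif(1, 0.1 * D, D / 2)
        width <- stats::runif(1, D / 8, D / 4)
        gain <- stats::runif(1, 1.2, 1.8)
        -gain * exp(-(seq_len(m) - center)^2 / (2 * width^2))
      },
      diverse = gp_curve(m, D / 3, 0.6)
    )
  })
  dev <- dev * tail_taper(m)
  out <- baseline_log_rate + dev
  attr(out, "deviation") <- dev
  out
}

#' Simulate spikes from a dilated snifflet
#'
#' Inhomogeneous-Poisson sampling by thinning: within each sniff the rate
#' is `exp(psi[j(u(t))])` under the given dilation scheme (piecewise
#' constant in time), candidate spikes are drawn homogeneously at the
#' sniff's maximum rate and accepted with probability rate/max. Spikes
#' occur only inside sniff intervals.
#'
#' @param psi Length-`K*D` log-rate template (spikes/s); `K*D` inferred
#'   from `D`.
#' @param sniffs A [sniff_train()].
#' @param D,K Snifflet parameterization of `psi`.
#' @param scheme Dilation scheme, see [build_design()].
#' @param d_ref Reference duration for `scheme = "none"`.
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times (seconds).
#' @export
sample_spike_train <- function(psi, sniffs, D = 30, K = 4,
                               scheme = "inhalation", d_ref = NULL,
                               seed = 1) {
  stopifnot(length(psi) == D * K)
  if (is.null(d_ref)) {
    d_ref <- if (nrow(sniffs) > 0) stats::median(sniffs$d_inh) else 0.1
  }
  if (nrow(sniffs) == 0 || all(psi == -Inf)) return(numeric(0))
  rate_max <- exp(max(psi))
  with_seed_local(seed, {
    out <- lapply(seq_len(nrow(sniffs)), function(i) {
      sn <- sniffs[i, ]
      dur <- sn$t_end - sn$t_onset
      n_cand <- stats::rpois(1, rate_max * dur)
      if (n_cand == 0) return(numeric(0))
      t <- sn$t_onset + stats::runif(n_cand) * dur
      u <- dilated_phase(t, sn, scheme, K, d_ref)
      r <- exp(psi[snifflet_bin_index(pmax(u, 0), D, K)])
      t[stats::runif(n_cand) < r / rate_max]
    })
    sort(unlist(out))
  })
}

## reversal phenotype for "flipped" concentration series: a broad
## suppression spanning the inhalation and early rest of sniff (a narrow
## negated bump would carry too few spikes to clear a pointwise 3-sigma
## criterion in log-rate space)
broad_suppression <- function(D, K, depth = 2) {
  m <- D * K
  j <- seq_len(m)
  -depth * exp(-(j - 0.5 * D)^2 / (2 * (0.6 * D)^2)) * tail_taper(m)
}

conc_multipliers <- function(pattern, n_conc) {
  if (n_conc == 1) return(1)
  base <- switch(pattern,
                 consistent = seq(0.8, 1.2, length.out = n_conc),
                 dropped = c(0, rep(1, n_conc - 1)),
                 flipped = c(1, rep(-1, n_conc - 1)),
                 none = rep(1, n_conc),
                 rlang::abort(paste0("unknown conc_pattern: ", pattern)))
  base
}

#' Generate a full synthetic population dataset
#'
#' Builds, for every cell, a session of consecutive sniffs covering all
#' odor x concentration conditions: each trial is a block of baseline
#' sniffs followed by an odor onset placed just before the next sniff, so
#' the first sniff after odor onset carries the odor response template
#' and the preceding three seconds carry baseline activity. Spikes are
#' drawn by [sample_spike_train()] from the cell's baseline template
#' (everywhere) or from baseline + odor deviation (on odor sniffs).
#' Tagged cells additionally receive light-trial blocks in which a light
#' pulse at inhalation onset evokes a short-latency burst.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (tibbles `spikes`, `sniffs`, `trials`,
#'   `light_trials`, `cells`) and `truth` (per cell-condition templates
#'   and per-cell tags, for scoring).
#' @export
make_population_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  D <- spec$D
  K <- spec$K
  b <- log(spec$baseline_rate)
  n_conc <- length(spec$concentrations)

  all_spikes <- list()
  all_sniffs <- list()
  all_trials <- list()
  all_light <- list()
  truth_templates <- list()
  cells <- tibble::tibble(cell_id = integer(), tagged = logical())

  for (cell in seq_len(spec$n_cells)) {
    tagged <- with_seed_local(child_seed(spec$seed, cell, 9001),
                              stats::runif(1) < spec$light$tag_fraction)
    base_dev <- with_seed_local(child_seed(spec$seed, cell, 1),
                                gp_curve(D * K, D / 3, spec$baseline_mod_sd))
    base_dev <- base_dev * tail_taper(D * K)
    psi_base <- b + base_dev

    conds <- tidyr::expand_grid(odor = spec$odors$odor,
                                concentration = spec$concentrations)
    conds <- dplyr::left_join(conds, spec$odors, by = "odor")

    ## one long session per cell; conditions occupy consecutive blocks
    n_per_trial <- spec$n_baseline_sniffs + 1
    n_sniffs_total <- nrow(conds) * spec$n_trials * n_per_trial + 1
    sniffs <- sample_sniff_train(n_sniffs_total, spec$sniff_params,
                                 seed = child_seed(spec$seed, cell, 2))
    d_ref <- stats::median(sniffs$d_inh)

    trials <- list()
    spk <- list()
    cursor <- 1L
    trial_no <- 0L
    for (ci in seq_len(nrow(conds))) {
      od <- conds$odor[ci]
      mode <- conds$mode[ci]
      conc_i <- match(conds$concentration[ci], spec$concentrations)
      dev <- attr(make_truth_snifflet(
        mode, D, K, baseline_log_rate = b,
        seed = child_seed(spec$seed, cell, 10 + match(od, spec$odors$odor))),
        "deviation")
      mult <- conc_multipliers(conds$conc_pattern[ci], n_conc)[conc_i]
      psi_odor <- if (mult >= 0) {
        psi_base + mult * dev
      } else {
        psi_base + abs(mult) * broad_suppression(D, K)
      }
      truth_templates[[length(truth_templates) + 1]] <- tibble::tibble(
        cell_id = cell, odor = od, concentration = conds$concentration[ci],
        mode = mode, conc_multiplier = mult,
        psi_base = list(psi_base), psi_odor = list(psi_odor))

      for (tr in seq_len(spec$n_trials)) {
        trial_no <- trial_no + 1L
        base_idx <- cursor:(cursor + spec$n_baseline_sniffs - 1L)
        odor_idx <- cursor + spec$n_baseline_sniffs
        cursor <- cursor + n_per_trial
        base_block <- sniffs[base_idx, ]
        odor_sniff <- sniffs[odor_idx, ]
        class(base_block) <- class(sniffs)
        class(odor_sniff) <- class(sniffs)
        t_on <- odor_sniff$t_onset - 0.005
        trials[[length(trials) + 1]] <- tibble::tibble(
          cell_id = cell, trial_id = trial_no, odor = od,
          concentration = conds$concentration[ci], t_odor_on = t_on)
        spk[[length(spk) + 1]] <- sample_spike_train(
          psi_base, base_block, D, K, scheme = "inhalation", d_ref = d_ref,
          seed = child_seed(spec$seed, cell, trial_no, 3))
        spk[[length(spk) + 1]] <- sample_spike_train(
          psi_odor, odor_sniff, D, K, scheme = "inhalation", d_ref = d_ref,
          seed = child_seed(spec$seed, cell, trial_no, 4))
      }
    }

    ## light-identification block appended after the last condition
    lt <- spec$light
    if (lt$n_trials > 0) {
      t_start <- max(sniffs$t_end) + 5
      light_sniffs <- sample_sniff_train(
        2 * lt$n_trials, spec$sniff_params,
        seed = child_seed(spec$seed, cell, 5), t0 = t_start)
      is_light <- rep(c(TRUE, FALSE), lt$n_trials)
      spk[[length(spk) + 1]] <- sample_spike_train(
        psi_base, light_sniffs, D, K, scheme = "inhalation", d_ref = d_ref,
        seed = child_seed(spec$seed, cell, 6))
      if (tagged) {
        pulse_t <- light_sniffs$t_onset[is_light]
        burst <- with_seed_local(child_seed(spec$seed, cell, 7), {
          lapply(pulse_t, function(t0) {
            lam <- lt$gain * spec$baseline_rate * lt$duration
            n <- stats::rpois(1, lam)
            t0 + lt$latency + stats::runif(n) * lt$duration
          })
        })
        spk[[length(spk) + 1]] <- sort(unlist(burst))
      }
      all_light[[length(all_light) + 1]] <- tibble::tibble(
        cell_id = cell,
        t_sniff_on = light_sniffs$t_onset,
        light = is_light)
      sniffs_out <- dplyr::bind_rows(tibble::as_tibble(sniffs),
                                     tibble::as_tibble(light_sniffs))
    } else {
      sniffs_out <- tibble::as_tibble(sniffs)
    }

    all_spikes[[cell]] <- tibble::tibble(cell_id = cell,
                                         t = sort(unlist(spk)))
    sniffs_out$cell_id <- cell
    all_sniffs[[cell]] <- sniffs_out
    all_trials[[cell]] <- dplyr::bind_rows(trials)
    cells <- dplyr::bind_rows(cells,
                              tibble::tibble(cell_id = cell, tagged = tagged))
  }

  empty_or <- function(lst, schema) {
    out <- dplyr::bind_rows(lst)
    if (nrow(out) == 0) schema else out
  }
  dataset <- list(
    spikes = empty_or(all_spikes,
                      tibble::tibble(cell_id = integer(), t = double())),
    sniffs = empty_or(all_sniffs, tibble::tibble(
      sniff_id = integer(), t_onset = double(), t_inh_end = double(),
      t_end = double(), d_inh = double(), d_sniff = double(),
      alpha = double(), cell_id = integer())),
    trials = empty_or(all_trials, tibble::tibble(
      cell_id = integer(), trial_id = integer(), odor = character(),
      concentration = character(), t_odor_on = double())),
    light_trials = empty_or(all_light, tibble::tibble(
      cell_id = integer(), t_sniff_on = double(), light = logical())),
    cells = cells,
    meta = list(D = D, K = K, seed = spec$seed,
                baseline_rate = spec$baseline_rate)
  )
  list(dataset = dataset,
       truth = list(templates = dplyr::bind_rows(truth_templates),
                    cells = cells))
}
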