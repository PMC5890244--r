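count_spikes_per_sniff <- function(spike_t, sniffs) {
  if (nrow(sniffs) == 0) return(numeric(0))
  vapply(seq_len(nrow(sniffs)), function(i) {
    sum(spike_t >= sniffs$t_onset[i] & spike_t < sniffs$t_end[i])
  }, numeric(1))
}

#' Run the full response analysis on a dataset
#'
#' For every cell: fits the baseline snifflet from the sniffs in the
#' three seconds before each odor onset, then for every odor and
#' concentration fits the odor snifflet from the first sniff after each
#' onset (both restricted to inhalations longer than `min_d_inh`), calls
#' the first significant deviation, computes spike-count response
#' profiles, categorizes concentration series when three concentrations
#' are present, classifies light responsiveness from the light-trial
#' PSTHs, and assembles population summaries and between-group tests
#' (tagged vs untagged cells). Per-cell failures are reported and
#' skipped. Deterministic for a fixed dataset and configuration.
#'
#' @param dataset A dataset list ([make_population_dataset()]'s
#'   `$dataset`, or [load_dataset()] output).
#' @param config A [snifflet_config()].
#' @param min_d_inh Inhalation-duration filter in seconds (default 0.1).
#' @param baseline_window Pre-odor baseline window in seconds (default 3).
#' @param k_sig Significance threshold in combined SDs (default 3).
#' @return A list of class `snifflet_results`: tibbles `calls`,
#'   `categories`, `profiles`, `opto`, `tests`, a `population` tibble of
#'   mean normalized curves per group and odor, and the per-cell `fits`.
#' @export
run_full_analysis <- function(dataset, config = snifflet_config(),
                              min_d_inh = 0.1, baseline_window = 3,
                              k_sig = 3) {
  empty <- structure(list(
    calls = tibble::tibble(), categories = tibble::tibble(),
    profiles = tibble::tibble(), opto = tibble::tibble(),
    tests = tibble::tibble(), population = tibble::tibble(),
    fits = list(), config = config), class = "snifflet_results")
  if (nrow(dataset$trials) == 0) return(empty)

  cell_ids <- sort(unique(dataset$trials$cell_id))
  concs <- unique(dataset$trials$concentration)
  tagged_lookup <- if (!is.null(dataset$cells)) {
    stats::setNames(dataset$cells$tagged, dataset$cells$cell_id)
  } else NULL

  calls <- list(); profiles <- list(); fits <- list(); opto <- list()
  for (cell in cell_ids) {
    res <- tryCatch(
      analyze_cell(cell, dataset, config, min_d_inh, baseline_window,
                   k_sig),
      error = function(e) {
        rlang::inform(sprintf("cell %s skipped: %s", cell,
                              conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    calls[[length(calls) + 1]] <- res$calls
    profiles[[length(profiles) + 1]] <- res$profile
    fits[[as.character(cell)]] <- res$fits
    if (!is.null(res$opto)) opto[[length(opto) + 1]] <- res$opto
  }
  calls <- dplyr::bind_rows(calls)
  profiles <- dplyr::bind_rows(profiles)
  opto <- dplyr::bind_rows(opto)

  categories <- tibble::tibble()
  if (length(concs) == 3 && nrow(calls) > 0) {
    categories <- calls |>
      dplyr::group_by(.data$cell_id, .data$odor) |>
      dplyr::filter(dplyr::n() == 3) |>
      dplyr::arrange(match(.data$concentration, concs), .by_group = TRUE) |>
      dplyr::summarise(
        category = categorize_concentration(.data$polarity),
        .groups = "drop")
  }

  population <- tibble::tibble()
  tests <- tibble::tibble()
  if (!is.null(tagged_lookup) && nrow(calls) > 0) {
    calls$tagged <- unname(tagged_lookup[as.character(calls$cell_id)])
    population <- population_curves(fits, tagged_lookup)
    tests <- group_tests(calls, profiles, tagged_lookup)
  }

  structure(list(calls = calls, categories = categories,
                 profiles = profiles, opto = opto, tests = tests,
                 population = population, fits = fits, config = config),
            class = "snifflet_results")
}

analyze_cell <- function(cell, dataset, config, min_d_inh,
                         baseline_window, k_sig) {
  spk <- dataset$spikes$t[dataset$spikes$cell_id == cell]
  sn_tab <- dataset$sniffs[dataset$sniffs$cell_id == cell, ]
  sniffs <- sniff_train(sn_tab[, c("t_onset", "t_inh_end", "t_end")])
  trials <- dataset$trials[dataset$trials$cell_id == cell, ]

  base_sn <- baseline_sniffs(sniffs, trials$t_odor_on, baseline_window)
  base_sn <- filter_by_inhalation(base_sn, min_d_inh)
  if (nrow(base_sn) == 0) rlang::abort("no usable baseline sniffs")
  if (is.null(config$d_ref)) config$d_ref <- stats::median(sniffs$d_inh)
  base_fit <- fit_snifflet(spk, base_sn, config)
  base_count <- mean(count_spikes_per_sniff(spk, base_sn))

  conds <- dplyr::distinct(trials, .data$odor, .data$concentration)
  cell_calls <- list(); odor_fits <- list(); counts <- numeric(0)
  for (i in seq_len(nrow(conds))) {
    tri <- trials[trials$odor == conds$odor[i] &
                    trials$concentration == conds$concentration[i], ]
    first <- dplyr::bind_rows(lapply(tri$t_odor_on, function(t0) {
      tibble::as_tibble(first_sniff_after(sniffs, t0))
    }))
    first <- sniff_train(first[!duplicated(first$sniff_id),
                               c("sniff_id", "t_onset", "t_inh_end", "t_end")])
    first <- filter_by_inhalation(first, min_d_inh)
    if (nrow(first) == 0) next
    ofit <- fit_snifflet(spk, first, config)
    cfit <- fit_constant(spk, first, config)
    call <- first_significant_deviation(ofit, base_fit, k = k_sig)
    cell_calls[[length(cell_calls) + 1]] <- dplyr::bind_cols(
      tibble::tibble(cell_id = cell, odor = conds$odor[i],
                     concentration = conds$concentration[i],
                     n_sniffs = nrow(first),
                     constant_best = cfit$log_evidence >= ofit$log_evidence),
      call)
    key <- paste(conds$odor[i], conds$concentration[i], sep = "@")
    odor_fits[[key]] <- ofit
    counts[key] <- mean(count_spikes_per_sniff(spk, first))
  }
  if (length(cell_calls) == 0) rlang::abort("no analyzable conditions")

  prof <- rate_profile(tibble::tibble(odor = names(counts),
                                      count = unname(counts)), base_count)
  prof$cell_id <- cell

  opto_row <- NULL
  if (!is.null(dataset$light_trials) && nrow(dataset$light_trials) > 0) {
    lt <- dataset$light_trials[dataset$light_trials$cell_id == cell, ]
    if (nrow(lt) > 0) {
      p_light <- psth(spk, lt$t_sniff_on[lt$light])
      p_ctrl <- psth(spk, lt$t_sniff_on[!lt$light])
      cls <- classify_light_response(p_light, p_ctrl)
      opto_row <- dplyr::bind_cols(tibble::tibble(cell_id = cell), cls)
    }
  }

  list(calls = dplyr::bind_rows(cell_calls), profile = prof,
       fits = list(baseline = base_fit, odor = odor_fits),
       opto = opto_row)
}

population_curves <- function(fits, tagged_lookup) {
  rows <- list()
  for (cell in names(fits)) {
    of <- fits[[cell]]$odor
    if (length(of) == 0) next
    norm <- normalize_by_peak(of)
    if (isTRUE(attr(norm, "degenerate"))) next
    norm$cell_id <- as.integer(cell)
    rows[[length(rows) + 1]] <- norm
  }
  if (length(rows) == 0) return(tibble::tibble())
  curves <- dplyr::bind_rows(rows)
  curves$tagged <- unname(tagged_lookup[as.character(curves$cell_id)])
  curves |>
    dplyr::group_by(.data$tagged, .data$odor, .data$bin) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
      n_cells = dplyr::n(), .groups = "drop")
}

group_tests <- function(calls, profiles, tagged_lookup) {
  out <- list()
  for (od in unique(calls$odor)) {
    a <- calls[calls$odor == od & calls$tagged, ]
    b <- calls[calls$odor == od & !calls$tagged, ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    chi <- tryCatch(polarity_table_test(a, b), error = function(e) NULL)
    if (!is.null(chi)) {
      chi$odor <- od
      out[[length(out) + 1]] <- chi
    }
    ks <- tryCatch(latency_cdf_test(a$latency_u, b$latency_u),
                   error = function(e) NULL)
    if (!is.null(ks)) {
      ks$odor <- od
      out[[length(out) + 1]] <- ks
    }
  }
  dplyr::bind_rows(out)
}

#' Write analysis outputs to disk
#'
#' Writes the result tables as CSV, a JSON summary, and summary figures
#' (population snifflet curves, latency CDFs, concentration-category
#' bars) into `out_dir`.
#'
#' @param results A [run_full_analysis()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_report <- function(results, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) rlang::abort("cannot create output directory")
  files <- character(0)
  for (nm in c("calls", "categories", "profiles", "opto", "tests",
               "population")) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(results[[nm]]), p)
    files <- c(files, p)
  }
  summ <- list(
    n_cells = length(results$fits),
    n_calls = nrow(results$calls),
    n_responsive = if (nrow(results$calls) > 0)
      sum(results$calls$polarity != "none") else 0,
    categories = if (nrow(results$categories) > 0)
      as.list(table(results$categories$category)) else list(),
    n_light_responsive = if (nrow(results$opto) > 0)
      sum(results$opto$responsive) else 0,
    config = results$config[c("delta", "D", "K", "scheme")]
  )
  pj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, pj, auto_unbox = TRUE, digits = NA)
  files <- c(files, pj)

  if (nrow(results$population) > 0) {
    p <- file.path(out_dir, "population_snifflets.png")
    ggplot2::ggsave(p, plot_population(results$population),
                    width = 8, height = 4, dpi = 120)
    files <- c(files, p)
  }
  if (nrow(results$calls) > 0 && "tagged" %in% names(results$calls)) {
    p <- file.path(out_dir, "latency_cdf.png")
    ggplot2::ggsave(p, plot_latency_cdf(results$calls),
                    width = 6, height = 4, dpi = 120)
    files <- c(files, p)
  }
  if (nrow(results$categories) > 0) {
    p <- file.path(out_dir, "categories.png")
    ggplot2::ggsave(p, plot_categories(results$categories),
                    width = 6, height = 4, dpi = 120)
    files <- c(files, p)
  }
  invisible(files)
}
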