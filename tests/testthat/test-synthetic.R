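test_that("sniff trains follow the slow/fast inhalation mixture", {
  expect_equal(nrow(sample_sniff_train(0)), 0)
  expect_error(sample_sniff_train(5, sniff_params = list(median_fast = -1)),
               "invalid")

  big <- sample_sniff_train(2000, seed = 23)
  frac_slow <- mean(big$d_inh > 0.1)
  expect_gte(frac_slow, 0.6)
  expect_lte(frac_slow, 0.9)
  # consecutive, non-overlapping cycles
  expect_true(all(diff(big$t_onset) > 0))
  expect_equal(big$t_end[-nrow(big)], big$t_onset[-1])

  # determinism
  expect_identical(sample_sniff_train(50, seed = 24),
                   sample_sniff_train(50, seed = 24))
})

test_that("truth templates have the advertised shapes", {
  flat <- make_truth_snifflet("constant", D = 30, K = 4, seed = 1)
  expect_equal(as.numeric(flat), rep(log(8), 120))

  st <- make_truth_snifflet("stereotyped", D = 30, K = 4, seed = 2)
  expect_lte(which.max(st), 10)
  expect_gte(max(st), log(8) + log(3))

  inh <- make_truth_snifflet("inhibitory", D = 30, K = 4, seed = 3)
  expect_lt(min(inh), log(8) - 1)
  expect_lte(which.min(inh), 30)

  # diverse mode: first excursion sign is balanced across seeds
  sign_first <- vapply(1:100, function(s) {
    dev <- attr(make_truth_snifflet("diverse", D = 30, K = 4, seed = s),
                "deviation")
    idx <- which(abs(dev) > 0.3)[1]
    if (is.na(idx)) 0 else sign(dev[idx])
  }, numeric(1))
  pos <- mean(sign_first[sign_first != 0] > 0)
  expect_gte(pos, 0.35)
  expect_lte(pos, 0.65)
})

test_that("spike sampling is inhomogeneous Poisson with the dilated rate", {
  sn <- sample_sniff_train(500, seed = 25)
  expect_length(sample_spike_train(rep(-Inf, 120), sn, seed = 1), 0)

  # flat rate: count matches Poisson mean within 3 SD
  tot_time <- sum(sn$t_end - sn$t_onset)
  lam <- 5 * tot_time
  spk <- sample_spike_train(rep(log(5), 120), sn, seed = 26)
  expect_lt(abs(length(spk) - lam), 3 * sqrt(lam))
  expect_true(all(diff(spk) >= 0))

  # time-rescaling: transformed ISIs are Exp(1)
  sn2 <- sample_sniff_train(1200, seed = 27)
  psi <- make_truth_snifflet("stereotyped", D = 30, K = 4, seed = 27)
  spk2 <- sample_spike_train(psi, sn2, seed = 28)
  obs <- build_design(spk2, sn2, delta = 0.001, D = 30, K = 4)
  rate <- exp(psi[obs$bin])
  cum <- cumsum(rate * obs$width)
  # integrated intensity at each spike, by distributing spikes to bins
  lam_at_spike <- rep(cum, obs$y)
  z <- diff(lam_at_spike)
  z <- z[z > 0]
  ks <- suppressWarnings(stats::ks.test(z, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("population datasets are reproducible and well-formed", {
  spec <- synthetic_spec(n_cells = 2, n_trials = 3, seed = 31,
                         light = list(tag_fraction = 1, latency = 0.006,
                                      gain = 15, duration = 0.01,
                                      n_trials = 5))
  a <- make_population_dataset(spec)
  b <- make_population_dataset(spec)
  expect_identical(a, b)

  d <- a$dataset
  expect_setequal(unique(d$trials$cell_id), 1:2)
  expect_equal(nrow(d$trials), 2 * 2 * 3)
  expect_true(all(d$spikes$t >= 0))
  expect_equal(nrow(a$truth$templates), 4)

  # empty population: valid schema, zero rows
  e <- make_population_dataset(synthetic_spec(n_cells = 0))$dataset
  expect_named(e$spikes, c("cell_id", "t"))
  expect_equal(nrow(e$trials), 0)

  # file-level determinism through the text writers
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  write_dataset(d, d1)
  write_dataset(d, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("fitting generated data recovers the generating template", {
  sn <- sample_sniff_train(400, seed = 33)
  truth <- make_truth_snifflet("stereotyped", D = 12, K = 3, seed = 33)
  spk <- sample_spike_train(truth, sn, D = 12, K = 3, seed = 34)
  cfg <- snifflet_config(D = 12, K = 3, delta = 0.005,
                         rho_grid = seq(log(0.05), log(5), length.out = 4),
                         len_grid = c(1, 4, 12), refine = FALSE)
  fit <- fit_snifflet(spk, sn, cfg)
  expect_gt(cor(fit$psi, as.numeric(truth)), 0.9)
  expect_lte(abs(which.max(fit$psi) - which.max(truth)), 1)
})
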