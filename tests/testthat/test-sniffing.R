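test_that("sniff_train enforces cycle invariants", {
  expect_s3_class(regular_sniffs(3), "sniff_train")
  expect_error(sniff_train(data.frame(t_onset = 0, t_inh_end = 0,
                                      t_end = 0.3)), "d_inh")
  expect_error(sniff_train(data.frame(t_onset = 0, t_inh_end = 0.4,
                                      t_end = 0.3)), "t_inh_end")
  expect_error(sniff_train(data.frame(t_onset = c(0, 0.1),
                                      t_inh_end = c(0.15, 0.2),
                                      t_end = c(0.3, 0.3))), "overlap")
  tr <- regular_sniffs(2, d_inh = 0.12)
  expect_equal(tr$alpha, 1 / tr$d_inh)
})

test_that("detect_sniffs recovers sinusoidal inhalation epochs", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  expect_equal(nrow(detect_sniffs(rep(0, 4000), fs)), 0)
  expect_error(detect_sniffs(c(0, NA, 1), fs), "non-finite")

  clean <- detect_sniffs(-sin(2 * pi * 2.5 * t), fs)
  expect_equal(nrow(clean), 10)
  expect_true(all(abs(clean$d_inh - 0.2) < 0.025))
  expect_true(all(abs(diff(clean$t_onset) - 0.4) < 0.01))

  set.seed(11)
  noisy <- detect_sniffs(-sin(2 * pi * 2.5 * t) + rnorm(length(t), 0, 0.05),
                         fs)
  expect_equal(nrow(noisy), 10)
  expect_true(max(abs(noisy$t_onset - clean$t_onset)) <= 0.005)
})

test_that("detect_sniffs onsets scale with a time-dilated trace", {
  fs <- 1000
  t1 <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tr1 <- detect_sniffs(-sin(2 * pi * 2.5 * t1), fs)
  # same waveform played at half speed, sampled at the same rate
  c_fac <- 2
  t2 <- seq(0, 8 - 1 / fs, by = 1 / fs)
  tr2 <- detect_sniffs(-sin(2 * pi * 2.5 * t2 / c_fac), fs)
  expect_equal(nrow(tr2), nrow(tr1))
  # interior cycles scale to within a sample or two; the first and last
  # cycle carry a few ms of running-median baseline edge effect
  d <- abs(tr2$t_onset - c_fac * tr1$t_onset)
  inner <- seq(3, length(d) - 2)
  expect_true(max(d[inner]) <= 2 / fs + 1e-9)
  expect_true(max(d) <= 0.005 + 1e-9)
})

test_that("filter_by_inhalation keeps strictly longer inhalations", {
  tr <- sniff_train(data.frame(t_onset = c(0, 0.4, 0.8),
                               t_inh_end = c(0.08, 0.52, 0.95),
                               t_end = c(0.4, 0.8, 1.2)))
  expect_equal(nrow(filter_by_inhalation(tr, 0.10)), 2)
  expect_equal(filter_by_inhalation(tr, 0), tr)
  # idempotence
  once <- filter_by_inhalation(tr, 0.10)
  expect_equal(filter_by_inhalation(once, 0.10), once)
  # brute-force oracle on a large random train
  big <- sample_sniff_train(1000, seed = 42)
  kept <- filter_by_inhalation(big, 0.1)
  expect_equal(kept$sniff_id, big$sniff_id[big$d_inh > 0.1])
})

test_that("first_sniff_after returns the next onset or nothing", {
  tr <- sniff_train(data.frame(t_onset = c(1, 2), t_inh_end = c(1.1, 2.1),
                               t_end = c(2, 3)))
  expect_equal(first_sniff_after(tr, 1.5)$t_onset, 2)
  expect_equal(first_sniff_after(tr, 1.0)$t_onset, 1)
  expect_equal(nrow(first_sniff_after(tr, 2.5)), 0)
  # linear-scan oracle on random trains and events
  big <- sample_sniff_train(200, seed = 5)
  set.seed(6)
  for (ev in runif(20, -1, max(big$t_onset) + 1)) {
    got <- first_sniff_after(big, ev)
    cand <- big$t_onset[big$t_onset >= ev]
    if (length(cand) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$t_onset, min(cand))
    }
  }
})

test_that("baseline_sniffs selects pre-odor windows without duplicates", {
  tr <- sniff_train(data.frame(t_onset = c(6.5, 8, 9.5, 10.5),
                               t_inh_end = c(6.6, 8.1, 9.6, 10.6),
                               t_end = c(8, 9.5, 10.5, 11)))
  expect_equal(nrow(baseline_sniffs(tr, numeric(0))), 0)
  expect_equal(baseline_sniffs(tr, 10)$t_onset, c(8, 9.5))
  # overlapping windows: each sniff appears once
  overlap <- baseline_sniffs(tr, c(10, 10.6))
  expect_equal(overlap$t_onset, c(8, 9.5, 10.5))
  expect_false(any(duplicated(overlap$sniff_id)))
  # set-membership oracle
  big <- sample_sniff_train(300, seed = 7)
  onsets <- c(20, 21, 60)
  got <- baseline_sniffs(big, onsets)
  member <- vapply(big$t_onset, function(t0) {
    any(t0 >= onsets - 3 & t0 < onsets)
  }, logical(1))
  expect_equal(got$sniff_id, big$sniff_id[member])
})
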