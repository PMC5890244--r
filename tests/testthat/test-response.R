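test_that("first significant deviation scans bins in order", {
  base <- fake_fit(rep(1, 30), var = rep(0.005, 30), D = 15, K = 2)
  expect_equal(first_significant_deviation(base, base)$polarity, "none")

  up <- base
  up$psi[10:30] <- up$psi[10:30] + 0.5
  call <- first_significant_deviation(up, base)
  expect_equal(call$polarity, "excitatory")
  expect_equal(call$latency_bin, 10L)
  expect_equal(call$latency_u, 9 / 15)

  mixed <- base
  mixed$psi[5] <- mixed$psi[5] - 0.4
  mixed$psi[20] <- mixed$psi[20] + 0.6
  call2 <- first_significant_deviation(mixed, base)
  expect_equal(call2$polarity, "inhibitory")
  expect_equal(call2$latency_bin, 5L)

  other <- fake_fit(rep(1, 20), D = 10, K = 2)
  expect_error(first_significant_deviation(up, other), "share D and K")
})

test_that("threshold scales with the combined posterior deviation", {
  base <- fake_fit(rep(0, 10), var = rep(0.02, 10), D = 10, K = 1)
  odor <- fake_fit(rep(0.5, 10), var = rep(0.02, 10), D = 10, K = 1)
  # combined sd = 0.2; 0.5 > 3*0.2*... -> 0.6 fails, k = 2 passes
  expect_equal(first_significant_deviation(odor, base, k = 3)$polarity,
               "none")
  expect_equal(first_significant_deviation(odor, base, k = 2)$polarity,
               "excitatory")
})

test_that("preferred phase is the argmax bin midpoint, earliest on ties", {
  flat <- fake_fit(rep(1, 12), D = 6, K = 2)
  expect_equal(preferred_phase(flat), 0.5 / 6)
  peaked <- fake_fit(c(0, 0, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0), D = 6, K = 2)
  expect_equal(preferred_phase(peaked), 2.5 / 6)
  set.seed(9)
  for (i in 1:10) {
    psi <- rnorm(12)
    expect_equal(preferred_phase(fake_fit(psi, D = 6, K = 2)),
                 (which.max(psi) - 0.5) / 6)
  }
})

test_that("concentration categories match the decision table on all triples", {
  # independent oracle: the verbal decision table, evaluated directly
  oracle <- function(p) {
    if (all(p == "none")) return("omitted")
    if ("excitatory" %in% p && "inhibitory" %in% p) return("flipped")
    if ("none" %in% p) return("dropped")
    "consistent"
  }
  lv <- c("excitatory", "inhibitory", "none")
  for (a in lv) for (b in lv) for (c in lv) {
    expect_equal(categorize_concentration(c(a, b, c)), oracle(c(a, b, c)),
                 info = paste(a, b, c))
  }
  expect_equal(categorize_concentration(c("excitatory", "excitatory",
                                          "excitatory")), "consistent")
  expect_equal(categorize_concentration(c("excitatory", "none",
                                          "excitatory")), "dropped")
  expect_equal(categorize_concentration(rep("none", 3)), "omitted")
  expect_equal(categorize_concentration(c("excitatory", "inhibitory",
                                          "excitatory")), "flipped")
  # precedence is configurable when both flipped and dropped apply
  both <- c("excitatory", "none", "inhibitory")
  expect_equal(categorize_concentration(both), "flipped")
  expect_equal(categorize_concentration(both, precedence = "dropped"),
               "dropped")
  expect_error(categorize_concentration(c("excitatory", "none")), "exactly 3")
})

test_that("rate profiles normalize baseline to 0 and the peak odor to 1", {
  prof <- rate_profile(c(A = 5, B = 12, C = 9), 5)
  expect_equal(prof$response, c(0, 1, 4 / 7))
  expect_false(prof$degenerate[1])

  deg <- rate_profile(c(A = 5, B = 5), 5)
  expect_true(all(deg$degenerate))

  # invariance under positive affine rescaling of all counts
  a <- rate_profile(c(A = 5, B = 12, C = 9), 5)$response
  b <- rate_profile(c(A = 5, B = 12, C = 9) * 3 + 2, 5 * 3 + 2)$response
  expect_equal(a, b)
})
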