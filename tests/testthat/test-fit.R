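test_that("with no data the posterior equals the prior", {
  sn <- regular_sniffs(0)
  obs <- build_design(numeric(0), sn, D = 3, K = 2)
  C <- asd_covariance(6, 0, 2)
  fit <- map_fit(obs, C, prior_mean = 1.3)
  expect_equal(fit$psi, rep(1.3, 6))
  expect_equal(fit$Sigma, C)
  expect_equal(log_evidence(obs, 0, 2, 1.3), 0, tolerance = 1e-8)
})

test_that("a single snifflet bin recovers the Poisson rate MLE", {
  # 10 s of binned time in one bin, 50 spikes, near-flat prior
  sn <- regular_sniffs(10, d_inh = 0.5, d_sniff = 1)
  set.seed(2)
  spikes <- sort(runif(50, 0, 10))
  obs <- build_design(spikes, sn, delta = 0.01, D = 1, K = 1)
  fit <- map_fit(obs, matrix(100), prior_mean = 0)
  expect_equal(fit$psi, log(5), tolerance = 0.02)
})

test_that("Newton MAP matches a derivative-free optimizer", {
  set.seed(31)
  sn <- sample_sniff_train(40, seed = 31)
  spikes <- sample_spike_train(rep(log(10), 8), sn, D = 4, K = 2, seed = 32)
  obs <- build_design(spikes, sn, delta = 0.01, D = 4, K = 2)
  C <- asd_covariance(8, 0.5, 2)
  pm <- log(length(spikes) / sum(obs$width))
  fit <- map_fit(obs, C, pm)

  ss <- snifflet:::obs_suffstats(obs)
  # derivative-free search in the prior-whitened basis psi = pm + R'z,
  # which removes the correlated valley of the smoothness prior
  R <- chol(C)
  negobj_z <- function(z) {
    psi <- pm + as.numeric(t(R) %*% z)
    -(sum(ss$n * psi - ss$T * exp(psi)) - 0.5 * sum(z^2))
  }
  opt <- optim(rep(0, 8), negobj_z, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  opt <- optim(opt$par, negobj_z, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  zb <- opt$par
  for (sweep in 1:10) {
    for (j in 1:8) {
      f1 <- function(v) {
        z <- zb
        z[j] <- v
        negobj_z(z)
      }
      zb[j] <- optimize(f1, c(zb[j] - 0.5, zb[j] + 0.5),
                        tol = 1e-11)$minimum
    }
  }
  sol <- pm + as.numeric(t(R) %*% zb)
  expect_lt(max(abs(fit$psi - sol)), 1e-4)
})

test_that("the MAP objective is concave: all Newton starts agree", {
  sn <- sample_sniff_train(60, seed = 41)
  spikes <- sample_spike_train(make_truth_snifflet("diverse", D = 4, K = 2,
                                                   seed = 41),
                               sn, D = 4, K = 2, seed = 42)
  obs <- build_design(spikes, sn, delta = 0.01, D = 4, K = 2)
  ss <- snifflet:::obs_suffstats(obs)
  C <- asd_covariance(8, 0, 3)
  ref <- snifflet:::map_fit_stats(ss$n, ss$T, C, 1, tol = 1e-9)$psi
  set.seed(43)
  for (i in 1:5) {
    alt <- snifflet:::map_fit_stats(ss$n, ss$T, C, 1, tol = 1e-9,
                                    psi_init = rnorm(8, 1, 2))$psi
    expect_lt(max(abs(alt - ref)), 1e-6)
  }
})

test_that("prior scale controls shrinkage between prior mean and MLE", {
  sn <- regular_sniffs(30)
  set.seed(51)
  spikes <- sort(runif(150, 0, max(sn$t_end)))
  obs <- build_design(spikes, sn, delta = 0.01, D = 4, K = 2)
  ss <- snifflet:::obs_suffstats(obs)
  pm <- 0.2
  tight <- map_fit(obs, asd_covariance(8, log(1e-8), 1), pm)
  expect_lt(max(abs(tight$psi - pm)), 1e-3)
  loose <- map_fit(obs, asd_covariance(8, log(1e6), 1e-3), pm)
  has_data <- ss$T > 0 & ss$n > 0
  expect_equal(loose$psi[has_data], log(ss$n / ss$T)[has_data],
               tolerance = 1e-3)
})

test_that("Laplace evidence agrees with 2-D quadrature on a toy model", {
  sn <- regular_sniffs(6, d_inh = 0.15, d_sniff = 0.3)
  set.seed(61)
  spikes <- sort(runif(12, 0, max(sn$t_end)))
  obs <- build_design(spikes, sn, delta = 0.05, D = 1, K = 2)
  rho <- log(0.8)
  len <- 1.5
  pm <- log(12 / sum(obs$width))
  lap <- log_evidence(obs, rho, len, pm)

  ss <- snifflet:::obs_suffstats(obs)
  C <- asd_covariance(2, rho, len)
  Cinv <- solve(C)
  grid <- seq(pm - 4, pm + 4, length.out = 401)
  h <- diff(grid)[1]
  joint <- outer(grid, grid, Vectorize(function(p1, p2) {
    psi <- c(p1, p2)
    q <- psi - pm
    ll <- sum(ss$n * psi - ss$T * exp(psi))
    lp <- -0.5 * sum(q * (Cinv %*% q)) -
      0.5 * log(det(2 * pi * C))
    ll + lp
  }))
  quad <- log(sum(exp(joint - max(joint)))) + max(joint) + 2 * log(h)
  expect_equal(lap, quad, tolerance = 1e-2)
})

test_that("evidence is invariant to permuting observation bins", {
  sn <- sample_sniff_train(30, seed = 71)
  spikes <- sample_spike_train(rep(log(8), 12), sn, D = 6, K = 2, seed = 72)
  obs <- build_design(spikes, sn, delta = 0.01, D = 6, K = 2)
  set.seed(73)
  perm <- structure(tibble::as_tibble(obs)[sample(nrow(obs)), ],
                    delta = attr(obs, "delta"),
                    D = attr(obs, "D"), K = attr(obs, "K"),
                    scheme = attr(obs, "scheme"),
                    d_ref = attr(obs, "d_ref"))
  expect_equal(log_evidence(obs, 0, 2, log(8)),
               log_evidence(perm, 0, 2, log(8)))
})

test_that("fit_snifflet recovers a constant rate as near-flat", {
  sn <- sample_sniff_train(300, seed = 81)
  spikes <- sample_spike_train(rep(log(5), 12), sn, D = 6, K = 2, seed = 82)
  fit <- fit_snifflet(spikes, sn, cfg_small())
  expect_lt(max(fit$psi) - min(fit$psi), 0.3)
})

test_that("fit_snifflet at the chosen hyperparameters equals map_fit", {
  sn <- sample_sniff_train(100, seed = 91)
  truth <- make_truth_snifflet("stereotyped", D = 6, K = 2, seed = 91)
  spikes <- sample_spike_train(truth, sn, D = 6, K = 2, seed = 92)
  cfg <- cfg_small()
  fit <- fit_snifflet(spikes, sn, cfg)
  obs <- build_design(spikes, sn, delta = cfg$delta, D = 6, K = 2,
                      d_ref = cfg$d_ref)
  C <- asd_covariance(12, fit$hyper["rho"], fit$hyper["delta_len"])
  direct <- map_fit(obs, C, fit$prior_mean)
  expect_equal(fit$psi, direct$psi, tolerance = 1e-8)
  expect_equal(fit$var, direct$var, tolerance = 1e-8)
})

test_that("constant-rate fit shrinks sensibly and loses on modulated data", {
  sn <- sample_sniff_train(200, seed = 101)
  truth <- make_truth_snifflet("stereotyped", D = 6, K = 2, seed = 101)
  spikes <- sample_spike_train(truth, sn, D = 6, K = 2, seed = 102)
  cfg <- cfg_small()
  cst <- fit_constant(spikes, sn, cfg)
  expect_equal(cst$psi[1],
               log(cst$n_spikes / sum(sn$t_end - sn$t_onset)),
               tolerance = 0.05)
  full <- fit_snifflet(spikes, sn, cfg)
  expect_lte(cst$log_evidence, full$log_evidence + 10)

  # zero spikes: the mode sits below the prior mean (data pull toward 0)
  expect_warning(z <- fit_constant(numeric(0), sn[1:10, ], cfg), NA)
  expect_lt(z$psi[1], z$prior_mean)
})

test_that("predict_rate dilates the fitted pattern per sniff", {
  flat <- fake_fit(rep(log(5), 12), D = 6, K = 2)
  sn <- regular_sniffs(1)
  tr <- predict_rate(flat, sn[1, ])
  expect_equal(tr$rate, rep(5, nrow(tr)))

  bumpy <- fake_fit(make_truth_snifflet("stereotyped", D = 6, K = 2,
                                        seed = 7)[1:12], D = 6, K = 2)
  a <- sniff_train(data.frame(t_onset = 0, t_inh_end = 0.1, t_end = 0.2))
  b <- sniff_train(data.frame(t_onset = 0, t_inh_end = 0.2, t_end = 0.4))
  ra <- predict_rate(bumpy, a[1, ], delta = 0.005)
  rb <- predict_rate(bumpy, b[1, ], delta = 0.010)
  expect_equal(ra$rate, rb$rate)
})
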