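#' Squared-exponential smoothing prior covariance
#'
#' Covariance of the Gaussian smoothness prior placed over the snifflet
#' coefficients (an automatic-smoothness-determination prior):
#' `C[j, k] = exp(rho) * exp(-(j - k)^2 / (2 delta_len^2))` on bin indices,
#' so that `exp(rho)` is the marginal prior variance and `delta_len` the
#' correlation length in bins. Distance is the plain bin-index difference,
#' continuous across the inhalation/rest boundary. A jitter of
#' `1e-6 * exp(rho)` is added to the diagonal for conditioning.
#'
#' @param m Number of coefficients.
#' @param rho Log marginal variance.
#' @param delta_len Length-scale in bins, `> 0`.
#' @return An `m x m` positive-definite matrix.
#' @export
asd_covariance <- function(m, rho, delta_len) {
  stopifnot(m >= 1)
  if (delta_len <= 0) rlang::abort("length-scale delta_len must be > 0")
  j <- seq_len(m)
  d2 <- outer(j, j, function(a, b) (a - b)^2)
  C <- exp(rho) * exp(-d2 / (2 * delta_len^2))
  C + diag(1e-6 * exp(rho), m)
}

#' MAP estimate of the snifflet under a Gaussian prior
#'
#' Maximizes the penalized Poisson log-likelihood
#' `sum_j [n_j psi_j - T_j exp(psi_j)] - (psi - m)' C^{-1} (psi - m) / 2`
#' where `n_j` and `T_j` are the spike count and time exposure mapped to
#' snifflet bin `j`. The objective is strictly concave, solved by damped
#' Newton iterations with backtracking. The posterior is approximated as
#' Gaussian at the mode (Laplace), with covariance
#' `(H_lik + C^{-1})^{-1}`, `H_lik = diag(T_j exp(psi_hat_j))`.
#'
#' @param obs A [build_design()] result.
#' @param C Prior covariance (from [asd_covariance()]).
#' @param prior_mean Scalar prior mean log-rate.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return A list with `psi` (MAP log-rates), `Sigma` (posterior
#'   covariance), `var` (its diagonal), `loglik` (Poisson term at the
#'   mode), `n_iter` and `grad_norm`.
#' @export
map_fit <- function(obs, C, prior_mean, tol = 1e-6, max_iter = 100) {
  ss <- obs_suffstats(obs)
  map_fit_stats(ss$n, ss$T, C, prior_mean, tol = tol, max_iter = max_iter)
}

map_fit_stats <- function(n_j, T_j, C, prior_mean, tol = 1e-6,
                          max_iter = 100, psi_init = NULL) {
  m <- length(n_j)
  stopifnot(nrow(C) == m, ncol(C) == m, length(T_j) == m)
  R <- tryCatch(chol(C), error = function(e) {
    rlang::abort("prior covariance is not positive definite")
  })
  Cinv <- chol2inv(R)

  if (all(T_j == 0)) {
    return(list(psi = rep(prior_mean, m), Sigma = C, var = diag(C),
                loglik = 0, n_iter = 0L, grad_norm = 0))
  }

  obj <- function(psi) {
    q <- psi - prior_mean
    sum(n_j * psi - T_j * exp(psi)) - 0.5 * sum(q * (Cinv %*% q))
  }
  ## gradient entries scale with spike counts, so the convergence
  ## criterion is tol relative to the total count (tol itself for small
  ## problems). At curvature T_j exp(psi) ~ n_j this bounds the psi
  ## error near tol per bin.
  tol_eff <- tol * max(1, sum(n_j))
  psi <- if (is.null(psi_init)) rep(prior_mean, m) else psi_init
  f <- obj(psi)
  if (!is.finite(f)) {
    psi <- rep(prior_mean, m)
    f <- obj(psi)
  }
  grad_norm <- Inf
  stagnated <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- T_j * exp(psi)
    g <- as.numeric(n_j - mu - Cinv %*% (psi - prior_mean))
    grad_norm <- max(abs(g))
    if (grad_norm < tol_eff) break
    H <- Cinv + diag(mu, m)
    step <- as.numeric(solve(H, g))
    if (max(abs(step)) < 1e-12 * (1 + max(abs(psi)))) {
      ## the iterate can no longer move in double precision: under a
      ## near-singular prior the gradient's rounding-noise floor can sit
      ## above tol while the mode itself is converged
      stagnated <- TRUE
      break
    }
    lam <- 1
    if (grad_norm > 1e-3) {
      ## backtrack only while far from the optimum; near it the pure
      ## Newton step converges quadratically and objective comparisons
      ## hit floating-point noise
      repeat {
        cand <- psi + lam * step
        fc <- obj(cand)
        if (is.finite(fc) && fc >= f - 1e-9 * (1 + abs(f))) break
        lam <- lam / 2
        if (lam < 1e-10) break
      }
    }
    psi <- psi + lam * step
    f <- obj(psi)
  }
  if (grad_norm >= tol_eff && !stagnated) {
    mu <- T_j * exp(psi)
    g <- as.numeric(n_j - mu - Cinv %*% (psi - prior_mean))
    grad_norm <- max(abs(g))
    if (grad_norm >= tol_eff) {
      rlang::abort(sprintf(
        "Newton did not converge in %d iterations (gradient max-norm %.3g)",
        max_iter, grad_norm))
    }
  }
  psi <- as.numeric(psi)
  H <- Cinv + diag(T_j * exp(psi), m)
  Sigma <- chol2inv(chol(H))
  list(psi = psi, Sigma = Sigma, var = pmax(diag(Sigma), 0),
       loglik = sum(n_j * psi - T_j * exp(psi)),
       n_iter = it, grad_norm = grad_norm)
}

#' Laplace-approximated log evidence of the snifflet model
#'
#' Log marginal likelihood of the binned spikes under the Gaussian prior
#' with hyperparameters `(rho, delta_len)`, approximated at the posterior
#' mode: `L(psi_hat) - q'C^{-1}q/2 - log det C / 2 - log det(H) / 2` with
#' `q = psi_hat - prior_mean` and `H = H_lik + C^{-1}` (the `(2*pi)^{m/2}`
#' factors of the prior normalizer and the Laplace integral cancel).
#' With no observed bins the evidence is exactly 0.
#'
#' @inheritParams map_fit
#' @param rho,delta_len Prior hyperparameters, see [asd_covariance()].
#' @return Scalar log evidence.
#' @export
log_evidence <- function(obs, rho, delta_len, prior_mean) {
  ss <- obs_suffstats(obs)
  log_evidence_stats(ss$n, ss$T, rho, delta_len, prior_mean)
}

log_evidence_stats <- function(n_j, T_j, rho, delta_len, prior_mean,
                               psi_init = NULL) {
  as.numeric(evidence_with_fit(n_j, T_j, rho, delta_len, prior_mean,
                               psi_init)$ev)
}

## evidence plus the MAP it was evaluated at, so a hyperparameter search
## can warm-start successive Newton solves
evidence_with_fit <- function(n_j, T_j, rho, delta_len, prior_mean,
                              psi_init = NULL) {
  m <- length(n_j)
  C <- asd_covariance(m, rho, delta_len)
  fit <- map_fit_stats(n_j, T_j, C, prior_mean, psi_init = psi_init)
  q <- fit$psi - prior_mean
  Rc <- chol(C)
  Cinv <- chol2inv(Rc)
  H <- Cinv + diag(T_j * exp(fit$psi), m)
  Rh <- chol(H)
  ev <- fit$loglik - 0.5 * sum(q * (Cinv %*% q)) -
    sum(log(diag(Rc))) - sum(log(diag(Rh)))
  list(ev = ev, psi = fit$psi)
}

#' Configuration for snifflet fitting
#'
#' @param delta Time-bin width in seconds.
#' @param D Snifflet bins per inhalation.
#' @param K Relative sniff-duration multiple.
#' @param scheme Dilation scheme, see [build_design()].
#' @param rho_grid,len_grid Hyperparameter search grids: log marginal
#'   variance and length-scale (bins). Defaults: 7 log-spaced values each.
#' @param refine If `TRUE` (default), refine the grid optimum by
#'   Nelder-Mead on `(rho, log delta_len)`.
#' @param d_ref Reference duration for `scheme = "none"`.
#' @return A list of class `snifflet_config`.
#' @export
snifflet_config <- function(delta = 0.005, D = 30, K = 4,
                            scheme = "inhalation",
                            rho_grid = seq(log(0.01), log(10), length.out = 7),
                            len_grid = exp(seq(log(0.5), log(max(D * K / 2, 2)),
                                               length.out = 7)),
                            refine = TRUE,
                            d_ref = NULL) {
  structure(list(delta = delta, D = D, K = K, scheme = scheme,
                 rho_grid = rho_grid, len_grid = len_grid,
                 refine = refine, d_ref = d_ref),
            class = "snifflet_config")
}

default_prior_mean <- function(n_total, T_total) {
  if (T_total <= 0) return(0)
  log(max(n_total, 0.5) / T_total)
}

new_snifflet_fit <- function(psi, var, config, rho, delta_len, prior_mean,
                             log_evidence, n_sniffs, n_spikes, d_ref,
                             constant = FALSE, flat_data = FALSE) {
  structure(
    list(psi = psi, var = var, D = config$D, K = config$K,
         scheme = config$scheme, delta = config$delta,
         hyper = c(rho = rho, delta_len = delta_len),
         prior_mean = prior_mean, log_evidence = log_evidence,
         n_sniffs = n_sniffs, n_spikes = n_spikes, d_ref = d_ref,
         constant = constant, flat_data = flat_data),
    class = "snifflet_fit")
}

#' @export
print.snifflet_fit <- function(x, ...) {
  cat(sprintf(
    "<snifflet_fit> %s model, D=%d K=%d, scheme=%s\n  %d sniffs, %d spikes; log evidence %.2f\n  hyper: exp(rho)=%.3g, length-scale=%.3g bins; prior mean %.3f log sp/s\n",
    if (x$constant) "constant-rate" else "snifflet",
    x$D, x$K, x$scheme, x$n_sniffs, x$n_spikes, x$log_evidence,
    exp(x$hyper["rho"]), x$hyper["delta_len"], x$prior_mean))
  invisible(x)
}

#' Fit a snifflet to spikes over a set of sniffs
#'
#' Full estimation pipeline for one cell and condition: bins the spikes
#' over the given sniffs under the chosen dilation scheme, selects the
#' smoothness-prior hyperparameters by maximizing the Laplace-approximated
#' evidence over a log-spaced grid (with optional Nelder-Mead refinement),
#' and returns the posterior mode with marginal posterior variances. The
#' prior mean is the constant-rate log MLE `log(spikes / binned time)`, so
#' the prior shrinks toward the constant fit. Deterministic given the
#' configuration.
#'
#' @param spikes Spike times (seconds) or a data frame with column `t`.
#' @param sniffs A [sniff_train()] with at least one sniff.
#' @param config A [snifflet_config()].
#' @return A `snifflet_fit` object; see [tidy.snifflet_fit()] and
#'   [glance.snifflet_fit()] for tabular views.
#' @export
fit_snifflet <- function(spikes, sniffs, config = snifflet_config()) {
  if (nrow(sniffs) == 0) rlang::abort("fit_snifflet() needs at least one sniff")
  obs <- build_design(spikes, sniffs, delta = config$delta, D = config$D,
                      K = config$K, scheme = config$scheme,
                      d_ref = config$d_ref)
  fit_snifflet_obs(obs, config, n_sniffs = nrow(sniffs))
}

fit_snifflet_obs <- function(obs, config, n_sniffs) {
  ss <- obs_suffstats(obs)
  m <- config$D * config$K
  n_spikes <- sum(ss$n)
  T_total <- sum(ss$T)
  prior_mean <- default_prior_mean(n_spikes, T_total)
  flat_data <- n_spikes == 0

  warm <- new.env(parent = emptyenv())
  warm$psi <- NULL
  ev_fun <- function(rho, len) {
    res <- evidence_with_fit(ss$n, ss$T, rho, len, prior_mean,
                             psi_init = warm$psi)
    warm$psi <- res$psi
    res$ev
  }
  grid <- expand.grid(rho = config$rho_grid, len = config$len_grid,
                      KEEP.OUT.ATTRS = FALSE)
  ev <- mapply(ev_fun, grid$rho, grid$len)
  best <- which.max(ev)
  rho <- grid$rho[best]
  len <- grid$len[best]
  best_ev <- ev[best]

  if (isTRUE(config$refine)) {
    ## refinement stays inside the grid's box: in particular the prior
    ## variance is floored at the smallest grid value, so flat data
    ## cannot drive the prior (and with it the posterior variance) to a
    ## degenerate zero
    lo <- c(min(config$rho_grid), log(min(config$len_grid)))
    hi <- c(max(config$rho_grid), log(max(config$len_grid)))
    clamp <- function(p) pmin(pmax(p, lo), hi)
    opt <- stats::optim(
      c(rho, log(len)),
      function(p) {
        p <- clamp(p)
        -ev_fun(p[1], exp(p[2]))
      },
      method = "Nelder-Mead",
      control = list(maxit = 50, reltol = 1e-6))
    if (-opt$value > best_ev) {
      par <- clamp(opt$par)
      rho <- par[1]
      len <- exp(par[2])
      best_ev <- -opt$value
    }
  }

  C <- asd_covariance(m, rho, len)
  fit <- map_fit_stats(ss$n, ss$T, C, prior_mean)
  if (flat_data) {
    rlang::warn("no spikes in any analysis sniff; returning prior-mean fit")
  }
  new_snifflet_fit(fit$psi, fit$var, config, rho, len, prior_mean,
                   best_ev, n_sniffs, n_spikes, attr(obs, "d_ref"),
                   flat_data = flat_data)
}

#' Fit a constant-rate model for comparison
#'
#' One-parameter version of the snifflet model: a single log-rate with the
#' same Poisson likelihood and a scalar Gaussian prior, with its own
#' evidence-optimized prior variance. Its Laplace evidence is directly
#' comparable to [fit_snifflet()]'s; cells whose evidence favors this
#' model are "constant-best" and are conventionally omitted from snifflet
#' population displays.
#'
#' @inheritParams fit_snifflet
#' @return A `snifflet_fit` with `constant = TRUE`; `psi` and `var` are
#'   the scalar fit replicated over all `K*D` bins.
#' @export
fit_constant <- function(spikes, sniffs, config = snifflet_config()) {
  if (nrow(sniffs) == 0) rlang::abort("fit_constant() needs at least one sniff")
  obs <- build_design(spikes, sniffs, delta = config$delta, D = config$D,
                      K = config$K, scheme = config$scheme,
                      d_ref = config$d_ref)
  ss <- obs_suffstats(obs)
  n_tot <- sum(ss$n)
  T_tot <- sum(ss$T)
  prior_mean <- default_prior_mean(n_tot, T_tot)

  ev_fun <- function(rho) {
    log_evidence_stats(n_tot, T_tot, rho, 1, prior_mean)
  }
  ev <- vapply(config$rho_grid, ev_fun, numeric(1))
  rho <- config$rho_grid[which.max(ev)]
  opt <- stats::optimize(function(r) -ev_fun(r),
                         interval = c(max(rho - 2, min(config$rho_grid)),
                                      min(rho + 2, max(config$rho_grid))))
  if (-opt$objective > max(ev)) {
    rho <- opt$minimum
  }
  C1 <- asd_covariance(1, rho, 1)
  fit <- map_fit_stats(n_tot, T_tot, C1, prior_mean)
  m <- config$D * config$K
  new_snifflet_fit(rep(fit$psi, m), rep(fit$var, m), config, rho, 1,
                   prior_mean, ev_fun(rho), nrow(sniffs), n_tot,
                   attr(obs, "d_ref"), constant = TRUE)
}

#' Predicted firing rate over one sniff
#'
#' Evaluates the fitted snifflet on a given sniff's support, applying that
#' sniff's dilation: the rate at time `t` is `exp(psi[j(u(t))])`, with the
#' phase beyond `u = K` clamped to the last bin so the trace covers the
#' whole cycle up to the next onset.
#'
#' @param fit A `snifflet_fit`.
#' @param sniff A one-row [sniff_train()].
#' @param delta Output time step (defaults to the fit's bin width).
#' @return A tibble with columns `t` (seconds) and `rate` (spikes/s).
#' @export
predict_rate <- function(fit, sniff, delta = NULL) {
  stopifnot(inherits(fit, "snifflet_fit"), nrow(sniff) == 1)
  if (is.null(delta)) delta <- fit$delta
  n_pts <- max(1L, ceiling((sniff$t_end - sniff$t_onset) / delta - 1e-9))
  t <- sniff$t_onset + delta * (seq_len(n_pts) - 1)
  u <- dilated_phase(t, sniff, fit$scheme, fit$K, fit$d_ref)
  j <- snifflet_bin_index(pmax(u, 0), fit$D, fit$K)
  tibble::tibble(t = t, rate = exp(fit$psi[j]))
}
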