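# shared fixtures; everything is generated in code at test time

regular_sniffs <- function(n, d_inh = 0.12, d_sniff = 0.35, t0 = 0) {
  on <- t0 + (seq_len(n) - 1) * d_sniff
  sniff_train(data.frame(t_onset = on, t_inh_end = on + d_inh,
                         t_end = on + d_sniff))
}

# small, fast fitting configuration for unit tests
cfg_small <- function(...) {
  snifflet_config(D = 6, K = 2, delta = 0.01,
                  rho_grid = seq(log(0.05), log(5), length.out = 4),
                  len_grid = c(1, 3, 6),
                  refine = FALSE, ...)
}

# a snifflet_fit stub with prescribed psi/var, for response-metric tests
fake_fit <- function(psi, var = rep(0.01, length(psi)), D = NULL, K = 1,
                     prior_mean = mean(psi)) {
  if (is.null(D)) D <- length(psi) / K
  structure(
    list(psi = psi, var = var, D = D, K = K, scheme = "inhalation",
         delta = 0.005, hyper = c(rho = 0, delta_len = 1),
         prior_mean = prior_mean, log_evidence = NA_real_,
         n_sniffs = NA_integer_, n_spikes = NA_integer_, d_ref = 0.1,
         constant = FALSE, flat_data = FALSE),
    class = "snifflet_fit")
}
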