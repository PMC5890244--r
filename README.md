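# snifflet

Sniff-warped Poisson models of olfactory bulb spike trains.

## The problem

In awake, freely breathing animals, the spiking of mitral/tufted (MT)
cells in the olfactory bulb is locked to the respiration cycle, and
sniffs vary widely in duration from one cycle to the next. A PSTH
aligned to odor onset therefore smears response timing, and recordings
from animals with different sniff statistics cannot be compared
directly. This package is for electrophysiologists analysing such
recordings: it models each cell–condition pair as a single log
firing-rate pattern over *normalized* sniff time — a **snifflet** —
that is temporally dilated on every sniff by the reciprocal of that
sniff's inhalation duration, and builds the downstream response
statistics on top of that representation.

## The model

With sniff onsets $\tau_i$, inhalation durations $d_i^{\mathrm{inh}}$
and dilation factors $\alpha_i = 1/d_i^{\mathrm{inh}}$, the firing rate
is

$$
r(t) = \exp\Big[\sum_{i=1}^{n} \psi\big(\alpha_i(t-\tau_i)\big)\,
\Pi(\tau_i \le t < \tau_{i+1})\Big],
$$

where $\psi$ is a length-$KD$ vector over normalized sniff time ($D$
bins tile the inhalation, $(K-1)D$ the rest of the sniff; defaults
$D=30$, $K=4$) and $\Pi$ resets the pattern at each sniff onset.
Spikes are Poisson in $\Delta = 5$ ms bins. $\psi$ carries a Gaussian
smoothness prior with squared-exponential covariance whose scale and
length-scale are chosen by maximizing the Laplace-approximated model
evidence; the posterior mode is found by Newton ascent (the problem is
convex) and marginal posterior variances come from the Laplace
approximation. Response polarity and latency are the sign and position
of the first bin where an odor snifflet deviates from the baseline
snifflet by more than 3 combined SDs in log-rate space. A
cross-validation module compares dilation schemes (inhalation, full
sniff, two-piece, none), a PSTH module identifies light-responsive
cells for optogenetic tagging, and a synthetic-data generator produces
sniff trains, dilated Poisson spike trains and whole cell populations
with known ground truth.

See the methods vignette (`vignettes/snifflet-methods.Rmd`) for the
full model description and design rationale.

## Worked example

Simulate a cell with an early excitatory transient, keep the slow
sniffs, and fit:

```r
library(snifflet)

sniffs <- sample_sniff_train(400, seed = 42)
truth  <- make_truth_snifflet("stereotyped", D = 30, K = 4, seed = 42)
spikes <- sample_spike_train(truth, sniffs, D = 30, K = 4, seed = 43)

slow <- filter_by_inhalation(sniffs, 0.1)   # keep d_inh > 100 ms
fit  <- fit_snifflet(spikes, slow, snifflet_config())
fit
#> <snifflet_fit> snifflet model, D=30 K=4, scheme=inhalation
#>   285 sniffs, 1347 spikes; log evidence 2252.17
#>   hyper: exp(rho)=0.328, length-scale=6.54 bins; prior mean 2.506 log sp/s

cor(fit$psi, as.numeric(truth))
#> [1] 0.9651358
```

285 of the 400 sniffs have inhalations longer than 100 ms; the fitted
log-rate pattern correlates 0.96 with the generating template. The
evidence-optimized prior settled on a marginal variance of 0.33 and a
smoothness length of 6.5 bins, and the prior mean 2.51 log sp/s is the
constant-rate estimate (about 12 sp/s). The constant-rate alternative
fits far worse (`fit_constant()` evidence 2027 vs 2252), so this cell
would not be flagged "constant-best".

Calling the response against a flat reference cell:

```r
flat <- fit_snifflet(sample_spike_train(rep(log(8), 120), sniffs, seed = 9),
                     slow, snifflet_config())
first_significant_deviation(fit, flat)
#> # A tibble: 1 × 3
#>   polarity   latency_bin latency_u
#>   <chr>            <int>     <dbl>
#> 1 excitatory           2    0.0333
```

The first significant (3σ) deviation is excitatory at snifflet bin 2 —
a latency of 0.03 inhalation durations, i.e. right at inhalation onset,
as injected. `tidy(fit)` gives the per-bin table, `glance(fit)` the
one-row summary, `autoplot(fit)` the rate curve with its posterior
band. `make_population_dataset()` + `run_full_analysis()` +
`write_report()` run the same machinery over a whole synthetic
population, producing call tables, concentration categories,
opto-tagging results, population averages and group tests.

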