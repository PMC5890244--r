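---
title: "Sniff-warped models of olfactory bulb spike trains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sniff-warped models of olfactory bulb spike trains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snifflet)
```

## The problem

Mitral/tufted (MT) cells in the olfactory bulb of an awake, freely
breathing animal are driven as much by respiration as by odors. Sniff
frequency and inhalation duration vary widely from cycle to cycle, so a
conventional PSTH aligned to odor onset smears the temporal structure of
a response, and responses cannot be compared across animals with
different sniffing. This package implements an analysis that removes
that nuisance variable: each cell–condition pair is summarized by a
single firing-rate pattern over *normalized* sniff time — a "snifflet" —
that is stretched or compressed on every individual sniff according to
how long that sniff's inhalation lasted.

## The model

Let $\tau_i$ be the onset of the $i$-th sniff, $d_i^{\mathrm{inh}}$ its
inhalation duration, and $\alpha_i = 1/d_i^{\mathrm{inh}}$ the per-sniff
dilation factor. The firing rate is

$$
r(t) \;=\; \exp\!\Big[\textstyle\sum_{i=1}^{n}
\psi\big(\alpha_i (t - \tau_i)\big)\cdot
\Pi(\tau_i \le t < \tau_{i+1})\Big],
$$

where $\psi(\cdot)$ is the log-rate snifflet and the indicator
$\Pi(\cdot)$ resets the pattern at the next sniff onset. $\psi$ is
parameterized as a length-$KD$ vector: the first $D$ bins tile the
inhalation (phase $u \in [0,1)$), the remaining $(K-1)D$ bins tile the
rest of the sniff ($u \in [1,K)$); phases beyond $K$ clamp to the last
bin so the rate is defined up to the next onset. Defaults are $D = 30$,
$K = 4$.

Spikes are modeled as an inhomogeneous Poisson process. Time is
discretized into bins of width $\Delta$ (default 5 ms), each bin mapped
to a snifflet bin through its center (nearest-bin indicator rather than
interpolation, matching the vector parameterization), and the likelihood
collapses to per-snifflet-bin sufficient statistics: spike count $n_j$
and time exposure $T_j$.

Four dilation schemes are implemented for model comparison: the
reciprocal of the inhalation duration (the default and the
best-supported choice), the reciprocal of the full sniff duration,
separate dilation of the inhalation and the rest of the sniff, and no
dilation (a fixed reference duration, by default the session's median
inhalation). `cv_loglik()` scores schemes by cross-validated held-out
Poisson log-likelihood with interleaved, deterministic fold assignment;
`compare_dilation_schemes()` ranks them.

## Estimation

A Gaussian smoothness prior with squared-exponential covariance
$C_{jk} = e^{\rho}\exp(-(j-k)^2/2\delta^2)$ is placed over the snifflet
coefficients (an automatic-smoothness-determination prior); distance is
the raw bin index, continuous across the inhalation/rest boundary. The
prior mean is the constant-rate log MLE $\log(\text{spikes}/\text{binned
time})$, so shrinkage is toward the constant fit and the empty-data
limit is sensible. The posterior mode is found by damped Newton
iterations — the objective is strictly concave — and the posterior is
approximated as Gaussian at the mode (Laplace), keeping only the
marginal variances for downstream comparisons.

Hyperparameters $(\rho, \delta)$ maximize the Laplace-approximated log
evidence

$$
\log Z \approx L(\hat\psi)
- \tfrac12 (\hat\psi - m)^\top C^{-1} (\hat\psi - m)
- \tfrac12 \log\det C - \tfrac12 \log\det(H_{\mathrm{lik}} + C^{-1}),
$$

in which the $(2\pi)^{m/2}$ factors of the prior normalizer and the
Laplace integral cancel exactly; with no observed bins the expression is
identically zero, which the test suite verifies against a direct 2-D
quadrature on a toy model. The search is a log-spaced grid (7×7 by
default) followed by Nelder–Mead refinement from the grid optimum — clamped to
the grid's box, so in particular the prior variance never drops below
the smallest grid value and flat data cannot collapse the posterior
variance to a degenerate zero — with Newton solves warm-started from
the previous hyperparameter's mode. The whole fit is deterministic
given its configuration.

`fit_constant()` fits the one-parameter constant-rate model with the
same likelihood and its own evidence-optimized scalar prior; a
cell–condition whose constant evidence exceeds the snifflet evidence is
flagged "constant-best" and omitted from normalized population displays.

## Numerical choices

* Prior conditioning: jitter of $10^{-6} e^{\rho}$ on the diagonal of
  $C$.
* Newton: backtracking line search while the gradient max-norm exceeds
  $10^{-3}$, pure Newton steps below it (near the optimum, objective
  comparisons hit floating-point noise while the pure step converges
  quadratically); convergence at gradient max-norm below
  $10^{-6}\max(1, \sum_j n_j)$ — the gradient scales with spike
  counts, so the tolerance is relative to that scale; at most 100
  iterations.
* Bins tiling a sniff: full $\Delta$-width bins plus a truncated final
  bin closing $[\tau_i, \tau_{i+1})$; exposure uses true bin widths.
* Ties in `preferred_phase()` resolve to the earliest bin.
* Degenerate inputs: zero spikes give a prior-mean fit with a warning
  flag; an all-baseline rate profile is flagged degenerate rather than
  divided by zero.

## Response statistics

`first_significant_deviation()` scans bins in temporal order and
reports the first bin where odor and baseline snifflets differ by more
than $k\sigma$ (default $k=3$) in log-rate space, with
$\sigma = \sqrt{\mathrm{var}_{\mathrm{odor}} +
\mathrm{var}_{\mathrm{base}} + 1/N_{\mathrm{odor}} +
1/N_{\mathrm{base}}}$: the marginal posterior variances (summed — the
standard choice for independent posteriors) plus the $1/N$ sampling
variance of each fit's estimated prior-mean level, which the Laplace
posterior treats as fixed and would otherwise omit.
No multiplicity correction is applied across bins; the synthetic null
calibration below quantifies the resulting family-wise false-call rate.
Latency is reported natively in dilated phase $u$ (inhalation
durations); multiply by a reference inhalation duration (e.g. the
session median) for milliseconds.

Concentration series of three calls are categorized *consistent* /
*dropped* / *flipped* / *omitted*. When a triple satisfies both the
flipped and the dropped condition (e.g. excitatory, none, inhibitory),
*flipped* wins by default — a polarity reversal is the stronger, more
specific event — and the precedence is configurable.

Two population normalizations are provided. `normalize_cell_set()`
applies one affine map per cell (zero mean onset value across odors,
unit global peak). `normalize_by_peak()` scales by the cell's largest
across-odor *amplitude*, defined as the maximum absolute deviation of
the exponentiated snifflet from the cell's constant (prior-mean) rate —
the amplitude scale is otherwise underdetermined, and this definition
makes the peak odor attain exactly 1 for excitatory peaks.

Group comparisons go through `stats::chisq.test` (Pearson, uncorrected),
`stats::ks.test` (two-sample) and `stats::wilcox.test` (signed-rank)
behind thin wrappers that handle the degenerate all-tied case; the test
suite checks each against independent closed-form computations.

## Optogenetic identification

`psth()` bins spikes in 4 ms bins over [-50, 100] ms around light pulses
triggered at inhalation onset, with edges anchored at the event.
`classify_light_response()` calls a cell light-responsive when the light
PSTH exceeds the no-light PSTH by at least one reference SD in some bin
starting within 50 ms; the latency is the first such bin's start. With
4 ms bins at single-digit baseline rates many control bins contain zero
spikes in every trial, making the empirical across-trial SD zero and a
raw "1 SD" criterion vacuous; the reference SD is therefore floored at
$\sqrt{\bar c + 1/n_{\mathrm{trials}}}$, the Poisson SD implied by the
observed control rate plus one-spike resolution. This restores
calibration in sparse bins and leaves well-populated bins untouched. A
pooled-SD variant is available via `pooled_sd = TRUE`.
`latency_exclusion()` removes slow responders by a fixed 20 ms cutoff or
by the Tukey upper fence $Q_3 + 1.5\,\mathrm{IQR}$ (type-7 quartiles;
the fence convention is stated because it changes the bound).

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth without any downloads. It emulates:

* **Sniffing.** Inhalation durations from a two-component log-normal
  mixture — medians 60 ms (fast) and 150 ms (slow), common
  $\sigma_{\log} = 0.4$, fast weight 0.15 — and log-normal exhalations
  (median 200 ms). These values reproduce the two features of real
  freely-breathing recordings that matter here: about 75% of sniffs
  have inhalations longer than 100 ms, and durations spread over close
  to a decade. The broad spread is not cosmetic — per-sniff dilation
  variability is exactly what makes the dilation-scheme comparison
  identifiable.
* **Templates.** Per cell–odor log-rate deviations on a baseline of
  8 spikes/s (a free parameter in the plausible range for these
  neurons) with a mild smooth baseline phase tuning (SD 0.2):
  *stereotyped* = early excitatory bump (center within the first third
  of inhalation, gain at least $\log 3$) plus a smooth tail;
  *diverse* = Gaussian-process draw (length-scale $D/3$, SD 0.6) with
  random first-excursion sign; *inhibitory* = early suppression;
  *null* = no deviation. Deviations taper toward baseline over the late
  sniff, where data coverage is sparse.
* **Concentration series.** Per-concentration multipliers on the
  deviation: graded same-sign scaling (*consistent*), a zeroed lowest
  concentration (*dropped*), or a polarity reversal (*flipped*). A
  reversal is implemented as a broad suppression spanning the
  inhalation rather than a sign-flipped narrow bump: a narrow
  suppression carries too few spikes to clear a pointwise $3\sigma$
  criterion in log space, while a broad one is both detectable and the
  more realistic reversal phenotype.
* **Spiking.** Exact inhomogeneous-Poisson sampling by thinning against
  the dilated piecewise-constant rate; the time-rescaling theorem (KS
  test of rescaled ISIs against Exp(1)) is verified in the suite.
* **Light trials.** Tagged cells receive an added rate pulse of 15×
  baseline for 10 ms at 6 ms latency after pulses triggered at
  inhalation onset — roughly one extra tightly time-locked spike per
  pulse, typical of direct channelrhodopsin drive — with 50 light and
  50 no-light trials.
* **Sessions.** Each trial is a block of baseline sniffs followed by an
  odor onset placed 5 ms before the next sniff, so "first sniff after
  odor onset" and "three seconds before onset" select exactly the
  intended sniffs. All randomness derives from one master seed through
  per-cell, per-condition child seeds, so any subset is independently
  reproducible and the dataset is byte-identical across runs.

What passing tests on these data do **not** show: robustness to
non-Poisson spiking (bursting, refractoriness), sniff-to-sniff rate
drift, overlap of responses across sniffs (the no-reset model variant
is not implemented), imperfect sniff detection, or the particular
response statistics of the real recorded populations.

## Problem sizes used by the test and acceptance runs

Chosen so the full chain is exercised at meaningful statistical power:
oracle agreement on 20 instances with $KD \le 8$; template recovery on
500 sniffs at $D=30, K=4$; scheme recovery on 10 replicate seeds of 400
sniffs at $D=12, K=3$ with 4 folds and a reduced hyperparameter grid
(the evidence surface is smooth, and the reduced grid changes none of
the rankings); calibration and power on 100 cells × {null, stereotyped}
odors at the generator's default 60 trials per condition; opto tagging
on 40 cells at default light settings. Scheme recovery uses
diverse-mode templates because structure throughout the sniff cycle —
not just the inhalation transient — is what distinguishes inhalation
dilation from the two-piece alternative.

## Known limitations

* The exact smoothness-prior parameterization and evidence-optimization
  algorithm of the original analysis are not printed in any source
  available to this package; the squared-exponential kernel with
  grid-plus-simplex evidence search is a faithful, documented stand-in.
* The pressure-based sniff detector is a convention (low-pass smooth,
  running-median baseline, MAD-scaled trigger extended to zero
  crossings); no detection algorithm is prescribed by the analysis this
  package implements, and detector parameters should be validated per
  recording setup.
* Pointwise $3\sigma$ calls apply no multiple-comparison correction
  across the $KD$ bins; the null false-call rate is quantified on
  synthetic data instead.
* The `none` scheme's reference duration defaults to the session median
  inhalation; comparisons across sessions with very different sniffing
  should fix `d_ref` explicitly.
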