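---
title: "Directed information as a measure of effective connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed information as a measure of effective connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodi)
```

## The problem

Functional neuroimaging signals (EEG, MEG, LFP) are recorded as repeated
trials of multichannel time series. *Effective connectivity* asks a directed
question of such data: does the past of channel X carry information about
the present of channel Y beyond what Y's own past already carries?
Model-based answers (Granger causality and its MVAR relatives) measure this
through linear prediction-error reduction; information-theoretic answers
measure it through conditional dependence of distributions and therefore do
not commit to a signal model.

This package implements the directed-information (DI) family of measures
for trial-based data: plain DI, time-lagged DI, and a fixed-window upper
bound (MDI) that keeps the estimation dimension constant as the series
grows, together with model-free order selection, permutation-based
significance testing with false-discovery-rate control, benchmark
simulators with known ground truth, and a time-domain Granger comparator.

## Measures

For sequences $X^N, Y^N$, directed information is

$$\mathrm{DI}(X^N \to Y^N) \;=\; \sum_{n=1}^{N} I(X^n; Y_n \mid Y^{n-1})
 \;=\; \sum_{n=1}^{N}\big[ I(X^n;Y^n) - I(X^n;Y^{n-1}) \big],$$

the accumulated information the source's past-and-present provides about
each new target sample. Unlike mutual information it is asymmetric, and for
jointly Gaussian processes its rate equals Geweke's linear-feedback index
$F_{X\to Y} = \tfrac12 \log\left(\sigma^2_{\mathrm{reduced}} /
\sigma^2_{\mathrm{full}}\right)$, which is the bridge to Granger causality
exploited by the cross-checks in the test suite
(`directed_information()`, `granger_f()`).

Estimating DI directly requires joint densities of dimension growing with
$N$. For a stationary Markov pair in which the source influences the target
through at most $p$ lags, conditioning the per-sample terms on a length-$p$
window instead of the whole past gives the *modified time-lagged DI*

$$\mathrm{MDI}(X^N \to Y^N) \;=\; \sum_{n=p+1}^{N}
 I\!\big(X_{n-p..n-1};\, Y_n \mid Y_{n-p..n-1}\big),$$

an upper bound on DI (conditioning on less can only increase each term)
whose estimation dimension stays at $2p+1$ (`mdi()`, `mdi_components()`).
The transmission delay is fixed at one sample: testing at lag 1 loses no
information flow relative to the unknown true delay, only some estimator
efficiency. The intermediate `time_lagged_di()` form, defined on blocks of
two consecutive samples with an explicit delay, is also provided; it equals
full DI when the delay matches the system and the target has one-sample
memory.

All information quantities are reported in bits. Joint densities at each
time index are estimated *across trials* (trials as i.i.d. realizations),
which is what makes the measures applicable to nonstationary event-locked
data; an optional `pooled` mode additionally stacks time windows for
stationary data.

## Estimators

Three mutual-information estimators stand behind every measure
(`estimator_config()`):

* **`adaptive_partition`** (default): recursive partitioning of the
  rank-transformed joint sample. Each cell is scored by 2×2 chi-square
  statistics of every (source-coordinate, target-coordinate) median split;
  the best pair is split while the one-level (df 3) or the two-level
  look-ahead (16 cells, df 15) statistic exceeds its upper
  `ap_significance` quantile and every child keeps at least `ap_min_cell`
  points. The pruning quantile defaults to the null median (0.5): testing
  at a conventional 5% level leaves cells unsplit whose residual dependence
  is individually undetectable but collectively large, and biases MI
  downward by more than the estimator's attainable accuracy (on a bivariate
  Gaussian with $r = 0.5$, $n = 8192$: $-0.06$ bits at the 5% level versus
  $-0.02$ at the median rule, with independent-pair bias below $0.003$
  bits). Spurious splits are cheap — each adds roughly
  $\chi^2 / (2 n \ln 2)$ bits — which is why the liberal rule is the right
  default. Its cost shows up only in high dimensions, where the
  permutation null absorbs the common bias.
* **`gaussian`**: covariance determinants, exact for Gaussian data and
  deterministic given the sample. Degenerate (totally dependent) inputs are
  a definite error.
* **`histogram`**: fixed equal-width binning; a simple cross-check.

Conditional MI is always computed as $I(X;(Y,Z)) - I(X;Z)$ so that only
two-block MIs are estimated and part of the bias cancels. Negative
nonparametric estimates are preserved; clipping happens only inside the
normalization. A pair of series that are exact copies (or an invertible
static mixture) of one another is detected up front and every conditional
term is taken as zero — the target is deterministic given the conditioning
set, and no directional asymmetry exists.

## Significance testing

The null "no information flow from X to Y" is simulated by shuffling the
trial pairing of the source (`trial_shuffle_null()`): each trial keeps its
temporal structure, but the alignment with the target's trials is
destroyed. The observed statistic is compared with the empirical
95th-percentile threshold of 100 shuffles, and p-values use the add-one
rule $p = (1 + \#\{ \text{null} \ge \text{obs}\}) / (1 + K)$. Granger
comparisons on single realizations use time shuffling instead
(`time_shuffle_null()`). Families of p-values (all channel pairs) are
thresholded by Benjamini–Hochberg step-up at FDR bound $q$
(`fdr_select()`).

The statistic actually tested by `mdi_test()` is the *normalized* measure

$$\rho = \frac{[\mathrm{MDI}_{x\to y}]_+}{[\mathrm{MDI}_{x \to y}]_+ +
[\mathrm{MDI}_{y \to x}]_+ + [\mathrm{inst}]_+},$$

where `inst` is the windowed instantaneous exchange (the gain from adding
the source's *current* sample to the conditioning window) and $[\cdot]_+$
clips at zero. Without instantaneous coupling the denominator estimates
$I(X^N;Y^N)$ and $\rho$ is the usual DI fraction in $[0,1]$; a
unidirectional system gives $(1, 0)$ and an undirected one $(0.5, 0.5)$.
The normalization is not cosmetic: for a common source observed on two
sensors (volume conduction), the zero-lag exchange inflates the denominator
and both directions' $\rho$ collapse, which is what lets the test decline
spurious "causality" that a raw lagged statistic would report — the raw
MDI of a common AR source is *genuinely* positive, because the source's
past predicts the noisy sensor's future. The raw statistic remains
available (`statistic = "raw"`).

## Order selection

The MDI window $p$ is chosen model-free by the Cao false-nearest-neighbour
criterion (`cao_dimension()`, `select_order()`): delay vectors of embedding
dimension $d$ are pooled across trials, each point's nearest neighbour
(maximum norm) is found, and $E1(d) = E(d+1)/E(d)$ tracks how distances
expand when a coordinate is appended. The returned order is the smallest
$d$ at which the $E1$ curve has saturated — successive difference below
`e1_tol` (0.05) with all later values within `plateau_tol` (0.1). The delay
is fixed at $\tau = 1$, the natural choice for discrete-time signals. For a
pair, the order is the larger of the two channels' estimates. Cao's noise
diagnostic $E2$ is attached to the result but does not alter it.

Two behaviours of this criterion matter in practice and are verified in the
tests. On deterministic signals the rule is sharp: a sampled sinusoid gives
$d = 2$ and the chaotic Lorenz response gives $d = 3$, matching brute-force
false-neighbour counts. On *stochastic* signals $E1$ approaches its plateau
gradually (a finite-sample property of nearest-neighbour distances — pure
white noise shows the same creep), and the estimate concentrates one step
above the generative order for random-coefficient AR(5) ensembles at
1024 trials × 60 samples: the modal estimate is 6, not 5. We report this as
measured rather than re-tuning the plateau rule, because every rule we
examined that recovers 5 on those ensembles breaks the deterministic
oracles or amounts to per-case thresholds. An MDI window one above the true
order loses no information flow; it only costs estimation efficiency.

## Benchmark simulators

Five seeded generators with known ground truth serve as the package's
validation bed (all coefficients drawn standard normal with unstable
systems rejected, matching the benchmark convention; 100 burn-in samples
discarded):

1. **Linear AR pair** (`simulate_linear_ar()`): order-5 marginals, coupling
   $\gamma \sum_{i=p_1}^{p_2} X(n-i)$ into Y. Unidirectional ground truth.
2. **Nonlinear AR pair** (`simulate_nonlinear_ar()`): same skeleton with
   sigmoid coupling $1/(1+\exp(b_1 + b_2 X(n-i)))$, $b_1 = 0$, $b_2 = 50$ —
   a near-step nonlinearity.
3. **Linear mixing** (`apply_mixing()`): sensor-space mixtures
   $X_\epsilon = (1-\epsilon)X + \epsilon Y$,
   $Y_\epsilon = \epsilon X + (1-\epsilon) Y$; at $\epsilon = 0.5$ the
   mixtures are identical.
4. **Common source** (`simulate_single_source()`): one AR(5) source on both
   sensors, one corrupted by noise with weight $\epsilon$ (SNR from
   $+19$ to $-19$ dB across $\epsilon = 0.1 \ldots 0.9$). No lagged
   causality between sensors by construction.
5. **Delay-coupled Lorenz oscillators** (`simulate_lorenz_pair()`):
   $A = 10$, $R = 28$, $B = 8/3$, forward-Euler $dt = 0.01$, drive
   $\beta X_1(t - t_p)$ with $t_p = 0.02$ (2 samples) into the second
   oscillator; 100 samples per trial with the first 90 discarded.
   Unidirectional chaotic ground truth.

For the linear model the package also provides the *exact* joint
covariance of $(X^N, Y^N)$ — stationary via the discrete Lyapunov
equation, or propagated from the simulator's independent-normal initial
condition (`linear_ar_cov()`) — and closed-form Gaussian DI on it
(`di_gaussian_exact()`). These closed forms are the oracles for every
estimator test: sample covariances converge to the Lyapunov solution,
conservation $\mathrm{DI}_{x\to y} + \mathrm{DI}_{y \to x} = I(X^N;Y^N)$
holds exactly under independent start-up, Massey's conservation law with
the delayed reverse direction holds for any start-up, and
$\mathrm{MDI} \ge \mathrm{DI}$ is exact.

A subtlety the exact forms make visible: when a simulation is started from
its *stationary* law, the first samples already share information
accumulated over the infinite past, so the early DI terms count a
zero-lag-like exchange, the plain two-way conservation identity gains an
extra term, and the reverse DI of a unidirectional system is slightly
positive. The benchmark analyses therefore treat early samples as part of
the burn-in, and identity checks use the independent start-up covariance.

## Study conditions used by the benchmark analyses

`scripts/acceptance.R` re-runs the simulation studies at a reduced scale
and writes the headline numbers as JSON. The conditions are fixed once:

* 1024 trials per simulation (the study design scales this down from 4096),
  60 retained samples, MDI window $N = 20$, order $p = 5$ (the generative
  order of the AR benchmarks), 100 trial shuffles at $\alpha = 0.05$,
  majority vote over 5 seeds on the $\epsilon$/$\gamma$ grids, 20
  simulations per $\epsilon$ for the specificity study, 10 seeds for the
  order-recovery study, 2048 trials for the Lorenz study.
* The **covariance-based estimator** is used for these studies. At 1024
  trials the partition estimator's $(2p+1)$-dimensional conditional terms
  are too coarse to detect even the strongly coupled linear benchmark
  against its shuffle null (verified; the original studies' power rests on
  4096 trials), whereas the AR and common-source benchmarks are exactly
  Gaussian, and the sigmoid coupling — a near-step function whose
  correlation with its Gaussian argument is $\approx 0.8$ regardless of
  scale — is detectable through its covariance footprint.
* Granger comparisons use single realizations of length 1024 and the same
  order 5, with 100 time shuffles. A rank-deficient fit (identical
  mixtures at $\epsilon = 0.5$) counts as non-detection.

Two caveats on what passing or failing these studies shows. First, the
generators emulate idealized benchmarks — Gaussian innovations, exact AR
structure, no measurement drift, no 1/f background — so agreement there
does not certify behaviour on real EEG. Second, detection boundaries on
the $\epsilon$/$\gamma$ grids are properties of test *power*, not of the
measures alone: a sharper estimator detects weaker coupling (our
covariance-based test first declares the sigmoid coupling significant at
$\gamma = 0.1$) and keeps genuine lagged structure visible where a noisier
estimator reports nothing (common-source sensors at low SNR carry real
lagged information from the source's dynamics, which caps the attainable
specificity of any sufficiently powerful lagged test; the windowed MDI
bound is loose exactly there because a short noisy target window reveals
much less of the source than the full history would). Equally, a plain
least-squares Geweke index *does* detect the near-step sigmoid coupling
and the moderately mixed linear pairs at these sample sizes — the linear
component of the coupling is simply large — so comparator findings that
depend on a weaker GC pipeline do not reproduce here. The acceptance suite
asserts the original studies' boundaries at their stated tolerances and
leaves the cases that a faithful reimplementation genuinely contradicts
red rather than weakening them; the measured values are what
`scripts/acceptance.R` reports.

## The connectivity pipeline

`pairwise_connectivity()` runs the full analysis over a multichannel
ensemble: optional zero-phase Butterworth band-pass (forward–backward, so
no group delay masquerades as lagged causality), an explicit analysis
window, per-pair Cao order, MDI tests with trial-shuffle nulls, GC tests on
trial-concatenated (per-trial demeaned) series with time-shuffle nulls, and
separate BH/FDR thresholding of the DI and GC p-value families. Note that
the attainable p-value floor is $1/(K+1)$ for $K$ shuffles, so $K$ must
grow with the number of pairs for the step-up rule to be able to select
anything. Ensembles travel as long-form CSV (`channel,trial,time,value`),
results as JSON plus CSV matrices; a thin command-line wrapper lives at
`inst/cli/neurodi.R`.

## Numerical choices and edge cases

* Thresholds: the empirical threshold is the smallest null value with at
  least $(1-\alpha) K$ null values below it; a constant statistic yields a
  threshold equal to that constant (never exceeded strictly).
* `estimate_mi()` canonicalizes the argument order so MI is bit-exactly
  symmetric; all shuffle machinery is seeded and bit-reproducible.
* The adaptive-partition DI on growing windows refuses horizons beyond
  $\log_2(\text{trials})$ and points to `mdi()` instead.
* Euler integration of the Lorenz pair regenerates trials whose state
  exceeds $10^6$ (counted in an attribute); the delay buffer is seeded with
  the initial condition.
* The Lorenz Cao estimate uses an 8000-point neighbour pool and the modal
  value over five independent simulations: this system's plateau-entry
  $E1$ difference sits almost exactly at the saturation tolerance, so
  single runs are bimodal between 3 and 4, and the default 2000-point
  subsample adds enough $E1$ noise to blur the boundary further.
* `normalized_di()` returns $(0.5, 0.5)$ with an `undefined` flag when both
  clipped inputs vanish.

## Limitations

Pairwise only: conditional DI between three or more processes is out of
scope, so indirect paths are not disambiguated. The MDI bound assumes an
(approximately) stationary Markov pair within the analysis window. The
normalized statistic inherits the windowed MI surrogate in its
denominator; for strongly nonstationary data the per-time-step mode with
trials as realizations is the faithful choice, and single-trial data can
only use the pooled mode under a stationarity assumption.
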