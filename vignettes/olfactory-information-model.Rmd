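---
title: "An information-theoretic model of odor coding in the fly mushroom body"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An information-theoretic model of odor coding in the fly mushroom body}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymi)
```

## The question

*Drosophila* learns odors at synapses downstream of the mushroom body, so
whatever the antenna detects must survive two noisy relays — the antennal
lobe and the projection-neuron → Kenyon-cell synapses — before it can be
learned. `flymi` treats this pathway as a discrete information channel and
asks how transmission efficiency, the mutual information (MI) between odor
identity and the Kenyon-cell population state, depends on four knobs: the
connectivity rate `r` between antennal lobe and mushroom body, the
Kenyon-cell firing threshold `theta`, the odor concentration `c`, and the
strength `alpha` of activity-dependent feedback inhibition onto the
Kenyon cells.

The study is fully synthetic: the package's environment generator *is* the
data source, and every result is a Monte-Carlo experiment whose conditions
are fixed by the model's defaults.

## The model, stage by stage

**Environment.** A panel holds 𝔎 equiprobable odors (default 5) over
`n_glomeruli = 50` glomeruli, identified one-to-one with olfactory
projection neurons (OPNs). An odor is a fixed subset of "reachable" OPNs —
the glomeruli its chemical components can excite — plus a concentration
`c` shared by all odors of an experiment. Subset sizes are drawn from
Normal(μ = 35, σ² = 8), rounded, and clamped to [1, 50]; we read the 8 as
a *variance* (sd ≈ 2.83). Clamping keeps every odor detectable and is
essentially inert at the defaults (a draw below 1 is a > 12-sigma event);
the subsets themselves are uniform without replacement, so two odors are
distinguishable only through which ~35 of 50 OPNs they can recruit.

**Antennal lobe.** On each trial, each reachable OPN fires independently
with probability `1 - exp(-beta * c)` (`activation_probability()`), with
`beta = 1.32`. This is the only place concentration enters: low `c` makes
reached OPNs fire rarely, high `c` reliably. Unreached OPNs stay silent.

**Mushroom body.** One "fly" is one binary connectome: OPN `j` synapses
onto Kenyon cell `i` with probability `r` (default 0.3, the empirically
estimated sparseness of this projection). Kenyon cells are binary threshold
units firing iff their summed input *strictly* exceeds `theta`; we use the
strict inequality because the threshold is defined by the two-case rule
"fire above, stay silent at or below". The response stage is a pure
function — all trial-to-trial noise lives upstream.

**Feedback inhibition.** GABAergic feedback onto the calyx is modelled as
one lumped, stochastic spike-deletion step: each pre-inhibition spike in a
trial is removed independently with probability `exp(-alpha * activity)`,
computed once from the pre-inhibition state (a single pass, no fixed-point
iteration). Smaller `alpha` means stronger inhibition, and weakly active
trials are suppressed hardest — a homeostatic normalisation that prevents
the saturated, all-cells-fire regime at high concentration from collapsing
every odor onto the same state.

### What "activity" means in the inhibition law

The activity `χ̃` in `exp(-alpha * χ̃)` could be the *count* of active
Kenyon cells or their active *fraction*. The package defaults to the
fraction (the mean of the binary population state, a quantity in [0, 1]
that is invariant to the population size), and exposes the count reading
via `inhibition_activity = "count"`. Two reasons for the default:

* dimensional sense — with `alpha` in its working range 0.05–1.75 and the
  activity normalised to [0, 1], the deletion probability spans the full
  useful range for any `N_KC`, and the same `alpha` means the same thing
  for a 10- and a 20-cell population;
* behaviour — under the fraction reading, sweeping `alpha` at high
  concentration produces an interior optimum (moderate inhibition beats
  both no inhibition and very strong inhibition), which is the regime the
  model is meant to explore; under the count reading with `N_KC = 10`,
  `alpha * χ̃` is so large for any appreciable activity that only the very
  strongest inhibition setting differs from no inhibition at all.

Both readings are implemented, tested, and seed-stable.

## Measuring information

With `N_KC` cells the response is one of `2^N_KC` states, encoded as an
integer (`encode_state()`; cell `i` contributes `2^(i-1)`). From `N` trials
per odor we build the joint contingency table (`tabulate_trials()`; only
observed states are stored — unobserved states carry zero mass and cancel
from the sum) and apply the plug-in estimator (`plugin_mi()`), in bits by
default (`log_base` switches to natural log). For calculability the
probability of a never-observed state is floored at `1e-8`; under the
`0·log 0 = 0` convention this floor never changes the value, and we keep it
explicit rather than silently dropping it.

The plug-in estimator is biased upward at finite `N` — sampling noise looks
like information. `mi_extrapolate()` corrects this by quadratic
extrapolation: the trials of each odor are partitioned once, at random and
stratified per odor (so every subsample keeps the odors equiprobable), into
2 disjoint halves and 4 disjoint quarters; MI is estimated at `N`, `N/2`
(average of the two halves) and `N/4` (average of the four quarters); and
the exact solution of

$$ MI(N') = MI_\infty + a/N' + b/N'^2 $$

through those three points gives the reported `mi_corrected` $= MI_\infty$,
algebraically identical to subtracting the fitted `a/N + b/N^2` from the
full-sample estimate. One random partition per estimate is the standard
practice; at very small `N` the extrapolation can overshoot below zero, in
which case the estimate is floored at 0 with a classed warning (MI is
non-negative by definition). `N` must be at least 8 and divisible by 4 so
the partitions are exact.

```{r}
trials <- data.frame(odor = rep(1:4, each = 16), state = rep(c(3, 9, 1, 20), each = 16))
mi_extrapolate(trials, seed = 1)
```

A deterministic odor → state map has no sampling bias, so the correction
leaves it untouched (`a = b = 0`), and a perfect 4-odor channel sits at
the `log2(4) = 2`-bit ceiling.

## The experimental protocol

`experiment_config()` + `mi_sweep()` run the full design: per fly replicate
(default 20) a fresh odor panel and, per connectivity rate, a fresh
connectome are drawn; each (concentration, `r`) cell is simulated once per
fly — 100 trials per odor — and re-thresholded for every `theta` and
`alpha`, so the same afferent noise underlies the whole threshold sweep of
a fly, exactly as one animal would be tested across conditions. Corrected
MI is averaged across flies (`mi_mean`, `mi_sd`). Giving each fly its own
panel makes the fly average span odor-structure variability as well as
connectome variability; `shared_panel = TRUE` switches to a common panel
when only connectome variability is wanted.

Reproducibility is by construction: every sub-task (panel, connectome,
trial block, inhibition draw, subsampling partition) obtains its own seed
from the master seed through a labelled counter hash (`derive_seed()`), so
a sweep is bit-for-bit reproducible and independent of the order in which
grid points are evaluated.

Read-outs: `argmax_threshold()` (and its transpose `argmax_connectivity()`)
return the grid point maximising the across-fly mean; finite sampling can
tie, in which case the smaller value is returned with a message — a
deterministic, conservative tie-break. `autoplot()` renders `theta × r`
heatmaps; `write_sweep_csv()` archives a sweep with its full configuration
in comment headers.

## What the defaults imply

At `r = 0.3` the expected synaptic drive onto one Kenyon cell is
`r × 35 × (1 − e^{−βc})` — about 1.9 synaptic inputs at `c = 0.15` and 6.6
at `c = 0.75`. The informative threshold region therefore sits at small
`theta` for low concentration and shifts right as concentration (or `r`)
grows; thresholds beyond the drive's upper tail silence the population and
MI falls to zero. This scaling is worth keeping in mind when choosing
grids: the interesting structure of the `theta × r` surface lies near
`theta ≈ r × N_active`.

## What the generator does and does not emulate

The generator reproduces the statistical skeleton the model assumes:
equiprobable discrete odors, Gaussian-sized uniform reachable sets, one
shared concentration, Bernoulli connectomes, independent-per-trial OPN
noise. It does **not** emulate chemical similarity structure (overlap
between odors is purely combinatorial), odor mixtures, temporal dynamics,
correlated OPN noise, or glomerulus-specific tuning. Passing tests
therefore validate the model's internal consistency and its parameter
dependence — not quantitative predictions about real recordings.

## Numerical choices and scales

* Strict `>` threshold comparison; all-silent inputs always yield
  all-silent outputs.
* Corrected MI is clamped at 0 (warning class `flymi_warning_clamped`).
* The `1e-8` unobserved-state floor is kept explicit but inert.
* Ties in argmax read-outs break toward the smaller parameter, with a
  message.
* The test suite exercises the full protocol (20 flies, 100 trials, 20
  thresholds, 20 master seeds) only for the study-level checks; structural
  and property tests run at reduced scale (2–6 flies, 16–60 trials,
  coarse grids), which we chose as the smallest designs at which the
  tested properties are stable across seeds.
* `N_KC` up to ~25 is comfortable with the sparse (observed-states-only)
  tables; the dense `2^N_KC` state space is never materialised.

## Known limitations

* The antenna and antennal lobe are collapsed into a single stochastic
  stage; lateral-horn feed-forward inhibition is not distinguished from
  mushroom-body feedback — one lumped deletion probability stands for
  both.
* Neurons are binary per trial; no membrane dynamics, spike timing or
  rate coding.
* The quadratic extrapolation is the only bias correction offered; for
  severely undersampled regimes (many more states than trials) no
  second-order correction is trustworthy, and estimates near zero should
  be read as "indistinguishable from zero".
* Whether `alpha` should be rescaled when `N_KC` changes is an open
  modelling question; the fraction-based default makes the law
  size-invariant by construction, which is our answer to it, but the
  count-based variant intentionally is not.
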