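# flymi

Mutual information in a stochastic model of the *Drosophila* olfactory
circuit.

`flymi` is for computational neuroscientists who want to ask how much an
insect mushroom body can know about the odor environment, and how that
depends on circuit parameters. It simulates an abstract feed-forward model
of the fly olfactory pathway and measures transmission efficiency as the
mutual information (MI) between odor identity and the Kenyon-cell
population response, with proper finite-sampling bias correction.

## The model

An environment is a panel of 𝔎 equiprobable odors over 50 glomeruli (one
olfactory projection neuron, OPN, per glomerulus). Odor *k* reaches a fixed
random subset of OPNs whose size is drawn from a rounded
Normal(μ = 35, σ² = 8), clamped to [1, 50]. On each trial, every reached
OPN *j* fires independently,

&nbsp;&nbsp;&nbsp;&nbsp;P(χ<sub>j</sub> = 1) = 1 − e<sup>−βc</sup>,

with concentration c ∈ (0, 1] and β = 1.32. The antennal-lobe state is read
by N<sub>KC</sub> binary Kenyon cells through a Bernoulli(r) connectome
c<sub>ij</sub>; cell *i* fires iff its summed synaptic input strictly
exceeds the threshold Θ:

&nbsp;&nbsp;&nbsp;&nbsp;ψ<sub>i</sub> = 1 iff Σ<sub>j</sub> c<sub>ij</sub> χ<sub>j</sub> > Θ.

Optionally, activity-dependent feedback inhibition deletes each spike
independently with probability p<sub>I</sub> = e<sup>−α χ̃</sup>, where χ̃
is the trial's pre-inhibition mushroom-body activity (by default the active
*fraction* of Kenyon cells; a raw-count variant is available) and smaller α
means stronger inhibition.

Information transmission is measured as

&nbsp;&nbsp;&nbsp;&nbsp;MI = Σ<sub>n,k</sub> p(n, k) log₂ [ p(n, k) / (p(n) p(k)) ] ,

over the 2^N<sub>KC</sub> population states *n*, estimated from 100 trials
per odor with the plug-in estimator and corrected for finite-sampling bias
by quadratic extrapolation: MI is re-estimated on disjoint halves and
quarters of the trials, the quadratic MI(N′) = MI<sub>∞</sub> + a/N′ + b/N′²
is solved exactly, and MI<sub>∞</sub> is reported.

## Worked example

Estimate MI for one fly (one random connectome) smelling a 5-odor panel at
high concentration:

```r
library(flymi)

panel <- draw_odor_panel(5, concentration = 0.75, seed = 42)
cn <- sample_connectome(10, r = 0.3, seed = 2)
trials <- purrr::map_dfr(1:5, function(k) data.frame(
  odor = k,
  state = encode_state(simulate_trial(panel[k, ], cn, theta = 4,
    n_trials = 100, seed = derive_seed(3, k)))))
mi_extrapolate(trials, seed = 4)
#> Mutual information (5 odors, 100 trials/odor)
#>   plug-in: 0.5512 bits
#>   corrected (quadratic extrapolation): 0.4617 bits
```

The plug-in estimate overstates the transmitted information (any sampling
noise looks like signal); the extrapolation removes about 0.09 bits of
bias here. The ceiling for 5 equiprobable odors is log₂ 5 ≈ 2.32 bits.

Parameter sweeps follow the full protocol — per fly replicate a fresh odor
panel and connectome, 100 trials per odor, bias-corrected MI averaged over
20 flies — and return tidy tables:

```r
cfg <- experiment_config(concentration = 0.75, alpha = c(NA, 0.9),
                         theta = c(2, 4, 6, 8), seed = 1)
sw <- mi_sweep(cfg)
sw
#> # A tibble: 8 × 7
#>   concentration     r theta alpha mi_mean  mi_sd n_flies
#>           <dbl> <dbl> <dbl> <dbl>   <dbl>  <dbl>   <int>
#> 1          0.75   0.3     2  NA     0.278 0.156       20
#> 2          0.75   0.3     2   0.9   1.66  0.0741      20
#> 3          0.75   0.3     4  NA     0.930 0.271       20
#> 4          0.75   0.3     4   0.9   1.48  0.152       20
#> 5          0.75   0.3     6  NA     1.22  0.183       20
#> 6          0.75   0.3     6   0.9   0.685 0.197       20
#> 7          0.75   0.3     8  NA     0.764 0.216       20
#> 8          0.75   0.3     8   0.9   0.225 0.0931      20
argmax_threshold(sw, is.na(alpha))
#> [1] 6
```

At permissive thresholds the uninhibited circuit saturates (almost every
cell fires on every trial, states collapse, MI drops to 0.28 bits at
Θ = 2) and moderate feedback inhibition rescues the code (1.66 bits);
at strict thresholds inhibition silences an already sparse code and hurts.
`autoplot(sw)` draws Θ × r information surfaces as heatmaps;
`write_sweep_csv()` / `read_sweep_csv()` archive sweeps with their full
configuration; `tidy()` / `glance()` give broom-style access to MI
estimates.

Everything is deterministic given the master seed: each panel, connectome,
trial block, inhibition draw and subsampling partition derives its own
stream from it via a counter scheme (`derive_seed()`), so results do not
depend on evaluation order.

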