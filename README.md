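# iifdc

Individual-based simulation and analysis of zooplankton depth selection in
overlapping gradients of algal food and visual-predation risk, under the
**interference ideal free distribution with costs**.

Pelagic grazers such as *Daphnia* trade a high growth rate near the
food-rich, brightly lit surface against a low mortality risk at depth, and
both sides of the trade-off depend on how many conspecifics share a layer:
crowding reduces intake through interference, and the predation risk felt
by one individual depends on the local prey density through the predator's
functional response. `iifdc` is for modellers and experimentalists who
want to simulate this optimisation, fit its vital-rate parameters to trial
data, and compare simulated with observed depth distributions.

## The model

A 1-m column is discretised into 10 stacked sectors (0.6 L each). Each
sector offers an age class (juvenile or adult) at local density *D*
(ind L⁻¹):

* growth
  `g = g0 + a1·F/(a2+F) − b·D − (c + u·[adult])·log10(1+I) − κ·[kairomone]`,
* mortality `m = 1/L + P·C(D)/D`, where `C` is a threshold-disc functional
  response `C(N) = α·M^n/(1 + α·h·M^n)`, `M = max(N − γ, 0)` (Holling
  type II for `γ = 0, n = 1`; type III with a low-density prey refuge for
  `γ > 0`), and the attack coefficient `α = π·RD²·v·86.4` L d⁻¹ derives
  from the fish's visual reaction distance
  `RD = (r0 + k·log10(1+I) + l·[adult])·(w_red·α_band + w_green + w_blue·φ)`,
* fitness `g/m` (the Werner–Gilliam growth-to-mortality criterion), with
  non-positive growth ranked by growth alone, strictly below it.

Agents are updated asynchronously in random order; each compares the
*perceived* fitness of staying versus moving one sector up or down —
sub-threshold relative differences in food or light (detection thresholds
æ_F = 0.19 juvenile / 0.08 adult, æ_I = 0.10) are invisible — and moves to
the strict maximiser, ties broken uniformly at random. Simulations release
all individuals in the fifth sector from the top, run 200 steps, discard
the first 100, and average 100 replicates.

## Worked example

Simulate juveniles in the overlapping-gradient treatment under the type
III scenario:

```r
library(iifdc)
cfg <- simulation_config(n_individuals = 60, age = "juvenile",
                         treatment = "both", response_type = "III",
                         n_replicates = 100, seed = 42)
res <- run_replicates(cfg)
res
#> <occupancy_result> 60 individuals, treatment 'both', juvenile, type III
#>   grand mean depth 0.538 m over 100 replicates
#>   mean distribution: 0.067 0.083 0.100 0.100 0.100 0.100 0.100 0.117 0.117 0.117
```

The grand mean depth (0.538 m) sits below mid-column: the population has
been pushed off the food-rich surface by light-dependent risk, but not to
the bottom, because at 10 ind L⁻¹ the type III threshold still shelters
thinly occupied sectors. Repeating with `treatment = "none"` gives ≈0.5 m
(uniform spread), `"food"` pulls the population to the surface sectors and
`"risk"` pushes it to the deepest ones.

Fit a functional response to synthetic feeding trials and select the type:

```r
truth  <- fr_params(attack = 1.2, handling = 0.002, gamma = 3.4158, n = 2)
trials <- gen_consumption(truth, noise_sd = 15, seed = 8)
fit2 <- fit_functional_response(trials, "II")
fit3 <- fit_functional_response(trials, "III")
fit3
#> <fr_fit> type III: attack=0.8554 L/d, handling=0.002078 d, gamma=3.818 ind/L, n=2.17; SSE=1719 (dof 20)
sel <- compare_response_types(fit2, fit3)
#> selected type III (F = 187.7, p = 1.1e-13)
scale_gamma_for_age(fit3$params$gamma, 2)   # threshold for adult-sized prey
#> [1] 0.0382
bonferroni_alpha(0.05, 12)                  # battery-wide per-test level
#> [1] 0.00417
```

The F-test detects the planted foraging threshold (`γ`, `n` jointly ≠ 0),
and the adult threshold is the juvenile fit reduced by two orders of
magnitude. `run_pipeline(config, out_dir)` chains all stages — generate,
fit, simulate both response-type scenarios, and run the 12- and
16-comparison ANCOVA batteries — into a directory of CSV reports; see the
methods vignette (`vignettes/iifdc-methods.Rmd`) for the model's
assumptions, parameter defaults and limitations.

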