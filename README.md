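# reactburst

Kinetic Monte Carlo simulation and closed-form theory for **reversible
dimerization in a compartmentalized membrane**.

The plasma membrane is not a free two-dimensional liquid: the actin
meshwork beneath it fences molecules into domains of tens of nanometers
between which they *hop* with a small crossing probability.  For a
reversible reaction M + M ⇌ D this has a striking consequence at the
single-molecule level: the long-run reaction rate is unchanged by the
fences, but reactions arrive in **bursts** — a dissociated pair trapped in
one compartment re-encounters and re-reacts many times before one partner
finally escapes, after which a long silent gap follows.  `reactburst` is
for quantitative membrane biophysicists who want to simulate that process,
measure it, and check it against theory, all in one package.

## The model

Random walkers on a periodic L × L square lattice (spacing a, time step
Δt) tiled into n × n-site compartments.  Interior sites step in each of
the 4 directions with probability 1/4; at a site with b adjacent barriers,
each barrier direction is taken with probability p and each remaining
direction with (1 − b·p)/(4 − b) — the walker always moves, and p = 1/4 is
exactly the free walk.  Co-occupying monomers dimerize with probability
p_r per step; dimers dissociate in place after an exponential lifetime
(mean τ_d, rounded up to whole steps) and obey the same step rule.  A
labeled *tracer* yields the event log.

The analytical layer provides, in closed form, the boundary permeability
P(p) = (a/Δt)/(4(1−p)/(3p) + 6/(1−p) − 12), the confinement strength
κ = Pℓ_c/D_micro, the hindrance ratio D_micro/D_macro = 1 + 1/κ, the
escape-time spectrum of a compartment (eigenrates from
α·tan(αℓ_c/2) = P/D), the fugitive probability
P_fug = T_re/(T_re + T_esc,2), the geometric burst-amplitude law with mean
⟨A⟩ = (1 − (1−P_fug)(1−p_r))/P_fug, the rate-invariance constant
c = 1/(2C) ≈ 1.04, and the equilibrium monomer fraction
φ = (−K + √(K² + 4NK))/(2N).  Every approximate formula is gated by an
exact Markov-chain oracle (absorbing chain, product chain, homogenization
corrector) computed by the package itself.

## Worked example

Ten molecules in a 10 × 10 array of 20 × 20-site compartments, strong
confinement (p = 0.002), diffusion-limited reaction (p_r = 1), dimer
lifetime 100 steps:

```r
library(reactburst)
cfg <- sim_config(lattice_spec(200, 20),
                  sim_params(crossing_prob = 0.002, reaction_prob = 1,
                             mean_dimer_lifetime = 100, n_particles = 10,
                             n_steps = 5e6, seed = 42))
log <- simulate_reactions(cfg)
log
#> <event_log> 2306 tracer reactions over 5e+06 steps (rate 0.000461/step), monomer fraction 0.953

part <- segment_bursts(log)      # tau_crit defaults to the pair escape time
part
#> <burst_partition> 168 bursts (tau_crit = 1848, dissociation_to_reaction), 167 gaps
#>   mean amplitude 13.7, mean gap 2.643e+04 steps

burst_theory(0.002, 20)[, c("kappa", "diffusion_ratio", "p_fug", "mean_amplitude")]
#>    kappa diffusion_ratio  p_fug mean_amplitude
#> 1 0.1213           9.242 0.1023          9.776
```

Reading the numbers: 2 306 reactions over 5 × 10⁶ steps is essentially the
free-diffusion rate (the invariance result), but they are concentrated in
168 bursts averaging ~14 reactions each, separated by gaps of ~2.6 × 10⁴
steps — three orders of magnitude longer than the within-burst waiting
time.  The closed-form pipeline predicts the burst amplitude from the
escape/re-encounter race (9.8 vs 13.7 observed; the simulated record also
merges bursts whose excursions return quickly, and censored first/last
bursts are retained).  `ratio_stats()` on a confined-vs-free pair of runs
shows R_mean ≈ 1 with R_std > 2 — the dispersion, not the mean, carries
the confinement signature.

Diagnostics: `autoplot(log)` (cumulative reaction staircase),
`autoplot(part)`, `plot_msd(estimate_msd(...))`, `autoplot(escape_spectrum(...))`;
`tidy()`/`glance()` return tibbles for every result type.  A thin CLI over
the same functions lives in `inst/cli/reactburst`
(`simulate`, `analyze`, `theory`, `validate`).

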