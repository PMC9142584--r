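# fibrilmix

Quantifying how two protein isoforms mix along the axis of an amyloid
filament from intermolecular REDOR solid-state NMR.

## The problem

Alzheimer's-disease tau filaments recruit both 4R and 3R tau isoforms
into one parallel-in-register cross-β fold, with hydrogen-bonded
neighbours stacked ~4.8 Å apart along the fibril axis. A ¹⁵N–¹³C REDOR
experiment on mixed-labeled samples (one isoform ¹⁵N-labeled, the other
¹³C-labeled) measures how often a ¹³C-labeled monomer sits next to a
¹⁵N-labeled one: the faster the dipolar dephasing S/S₀ decays with
mixing time, the higher the neighbour-labeling probability p(N→C).
`fibrilmix` implements the quantitative chain of reasoning that turns
such dephasing curves into a statistical description of isoform mixing,
for NMR spectroscopists and structural biologists working on mixed
amyloid systems.

## The model

Isoform succession along the axis is a two-state Markov chain with
transition probabilities p₄→₃ and p₃→₄. Assuming a uniform composition,
flux balance gives the stationary 4R mole fraction

    χ₄ = p₃→₄ / (p₃→₄ + p₄→₃)

and a mixing quotient, analogous to an equilibrium constant of mixing,

    Q = p₃→₄ p₄→₃ / (p₄→₄ p₃→₃),   p₄→₄ = 1 − p₄→₃,  p₃→₃ = 1 − p₃→₄,

with Q > 1 favouring alternation, Q < 1 favouring homotypic (block-like)
contacts and Q = 1 composition-agnostic mixing.

The transition probabilities are estimated by linear interpolation of
the measured S/S₀ values between two bracketing calibration curves with
known ¹³C fractions, point by point over the 8–25 ms mixing-time window,
after replicate averaging and division by the 0 %-¹³C reference curve
(natural-abundance correction). Spectral noise is propagated to the
estimate first-order. For synthetic data and property tests the forward
model is the second-moment (Van Vleck) Gaussian approximation,
M₂ = (1/5) Σᵢ (3000 Hz / rᵢ³)² and S/S₀(t) = exp(−4 M₂ t² / 3π²),
weighted over the four packing modes (N–N–N, N–N–C, C–N–N, C–N–C) by
their binomial probabilities. Monte-Carlo samplers generate isoform
chains under the rejection criteria used for filament models, and a
rigid-body helical builder (4.7 Å rise, 1°/monomer twist) produces long
annotated filaments in mmCIF.

## Worked example

```r
library(fibrilmix)

# measured transition probabilities with their uncertainties
p <- transition_probs(0.37, 0.56, p43_err = 0.03, p34_err = 0.02)
probabilities_to_descriptors(p)
#> Isoform mixing descriptors
#>   chi4 (4R mole fraction): 0.6022 +/- 0.0212
#>   Q    (mixing quotient):  0.7475 +/- 0.1137
```

The filament is 60 % 4R tau, and Q slightly below 1 means a small
preference for homotypic 4R–4R / 3R–3R contacts. The full estimation
pipeline runs on synthetic data generated at those probabilities:

```r
cfg <- synthesis_config(seed = 42)            # calibration + seeded curves
fit <- estimate_full_dataset(generate_seeded_dataset(cfg),
                             generate_calibration_series(cfg))
tidy(fit)
#> # A tibble: 4 x 3
#>   term  estimate std.error
#> 1 p43      0.370    0.0147
#> 2 p34      0.561    0.0176
#> 3 chi4     0.603    0.0121
#> 4 Q        0.749    0.0714
```

The estimator recovers the generating probabilities (0.37, 0.56) with
uncertainties on the scale a real campaign reports. A 360-monomer chain
accepted by the ±1-percentage-point rejection rule:

```r
ch <- simulate_until_match(transition_probs(0.37, 0.56),
                           length = 360, tol = 0.01, seed = 1)
chain_stats(ch)
#> # A tibble: 1 x 7
#>   length    n4    n3 chi4_emp   f43   f34 Q_emp
#> 1    360   219   141    0.608 0.362 0.567 0.745
```

`replicate_helix()` + `assign_isoforms()` then turn such chains into an
annotated filament model (~170 nm for 360 monomers at 4.7 Å rise), and
`run_pipeline()` chains all stages from curve files to estimate JSON,
chains and filament.

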