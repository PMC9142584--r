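---
title: "Methods: isoform mixing statistics of amyloid filaments from REDOR dephasing"
author: "fibrilmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform mixing statistics of amyloid filaments from REDOR dephasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the design of the
synthetic-data generator, and the numerical choices that a maintainer
would otherwise have to reverse-engineer from the code.

## The two-state Markov model of isoform succession

A parallel-in-register cross-β filament stacks monomers ~4.8 Å apart
along its axis. When two isoforms (4R and 3R tau) co-assemble, the
identity of each monomer's axial neighbours is modelled as a two-state
Markov chain with transition probabilities `p43` (a 4R monomer is
followed by 3R) and `p34` (3R followed by 4R); the complements
`p44 = 1 - p43` and `p33 = 1 - p34` are always derived, never stored.
Two assumptions underlie this: the composition is uniform along the
fibril, and there are no correlations beyond nearest neighbours (the
chain is first-order). Under those assumptions flux balance between the
two states fixes the stationary 4R mole fraction

$$\chi_4 = \frac{p_{3\to4}}{p_{3\to4} + p_{4\to3}},$$

and the preference for homotypic versus heterotypic contacts is captured
by the mixing quotient

$$Q = \frac{p_{3\to4}\,p_{4\to3}}{p_{4\to4}\,p_{3\to3}},$$

the analogue of an equilibrium constant for converting 4–4 and 3–3
interfaces into 4–3 interfaces. $Q = 1$ is composition-agnostic mixing
($p_{3\to4} = p_{4\to4} = \chi_4$); perfect alternation has infinite
$Q$ (the package raises an error rather than returning `Inf`);
$p_{43} = p_{34} = 0$ is two segregated homopolymers, a legal but
degenerate input on which any composition is stationary, so operations
that need a unique $\chi_4$ raise an error rather than returning 0/0.
A note on the one-step composition recursion sometimes quoted for this
model family: the self-consistent balance requires the heterotypic
probabilities, and `stationarity_residual()` implements that form,
$\chi_4 p_{4\to3} - (1-\chi_4) p_{3\to4}$, which vanishes exactly at the
stationary composition above.

The inverse map $(\chi_4, Q) \to (p_{43}, p_{34})$ eliminates
$p_{34} = p_{43}\chi_4/(1-\chi_4)$ and solves the resulting quadratic in
$p_{43}$; the root inside $(0,1)$ is selected, $Q = 1$ is handled as the
linear (agnostic) special case, and a bisection fallback with tolerance
1e-12 guards degenerate discriminants. Round trips are exact to better
than 1e-9 across $(0.01, 0.99)^2$ (property-tested on 1000 seeded
draws).

Uncertainties are propagated first-order (Gaussian): for example
$\sigma_{\chi_4} = \sqrt{(p_{43}\sigma_{34})^2 + (p_{34}\sigma_{43})^2}/(p_{34}+p_{43})^2$.
A Monte-Carlo oracle (10^6 Gaussian draws pushed through the closed
forms) backs this in the test suite; at the measured probabilities the
first-order and MC values agree to a few percent.

## The REDOR forward model

The forward model predicts the dephasing ratio S/S₀ of a ¹⁵N-labeled
monomer whose axial neighbours are ¹³C-labeled with probability `pNC`.
Each of the four packing modes (N–N–N, N–N–C, C–N–N, C–N–C) occurs with
binomial probability $(1-p)^2, p(1-p), (1-p)p, p^2$ and contributes a
Gaussian decay with the second moment of its ¹⁵N–¹³C couplings:

$$M_2 = \frac{1}{5}\sum_i \left(\frac{3000\ \mathrm{Hz}}{r_i^3}\right)^2,
\qquad \frac{S}{S_0}(t) = \exp\!\left(-\frac{4 M_2 t^2}{3\pi^2}\right),$$

with $r_i$ in Å. Second moments are additive over spins, so the
two-sided C–N–C mode uses $M_{2,\mathrm{succ}} + M_{2,\mathrm{prec}}$;
a per-mode radius override reproduces the convention of truncating the
two-sided mode at a tighter radius (default 5.5 Å versus 5.8 Å) so its
spin count matches a nine-spin reference set. The Gaussian approximation
deliberately absorbs powder averaging, finite-pulse effects, ¹³C
chemical shifts and ¹³C–¹³C couplings; explicit quantum spin dynamics is
out of scope because the estimator never fits the forward model to data
— the forward model only generates curve *shapes* for synthesis and
property tests, while quantification relies on experimental-style
calibration curves.

Natural-abundance ¹³C in the ¹⁵N-labeled monomers dephases even a
0 %-¹³C sample. This background is not added to $M_2$; it is modelled as
a separate Gaussian decay $\exp(-k t^2)$ whose single rate constant is
anchored by one datum — the all-¹⁵N reference dephasing to 0.84 at
25 ms, giving $k \approx 279\ \mathrm{s^{-2}}$ — and removed in analysis
by pointwise division (`natural_abundance_correct()`), with noise
propagated by the quotient rule. Division by the same reference is an
exact algebraic inverse of the synthetic background, which the tests
exploit.

`geometry_from_structure()` extracts the two one-sided distance lists
from a deposited structure: chains are ordered by mean z (the fibril
axis is +z of the input frame), the chain above the reference chain is
"succeeding", and both lists are always computed so the assignment can
be swapped if a deposited structure is oriented the other way.

## The calibration-interpolation estimator

At each mixing time $i$ in the analysis window the measured ratio is
linearly interpolated between the two bracketing calibration curves, on
the percent scale:

$$p_i = \frac{m_i - h_i}{\ell_i - h_i}\,(\ell\% - h\%) + h\%,$$

where $\ell$ is the lower ¹³C fraction (less dephasing, higher S/S₀).
The final estimate is the mean of $p_i$ over the window, by default
8–25 ms (18 points of the default 28-point grid). Defaults follow the
experimental design this implements: replicates averaged first
(pointwise mean, noise rms/√n), natural-abundance correction applied
uniformly to measured *and* calibration curves before interpolation, and
brackets of 0.30/0.40 for the scheme measuring `p43` and 0.50/0.60 for
the scheme measuring `p34`. Window and brackets are arguments, not
constants.

Three numerical rules matter. Points where the two calibration curves
coincide are excluded with a warning (the estimate reports the effective
number of points used); if every window point is excluded the call
errors. Per-point values falling outside the bracket are retained, not
clipped — clipping would bias the mean — but if more than half of the
window lies outside the span the call errors and advises wider brackets.
Per-point noise on S/S₀ is computed by the quotient rule from the S and
S₀ noise (how the per-point noise is best derived from the two spectra
is not uniquely defined; the quotient rule is the documented choice).

The propagated uncertainty multiplies the bracket width in percentage
points by the rms over the window of the per-point first-order sigmas,
each combining the measured-curve noise scaled by the calibration gap
and each calibration curve's noise scaled by the interpolation-weight
ratio. Note what this is: the rms *per-point* uncertainty, with no
$1/\sqrt{n}$ reduction for averaging over the window. For the window
mean it is therefore conservative — under independent per-point noise
the mean's scatter is about $\sqrt{18}$ times smaller — and empirical
coverage of the ±1σ interval in simulation is correspondingly near
100 %, not the nominal 68 %. The package keeps the conservative form
because it is the field's reported convention for this estimator and it
reproduces the uncertainty scale practitioners quote; the test suite
checks both directions (coverage at least nominal, and the reported
error exceeding the empirical SD of the estimate).

The Monte-Carlo calibration of the error formula compares it against
the rms over the window of per-point MC standard deviations — the
quantity the formula actually propagates — at signal-to-noise ratios of
5000, 10000 and 20000 (500 realizations each). Those levels are chosen
so that the calibration gap exceeds the spectral noise across the whole
window, the regime in which first-order propagation is defined: with
the packaged geometry the gap between the 0.30 and 0.40 curves shrinks
to ~0.0014 S/S₀ units at 8 ms, so at lower S/N the interpolation
denominator can change sign and the MC scatter of a ratio estimator
diverges — no closed-form propagation tracks that regime, and real
campaigns avoid it by having larger gaps at equal nominal S/N (see the
next section).

## The synthetic-data generator

`synthesis_config()` bundles the study conditions: the packaged spin
geometry, the 28-point mixing-time grid (0.1–25 ms, rotor-synchronized
at 20 kHz MAS, 18 points in the 8–25 ms window; the exact experimental
grid is not public, so the default is a documented choice), calibration
fractions 0–0.7 in steps of 0.1, truth probabilities (0.37, 0.56), two
independently fibrillized replicates per labeling scheme, the 0.84-at-
25-ms background anchor, and the per-point S/N. Calibration curves are
returned as the average of the configured replicates, mirroring the
experimental design in which each calibration curve is the average of
two samples. Noise is independent Gaussian on S and S₀ with
$\sigma = 1/\mathrm{S/N}$, the ratio formed afterwards — the same route
by which spectral noise enters the error propagation. Identical master
seeds give bit-identical datasets; the seeded-sample stream is offset
from the calibration stream so the two are independent but jointly
reproducible.

The packaged default geometry is a *synthetic fixture*, not extracted
from a deposited structure: five succeeding-side and eight
preceding-side carbons in 4.1–5.8 Å, nine of them within the 5.5 Å
two-sided truncation. It reproduces the qualitative features that matter
(distance range, spin counts, family ordering) but dephases much less
than real samples, because real dephasing includes longer-range spins
and is deeper at late mixing times. One consequence is a calibrated
mapping rather than a literal one for noise: the default S/N of 3000 is
chosen so that the propagated uncertainties land near the ±0.03/±0.02
scale a real campaign reports. This mapping — high nominal S/N
compensating for shallow model dephasing — is an assumption of the
synthetic design, stated here so nobody reads the default as a claim
about spectrometer performance.

What passing tests on synthetic data do show: the estimator is exact at
calibration endpoints, linear in between, recovers generating
probabilities to ±0.01 without noise (the residual is the quadratic-in-p
curvature of the mixture model, far below that bound), is monotone in
the generating fraction, swaps its two outputs under label-scheme
reversal, and carries a conservative, first-order-consistent error bar.
What they do not show: robustness to structured artefacts real spectra
contain (drift, baseline distortions, isoform-dependent core sizes
changing the number of observable amides), none of which the generator
emulates.

## Chain simulation and filament construction

`simulate_chain()` draws the Markov chain directly; the first monomer
comes from the stationary distribution (the original construction does
not specify the initial state; stationary start is the documented
choice, overridable via `init`). Empirical transition fractions use
positions 1..n−1 as denominators — the last monomer has no successor —
and a fraction whose predecessor count is zero is `NA`, not 0.
`simulate_until_match()` redraws whole chains (no MCMC repair) until
both empirical fractions are within ±1 percentage point of their
targets, the rule used for 360-monomer filament models; at the measured
probabilities acceptance typically needs on the order of 20 attempts.
`simulate_until_descriptors()` does the same for 100-monomer models
with relative windows of 10 % on Q and 5 % on χ₄. Each call seeds one
RNG stream and consumes it sequentially across attempts, so results are
reproducible regardless of how many rejections occur, and the
pre-call RNG state of the session is restored on exit. Two
protofilaments are always simulated independently — no state is shared
between them.

`replicate_helix()` applies rigid-body symmetry: monomer k is the seed
rotated by k·twist about the z axis and translated k·rise along it,
with defaults of 4.7 Å and 1°/monomer (a full turn in 360 monomers,
~170 nm). The handedness of the twist is not specified by the
construction this follows; the default is left-handed, consistent with
known paired-helical-filament morphology, with a `handedness` flag to
override, and the rotation is about the shared axis for all
protofilaments. Isoform labels attach per monomer and are written to
mmCIF with the monomer index in `label_entity_id` and a two-level
B-factor convention (4R → 0, 3R → 50) plus a JSON sidecar; mmCIF is
the required output beyond 99,999 atoms, where fixed-width PDB serials
overflow (the PDB writer refuses larger models). The mmCIF reader in
the package parses only the files the package writes; deposited
structures go through `read_structure()` (bio3d).

## Problem sizes and budgets used by the test suite

Stochastic tests use fixed seeds and deliberately moderate sizes chosen
to make sampling error negligible relative to the asserted tolerances:
10^6-monomer chains for law-of-large-numbers checks (binomial SD
≈ 0.0005), 200 chains of 360 monomers for pooled-fraction and
rejection-rule checks, 200 noisy datasets for error-bar coverage, 500
Monte-Carlo realizations per S/N level for the error-propagation
calibration, and 10^6 draws for the uncertainty-propagation oracle.

## Known limitations

* The Markov model is first-order by construction; longer-range
  correlations, if present, are invisible to it.
* The estimator assumes both isoforms contribute equally many rigid
  amides; a core-size difference between isoforms would bias both
  probabilities in opposite directions.
* The forward model is a curve-shape generator, not a quantitative
  simulator: absolute dephasing depths are underestimated, which is why
  quantification goes through calibration curves and why the synthetic
  noise mapping is calibrated rather than literal.
* The reported uncertainty is conservative for the window mean (no
  √n reduction), by design.
* Helical construction is purely rigid-body: no energy minimization,
  clash relief or map fitting.
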