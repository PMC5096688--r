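---
title: "Modeling prion aggregate dynamics and inferring R0"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling prion aggregate dynamics and inferring R0}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propagon)
```

## The model

`propagon` implements a discrete nucleated-polymerization model (NPM) of
amyloid propagation in dividing yeast cells, written for the Sup35 /
[PSI+] system but parameterized generically.  Soluble protein monomer
`s` is synthesized at rate `alpha` and lost by growth dilution at rate
`mu`; fibers of `i >= n0` monomers grow by templated conversion at both
ends (propensity `2 beta s` per fiber), and every internal bond of a fiber
is severed by chaperones (Hsp104/Ssa1/Sis1) at rate `gamma`.  Break
products below the nucleus size `n0` are thermodynamically unstable and
dissolve back to monomer immediately.  Guanidine hydrochloride, which
inactivates Hsp104, is modeled as `gamma = 0`.

Writing `u_i` for the abundance of size-`i` fibers, the size-resolved
system (implemented in `full_derivatives()` / `integrate_full()`) is

$$\frac{du_i}{dt} = 2\beta s (u_{i-1} - u_i) - \gamma (i-1) u_i - \mu u_i
  + 2\gamma \sum_{j > i} u_j, \qquad i \ge n_0 .$$

Its first three moments — `s`, fiber number $U = \sum u_i$ and aggregated
mass $M = \sum i\,u_i$ — obey

$$\begin{aligned}
ds/dt &= \alpha - \mu s - 2\beta s U + \gamma n_0 (n_0 - 1) U\\
dU/dt &= \gamma\,(M - (2 n_0 - 1) U) - \mu U\\
dM/dt &= 2\beta s U - \gamma n_0 (n_0 - 1) U - \mu M .
\end{aligned}$$

A point worth stating explicitly, because it shapes the test strategy:
**this moment system is exact, not a closure approximation**, as long as
the size distribution is supported on sizes `>= n0`.  For any fiber of
size `j >= n0`, each of its `j - 1` bonds breaks at rate `gamma`; the
pieces retained (size `>= n0`) number `2(j - n0)` per unit `gamma`-rate
and the dissolved pieces return exactly
$2\gamma\sum_{k=1}^{n_0-1} k = \gamma n_0(n_0-1)$ monomers per fiber,
independent of `j`.  Summing the size-resolved equations therefore
reproduces the moment equations identically.  The only discrepancy between
`integrate_moments()` and `integrate_full()` is the finite truncation
`i_max` of the latter, which is chosen adaptively (smallest power of two
with boundary mass loss below 0.1% of total protein, reported in the
result attributes, never silently ignored).

Total protein `T = s + M` obeys `dT/dt = alpha - mu T` exactly, giving the
closed form `T(t) = T(0) e^{-mu t} + (alpha/mu)(1 - e^{-mu t})` used as a
conservation oracle by every integrator test.

## Steady states and R0

Besides the aggregate-free state `s = alpha/mu`, the model has a
coexistence state (`steady_state_coexistence()`)

$$s^* = \frac{\gamma^2 n_0(n_0-1) + \mu(\gamma(2n_0-1) + \mu)}{2\beta\gamma},
\qquad M^* = \frac{\alpha}{\mu} - s^*, \qquad
U^* = \frac{\gamma M^*}{\gamma(2n_0-1)+\mu}.$$

The basic reproductive number of an aggregate — the expected number of new
heritable templates each aggregate produces in its lifetime — comes from
linearizing the `(U, M)` subsystem around the aggregate-free state:

$$R_0 = \frac{2\beta\gamma\,\alpha/\mu}
            {\mu^2 + \mu\gamma(2n_0-1) + \gamma^2 n_0(n_0-1)} .$$

Aggregates persist exactly when `R0 > 1`, and at coexistence
`R0 = (alpha/mu) / s*`: **R0 is the inverse of the steady-state soluble
fraction**.  This identity (exact, tested to 1e-8 over random parameter
draws) is what lets `r0_from_soluble_fraction()` turn a routine
thermal-solubility measurement into an estimate of aggregate
reproduction, and `gamma_from_soluble_fraction()` invert it for the
fragmentation rate.  In the continuum limit the denominator becomes
$(\gamma x_0 + \mu)^2$, the classical NPM threshold, which is a useful
cross-check on the algebra.

The inversion for `gamma` is a quadratic with two positive roots (R0 is
non-monotone in `gamma`: very fast severing grinds fibers below `n0` and
wastes them).  The small root — continuous with the subcritical boundary
as `f -> 1` — is returned by default and both roots are always attached,
with an explicit infeasibility error (reporting the attainable range) when
the requested fraction is below the optimum.  Reliable inversion in
practice requires working on the ascending branch,
`gamma < mu / sqrt(n0 (n0-1))`, where the elasticity of `gamma` with
respect to the measured fraction stays near 1.

## Parameters, units, defaults

Amounts are in arbitrary "monomer units" and time in minutes; only
dimensionless observables (soluble fraction, R0) and rate ratios are
interpreted across strains.

| parameter | meaning | default (panel) | why |
|---|---|---|---|
| `alpha` | synthesis, units/min | 100 | sets the molecule scale (~1e4 monomers/cell) |
| `beta`  | conversion per fiber end | calibrated | so the fastest strain (R2E2) has R0 = 10 |
| `gamma` | severing per bond, /min | 1.25–2.2e-4 | strict strain ordering, ascending branch |
| `mu`    | dilution, /min | ln 2 / doubling time | measured per strain |
| `n0`    | nucleus size, monomers | 4 | four repeats are the minimum for propagation; any integer >= 2 accepted |
| `elongation_ends` | growing ends | 2 | fibers elongate at both ends; 1 selectable |

## The stochastic simulator

`simulate_well_mixed()` is an exact event-driven (Gillespie) realization
of the same rates at integer molecule counts, with the event loop in
C++.  It is the brute-force oracle for the deterministic layer: ensemble
means of `(s, U, M)` over 500 runs stay within 3 standard errors of the
moment ODEs at the ~1e4-molecule scale of the default panel (mean-field
correlations `cov(s, U)` are below resolution at that scale).

`simulate_lineage()` follows one focal cell through a curing/recovery
`protocol()`: within a phase the fragmentation rate is scaled by the
phase's `gamma_scale` (0 = GdnHCl), there is **no continuous dilution**,
and every `t_d` minutes the cell divides — each fiber is retained
independently with probability `p_keep` (0.5 = symmetric partition, so
counts halve per generation when fragmentation is off) and the monomer
pool is split binomially.  Implementing dilution solely by division keeps
the expected dilution rate at `ln 2 / t_d`, consistent with the ODE `mu`,
without double counting.  An audit mode re-checks mass balance and
fragmentation bookkeeping after every event.  `simulate_population()`
keeps all daughters, so whole-population conservation laws (total
propagons constant under pure division) are testable exactly.

A propagon is counted as any fiber of size `>= n0` — the model's heritable
unit, matching the colony-based dilution assay that operationally defines
propagons (`propagon_assay()` adds binomial plating efficiency if wanted).

`amplification_rate()` fits the slope of log summary propagon count
against time during recovery.  Mean and median summaries are both
available; the default is the mean, which remains informative while many
cells still carry 0–2 propagons just after curing (the median of a mostly
sub-1 distribution is degenerate early in recovery).

## Statistical layer

The point estimate of R0 for a strain is `1 / mean(f)` over replicate
soluble fractions: `f` is the measured quantity, so the plug-in inverse
of its mean is the natural estimator (`mean(1/f)` is selectable).

Confidence intervals at `n ~ 6` replicates need care.  In design
simulations under the generator's own noise model, the plain percentile
bootstrap of `1/mean` covered a nominal 95% interval only ~86% of the
time — the familiar small-`n` narrowness of percentile intervals.
`bootstrap_r0()` therefore defaults to the **wider of** an equal-tailed
studentized (bootstrap-t) interval and a Hesterberg expanded-percentile
interval, computed from the same resamples; this sits near 95% coverage
while guarding against the instability of studentized tails (degenerate
resample variances) and the narrowness of percentile tails.  Plain
`"percentile"`, `"expanded"` and `"student"` remain selectable.

Strain comparisons (`compare_r0()`, `compare_strains()`) estimate
`delta = R0(a) - R0(b)` with independent resampling and declare
significance exactly when the interval excludes zero.  The default is a
*symmetric* studentized bootstrap interval at **99%** confidence, with
resample standard errors floored at half the plug-in standard error.
Two deliberate conservatisms: the symmetric statistic and SE floor tame
the heavy studentized tails at `n = 6`, and the 99% default reflects that
pairwise comparisons are reported without any multiplicity correction, so
a per-pair test near the 1% level keeps the family-wise error of a
six-strain screen at a conventional scale.

## The synthetic panel

`default_panel()` encodes six prion-propagating strains.  What is taken
as given: per-strain doubling times (97.7–166.0 min; the double variant
R1-5dRPR is assigned its parent dRPR value), replicate count 6, and
additive Gaussian measurement noise with sd 0.01 on the soluble fraction.
What is designed, once, to reproduce the qualitative biology:

* fragmentation rates strictly ordered
  `R2E2 > R2E1 > RWT > R1-5 > dRPR > R1-5dRPR`;
* R1-5's rate is *solved* so its steady-state soluble fraction equals
  wildtype's exactly — the two strains are experimentally
  indistinguishable, and with per-strain growth rates this cannot be
  achieved with literally equal `gamma` (the solved value differs from
  wildtype's by <2% and respects the ordering);
* `beta` is calibrated so R2E2 sits at R0 = 10, putting the panel's R0
  span at roughly 1.5–10.  A wider span (tens) is incompatible with the
  fixed noise floor: a strain at R0 = 35 has soluble fraction 0.029,
  whose replicate mean carries ~14% relative error — far too coarse to
  recover `gamma` within 10%.  The slow-growing repeat-expansion strain
  already multiplies its R0 by ~4 through `alpha/mu`, so the span above
  is what the measured doubling times allow while keeping every strain
  comfortably supercritical and the inversion well conditioned.

The propagon-assay generator simulates 64 cells per strain per time
course.  The number of sampled cells is an assay-design choice; 64 is the
smallest power of two at which a power analysis showed the binding
comparison (wildtype vs dRPR recovery rates, a ~15% difference in
`gamma`) is correctly ordered in well over 95% of simulated studies.

What the generator deliberately does *not* emulate: between-day replicate
structure (noise is iid), conformational strain variants, chaperone
expression dynamics, mother–daughter retention bias (`p_keep` is
configurable but defaults to symmetric), cell-size variation, and
nucleation of new prion states (cells cured to zero propagons stay
cured).  Passing the end-to-end tests therefore demonstrates internal
consistency of model + inference under these idealizations, not that real
measurements obey them.

## Numerical choices

* ODE solver: `deSolve::lsoda`, `rtol = 1e-8`, `atol = 1e-10`; the moment
  system is mildly stiff near the persistence threshold.
* Negative undershoot: values within the absolute tolerance of zero are
  clipped for reporting; anything more negative raises an error rather
  than being masked.
* Size-resolved truncation: `i_max` adaptive as described above, capped
  at `2^13` with a loud warning carrying the realized loss.
* Bootstrap: `n_boot = 10000`; degenerate (zero-variance) replicate sets
  return point-mass intervals; seeded runs are bit-reproducible and leave
  the caller's RNG state untouched.
* Event simulation: exact SSA; an event budget (default 5e7 per segment)
  aborts unbounded-growth configurations with a diagnostic instead of
  hanging.

## Problem sizes used by the automated checks

The package's test suite re-derives every headline claim at these sizes:
50 random parameter sets for the conservation law; 100 for the
R0–soluble-fraction identity; 20 for moment-vs-size-resolved agreement
(1%); 500 stochastic runs against the ODE (3 SE); 250 lineages for the
curing decay law; 200 synthetic panels for `gamma` recovery (within 10%)
and CI coverage (93–97%); 100 studies for the strain-comparison
conclusions and recovery-rate ordering.  `scripts/acceptance.R` recomputes
the same quantities from scratch at slightly reduced sizes and writes
them as JSON.

## Known limitations

R0 inference leans on the steady-state identity `f = 1/R0`, which assumes
the culture is at the coexistence steady state and that total Sup35 is
conserved at `alpha/mu`; transient or stressed cultures violate this.
The fragmentation inversion requires `alpha`, `beta`, `n0` to be known or
fixed by convention — only *relative* `gamma` across strains is
meaningful, exactly as only relative R0 is interpreted.  The lineage
simulator uses deterministic division intervals (no age structure) and
ignores mother–daughter asymmetry by default.  Fragmentation is
size-independent per bond; chaperone saturation would bend the large-`R0`
end of the scale.
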