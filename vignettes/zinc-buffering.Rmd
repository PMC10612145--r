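---
title: "Zinc binding thermodynamics and buffering of metallothioneins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zinc binding thermodynamics and buffering of metallothioneins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znbuffer)
```

## The model

Metallothioneins (MTs) are small cysteine-rich proteins that bind
several Zn(II) ions with graded affinities, from nanomolar "weak" sites
to low-femtomolar "tight" sites in bacterial family members. `znbuffer`
represents such a protein by its **macroscopic stepwise apparent
dissociation constants** at a fixed pH: step $i$ is the association of
the $i$-th Zn(II) onto the $\mathrm{Zn}_{i-1}$ protein, with constant
$K_{d,i}$ stored as $\mathrm{p}K_{d,i} = -\log_{10} K_{d,i}$, ordered
tightest first. The cumulative (Adair) association constants are

$$\log_{10}\beta_i = \sum_{j \le i} \mathrm{p}K_{d,j},$$

and the molar fraction of the $\mathrm{Zn}_i$ species at free Zn(II)
concentration $z$ is proportional to $\beta_i z^i$. Everything is
evaluated in $\log_{10}$ space with max-subtraction: a 9-site protein
reaches $\beta_9 \sim 10^{90}$, far beyond double range.

Assumptions worth stating explicitly:

* Constants are **conditional** (apparent) values at one pH, exactly as
  tabulated. No proton competition, ternary species, activity or
  ionic-strength corrections are modelled, and no statistical factors
  are added to tabulated constants.
* Grouped constants ("sites 4–7: 11.2") expand to repeated identical
  step constants, one per site — this is how speciation software is
  conventionally fed and how the reference distributions are
  reconstructed.
* Site filling is tightest-first. Competition tables often index
  constants from the holo protein (their $K_{d1}$ is the weakest site);
  `dissociation_order_index()` makes that conversion explicit rather than
  leaving an off-by-one trap.

Where a model of *independent* sites is needed (estimator consistency
checks, generators for site-wise fits), `independent_sites_model()`
composes per-site constants into the equivalent macroscopic ladder via
elementary symmetric polynomials, again in log space. For $n$ equal
sites this is the familiar statistical ladder
$K_{d,\mathrm{step}\,i} = K_d \, i/(n-i+1)$, and mean occupancy divided
by $n$ then equals $z/(z+K_d)$ exactly — a property the test suite
checks to machine precision.

## The equilibrium solver

`solve_free_zinc()` solves the scalar mass balance

$$\mathrm{Zn}_\mathrm{tot} = z + P_\mathrm{tot}\,\bar n(z)
  + \sum_L L_\mathrm{tot}\frac{z}{z + K_{d,L}}
  + 2\,[\mathrm{ZnL}'_2](z),$$

where $\bar n$ is the protein binding curve and the 2:1 chromogenic
probe's own ligand balance ($L'_\mathrm{tot} = L'_\mathrm{free} +
2[\mathrm{ZnL}'_2]$, $[\mathrm{ZnL}'_2] = z L'^2_\mathrm{free}/K_{d12}$)
is eliminated in closed form through the stable root of its quadratic.
Every bound term is strictly increasing in $z$, so the root is
bracketed by monotone bisection on $\log_{10} z$ over $[-20, -1]$
(200 iterations maximum, in practice ~60) and polished with up to five
damped Newton steps. The accepted root must reconstruct the total to a
relative $10^{-8}$. `zn_total = 0` returns an all-apo sentinel (free Zn
0, pZn undefined) instead of raising, so ratio grids that start at zero
behave gracefully.

The test suite compares this solver against an independent dense
log-grid sign-scan oracle on randomized systems (site constants in
[5, 16], totals in [0.1 µM, 1 mM]); agreement is required to
$10^{-6}$ log units.

## Speciation descriptors

* `speciation_vs_pzn()` is closed-form (free Zn is the independent
  variable); `speciation_vs_ratio()` solves the full mass balance per
  Zn/protein ratio.
* `peak_pzn()` uses the stationarity property of Adair fractions: the
  $\mathrm{Zn}_i$ fraction is maximal exactly where mean occupancy
  crosses $i$, located by bisection. Terminal species ($i = 0$, $i =
  n$) have no interior maximum and return signed-infinity sentinels
  with a flag.
* `buffering_window()` reports the pZn interval over which occupancy
  runs from a coverage fraction (default 90%) of the full load down to
  its complement — an operational definition of the protein's zinc
  buffering range.

With the bundled models these descriptors put the hexa-Zn species of
the 7-site frog MT at pZn 8.54 and the tri-Zn species of the
cyanobacterial MT at pZn 12.05, matching the reference landmarks (8.5,
12.1) within a tenth of a log unit. Two known flags from the source
data: (i) the penta-Zn frog species computes to pZn ≈ 9.72 where the
source text prints 9.6 — a near-miss inherent to the printed constants,
not a solver issue; (ii) the claim that the di-Zn cyanobacterial
species dominates at pZn 10 is inconsistent with the same table's
constants (the weakest site, 11.2, is ~94% occupied at pZn 10, and the
di-Zn peak computes to ≈ 13.7); we do not force agreement. Whether the
reconstructed distributions used the rounded moderate constant 12.9 or
the unrounded group mean 12.94 is unstated in the source; the bundled
model uses the printed 12.9.

## Estimators

**Average per-site constant (2:1 probe competition).** From transferred
equivalents $t$ out of $x$ sites: $[\mathrm{ZnL}_2] = t P_\mathrm{tot}$,
free Zn from the probe equilibrium, then
$K_d^\mathrm{av} = z\,t/(x - t)$ — the per-site empty/filled ratio.
This form reproduces the published per-protein averages from the same
printed transfers to ≤ 0.04 log units for 9 of 10 proteins; the
whole-molecule cooperative form misses by ~0.6 and is not used. The
remaining protein (the rice MT, printed 10.78) does not reproduce under
either form and is treated as a documented outlier, not force-fitted.

**Stepwise constants.** For transfers below one equivalent the closed
form $K_{d1} = z\,t/(1-t)$; for one to three equivalents an
equal-constant stepwise model over the weakest sites, solved for the
ratio $a = K/z$ by bisection on the geometric species ladder. The
model reproduces most published values; two documented residuals
remain (computed 10.51 vs printed 10.56, and 9.72 vs 10.01 for the
nine-site snail protein), consistent with the source's unpublished
worked examples. We implement the stated model and do not tune.

**Weak-site isotherm fits.** Transferred equivalents versus pZn are
fitted to a sum of per-site release terms $K_d/(K_d + z)$ (one or two
sites), or to a cooperative single-constant Hill variant for proteins
that release several weak ions together. When the protein total is
supplied, the probe-read transfer is first corrected for the free
Zn(II) the probe does not hold ($t' = t + z/P_\mathrm{tot}$) so the
fitted quantity is the occupancy actually lost by the protein; without
this correction the weakest constants bias by up to ~0.1 log unit at
the low-probe end.

**Hill fits.** pH titrations fit
$A = A_\mathrm{lo} + (A_\mathrm{hi}-A_\mathrm{lo})/(1 +
10^{\,n(\mathrm{p}K_a' - \mathrm{pH})})$ with the Hill coefficient free
by default (the source does not state whether it was fixed) and
fixable by argument. Metal-buffer CD isotherms are fitted iteratively:
Hill fit against pZn, conversion of ellipticity to protein-bound Zn via
the fitted plateaus, per-point correction of the buffer's free Zn for
pool depletion ($z' = K_{d,\mathrm{chel}}(\mathrm{ZnL} -
\mathrm{transferred})/(L_\mathrm{free} + \mathrm{transferred})$), and
refit until the constant moves < 0.01.

**Tight/moderate refinement.** Mirrors "manual mode" refinement in
speciation software: weak constants, probe constants and totals fixed;
grouped tight/moderate constants scanned over a −logKd grid (default
[9, 16], step 0.05, matching the one-decimal precision of grouped
published constants) minimizing squared pZn residuals of the modelled
apo-titration curve, with coordinate-descent sweeps whose objective is
non-increasing, ties broken toward the tighter constant. Two design
choices were genuinely open:

* *Detection ceiling.* With ideal solver-generated pZn data every
  constant is identifiable, which misrepresents a fluorescent probe
  whose signal vanishes far above its $K_d$. We therefore censor
  observed and modelled pZn at `pzn_ceiling` (default probe p$K_d$ + 4,
  i.e. signal below $10^{-4}$ of dynamic range).
* *Flatness flag.* A group whose objective profile varies by less than
  `flat_tol` (default 0.01 pZn² — under a 0.1-pZn effect on a single
  point, below experimental reproducibility) is reported as
  "underestimated range" with `NA`, reproducing the exclusion of
  bacterial tight sites from fluorescent-probe refinement. Measured
  profiles make the margin comfortable: ~0.002 for the bacterial tight
  group versus ~0.23 for the still-identifiable moderate group.

**Kinetics.** TNB⁻ appearance traces fit
$A(t) = A_0 + A_\mathrm{amp}(1 - e^{-kt})$ with the baseline fitted,
not forced to zero (trace baselines are unspecified in the source
data). Titration endpoints are continuous piecewise-linear least
squares with one or two free knots (grid-initialized, locally refined,
knots confined to the interior, ties toward smaller abscissa); the
chelator-dependence of oxidation rates is ordinary least squares of
$\log_{10} k_\mathrm{obsd}$ on chelator $-\log K_d$.

## The synthetic-data generator

Every experiment type the estimators consume can be forward-simulated
from ground truth: 2:1 probe competition transfers, 1:1 probe transfer
isotherms and apo-titrations (both through the full equilibrium
solver), pH titrations, metal-buffer CD series, and exponential kinetic
traces. Noise is Gaussian on the signal, with amplitude expressed as a
fraction of each trace's dynamic range — the way instrument noise
presents — and fully determined by an integer seed. Default conditions
follow the reference experiments: 1 µM protein with 200 µM chromogenic
probe; 0.5 µM protein with 0.05–5 µM fluorescent probe; 20 µM protein
against 0.5 mM complexones at 5–85% Zn saturation; 2% noise where noise
is used.

What the generator deliberately does **not** emulate: instrument drift,
photobleaching, inner-filter effects, heteroscedastic noise, and slow
equilibration kinetics. The last point matters for interpretation: the
bundled bacterial models carry the fluorescent-probe-derived weakest
constants, and forward-simulating their 2:1-probe competition yields
larger transfers (~0.45 eq) than the hours-long experiments report
(~0.05 eq) — the source's two experiment families are themselves
inconsistent by ~2 log units for those proteins. Passing recovery
tests therefore demonstrates estimator correctness on data generated
by the stated equilibrium model, not that every printed observable is
mutually consistent.

The pZn values attached to simulated datasets come from the same
solver used in fitting, deliberately: recovery tests then isolate
estimator error from solver error. Solver correctness is established
separately against the independent grid-scan oracle.

## Fixture models

The bundled registry (`make_fixture_models()`, YAML under
`inst/extdata/`) holds the ten reference proteins with their stepwise
constants, the apparent thiol p$K_a'$ values used as simulation truth,
the three weak-to-moderate competition chelators (ATP, triphosphate,
NTA), the three high-affinity complexones (HEDTA, EDTA, TPEN) and both
probes. Two curation notes: the bacterial models place two tight sites
at the metal-buffer constant, one intermediate site at the moderate
estimate, and the weakest site at the fluorescent-probe value; the
*Pseudomonas* protein has no usable metal-buffer measurement, so its
tight constant (14.49) is a **synthetic estimate** — the mean of the
two measured bacterial metal-buffer constants — and is labelled as such
in the YAML. A fourth complexone named in the experimental description
(CDTA) has no printed constant and is deliberately absent.

## Problem sizes and numerical choices

The shipped tests and the demonstration pipeline use sizes chosen to
exercise every code path while staying quick on one CPU: 100 randomized
solver-oracle comparisons, 200 Monte-Carlo replicates per fitter at 2%
noise, 21-point isotherms, 15-point refinement curves with a 0.05-log
grid, and speciation grids at 0.01 pZn resolution. Bisection
tolerances are $10^{-12}$ on $\log_{10} z$ (solver), $10^{-4}$ pZn
(peak location), $10^{-12}$ on the stepwise ratio; nonlinear fits run
Levenberg–Marquardt with bounded parameters and data-driven starting
values.

## Known limitations

No explicit proton or ternary equilibria (constants are conditional at
one pH); no Cd(II) models; no activity or ionic-strength corrections;
no mechanistic per-thiol oxidation kinetics; no Bayesian or global
multi-experiment fitting. The registry ships the constants as printed;
where the source's own numbers disagree between methods, both are kept
and the disagreement is documented rather than reconciled.
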