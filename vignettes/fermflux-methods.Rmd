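---
title: "Multiphase fermentation kinetics and dynamic parsimonious FBA: models and methods"
author: "fermflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase fermentation kinetics and dynamic parsimonious FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermflux)
```

# Scope and architecture

`fermflux` couples two model layers that remain strictly decoupled in the
direction of information flow:

1. a **continuous multiphase kinetic model** of the extracellular
   environment and biomass composition (41 ODEs), calibrated against
   replicate time-series data;
2. a **dynamic parsimonious flux balance analysis** (dFBA) in which the
   calibrated kinetic derivatives fix the exchange fluxes of a
   constraint-based metabolic network at each time step, under a
   time-varying cellular objective.

Fluxes never feed back into the kinetics. Calibration therefore never
invokes the LP layer, which keeps parameter estimation cheap and makes the
phase structure an *output* of the kinetic model rather than a set of
fitted breakpoints.

# The kinetic model

## States

Total biomass `X` (gDW/L) is carried together with its composition:
carbohydrate `XC`, protein `XP` and mRNA `XmRNA`, with
`dX/dt = dXC/dt + dXP/dt + dXmRNA/dt` integrated as its own (dependent)
equation — a deliberate redundancy that turns mass conservation into a
verifiable property of every trajectory. Nitrogen is tracked both as the
aggregate `YAN` (gN/L) and as the individual sources (ammonium plus 18
amino acids; proline is excluded because it is not assimilated
anaerobically). Sugars are sucrose, glucose and fructose; products are
ethanol, glycerol, acetate, succinate, lactate, malate and seven secondary
metabolites (acetate esters, higher alcohols, 2,3-butanediol). A
dimensionless regulatory state `GNS` tracks the transcriptional transition
to stationary phase. That gives 41 equations; with the sucrose equation and
both consumption branches active (the configuration shipped as the
`"suvarum25"` preset) 46 of the parameters are flagged estimable.

## Growth

Primary growth converts nitrogen uptake into biomass:

$$\mu_N = 14.0067 \sum_i \frac{NN_i}{MW_i}\,
  \frac{d[\mathrm{AA}_i]}{dt}\; Y_{x/N},$$

with `NN_i` nitrogen atoms and `MW_i` molecular weights from
`aminoAcidTable()`. Uptake derivatives are negative, so the implementation
negates the sum to keep `muN >= 0` during assimilation; `muN` and the
secondary growth rate `muC` are treated as volumetric rates
(g/(L·h)) throughout — dimensional consistency of the biomass balance
requires this, and the specific growth rate needed by the FBA layer is
computed separately as `(dX/dt)/X`. Uptake of each nitrogen source is
lag-gated mass action, `d[AA]/dt = -lag(t) * k_AA * [AA] * XP`, with the
closed-form Baranyi–Roberts adaptation factor
`lag(t) = a0 / (a0 + (1-a0) exp(-muMaxN t))`.

Secondary growth is carbohydrate (glycogen/trehalose-like) accumulation
after nitrogen exhaustion, a proportional controller toward a set point for
the carbohydrate fraction:

$$\mu_C = \phi_{N,S}\, X\, \Phi_C\, (\Theta_C - XC/X), \qquad
\phi_{N,S} = \frac{k_{sC}}{YAN + k_{sC}}.$$

## Sugars and products

Hexose uptake is Michaelis–Menten in the sugar, proportional to protein
biomass, and amplified by `(1 + alpha * muN)` — transporter induction
during growth. The factor is used exactly as written, without saturation;
at realistic `muN` values it stays below ~2. Sucrose hydrolyses first-order
and feeds half of its mass into each hexose (no hydration-mass correction —
a documented modelling convention). Product formation is proportional to
total hexose consumption with one of four laws per product:

| variant | law (`q` = hexose uptake rate, g/(L·h)) | default products |
|---|---|---|
| proportional | `Y * q` | ethanol |
| regulated decline | `Y * q * (1 - GNS)` | glycerol, lactate, acetate |
| nitrogen-delayed | `Y * q * phiNS` | succinate, ethyl/isoamyl acetate, isobutanol, isoamyl alcohol |
| delayed + repressed | `Y * q * phiNS * (1 - GNS)` | phenyl ethyl acetate, 2-phenyl ethanol, 2,3-butanediol |

Production is driven by the hexose *uptake* rate, not the net hexose
derivative: when sucrose is present its hydrolysis feeds the hexose pools,
and counting that release as (negative) uptake would make product
concentrations fall below zero. The two formulations coincide whenever
sucrose is absent.

Ethyl acetate is genuinely ambiguous between the last two laws;
the default is `nitrogen_delayed` and `selectProductModel()` chooses per
dataset by information criterion (AIC by default, ties to the simpler
variant). Acetate switches with the must type: in synthetic must
(`delta = 1`) it declines with `(1 - GNS)`; in natural must (`delta = 0`)
it is additionally consumed after nitrogen depletion
(`-kcAce * phiNS * XP * Ace * (1 - GNS)`). Succinate and malate carry
analogous consumption terms. `GNS` relaxes toward `phiNS * phiSugar` at
rate `tauGNS`, where `phiSugar = ksS / (Glx + F + ksS)` rises as sugars
run out.

Cell decay is off by default (`kD = 0`): the parsimonious model variant
does not need it. When `kD > 0`, the decay is modulated by an
ethanol-dependent factor `phiED`; no functional form is prescribed by the
model family, so the package uses a logistic in ethanol with midpoint
`phiEDmid` (77 g/L) and slope `phiEDslope` — a free design choice that only
matters when decay is enabled.

## Numerical treatment

Integration uses `deSolve::lsoda` (adaptive, stiffness-switching) at
`rtol = 1e-8`, `atol = 1e-10` by default (relaxed to `1e-7`/`1e-9` inside
calibration loops). Substrate concentrations are clipped at zero *inside
the rate laws only* — uptake terms vanish for non-positive substrate — so
the integrator state itself is never projected, which preserves smoothness
for the step-size controller. States more than `1e-6` below zero, or NaN
propagation, abort with the failure time.

## Phase detection

Phases are read off the solution: the lag phase ends when the adaptation
factor first reaches 0.99; exponential growth ends when `YAN` first drops
to `1e-4` gN/L; the growth–no-growth transition ends when `dX/dt` first
falls to `1e-6` gDW/(L·h) afterwards; the remainder is stationary. The
thresholds are configurable arguments of `detectPhases()`; the defaults
were chosen once as the natural "numerically null" scales of the model
(the qualitative definitions do not pin down constants). If nitrogen never
depletes or growth never becomes null within the horizon, the boundary is
set to the final time and a flag is recorded.

# Calibration

The cost is the weighted residual sum of squares over replicate means,
equivalent to maximum likelihood under independent Gaussian errors:

$$J(\theta) = \sum_d \left(\frac{y_d - y_m(\theta)}{\sigma_d}\right)^2.$$

Two weighting models are available. The default (`"pointwise"`) uses each
point's replicate standard deviation floored at 5% of the observable's
maximum — replicate sd can be exactly zero at a sampled time, and with
only three replicates pointwise `1/sd^2` weights are heavy-tailed enough to
destabilize the fit, so the floor is essential for real data. The
`"pooled"` model instead scales a per-observable median replicate CV by
each point's mean; it is the right choice when the noise is genuinely
multiplicative and is what the parameter-recovery benchmark uses for its
refinement stage.

Optimization is a seeded multistart (Latin hypercube over the bounds, plus
the supplied template) refined by bounded Levenberg–Marquardt on the
residual vector, all in log10 parameter space — rate and yield constants
span orders of magnitude, and log-scale moves follow the sloppy ridges of
ODE models far better than linear ones. Integration failures during the
search return a large penalized cost with a flag rather than aborting.
`parameterRecovery()` wires this into a two-stage protocol (coarse floored
weights for the global phase, pooled weights for refinement, with interior
restarts along any axis the coarse stage left pinned at a search bound);
the staging is a homotopy over weight sharpness, not extra data.

Confidence intervals come from the Cramér–Rao bound: the covariance is
approximated by the inverse Fisher information `F = J'J` with `J` the
weighted-residual sensitivities at the optimum (central differences,
relative step `1e-5`), and half-widths are
`t_{alpha/2, gamma} sqrt(C_ii)` with `gamma = Nd - eta`. A rank-deficient
`F` (structural non-identifiability) triggers a warning and a
pseudo-inverse. Goodness of fit is reported per observable as
`R^2 = 1 - SSres/SStot` on replicate means; zero-variance observables are
`NA`, and low signal-to-noise observables can simply be left out of the
dataset mapping.

# The constraint-based layer

`MetabolicNetwork` holds a sparse stoichiometric matrix, finite flux bounds
(infinite bounds are capped at ±1000 mmol/(gDW·h), the conventional
default) and *designated roles* — biomass drain, ATP maintenance
(hydrolysis), protein synthesis, exchanges — resolved by configurable
identifiers rather than hard-coded names, so a desk-scale test network and
a genome-scale SBML reconstruction share one code path. A minimal SBML
Level 3 (FBC v2) writer/reader is included (species, reactions,
stoichiometry, flux-bound parameters, chemical formulas for carbon
bookkeeping); no SBML bindings exist in the R dependency stack used here,
so the subset needed for constraint-based work is implemented directly.

`toyNetwork()` is a deterministic 23-reaction anaerobic yeast caricature:
lumped glycolysis (2 ATP + 2 NADH per hexose), fermentative branches to
ethanol (NADH sink), glycerol (strong NADH sink), acetate (NADH source)
and succinate, amino-acid synthesis, macromolecule polymerization
pseudo-reactions whose ATP coefficients carry the GAM decomposition, a
fixed-composition biomass assembly (0.29 carbohydrate / 0.59 protein /
0.12 RNA) *plus a carbohydrate-storage biomass route*. The storage route
matters: after nitrogen depletion the kinetic model keeps growing by
carbohydrate accumulation, and a fixed-composition biomass reaction with
no nitrogen supply would make every post-growth dFBA step infeasible. All
internal metabolic reactions balance carbon (`carbonBalance()`); biomass
assemblies are exempt, as in genome-scale practice, because their product
has no defined formula.

Growth-associated ATP maintenance decomposes as
`GAM = GAMb + GAM_prot + GAM_RNA + GAM_carb` with `GAMb = 30` mmol/gDW;
the polymerization coefficients (defaults 23.9, 2.6 and 5.0 mmol ATP per
gram of protein, RNA and carbohydrate) are literature-scale values shipped
as editable data, not code, and `applyGam()` wires them into the ATP
coefficients of the corresponding pseudo-reactions.

# Dynamic parsimonious FBA

At each output time (a uniform grid — the kinetic solution is dense and
interpolable, so the ODE solver's internal steps are irrelevant):

1. **Exchange bounds** (`exchangeBoundsAt()`): each mapped compound's
   specific flux is `v = (d[X]/dt)/(MW · X(t)) · 1000` mmol/(gDW·h) —
   note the division by biomass, required by dimensional analysis.
   Equality-class compounds get `lower = upper = v`. Inequality-class
   compounds (the noisy-measurement list: histidine, succinate, lactate,
   malate, isobutanol, isoamyl alcohol, phenyl ethyl acetate, 2-phenyl
   ethanol) keep the direction but not the magnitude floor: secretion
   becomes `(0, v)`, uptake `(v, 0)`. The biomass drain is fixed at the
   specific growth rate `(dX/dt)/X` in all phases; if that ever renders a
   step infeasible the relaxation ladder below opens it.
2. **Objective** (`objectiveAt()`): weights `(1 - phiNS)` on ATP
   hydrolysis and `phiNS` on protein synthesis — energy maximization while
   nitrogen lasts, shifting continuously to protein turnover as it
   depletes. The two terms have different natural magnitudes; optional
   per-term normalization constants are exposed (default 1, since no
   canonical normalization exists).
3. **Parsimonious solve** (`pfba()`): maximize the weighted objective,
   then fix it at `1 - 1e-6` of the optimum and minimize total absolute
   flux with a positive/negative split of the variables that straddle
   zero. Variables fixed by equality bounds are substituted out first.
4. **Infeasibility ladder**: widen inequality-class bounds by factors 2
   then 10, then open equality bounds to a ±5% relative window; every
   relaxation is logged with its time stamp. On the shipped fixture no
   relaxation is ever needed (a designed property, verified in tests).

The LP itself is solved by an in-package dense two-phase simplex with
Bland's anti-cycling rule. The FBA sub-problems arising here — many
variables fixed, all-zero right-hand sides, heavily degenerate bases — are
a pathological class for the general-purpose simplex implementations
available in this dependency stack (both crash on such instances), so the
package owns this ~150-line kernel, validates every solution against the
original constraints, polishes accepted vertices onto their active set by
QR, and is itself tested against brute-force vertex enumeration.
`fva()` provides flux variability ranges at near-optimal objective as the
standard check on how far parsimony narrows the solution space.

# Flux scores

For a phase `[tA, tB]`,

$$FS_r = 100 \times \frac{\int_{t_A}^{t_B} v_r\, DW\, dt}
  {\int_{t_A}^{t_B} |v_{Glx} DW|\,dt + \int_{t_A}^{t_B} |v_F DW|\,dt},$$

in mmol per mmol hexose × 100, integrated by the trapezoidal rule with
piecewise-linear interpolation at interval endpoints (consistent, and
exact for linear flux courses). `DW` is the kinetic biomass per unit broth
volume; any volume factor cancels in the ratio. Scores are signed by the
net integral — uptake reactions score negative. `NFS = FS / duration`
makes phases of different lengths comparable. The differential filter
between two conditions keeps reactions with `|log10(|S1/S2|)| >= 1e-3`;
one-sided zeros count as infinitely different (included), double zeros as
identical (excluded) — the score being exactly zero on one side is itself
the signal.

# The synthetic-data generator

`samplingDesign()` encodes the measurement structure calibration assumes:
seven sampling times, three biological replicates, multiplicative Gaussian
noise (`value = truth (1 + cv·z)`, truncated at zero — concentration
measurements are positive and chromatographic error scales with signal)
with CV 5% by default, drawn from R's seeded Mersenne–Twister. The default
sampling times (8, 20, 32, 44, 56, 68, 120 h) span lag to stationary phase
for the default `"fast"` profile and deliberately place two samples inside
the sugar-depletion window, where the Michaelis constants of hexose uptake
are identifiable at all; this is ordinary identifiability-aware design,
fixed once. The `"fast"`, `"slow"` and `"glycerol"` presets emulate
qualitatively distinct phenotypes (rapid uptake; slow fructose with high
succinate; high glycerol); `"suvarum25"` is the sucrose-bearing,
natural-must configuration whose estimable set holds 46 parameters
(lactate yield and the malate uptake constant are fixed — the two
lowest-information observables in that setting; estimability is always an
explicit, per-parameter configuration). Initial conditions mimic a
synthetic must: ~100 g/L of each hexose and ~0.3–0.4 gN/L of assimilable
nitrogen split over ammonium and amino acids.

`fermentationFixture()` bundles a kinetic trajectory, the toy network, a
compound map and a GAM spec into a matched end-to-end test bed. Its preset
was co-designed with the toy stoichiometry so that every dFBA step is
feasible without relaxation: hexoses and ethanol are equality-mapped,
nitrogen sources and minor products are inequality-mapped, the ethanol
yield (0.45 g/g ≈ 1.76 mmol/mmol hexose) leaves redox headroom for the
glycerol/acetate valves, the slow `tauGNS` keeps product declines gentle
within the 190 h horizon, and `PhiC = 0.3` makes the carbohydrate
set-point convergence fast enough that all four phases fit the horizon
with sugars still available. Problem sizes throughout the test suite —
~100 dFBA steps, 25 oracle instances, five recovered parameters at a
four-start budget — are the package's own choices for a desk-scale,
fully-reproducible test bed.

## What the generator does and does not emulate

It reproduces the *sampling structure* of bioreactor studies (sparse
times, few replicates, signal-proportional noise) and phenotype-scale
differences between presets. It does not emulate systematic measurement
bias, missing values, inter-replicate biological drift, temperature
effects, oxygen dynamics, ethanol-inhibition kinetics or proline
assimilation (all outside the model family). Passing the recovery tests
therefore demonstrates the estimator's correctness and the experiment
design's identifiability under the stated noise model — not robustness to
the full messiness of real fermentation data.

# Known limitations

* The dense simplex kernel is built for desk-scale networks (tens of
  reactions); genome-scale SBML models load, but solving them needs a
  sparse industrial LP solver outside this dependency stack.
* The direct (one-LP-per-step) dFBA can in principle produce flux
  discontinuities between steps; parsimony, the many equality constraints
  and the smooth objective suppress these in practice (verified on the
  fixture), but no continuity is enforced.
* The time-varying ATP/protein objective is a heuristic for regulatory
  adaptation, not a mechanistic regulation model.
* Fisher-information intervals are asymptotic; for heavily correlated
  parameter pairs they describe the ridge rather than marginal
  uncertainty.
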