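---
title: "The ParB clamp cycle: model, simulators and assay fitters"
author: "ParBcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ParB clamp cycle: model, simulators and assay fitters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ParBcycle)
```

## The model

ParB is the centromere-binding protein of bacterial ParABS partition
systems. With CTP it forms a DNA-entrapping sliding clamp: the parS
centromeric site catalyzes closure of the clamp's N-gate, the closed clamp
slides along flanking DNA, and CTP hydrolysis recycles closed clamps back
to the open, binding-competent form. Because hydrolysis continuously burns
energy, the steady state of this cycle is not an equilibrium, and the
apparent affinity of ParB for parS can be driven far below the equilibrium
dissociation constant of the open form. This package implements that
nonequilibrium steady-state theory, exact stochastic simulation of the
underlying reaction schemes, a 1D lattice model of clamp spreading, and
models/fitters for the in-vitro assays used to parameterize the cycle
(ITC, BLI, CTPase).

### The coarse clamp cycle

The coarse scheme has four ParB pools — open/closed, crossed with
free/DNA-bound — plus free DNA:

* open ⇌ closed off DNA: closure at `kOC`, reopening at `kCO`, hydrolysis
  recycling closed → open at `kH`;
* open ⇌ closed on DNA: `kOCdna` (the parS-catalyzed closure rate when the
  substrate is parS), `kCOdna`, and the same `kH`;
* only the **open** form binds or releases DNA, with dissociation constant
  `kdOpen`. Closed clamps can neither load nor unload — the steric geometry
  of the closed gate forbids it — so hydrolysis on DNA reopens the clamp
  *in place*, and unloading then proceeds from the open bound state.

Because the reaction graph over the pools is a tree, every edge carries
zero net flux at steady state. That gives closed-form pool ratios
(`openClosedPartition`) and the observed dissociation constant relating
total ParB, free DNA and total bound ParB (`kdObserved`):

$$K_d^{obs} = K_d^{open}\,
  \frac{k_{co}^{DNA}+k_h}{k_{co}+k_h}\;
  \frac{k_{oc}+k_{co}+k_h}{k_{oc}^{DNA}+k_{co}^{DNA}+k_h}.$$

Three limits are built into the tests as identities: a hydrolysis-dead
(EQ-mutant) cycle with unchanged open/closed equilibrium recovers
$K_d^{open}$ exactly; so does nonspecific DNA that leaves the transitions
untouched; and in the parS regime — closure on parS much faster than
everything else, hydrolysis dominating the free-pool rates so closed
clamps are recycled — the constant collapses to the fast-recycling form
`kdObservedApprox`:

$$K_d^{obs} \approx K_d^{open}\,\frac{k_h}{k_{oc}^{parS}+k_h}.$$

With the literature estimates $k_h \sim 1/\mathrm{min}$ and
$k_{oc}^{parS} \sim 1/\mathrm{s}$ the fold reduction
$(k_{oc}^{parS}+k_h)/k_h$ is 61 — the "ultra-affinity" a roughly 50-fold
gain over the equilibrium value — and one parS site can catalyze
$k_{oc}^{parS}/k_h = 60$ closure events per hydrolysis turnover, which is
why strongly substoichiometric parS saturates closure and hydrolysis:

```{r}
foldReduction(kH = 1 / 60, kOCparS = 1)
catalyticCapacity(kOCparS = 1, kH = 1 / 60)
```

`steadyState()` solves the full species composition for given ParB and
DNA totals: the free and bound pools behave as a single 1:1 binding
equilibrium with constant `kdObserved`, solved by the usual quadratic;
with `dnaClamped = TRUE` free DNA is held fixed (excess-substrate
approximation). At free DNA equal to `kdOpen` the ultra-affinity
parameterization binds a fraction $61/62 \approx 0.98$ of ParB, versus
$1/2$ for the hydrolysis-free nonspecific case:

```{r}
r <- rateSet(kOC = 0, kCO = 0, kOCdna = 1, kCOdna = 0, kH = 1 / 60,
             kdOpen = 1)
boundFraction(steadyState(r, parbTotal = 1, dnaTotal = 1,
                          dnaClamped = TRUE))
```

### Units

Rates are canonically 1/s and concentrations µM; `rateSet()` accepts
`units = "per_min"` because the literature mixes the two (the 50-fold
estimate itself combines a per-minute hydrolysis rate with a per-second
closure rate). Concentrations are never rescaled by the unit tag.

### Dynamic solvers and the association rate

The analytic theory needs only `kdOpen`. The ODE relaxation
(`relaxODE`, mass-action via `deSolve::lsoda` at `rtol = 1e-10`,
`atol = 1e-12`, so conservation holds to ≲1e-9) and the stochastic
simulator additionally need `kOn` and `kOffOpen = kOn * kdOpen`
separately. No measured value exists for the open-form binding kinetics,
so when `kOn` is not supplied, `defaultKon()` chooses it such that
unbinding is 100× faster than the slowest conformational rate: binding
then pre-equilibrates and the steady state is insensitive to the choice.
The default is flagged in solver output and fully overridable.

## Exact stochastic simulation

`simulateNetwork()` draws statistically exact sample paths (direct
method: exponential waiting times from the total propensity, reaction
choice proportional to propensities) with mass-action combinatorics on
integer copy numbers; the core loop is C++ for speed, but uses R's RNG so
that a `(seed, network)` pair fully determines the trajectory. Default
problem sizes are a statistical-precision choice, not a biological one:
500 ParB copies and a volume factor of 100 copies/µM give single-percent
Monte Carlo errors in a couple of CPU seconds. Time averages are
accumulated after a burn-in (default 10× the slowest network timescale,
capped at half the run) and split into 20 batches, whose batch means give
the standard errors used by every "within 3 SE" check.

`buildCoarseNetwork()` reproduces exactly the reactions of the analytic
scheme. `buildDetailedNetwork()` resolves the cycle into nucleotide
binding (CTP on/off), N–M untethering/retethering, closure off DNA and on
parS, and hydrolysis. The untethering and nucleotide rates have no
measured values; they are required, explicitly free parameters. After an
on-DNA hydrolysis event the clamp either exchanges CDP for CTP without
unloading — probability $p_{retain} = [CTP]/([CTP]+K_{d,CTP})$, the
fast-exchange competition between nucleotide re-capture and gate opening
— or unloads and reverts to the autoinhibited apo dimer. The CDP-bound
micro-states are deliberately folded into this split: the data constrain
the outcome probabilities, not the micro-order of release and exchange.
In the fast-exchange limit (CTP binding effectively instantaneous,
untethering fast) the detailed scheme reduces to the coarse one; the test
suite checks that the stationary bound fractions agree within Monte Carlo
error, mapping the coarse retention competition (reopen-vs-unbind) onto
$p_{retain}$.

`hydrolysisFlux()` divides post-burn-in hydrolysis events by ParB copies
and time — the in-silico counterpart of the malachite-green CTPase rate.

## 1D spreading

`simulateProfile()` injects clamps at parS at a Poisson loading rate;
each clamp performs a continuous-time random walk (1-bp hops at rate `D`
per direction, so `D` is the diffusion coefficient in bp²/s and a free
cohort broadens as $\sqrt{2Dt}$) and unloads at the effective rate
`kOff * (1 - pRetain)`. Roadblocks (e.g. transcription machinery proxies)
and window edges either reflect or absorb. Blocked hops are treated as
null events, which preserves exactness of the jump chain. Occupancy is
the time-averaged per-site dwell after burn-in (`mode = "steady"`) or the
terminal snapshot (`mode = "terminal"`, for transient cohorts).

In the regime without exclusion and roadblocks the steady-state profile
is the two-sided exponential of diffusion–decay balance,
$\lambda = \sqrt{D/k_{off}^{eff}}$, total clamp number
$= \text{loading rate}/k_{off}^{eff}$ (`analyticProfile`, the oracle for
the simulator; its FWHM is $2\lambda\ln 2$). No measured value of `D`
exists, so all absolute widths are reported as functions of `(D, rates)`;
the contrast between wild type (~15 kb peak widths) and hydrolysis-dead
EQ mutants (~40 kb) is treated as a qualitative ordering target only.

Two protocol choices deserve a note. First, paired wild-type/EQ runs are
compared at the same (long) observation time, about 20/k_off: width
metrics are amplitude-invariant, and at short times — in particular at
the point where the EQ cohort's *total* occupancy matches the wild-type
steady state, $t = 1/k_{off}$ — the EQ transient width is analytically
indistinguishable from the wild-type steady width (FWHM
$\approx 1.40\lambda$ vs $2\ln 2\,\lambda$). The EQ broadening is a
long-residence phenomenon and only emerges for $t \gg 1/k_{off}$.
Second, the one-sided profile asymmetry seen in vivo is modeled *only*
via explicit roadblocks; its mechanism is unresolved, so no default
roadblock is placed.

Profiles are 0-based half-open tracks; `binProfile()` sums occupancy into
ChIP-convention bins (1 kb default) conserving the total, and
`writeBedGraph()`/`readBedGraph()` round-trip through `rtracklayer`.
`peakWidth()` offers FWHM (linear interpolation across the half-max
crossings; a single-bin spike reports one bin width) and a central-mass
width (smallest symmetric parS-centered interval holding a fraction `q`
of the occupancy — symmetric by construction, so it is a conservative
measure on skewed profiles).

## Assay models

**ITC.** `wisemanHeat()` evaluates the 1:1 closed-form heat content
$Q = \Delta H V_o [\text{complex}]$ with the complex concentration from
the binding quadratic; the discriminant is clipped at zero against
round-off only (a genuinely negative discriminant raises an error).
`injectionHeats()` applies the displaced-volume correction
$\Delta Q(i) = Q(i) + \frac{dV_i}{V_o}\frac{Q(i)+Q(i-1)}{2} - Q(i-1)$
with the constant-volume dilution recursion for cell contents, and
normalizes per mole of injectant (Wiseman convention). The volume ratio
is read as $dV_i/V_o$ — injection over cell volume — the standard
perfusion correction. `fitITC()` refines $(K, \Delta H)$ by
Levenberg–Marquardt least squares (`minpack.lm`), $K$ on a log scale to
stay positive, stopping at a relative loss change below 1e-10 or 500
iterations, with deterministic initialization ($\Delta H$ from the first
injection heat, $K$ from the inflection injection) and a non-convergence
flag that is never silent. Stoichiometry is fixed at 1:1; no floating
n-parameter.

**BLI.** `fitOffRate()` fits $A e^{-k_{app}t} + c$ to the dissociation
phase; the baseline offset $c$ is estimated rather than assumed zero,
because real sensors drift. Non-decaying traces return a zero-rate flag
instead of an error. `retentionModel()` is the CTP re-capture
competition, $k_{app} = k_h K_{d,CTP}/([CTP]+K_{d,CTP})$: strictly
decreasing in CTP, bounded in $(0, k_h]$, half-maximal exactly at
$[CTP] = K_{d,CTP}$ — with the ITC-measured affinity (5–8 µM) the
predicted half-max falls inside the measured 5–10 µM retention window.
Note the package reports the CTP-free BLI off-rate (~0.4/min) and the
basal solution hydrolysis rate (~0.15/min) as distinct quantities and
does not force them equal; the data leave the discrepancy open.

**CTPase.** `hydrolysisRateFit()` converts OD620 through the linear
standard curve if raw readings are supplied, fits the initial linear
slope and normalizes by enzyme concentration (1.5 µM Pi/min at 10 µM
enzyme ⇒ 0.15/min). Clearly nonmonotonic series trigger a warning and a
Theil–Sen median-of-slopes fallback.

## Synthetic data

Every generator requires an explicit seed (`noiseSpec`; no global random
state is consumed — the RNG state is saved and restored around each
draw), embeds its ground truth and seed in the output metadata, and
inverts exactly through its fitter at zero noise. Defaults mirror the
standard assay conditions: a 280-µL-class ITC cell at 100 µM protein
(within the usual 80–120 µM range) titrated from a 2 mM syringe; a 5-min
BLI dissociation window; 10 µM enzyme, 1 mM CTP and 60 min for the
CTPase course (accumulation capped at substrate exhaustion). ChIP-like
tracks draw Poisson counts per bin at `depth * (background + occupancy)`
for the IP and `depth * background` for the input control; the flat
background defaults to 10% of the peak occupancy — a free parameter, as
no background level is specified by the data the generator emulates.

What the generators deliberately do **not** emulate: ITC baseline drift
and integration artifacts, BLI mass-transport limitation and association
kinetics (the association phase is cosmetic), sequencing-depth
heterogeneity, mappability or fragment-length effects in ChIP counts,
and any ParB–ParB bridging or condensation contribution to focus
retention. Passing recovery tests therefore demonstrates correctness of
the estimators under the declared noise models, not robustness to every
artifact of real instruments.

## Numerical choices and problem sizes

* Degenerate parameterizations (zero denominators, e.g. `kCO = kH = 0`)
  raise errors naming the offending rates; limits are never silently
  substituted.
* The steady-state quadratic takes the physical root and clips tiny
  negative round-off at zero before constructing species states.
* Test-suite problem sizes — 500-copy coarse networks, 200-copy detailed
  networks over ~2000 s, 2–20 kb lattice windows, 100-seed recovery
  studies — were chosen so each check resolves its effect within
  single-digit-percent Monte Carlo error in seconds; enlarging them
  tightens the checks without changing any conclusion.
* Monte Carlo standard errors come from 20 batch means; "agreement"
  always means within 3 SE of the relevant estimate.

## Limitations

The coarse theory treats a ParB dimer as a single unit (no dimerization
stoichiometry), assumes one hydrolysis rate on and off DNA, and
represents only CTP-bound states (nucleotide exchange is fast); the
detailed scheme relaxes the last assumption but not the first two. The
lattice model has no 3D nucleoid structure, no replication/transcription
dynamics beyond static roadblocks, and no parameter inference from
occupancy data — `D` remains a free parameter throughout.
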