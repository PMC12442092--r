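---
title: "Models and methods behind fluorokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorokin)
```

`fluorokin` models the feasibility of Cu(I)/NHC-catalysed additions of
alkylboranes to symmetric ketones. This vignette is the package's own
account of the models it implements, the assumptions behind them, the
parameters that matter, and the choices made where the design was open.

## 1. Standard-state thermochemistry

Solution-phase Gibbs energies are composed as

$$G_T^0 = E_{el} + H_{corr} - T S + RT\ln(C^0/C^{1\,\mathrm{atm}}),$$

where the electronic energy (large basis, solvent and dispersion included)
and the thermal corrections (smaller basis, rigid-rotor/harmonic-oscillator)
are ingested as numbers — the package performs no electronic-structure
computation. The last term converts the 1 atm ideal-gas reference of the
frequency calculation to the 1 M solution standard state:
$C^{1\,\mathrm{atm}} = P/(R T)$ is the molarity of an ideal gas, so at
393.15 K it is 0.031 M and the correction is 2.71 kcal/mol per molecule.

```{r}
s <- standard_state(T = 393.15)
c(gas_M = gas_standard_concentration(s), corr_kcal = standard_state_correction(s))
```

All constants are CODATA 2018 and live in one table (`phys_const`);
hartree inputs are converted with 627.5095 kcal/mol (27.2114 eV) per
hartree. The correction grows monotonically with temperature at fixed
`C0 = 1 M`, which the test suite asserts as a property.

## 2. Free-energy profiles and the overall barrier

A `gibbs_profile` is an ordered list of stationary points with energies
relative to its first point. Validity rules (first point not a TS and at
zero, no adjacent transition states, unique labels) are enforced at
construction, so downstream code can assume a legal profile.

The overall activation barrier uses the energetic-span idea restricted to
the forward sweep of the cycle: for each transition state take its energy
minus the lowest intermediate *preceding* it; the barrier is the largest
such span, and its TS/intermediate pair names the turnover-determining
states. Ties break toward the later transition state, which makes the
result deterministic. The reference cycle shipped with the package — a
fluorinated alkylborane adding to acetone — illustrates the rule:

```{r}
overall_barrier(cu_acetone_profile())
```

The 45.4 kcal/mol span runs from the borane-adduct resting state `I3` to
the C–C addition `TS2`, not from the immediately preceding intermediate
`I4`; measuring barriers from the resting state is what links the profile
to turnover kinetics.

Two readings of the transmetalation TS placement are supported.
The 16.9 kcal/mol investment of `TS1` is measured from the resting
intermediate `I3` by default (absolute +13.9), consistent with how the
overall barrier is measured; `cu_acetone_profile(ts1_from = "I1")` gives
the alternative reading (+16.9 absolute). The overall barrier is identical
under both because `TS2` determines it, but the transmetalation-limited
floor of the barrier sweep differs, which is why the flag exists. The
profile endpoint (−0.6 kcal/mol) is taken as stated; the final-step
reaction energy is derived from it rather than ingested separately, so the
two can never disagree.

## 3. Microkinetics

### Mechanism and rate constants

The five-step template (`cu_mechanism()`) maps profile points onto
elementary steps: halide activation (irreversible, off-cycle), borane
uptake, B→Cu transmetalation via `TS1` (releasing the fluoroborane),
C–C addition via `TS2` (consuming the ketone), and alkoxide/fluoride
exchange that regenerates the active catalyst and releases the product.
Profile points are composite states, so the species a step produces can
differ from the label its energy is read from: the release step's energy
is the profile endpoint while its products are `I2 + product`.

Rate constants are Eyring, $k = (k_B T/h)\,e^{-\Delta G^\ddagger/RT}$,
with bimolecular constants referenced to the 1 M standard state (same
numerical value, units M⁻¹s⁻¹). Steps with a located TS take
`ΔG‡ = G(TS) − G(preceding state)`; steps the mechanism treats as
barrierless take `ΔG‡ = max(ΔG_rxn, 0)` plus an optional intrinsic barrier
(default 0). Backward barriers always satisfy
`ΔG‡_b = ΔG‡_f − ΔG_rxn`, so every reversible step obeys detailed balance
exactly — a property the tests verify both algebraically and by relaxing a
closed two-state system to its Boltzmann ratio.

Raw Eyring constants for barrierless association steps reach the
prefactor, ~8×10¹² M⁻¹s⁻¹, which is unphysical and needlessly stiff. A
diffusion-limit cap (default 10⁹) therefore rescales *both* directions of
an offending step by the same factor: the equilibrium constant is
untouched, fast steps stay fast relative to everything else, and the
rate-limiting chemistry is unaffected.

### Simulation conditions

The defaults emulate a plausible batch protocol for this chemistry and are
the conditions under which every headline kinetic number is quoted:
393.15 K (120 °C), `[alkylborane] = [ketone] = 1 M`, `[CsF] = 2 M`
(two equivalents: one consumed by activation, one by product release),
`[catalyst] = 0.05 M` (5 mol%), 16 h horizon. They are deliberate,
configurable choices — the original batch recipe is not part of the
package's inputs — and the feasibility numbers below scale with them.

The ODE system is mass-action over the network's steps, integrated with
`deSolve::lsoda` (automatic stiff/non-stiff switching; rtol 10⁻⁸, atol
10⁻¹² M) on a log-spaced time grid of 400 points spanning nine decades up
to the horizon, so both the microsecond pre-equilibria and the 16-hour
scale are resolved. Conservation of the copper, boron and ketone-carbon
totals along every trace is asserted to 10⁻⁹ M in the tests.

### Barrier sweep and the feasibility limit

`barrier_sweep()` re-places the C–C addition TS alone — every other
stationary point frozen, exactly the "fix the TS height" experiment — so
the overall barrier takes each integer target value, re-simulates, and
records 16-h yields. `feasibility_limit()` returns the largest barrier
reaching 99% yield. Three regimes emerge on the
difluoromethyl-ketone-like template (native barrier 23.6 kcal/mol,
transmetalation floor 17.4): barriers ≤26 finish almost instantaneously
relative to 16 h, a narrow crossover follows, and yields collapse roughly
geometrically (each +1 kcal/mol multiplies the limiting rate constant by
`exp(−1/RT) ≈ 1/3.6` at 393 K).

Under the default conditions the computed limit is 27 kcal/mol. A
back-of-envelope check agrees: at a 29 kcal/mol span the turnover
frequency is `(k_B T/h)·exp(−29/RT)·[cat] ≈ 3×10⁻⁵ s⁻¹`, giving
`1 − exp(−1.8) ≈ 83%` in 16 h — short of quantitative. The 99% limit sits
at 29 kcal/mol only under roughly three-fold faster conditions (e.g.
~15 mol% catalyst or ~3 M substrates), so the limit should always be
quoted together with its conditions; the package treats the conditions as
first-class inputs for exactly this reason.

When a requested barrier falls below the transmetalation floor the C–C TS
cannot control the cycle; `shift_ts()` still performs the displacement but
warns that the realised barrier is floor-limited and the regime has
switched.

## 4. Conceptual-DFT descriptors

From frontier-orbital energies in the Koopmans-type approximation
(`I = −ε_HOMO`, `A = −ε_LUMO`): chemical potential `μ = (ε_H + ε_L)/2`,
electronegativity `χ = −μ`, hardness `η = ε_L − ε_H` (gap convention, not
halved), softness `S = 1/(2η)`, electrophilicity `ω = μ²/(2η)`, and the
electrodonating/electroaccepting powers
`ω± = (aI + bA)²/(16(I − A))` with `(a,b) = (3,1)` and `(1,3)`. The
identity `ω⁻ − ω⁺ = χ` holds exactly and is asserted as a property. The
hardness convention matters only up to an affine rescaling of descriptor
columns, and every downstream fit is proven invariant under such
rescalings, so the choice cannot move regression results.

The nucleophilicity index is `N = ε_HOMO − ε_HOMO(reference)` against an
explicitly supplied reference electrophile (conventionally
tetracyanoethylene at the same level of theory); there is deliberately no
default, since a silently assumed reference would shift every `N` in a
table. `N′` is implemented as the same offset against a second configured
reference — any affine variant of the index is absorbed by autoscaling, so
the fitted model is insensitive to the exact convention, and only raw
coefficient values would differ.

## 5. The barrier regression

`fit_barrier_mlr()` is ordinary least squares through a QR factorisation
(no regularisation — two descriptors, n ≈ 28), storing both the raw-unit
form and the autoscaled form. Autoscaling uses sample standard deviations
(ddof = 1); the standardized intercept equals the training mean, and the
standardized slopes are directly comparable importances. Cross-validation
refits the autoscaling inside every fold so no information leaks from the
held-out points; LOO R² is the predictive `1 − PRESS/SS_tot` (the standard
Q² definition, the reported statistic being stated without a formula), and
the LOO residuals are checked against the hat-matrix identity
`e_i/(1 − h_ii)` of an independent reference implementation. k-fold CV
shuffles into near-equal folds from an explicit seed — determinism is a
requirement, and the fold protocol is otherwise unspecified, so a seeded
shuffle is the package's choice. `rmse` uses the 1/n denominator (the
common machine-learning convention); the `1/(n−p−1)` variant is reported
alongside as `rmse_np` so comparisons with either convention are
unambiguous.

Predictions outside the training descriptor box are flagged (`extrapolated`
attribute plus a warning): the model is an interpolator among
electronically similar substrates, not a general barrier oracle.

## 6. What the synthetic generator emulates — and what it does not

`generator_spec()` freezes the emulated study design:

* 7 alkylboranes × 4 ketones (28 pairings). Borane `N′` uniform on
  [2, 5] eV; ketone LUMO levels at −0.655, −1.238, −1.906, −2.204 eV,
  representing four degrees of methyl fluorination of acetone (chosen once
  so the per-ketone barrier series means land near 46/35/24/18 kcal/mol).
* Barriers from the plane `ΔG‡ = 30.84 − 0.85·z(N′) + 10.69·z(ε_LUMO)` —
  the ketone term ~13× the borane term — with σ = 1 kcal/mol Gaussian
  noise, matching the ~1 kcal/mol residual scale of a DFT-level fit.
* A transmetalation floor of 17.4 kcal/mol: plane barriers below it are
  replaced by the floor and the regime switches, reproducing the
  observation that the most electrophilic ketone's systems become
  transmetalation-limited.
* Profiles that invert the span rule exactly, with the C–C TS placed 50
  kcal/mol above the alkoxide intermediate it collapses to, and a mildly
  exergonic product release (−2 kcal/mol) so fluorinated-ketone cycles are
  thermodynamically open. The reference acetone system instead carries its
  own nearly thermoneutral endpoint, which is what makes its fixed-barrier
  runs equilibrium-limited rather than purely kinetically limited.

All randomness derives from `spec$seed` (substrates from `seed`, barrier
noise from `seed + 1`), so every generated library is bit-reproducible.

What passing tests on these libraries shows: the pipeline's statistical
machinery is correct (exact recovery at σ = 0, unbiased-within-SE recovery
at σ = 1 over 200 seeds, planted-pair identification, regime switching).
What it does not show: that real substrates obey a two-descriptor plane,
that real profile shapes match the template away from the anchored levels,
or that the batch recipe matches a laboratory protocol — those claims
would need the original quantum-chemistry tables and experimental
conditions, which are outside the package's inputs.

## 7. Numerical choices and degenerate inputs

* Span ties break toward the later TS; profile validation rejects the
  degenerate shapes (leading TS, adjacent TSs, duplicate labels) instead
  of guessing.
* `shift_ts` targets below another step's floor warn and return the
  floor-limited profile rather than failing.
* Constant descriptor columns are a named error in `autoscale`; exact
  collinearity is a rank error in the fit; missing nucleophilicity
  references are errors, never defaults.
* Solver failures abort with the integrator's state rather than returning
  a partial trace; traces are clipped at zero only inside the rate law
  (`pmax(y, 0)`) to keep mass action well-defined against 10⁻¹²-scale
  negative excursions.
* Problem sizes are deliberately desk-scale: 8-point profiles, 11-species
  networks, 28-row regressions, 13-point sweeps, 200-seed recovery
  studies. The full suite runs in well under a minute.

## 8. Known limitations

* No temperature ramps, transport, or off-cycle decomposition; the
  mechanism template is fixed to the five-step cycle (though
  `build_network` accepts custom templates).
* The feasibility limit is conditions-dependent (Section 3) and is
  reported under the documented defaults only.
* Tunneling and diffusion corrections beyond the equilibrium-preserving
  cap are not modelled; for barriers of 17–46 kcal/mol at 393 K these are
  secondary to the exponential term.
* The regression is a linear interpolator; its extrapolation flag is a
  box test, not an applicability-domain model.
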