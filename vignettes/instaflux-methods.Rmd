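---
title: "Instationary 13C flux analysis: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instationary 13C flux analysis: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instaflux)
```

## The problem

A methylotrophic yeast growing in a carbon-limited chemostat on a
glucose-methanol mixture routes carbon through glycolysis, the pentose
phosphate pathway (PPP), the methanol oxidation/assimilation pathways, the
TCA cycle, and storage-carbohydrate cycling. Net fluxes through these
pathways cannot be observed directly. Instationary 13C metabolic flux
analysis (INST-13C-MFA) infers them from the transient enrichment of
mass-isotopomer distributions (MIDs) after the feed is switched to
isotopically labeled substrates: each intracellular pool washes in label at
a rate set by its flux-to-pool-size ratio, so the time courses constrain
both fluxes and pool sizes.

`instaflux` implements the full chain: atom-transition network parsing,
EMU-based simulation of MID dynamics, weighted least-squares estimation with
a chi-square acceptance test and linearized confidence intervals,
network-embedded thermodynamic (NET) consistency analysis of metabolite
concentrations, and macroscopic carbon/redox/ATP balance reconstruction.
A synthetic-data module generates seeded ground truths and noisy datasets
with the statistical structure of the experiment, so every stage is testable
without access to raw measurements.

## Labeling model

### EMU balances

The labeling state is propagated on elementary metabolite units (EMUs):
subsets of a metabolite's carbons whose MID can be balanced autonomously.
For EMU $i$ hosted by a metabolite with pool size $c_i$ (umol/gCDW),

$$ c_i \frac{dx_i}{dt} \;=\; \sum_{j \in \mathrm{in}(i)} v_j\,(y_j - x_i), $$

where $v_j$ are the directed fluxes of the producing reaction channels
(mmol/gCDW/h; the unit mismatch contributes a factor 1000) and $y_j$ is the
MID delivered by channel $j$ — the MID of a single precursor EMU, or the
convolution of several for condensation reactions. Because the flux
distribution is at metabolic steady state, total inflow equals total
outflow, and biomass drains need no separate dilution term: outflow leaves
at the pool's own composition, which is exactly what the $-x_i$ term
encodes.

The EMU formulation is equivalent to cumomer balancing but carries only the
variables required for the measured fragments. The equivalence is enforced
in the test suite by an independent brute-force oracle that integrates the
full positional-isotopomer system ($2^n$ states per metabolite) directly
from the atom maps; the EMU simulator agrees with it to better than $10^{-6}$
in every fraction at every time point on all toy networks.

### Numerical integration

Pool turnover times in this system span roughly four orders of magnitude
(sub-second for triose phosphates, hours for trehalose and glutamate), so
the ODE system is stiff; it is integrated with `lsoda` at `rtol = 1e-8`,
`atol = 1e-10`. Small systems (up to 240 EMU states) are integrated as one
coupled system, which keeps condensation coupling exact. Larger systems are
solved level by level in EMU size — the natural triangular structure of the
cascade — with the forcing from lower levels precomputed on a dense
logarithmic grid (3000 points from $10^{-7} t_\max$ to $t_\max$) and
linearly interpolated inside the solver. The interpolation error is far
below measurement noise and vanishes with grid refinement; on the shipped
network the transient solution at $t = 100$ h matches the independent
algebraic steady-state solver to $10^{-14}$.

All simulated MIDs are checked to sum to 1 within $10^{-6}$ (interpolation
and solver tolerances compound slightly above the $10^{-8}$ the algebra
guarantees); violations raise an error rather than being silently
renormalized.

### Initial condition and natural abundance

Measured MIDs are corrected for natural-abundance and derivatization mass
shifts before fitting (`correct_natural_abundance()`, a correction-matrix
least squares with clamping of small negatives and renormalization), so the
simulation starts from the abundance-free "all m+0" state and the feed
patterns are treated as exact.

## The shipped network

The package ships a reduced network for glucose-methanol co-assimilation
reconstructed from the pathway content of the study it emulates: 37 balanced
metabolites and 79 reactions counting bidirectional fluxes — glycolysis and
gluconeogenesis (including FBPase), oxidative and non-oxidative PPP,
methanol dissimilation (MetOH -> formaldehyde -> formate -> CO2) and
assimilation (dihydroxyacetone synthase), trehalose synthesis/degradation,
the pyruvate dehydrogenase bypass, TCA cycle with an aspartate lyase, the
alpha-ketoglutarate/glutamate and oxaloacetate/aspartate exchange pairs, an
unlabeled mitochondrial pyruvate source/sink pair, anaplerosis, and nine
biomass precursor drains. Cytosol and peroxisome are lumped; pyruvate is
split into cytosolic and mitochondrial pools. Exact reaction identities
could not all be resolved from pathway names alone; the network file
documents the mapping it uses.

Two representation choices deserve comment:

* **Symmetric products.** Reactions forming succinate or fumarate are
  written as two parallel reactions with mirrored atom maps, tied 1:1 by
  structural constraints. Tying parallel channels is algebraically identical
  to one reaction with two half-weight atom maps, and it makes the
  constraint accounting explicit: the tie constraints are first-class rows
  of the constraint system.
* **CO2 and the rate constraints.** CO2 is a balanced, labeled pool (it must
  be: methanol dissimilation labels it and anaplerosis consumes it). In a
  carbon-complete network, fixing both substrate uptakes and all nine
  biomass drains already determines CO2 excretion through carbon
  conservation, so the constraint set fixes the two uptakes and leaves the
  CO2 evolution rate as a model prediction instead of imposing it
  redundantly.

With the shipped constraint set (2 uptake rates, 9 biomass drains, the
pyruvate source/sink tie, and the 6 structural scramble ties) the directed
flux space has $79 - \operatorname{rank}[S; C] = 24$ free fluxes; 27 of the
37 pools are measured, leaving 10 to estimation — 34 parameters in total.

## Estimation

Free parameters are the 24 free *directed* fluxes and the base-10
logarithms of the unmeasured pools. Working on directed coordinates with box
bounds keeps every exchange flux non-negative and bounded without an extra
transform (an equivalent alternative would map exchanges through
$\beta/(1-\beta)$); pools are log-parameterized because their plausible
range spans decades, with default bounds $[10^{-3}, 50]$ umol/gCDW.

The measurement model is a constant 2% relative standard deviation per
mass-isotopomer fraction, floored at 0.002 so near-zero fractions do not
acquire infinite weight ("relative variance of 2%" is read as a relative
standard deviation; the off-by-square-root alternative would make typical
fractions of 0.3 carry absurd 55% errors). The objective is the weighted sum
of squared residuals over all fractions and times, minimized by multi-start
bounded Levenberg-Marquardt (`minpack.lm`). Because a single residual
evaluation is far cheaper than a full local optimization, starts are chosen
by screening: a seeded pool of random candidates (plus the deterministic box
midpoint) is ranked by SSR and the optimizer is launched from the best few —
without this, occasional noise realizations leave every naive start in the
basin of a poor local optimum. Completions
that would require negative directed fluxes contribute smooth linear
penalty residuals, and fluxes are floored at $10^{-9}$ during simulation so
EMU connectivity never collapses abruptly at the feasibility boundary.

A fit is accepted when its SSR lies below the 95% chi-square quantile at
`n_measurements - n_parameters` degrees of freedom. Covariances come from
linearized error propagation, $(J^\top W J)^{-1}$ with $J$ the
finite-difference sensitivity of all predicted fractions; rank-deficient
directions are flagged structurally unidentifiable and reported with
unbounded intervals rather than dropped.

## Synthetic data and what passing tests show

The generator's defaults are the study conditions: glucose fed as 80%
[1-13C1] + 20% [U-13C6], methanol 100% 13C, twenty sampling times spaced
exponentially from 5 s to 6 h ($t_k = 5\,\mathrm{s} \cdot (6\,\mathrm{h}/5\,
\mathrm{s})^{k/19}$), 2% relative noise, pools drawn log-uniformly from
0.01-20 umol/gCDW when not fixed. Noise is Gaussian per fraction, truncated
at zero, and each MID is renormalized to sum 1, mirroring how measured MIDs
are normalized. Renormalization correlates the noise within a MID and
shrinks it slightly, so the residual at the true parameters sits somewhat
below the nominal chi-square level; the calibration test therefore uses the
generator's `renormalize = FALSE` mode, which realizes the independent-noise
model the chi-square acceptance rule assumes. The generator does not emulate
chromatographic artifacts, replicate-correlated errors, or drift — passing
recovery tests show the estimator is correct and calibrated under the stated
noise model, not that real instruments behave this way.

The parameter-recovery and calibration studies run on a small branched
network (uptake, a decarboxylating branch, one reversible step, one
unmeasured pool) rather than the full 37-metabolite model: 25 replicate fits
of the full model would cost hours rather than minutes, and the estimator
code path is identical. The full network is exercised by simulation tests,
including the qualitative timing property that TCA-cycle fragments approach
isotopic steady state more slowly than upper-glycolysis fragments, and the
observation that the trehalose pool (turnover time about 3 h here) is still
measurably short of isotopic steady state at 6 h.

## NET analysis

Thermodynamic consistency is checked in log-concentration space: with
$x = \ln c$, the second-law constraint for a reaction with direction $d$ is
$d\,(\Delta_r G'^0 + RT\,S^\top x) \le -\varepsilon$ (with $\varepsilon =
10^{-6}$ kJ/mol standing in for strict inequality), which is linear in $x$.
Measured pools enter as 80% Student-t confidence ranges converted to mM with
a cell volume of 1.7 ml/gCDW; unmeasured metabolites receive a default range
of $10^{-3}$-10 mM. Minimizing and maximizing each $x_i$ subject to these
constraints (one LP per bound, solved with a simplex method behind a small
box-LP wrapper) tightens the ranges; infeasible systems are localized by
minimizing a common slack variable, and the constraints still violated at
the optimum name the incompatible reactions. Because every variable is
box-bounded, the LPs are always bounded and infeasibility is the only
failure mode.

Transformed standard Gibbs energies are *inputs* (YAML, per pH scenario) —
rebuilding a group-contribution database is out of scope — so quantitative
cofactor-ratio results depend on the supplied table. What the package
asserts and tests are structural properties: tightening is monotone (adding
a directed constraint never widens a range) and idempotent; a
forward-directed transaldolase running against the measured mass-action
ratio is reported infeasible while the channelled transketolase/transaldolase
variant (Xul5P + Rib5P <-> Fru6P + E4P) restores feasibility on the same
concentrations; and the minimum NAD+/NADH ratio decreases as the assumed
cytosolic pH rises from 7.0 through 7.2 to 7.5, since NADH-producing
reactions release a proton.

## Macroscopic balances

The respiratory quotient is CER/|OUR|; carbon recovery is the fraction of
substrate carbon (6 per glucose, 1 per methanol) recovered in biomass and
CO2. Measured rates are reconciled by weighted least-squares projection onto
the subspace satisfying carbon and degree-of-reduction conservation, with a
chi-square statistic on the balance residuals serving as a gross-error test.
The biomass elemental composition defaults to CH1.76O0.63N0.14 (degree of
reduction 4.08 against ammonia); it is configurable, and the consistency
verdict on any given rate set depends on it — with this placeholder
composition the shipped benchmark rates sit just outside the 95% test,
driven by the redox balance.

Cofactor rates are stoichiometric dot products with the net flux vector
(coefficients shipped as YAML; FADH2 tracked separately from NADH with
electrons pooled). The theoretical oxygen uptake assumes all surplus NADH
and FADH2 is respired, one O per electron pair; ATP from oxidative
phosphorylation is $2 \cdot (P/O) \cdot q_{O_2}$ with P/O = 1.48 mol ATP/mol
O; the non-growth-associated maintenance is the remainder after subtracting
the growth-associated demand, and a negative remainder is flagged rather
than clamped. No transhydrogenase closure is assumed: NADPH imbalances are
reported as they are.

## Degenerate inputs and tie-breaks

* Completion of free fluxes requiring a directed flux below $-10^{-6}$
  raises an error (smaller round-off is clamped to zero).
* EMUs whose total active inflow is zero are dropped when irrelevant to the
  targets and are an error when a measured fragment depends on them.
* Zero or negative pools on balanced metabolites are errors, as are
  non-positive concentrations in mass-action ratios.
* Infeasible NET systems return the violated reaction set, never a silently
  clamped range; negative abundance-corrected fractions warn and clamp.
* The free-flux basis picks its free coordinates by QR column pivoting on
  the null-space basis, which makes the selection deterministic for a given
  network and constraint set.

## Known limitations

* The shipped network is a reconstruction; reaction naming and the exact
  measured-fragment list differ from the original model, so fitted values on
  real data are not expected to reproduce the study's flux map numerically.
* Linearized confidence intervals understate uncertainty for strongly
  nonlinear parameters (notably large exchange fluxes); profile likelihoods
  are out of scope.
* The thermodynamic results are conditional on the supplied Gibbs-energy
  table; compartment-specific pH corrections and multi-species pKa
  transforms are not implemented.
* Tandem-MS and NMR positional data are not supported; measurements are
  MID time courses only.

## Worked example

```{r example, eval = FALSE}
net <- pichia_network()
basis <- free_flux_basis(net, pichia_constraints())
basis$n_free                       # 24 free fluxes

sys <- emu_decompose(net, pichia_fragments())
fx <- pichia_demo_fluxes()         # paper-like demonstration fluxes
mid <- simulate_inst(sys, fx, pichia_demo_pools(), pichia_feed(),
                     exp_time_grid())
autoplot(mid)

rates <- read_rates(instaflux_example("pichia_rates.csv"))
respiratory_quotient(rates)        # 0.79
carbon_recovery(rates)             # 99.4
```
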