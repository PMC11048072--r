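---
title: "Modelling CHO fed-batch metabolism: stoichiometric and kinetic methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CHO fed-batch metabolism: stoichiometric and kinetic methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chomet)
```

# Scope

`chomet` analyses central carbon metabolism of CHO cells in fed-batch
culture, with an emphasis on intensified high-seeding-density (HSD)
processes: cultures inoculated at around 10 million cells/mL from an (N-1)
perfusion pre-stage, so that most exponential growth happens upstream of the
production reactor. The package combines two modelling layers:

* a **stoichiometric layer** — a curated central-carbon network on which flux
  balance analysis (FBA) and metabolic flux analysis (MFA) are run against
  measured cell-specific exchange rates, and
* a **kinetic layer** — a reduced ODE model of twelve metabolic/biomass
  states plus reactor volume whose regulatory structure reproduces the
  lactate production-to-consumption shift and its dependence on asparagine.

Everything in between — converting offline concentration measurements into
specific rates, calibrating the kinetic model, selecting model structures,
and running feed-composition simulation studies — is provided as composable
functions, and a synthetic-data generator supplies fed-batch datasets with
the process structure the pipeline expects, so the entire analysis can be
exercised and tested without access to proprietary cultivation data.

# The stoichiometric network

The default network (`default_network()`) has 32 metabolites and 44
reactions: glycolysis as a single lump producing 2 ATP and 2 cytosolic NADH
per glucose, an oxidative pentose-phosphate entry, lactate dehydrogenase
(reversible) and lactate transport, pyruvate dehydrogenase, a two-step TCA
lump through oxaloacetate and 2-oxoglutarate, anaplerosis via pyruvate
carboxylase and a malic-enzyme route, catabolic lumps for asparagine,
aspartate, glutamate, serine, isoleucine and leucine with ammonium release,
oxidative phosphorylation, an ATP drain, and biomass/mAb pseudo-reactions.

Key stoichiometric choices:

* **P/O ratios.** Mitochondrial NADH is credited 3 ATP, FADH2 2 ATP, and
  cytosolic NADH enters at FADH2 yield through a
  glycerol-3-phosphate-shuttle equivalent. With these values, complete
  oxidation of glucose yields 36 ATP and the anaerobic glucose-to-lactate
  route yields 2 ATP — the two textbook figures the energetic discussion of
  overflow metabolism rests on. Both are recovered exactly by FBA on the
  shipped network (see `scripts/acceptance.R`).
* **Element closure.** Every internal reaction is carbon- and
  nitrogen-balanced; `check_balances()` verifies this and `build_network()`
  refuses unbalanced networks unless asked not to. Exchange reactions and
  the biomass, mAb and ATP-drain pseudo-reactions are exempt, as their
  elemental composition is not modelled.
* **Biomass and product.** Precursor coefficients of the biomass and mAb
  pseudo-reactions are documented defaults in the shipped reaction table
  (no measured composition stands behind them), editable by replacing the
  TSV.
  Compartments are annotations only; no membrane potential or proton
  accounting is attempted.

The network round-trips through a native two-table TSV format and through
SBML Level 3 with fbc flux bounds, reproducing the stoichiometric matrix
bit-identically.

## FBA and the LP solver

`apply_measurement_constraints()` implements the measurement-driven
constraint scheme: each measured exchange flux is boxed to ±10% of its
measured value, unmeasured reactions get a lower bound of 0 (irreversible)
or −1000 (reversible) and an upper bound of 1000. `solve_fba()` then
maximises biomass or mAb production.

Linear programmes are solved through quadratic programming
(`quadprog`): the problem `min ‖v‖² − t·c'v` is solved for increasing `t`;
for a compact polytope the solution becomes, beyond a finite `t`, exactly
the minimum-norm point of the optimal face (the objective gradient is
orthogonal to that face), so the escalation terminates with the exact LP
optimum. This has a welcome side effect: among alternate optima the
**minimum-2-norm flux distribution** is returned, making reported flux maps
reproducible without a secondary optimisation. Near-infinite bounds are
enforced lazily through an outer active-set loop, which keeps the quadratic
subproblems well conditioned; every reported solution is audited post hoc
against `S v = 0` and all bounds.

## MFA

`run_mfa()` reconciles measured exchange rates with the steady-state
constraint by weighted least squares: minimise `Σ w_j (v_j − q_j)²` over the
measured set subject to `S v = 0` and the irreversibility bounds, with
relative weights `w_j = 1/max(q_j², 1e-6)`. The QP is solved in
weight-scaled variables so the weight spread cannot degrade conditioning; a
vanishing ridge (`1e-8` of the median weight) on unmeasured fluxes keeps the
programme positive definite. The fit quality is reported as the pooled
`R² = 1 − SSR/SST` across measured fluxes — pooled rather than per-day,
which is one of the places where the method description leaves the exact
convention open and the package documents its choice. On
steady-state-consistent synthetic flux sets perturbed with 5% multiplicative
noise the median pooled R² exceeds 0.98, the validation threshold used for
the stoichiometric model.

## Phase windows and efficiency metrics

FBA is evaluated per sampled day inside condition-specific windows that
exclude the lag phase: days 4–13 for the standard fed-batch, days 0–11 for
the HSD control (an 11-day process), days 2–13 for the supplemented runs.
Days before the configurable changeover (default day 7, between the two
values suggested by the intracellular flux ratios) carry the biomass
objective; later days the product objective. The lactate/glucose
uptake-flux ratio (`lactate_glucose_ratio()`) condenses the carbon-source
usage: negative while lactate is produced, between 0 and 1 during efficient
co-consumption, above 1 when lactate is the primary carbon source.

# The kinetic model

## States and rate laws

States: Glc, Pyr, Lac, Amm, Asn, Asp, Glu, Ser, Ile, Leu (mmol/L), viable
biomass X (g dry weight/L), mAb (mg/L), and volume V (L). All rate laws are
multiplicative Michaelis–Menten terms; growth is a multiplicative Monod
expression over glucose, asparagine, serine, isoleucine and leucine, and
viability is represented implicitly by a first-order death rate removing
viable biomass (no dead-cell state).

The lactate shift is carried by four coupled regulations:

1. **Glycolysis activated by asparagine**:
   `r_gly = vmax_gly · Glc/(km_glc+Glc) · Asn/(ka_asn_gly+Asn)`.
2. **LDH feedback inhibition by lactate** with a parametric exponent:
   `r_ldh = vmax_ldh · Pyr/(km_pyr+Pyr) · ki^n/(ki^n + Lac^n)`.
3. **Lactate uptake inversely coupled to glycolysis**:
   `r_up = vmax_up · Lac/(km_lac+Lac) · α/(α + r_gly)`. The inverse
   coupling is implemented as a saturating inverse term rather than a
   literal `1/r_gly`, which would be singular at zero glycolytic flux; the
   term is strictly decreasing in `r_gly` and reaches its maximum when
   glycolysis is silent, which is the behaviour the coupling is meant to
   encode.
4. **Pyruvate entry into the TCA cycle inhibited by asparagine**:
   `r_tca = vmax_tca · Pyr/(km_pyr_tca+Pyr) · ki_asn/(ki_asn + Asn)`.

Under this structure, high asparagine keeps glycolysis active and the TCA
entry throttled, so pyruvate accumulates and drains to lactate; as
asparagine depletes, glycolysis slows, the inverse coupling releases lactate
uptake, and pyruvate flows into the TCA cycle — net lactate flux changes
sign. Clamping asparagine at its seeding level abolishes the sign change
(tested), which is the model's core causal claim.

Three model structures share this framework: variant 2 adds a
glutamate-to-aspartate lump (making the transamination effectively
reversible) and variant 3 a serine-to-pyruvate lump. The appendix-level
enumeration of secondary-reaction differences is not reproducible from the
available description, so these two variants are declared package choices.

## Lump bookkeeping

`kinetic_stoichiometry()` exposes the stoichiometry of all lumps over the
modelled states plus three virtual carbon pools (`CO2_sink`, `TCA_sink`,
`biomass_sink`). Every lump is carbon-closed over this extended set — for
example the aspartate-to-glutamate lump draws one TCA-pool carbon, and
glutamate deamination returns five — and the test suite verifies both the
closure and that the ODE right-hand side equals `N·r·X` for all three
structures. The integrator uses a hand-unrolled, allocation-free copy of the
same arithmetic (asserted identical to machine precision) because the
generic version dominates integration time otherwise.

## Fed-batch events

Simulation (`simulate_model()`, stiff-capable `lsoda`) applies all discrete
feeding as instantaneous perfectly mixed jumps at **daily checkpoints**,
mirroring once-daily sampling-and-feeding operation: scheduled boluses
(amino-acid-enriched bolus medium on days 1–6 for the BM condition; fixed
7 mL cysteine boluses on days 1–5 for LAC+CYS, acting through dilution only
since cysteine is not a state), the glucose-threshold refill (default:
below 11 mmol/L restore to 33 mmol/L from a 2.5 mol/L stock), and the
lactate trigger of the LAC+CYS condition (below 2 g/L ≈ 22.2 mmol/L on days
3–13, restore to 28 mmol/L). Trigger volumes follow from the mixing rule,
all applied boluses are logged, and the log supports exact mass audits
(tested). Continuous feeding enters the right-hand side as `F/V` dilution
with a fixed feed composition.

Daily rather than continuous threshold monitoring is a deliberate choice: it
matches how such processes are actually operated, keeps the event system
deterministic, and avoids root-finding across stiff transients.

## Reference parameters and what the generator emulates

The reference ("truth") parameter set shipped with the package was chosen
once, within the literature ranges for CHO central metabolism (Km of order
0.01–1 mmol/L for intracellular steps, a few mmol/L for transport lumps;
vmax of order 0.01–1 mmol/g_DW/h; µmax ≈ 0.02/h for the production stage;
250 pg dry weight per cell), such that the four culture conditions show the
qualitative physiology the analysis targets: the HSD control shifts from
lactate production to consumption around day 7; a modest reduction of feed
asparagine (factor 0.75) moves the shift one day earlier; a strong elevation
(factor 2) suppresses it entirely; the LAC+CYS condition reaches a
lactate/glucose uptake ratio above 1 after its shift (lactate as primary
carbon source); and the BM condition sustains amino acid levels, grows
longest and reaches the highest titer.

The synthetic generator (`generate_dataset()`) samples the truth simulation
at 13 points (daily for the 12-day HSD runs, every 28 h for the 14-day
standard fed-batch; seeding 10 vs 0.7 million cells/mL) and applies
multiplicative Gaussian noise (5% CV on concentrations and titer, 8% on
viable cell density), clipped at zero. Absolute concentration scales
(glucose 40, asparagine 10, lactate 1 mmol/L at seeding; feed glucose
500 mmol/L, feed asparagine 150 mmol/L) are documented synthetic defaults —
the study's own figures are normalized and its media proprietary, so these
values are calibrated to physiological plausibility, not to the source data.

What the generator does **not** emulate: analytical-chemistry artifacts
(derivatization recovery, internal standards), online signals (pH, pO2,
pCO2) and their interaction with metabolism, osmolality effects, product
quality, and any regulation of specific productivity beyond a constant
cell-specific rate. Tests passing on synthetic data therefore demonstrate
the internal consistency and statistical behaviour of the pipeline, not the
biological fidelity of the reference parameters to any particular cell line.

# Calibration and the ensemble

## Cost and optimiser

The calibration cost is `Σ_states Σ_t ((sim − obs)/scale)²` with
`scale` the maximum observed value per state, so concentrations measured in
tens of mmol/L and titers in g/L contribute comparably. Unobserved states
(pyruvate, in practice) are simply absent from the sum.

`fit_parameters()` is a scatter-search-style global optimiser in log10
parameter space: a Latin-hypercube initial population, a reference set of
the best members, pairwise convex/reflective combinations, and a final
`nlminb` polish of the incumbent, all within an evaluation budget and fully
deterministic given a seed. On noise-free synthetic data three-parameter
recovery reaches the generating values to better than 2%; on 5%-noise data
the parameters ranked most influential by Morris screening are recovered
within a few percent, while the weakly identifiable pair
(`vmax_up`, `alpha_gly`) trades off along a ridge — the expected behaviour,
since post-shift lactate uptake constrains mainly their combination.

## Structure selection and ensemble prediction

`compute_aic()` uses the Gaussian-residual form `n·ln(cost/n) + 2k` with an
optional small-sample correction. `build_ensemble()` retains structures
within ΔAIC ≤ 10 of the best and keeps the five lowest-cost parameter sets
per retained structure; `ensemble_predict()` simulates all members and
reports the pointwise mean as the combined prediction with the pointwise
min–max band, excluding (and logging) members whose integration fails.

## Viable parameter space

`sample_viable_space()` characterises the region where the cost stays below
a threshold in two stages: a flat-acceptance adaptive Metropolis walk (any
proposal below the threshold is accepted; the proposal covariance adapts to
the accepted history) followed by uniform resampling inside ellipsoids
fitted to k-means clusters of the accepted points, with every returned point
verified below the threshold by re-evaluation. This is a simplified,
documented re-implementation of the coarse-global/fine-local idea; it is
**not** a port of any specific toolbox, and its contract is coverage of the
viable region, not sampling from a posterior.

# Feed-composition studies

`scan_feed_asparagine()` scales the asparagine content of the continuous
feed and of the bolus medium jointly (both routes carry asparagine, and the
question being asked — more or less asparagine reaching the culture — does
not distinguish them), simulates the full ensemble per factor, detects the
shift on the ensemble-mean net lactate rate, and reports per-phase lactate
production rates and final titers. Default factors are 0.75 (modest
reduction) and 2.0 (strong elevation) around the unchanged medium.

`detect_lactate_shift()` needs an operational definition that the source
material never prints: here, the shift day is the first day whose
feed-corrected net volumetric lactate rate is negative and stays negative
for at least 48 h. The sustain rule suppresses single-day dips caused by
bolus-and-sampling granularity. With this definition the reference ensemble
gives shift days 5/6/7/9/none for factors 0.5/0.75/1/1.5/2 — monotone in
the factor, with the control at day 7.

One property deliberately **not** asserted at trajectory level: that
reducing `vmax_gly` alone can never delay the shift. At pyruvate
quasi-steady state the net lactate flux sign is governed by
`2·r_gly − r_tca`, and lowering `vmax_gly` also lowers pyruvate and hence
`r_tca`, so the onset time responds non-monotonically (verified numerically
on 10-point grids). The monotone statement that is true — and tested — is
the coupling itself: at any fixed state, net lactate uptake
(`r_up − r_ldh`) strictly increases as `vmax_gly` decreases.

# Numerical choices and degenerate inputs

* ODE integration: `lsoda`, relative/absolute tolerance 1e-7; negative state
  excursions are clipped to zero inside rate evaluation, and trajectories
  are audited to stay above −1e-9 across perturbed parameter sets.
* LP/QP: equality rows are reduced to an independent set by QR with
  pivoting; dropped rows are re-audited on the solution. Infeasibility is
  reported as a status, never silently converted to zeros.
* Outlier screen: centred moving median (5-point windows) with MAD-scaled
  residuals, default threshold 4 robust SDs, replacement by interpolation —
  a rule chosen for 13-point daily series where a failure mode is an
  isolated analytical spike. The threshold and window are arguments.
* LOWESS: `stats::lowess` with one pass and no robustness iterations
  (series are short and already screened), span 0.5 by default, evaluated at
  the observation times.
* Specific rates are computed per sampling interval and assigned to
  interval midpoints; sampling-volume losses are ignored in the balance.
  Samples record the pre-bolus state, so a bolus at a sampling time is
  attributed to the interval that starts there.
* Ties and degenerate inputs: zero measured flux pins the exchange to zero;
  a zero glucose flux yields a missing lactate/glucose ratio; an empty
  reaction table, duplicate ids, unknown metabolites and bound inversions
  are all hard errors.

# Problem sizes used in the shipped tests

The test suite and the acceptance script run at desk scale: 44-reaction
FBA/MFA problems, 20 MFA replicates, 12–14-day simulations at hourly dense
output, calibration budgets of a few hundred to 1500 cost evaluations, and
Morris screening with 6–8 base points. These sizes were chosen so that each
statistical conclusion (recovery tolerances, R² thresholds, shift patterns)
is stable under the fixed seeds used, while a full check of the package
completes in minutes on a single core.

# Known limitations

* The kinetic model omits regulation of specific productivity by lactate or
  osmolality; consequences of strongly elevated feed asparagine on titer are
  outside its competence, and it does not track dead cells, intracellular
  compartments, redox or ATP as dynamic states.
* The reference parameters are plausible, not fitted to any real cell line;
  quantitative conclusions transfer only after calibration to real data.
* The MFA weights, the pooled R² convention, the shift criterion, the
  growth-to-production changeover day and the bolus-attribution convention
  are documented package choices where the method description is silent.
* The viable-space sampler characterises ranges; it makes no claim of
  uniform coverage of strongly non-convex viable sets beyond what the
  ellipsoid stage captures.
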