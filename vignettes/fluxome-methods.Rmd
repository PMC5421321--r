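---
title: "Methods: compartmentalized 13C flux analysis and fermentation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmentalized 13C flux analysis and fermentation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`fluxome` re-implements, as a tested pipeline, the quantitative analyses
behind a substrate/oxygen study of citric-acid production in the oleaginous
yeast *Yarrowia lipolytica*: steady-state 13C metabolic flux analysis (MFA)
of central metabolism on glucose and/or glycerol, batch-fermentation
kinetics, and a two-fold FPKM rule for two-phase RNA-seq comparisons.  This
vignette records the model, the assumptions, and the design decisions that
were genuinely open.

## The metabolic network

The bundled compartmentalized network (`build_yarrowia_network()`) covers
glycolysis, the oxidative and non-oxidative pentose phosphate pathway
(PPP), the TCA cycle, pyruvate transport and pyruvate carboxylase, the
citrate-malate shuttle, ATP:citrate lyase (ACL) as the *only* cytosolic
acetyl-CoA source, a lipid drain from cytosolic acetyl-CoA, and a lumped
biomass drain on ten precursor pools.  PYR, OAA, MAL, CIT and AcCoA exist
as distinct cytosolic and mitochondrial pools; transport steps map carbons
identically.  Glycerol enters via glycerol 3-phosphate and the
membrane-bound G3P dehydrogenase to DHAP.  CO2 is a tracked one-carbon
pool, fed by every decarboxylation, drained to an unlabeled sink and
refixed by pyruvate carboxylase — this is what lets a 1-13C glucose label
reach OAA C4.

Networks are plain-text configs (one reaction per line with its
carbon-atom transition string); `read_network_config()` and
`write_network_config()` round-trip them exactly, and
`validate_carbon_balance()` checks that every mapped reaction moves each
carbon exactly once.

Decisions worth calling out:

* **Atom maps** are the canonical central-carbon maps (aldolase
  FBP(123456) to DHAP(321) + GAP(456); transketolase moves C1–C2 units,
  transaldolase C1–C3 units; both TCA-cycle CO2 losses of the first turn
  derive from OAA).  Succinate and fumarate are rotationally symmetric and
  are scrambled 50/50 on the consuming side of every directed reaction.
* **PFK is a single reversible PFK/FBPase step** in all modes.  On
  glycerol the hexose pool must be made gluconeogenically; splitting the
  pair into two irreversible reactions would add a futile-cycle degree of
  freedom that labeling cannot see.
* **The citrate-malate shuttle is two transport reactions** (citrate
  export; dicarboxylate carrier), not one coupled antiport.  A strict 1:1
  antiport makes the mitochondrial C4–C6 pool set a conserved moiety and
  forces the biomass flux to zero — net anaplerotic malate import is
  required for the mitochondrial AKG drained into biomass.
* **Malic enzyme, the glyoxylate shunt and polyol branches are excluded**
  from the fitted network; the glyoxylate cycle belongs to the
  transcriptome interpretation, not the flux model.
* **Reversibility defaults:** glycolysis (except the kinase steps into and
  out of the pathway), the non-oxidative PPP, fumarase and the malate
  dehydrogenases are reversible; decarboxylations, transports and drains
  are irreversible.
* **Biomass coefficients** are fixed constants from a standard yeast
  biomass equation (mmol per gDCW scale), stored in the config.  They are
  not values from the study; fits are tested to be insensitive to ±20%
  perturbations of them.

## Tracers and substrate EMUs

`bundled_mixture()` encodes the four cultivation recipes: 100% 1-13C
glucose (99 atom-% purity), 20% U-13C6 glucose, 20% U-13C3 glycerol, and
the mixed recipe of 50% U-13C3 glycerol + 20% 1-13C glucose + 30% natural
glucose.  The mixed recipe is interpreted as mass fractions of the total
C-source, partitioned per substrate pool (glycerol pool 50/50 labeled vs
natural; glucose pool 40/60) — the source text does not define the
denominator, so this reading is stated prominently here.  Within a tracer
species, positions are labeled independently: enriched positions carry the
isotopic purity (default 0.99), all others the natural 13C abundance
(default 0.0107).  Only carbon is modeled; 2H/15N/18O and
derivatization-atom corrections are out of scope.

## EMU simulation

`emu_decompose()` traces each measured fragment back to the substrate
inputs, producing the minimal elementary-metabolite-unit system;
`simulate_mdvs()` solves one linear system per EMU size (smallest first),
with condensations entering as discrete convolutions of smaller EMUs and
reversible reactions contributing forward and backward fluxes
(`v_fwd = max(v,0) + exchange`, `v_bwd = max(-v,0) + exchange`).  EMUs are
ordered deterministically (size, then metabolite name, then atom set); the
per-level systems are dense and solved by LU factorization.  A level
system with an unfed EMU (zero inflow) raises an error naming the EMU
rather than returning garbage.

The measured panel is a standard GC-MS proteinogenic amino-acid backbone
set, expressed through precursor pools: Ala (cytosolic pyruvate), Val
(mitochondrial pyruvate, twice), Ser and Gly (3-phosphoglycerate), Thr and
Asp (cytosolic OAA, i.e. the ACL/pyruvate-carboxylase node), Glu
(mitochondrial AKG), Phe (PEP twice + E4P) and secreted citrate.  Because
each fragment is a *full* carbon backbone, its mass distribution depends
only on the multiset of contributing precursor atoms, so amino-acid
synthesis is treated as measurement-only convolution — no back-flux, and
the stoichiometric system stays well-posed.  Compartment assignments
(Ala cytosolic, Val mitochondrial, Asp/Thr cytosolic, Glu mitochondrial)
are the conventional choices and are stated here because they are genuinely
uncertain in yeast.

The simulator is verified, in the test suite, against an independent
brute-force isotopomer solver (full 2^n state enumeration with damped
fixed-point iteration) on five bundled toy networks covering linear
chains, condensation, carbon loss at a branch point, symmetric scrambling
and a condensation-cleavage cycle; agreement is required to 1e-8 and is
observed at machine precision.

## Flux estimation

`fit_fluxes()` minimizes the variance-weighted SSR over the free net
fluxes (chosen so that the PPP entry, pyruvate carboxylase, citrate
secretion and the TCA flux act as coordinates; box [0, 300] normalized
units, reversible free fluxes [-300, 300]) and one exchange flux per
reversible reaction, parameterized as `x/(1-x)` with `x` in [0, 0.995].
All other net fluxes follow affinely from the steady-state balances and
the uptake-equals-100 normalization.  Parallel labeling experiments are
fitted jointly by stacking residuals (per-experiment fitting is a matter
of passing a single experiment).

Numerical choices:

* Levenberg-Marquardt (`minpack.lm`) with finite-difference gradients;
  per start, a first pass fits only the net free fluxes with exchange
  frozen at the start draw, then a joint pass polishes everything.  The
  staged scheme matters: single-stage fits from random starts reliably
  land in exchange-saturated local minima.
* Multistarts are drawn with the feasible-map sampler (uniform free
  fluxes, rejection on irreversibility); the best SSR wins, and the loop
  exits early once an essentially exact fit (SSR < 1e-8) is found.
* Measured MDVs are renormalized to sum 1, which makes the noise
  component along the MDV direction unobservable.  Residuals are
  therefore projected orthogonal to the simulated MDV before weighting,
  which restores the iid error model: the SSR is chi-square with
  (masses - 1) independent values per fragment minus the number of fitted
  parameters.  `goodness_of_fit()` applies the corresponding chi-square
  test, and its rejection rate calibrates to the nominal level in the
  suite (100 seeded fits on a toy network).
* The default measurement sd is 0.004 mol fraction (typical GC-MS
  repeatability), also used as the weighting sd for noise-free synthetic
  tables.

## What the synthetic generators emulate — and what they do not

`random_feasible_fluxmap()` samples steady-state maps with uptake pinned
to 100; `synthetic_mdv_measurements()` adds iid Gaussian noise to the
simulated panel and renormalizes, mimicking normalized GC-MS intensity
vectors; `synthetic_fermentation()` produces the piecewise batch shape of
the cultures (exponential growth at mu until nitrogen limitation, then
linear to a plateau; linear substrate consumption to depletion; citrate
onset after N-limitation, with optional re-consumption after glycerol
depletion, the oxygen-limited dual-substrate phenotype);
`synthetic_expression()` plants log-normal baselines with planted fold
changes and Poisson counting noise.  Default parameters are the
pO2-controlled blend culture (mu 0.22 1/h, glycerol 0.70 and glucose
0.30 g/L/h from 45 g/L each, nitrogen limitation at 15 h, citrate
0.6 g/L/h) and the pO2-controlled expression comparison (3000 genes, 640
up, 290 down, two replicates, 4e6 mapped fragments).  Everything is
deterministic under a fixed seed.

These generators do *not* emulate: metabolic (non-stationary) labeling
transients, correlated GC-MS channel noise or derivatization artifacts,
substrate-dependent growth-rate coupling (substrates decline linearly,
independent of biomass), pH/aeration dynamics, or over-dispersed RNA-seq
counts.  Passing the recovery tests therefore demonstrates correctness of
the estimators under their stated error models, not robustness to every
real-data pathology.

## Expression classification

FPKM is computed by its defining formula; the per-phase value is the
arithmetic mean over replicates (the source protocol used two biological
replicates without stating an aggregation rule).  The significance rule is
the stated two-fold criterion on `log2((FPKM_II + pseudo)/(FPKM_I +
pseudo))` with pseudo = 0.1 FPKM; genes below 1 FPKM in both phases are
"not expressed".  Both constants are package choices, config-overridable,
and not study values.  The FPKM denominator is the per-sample total mapped
fragments carried by the table; when the table covers only part of the
annotation, column sums would confound composition with regulation
(asymmetric planted regulation shifts every fold change), which is why the
generator supplies true depths.  Cufflinks' p-value machinery is
deliberately not reproduced.

## Fermentation analytics

Growth rates are least-squares slopes of log biomass (sliding three-sample
windows for the maximum, by default); consumption rates are negative
concentration slopes over the pre-depletion phase (samples above a
0.05 g/L floor) or a user window; yields are citrate produced over total
substrate consumed, reported at two decimals; limitation onsets are
linearly interpolated threshold crossings.  Phase windows are bounded by
detected limitation onsets where available because the source tables do
not define their phase boundaries.

## Known limitations

* **The glycerol-condition PPP split is not identifiable from U-13C3
  glycerol alone.**  The profile likelihood of the oxidative-PPP entry on
  synthetic U-13C3 data is flat (SSR changes by less than one unit between
  0 and 40% of uptake at sd 0.004), with or without non-oxidative-PPP
  exchange freedom: a uniformly labeled tracer carries no positional
  information, so the C1 loss that marks the oxidative PPP is invisible in
  an amino-acid MDV panel.  The glucose condition is identifiable (and
  recovered within about one percentage point in the suite) precisely
  because 1-13C glucose is positional.  Recovering a glycerol PPP split
  this way would require a positionally labeled glycerol tracer or
  additional measured quantities (e.g. labeled CO2); the package reports
  the fitted value but its glycerol-condition recovery test documents this
  failure mode rather than hiding it.
* Exchange fluxes are, as always in steady-state MFA, only weakly
  determined; point estimates of them should not be interpreted.
* Only carbon-backbone natural abundance is corrected
  (`apply_natural_abundance_correction()`); derivatization Si/H/N/O atoms
  are out of scope.
* Confidence intervals on fluxes (profile likelihood) are not part of the
  supported surface; the chi-square test on the SSR is.

## Problem sizes used by the test suite

The suite exercises the full glucose network (31 reactions, 226 EMUs) for
the recovery and closure checks (20 seeded ground-truth maps, joint
two-tracer fits), toy networks for the oracle-equivalence and calibration
loops (100 seeded fits), and 3000-gene expression tables; these sizes keep
the whole suite in the minutes range on a single CPU while leaving every
code path covered.
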