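---
title: "Two-layer modeling of fermentation metabolism with emkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer modeling of fermentation metabolism with emkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emkin)
```

## The modeling problem

Anaerobic fermenters such as *Clostridium thermocellum* distribute carbon
from a single substrate (cellobiose) over competing terminal pathways —
ethanol, acetate, lactate, formate, hydrogen, amino acids — under tight
redox coupling through the NAD(H), NADP(H) and ferredoxin pools. Two
complementary model layers describe this system:

* a **stoichiometric layer**: the network's mass balance `S v = 0` with
  flux bounds, analyzed by flux balance analysis (FBA), flux variability
  analysis (FVA) and substrate-normalized yield ranges; and
* a **kinetic layer**: an ensemble-modeling (EM) description in which every
  net reaction is decomposed into elementary mass-action steps, parameters
  are sampled so that each ensemble member reproduces a common reference
  steady state exactly, and perturbation data (mutant fermentation yields,
  intracellular pools, Michaelis–Menten constants) select among members.

`emkin` implements both layers plus the machinery that connects them:
genetic-algorithm (GA) selection over the sampled ensemble, leave-one-out
cross-validation, enzyme-level perturbation scans and robustness analysis.
A synthetic-data module generates ground-truth networks and noisy mutant
libraries with the statistical shape of multi-mutant fermentation panels,
so the entire pipeline is testable end to end without any external data.

## Stoichiometric layer

`fba()` and `fva()` solve the usual linear programs over
`S v = 0, lb ≤ v ≤ ub`. The LP engine is a dense bounded-variable two-phase
primal simplex with Bland's rule written for this package: the networks
involved have tens of reactions, where a dense exact method is more robust
than an iterative one, and no LP solver library is part of the package's
dependency footprint. Infinite bounds are truncated at ±1000 mmol/gDW/h
(the conventional big-M flux cap); FVA intervals that hit the cap are
flagged `truncated`. Optimal objective values are deterministic; flux
vectors may be any vertex of the optimal face. Reported fluxes below 1e-6
are rounded to zero; the simplex feasibility tolerance is 1e-9.

### Thermodynamically infeasible cycles

A TIC is a set of reactions that can circulate flux with every exchange
closed, which violates energy conservation. `findTICs()` applies the
definitional test — close all exchanges, run FVA, collect reactions whose
feasible range is still nonzero — then groups participants into connected
components and extracts a circulation direction from a nullspace basis of
the participating submatrix.

Alternate-cofactor isozymes (e.g. NADH- and NADPH-dependent hydrogenases
bridged by a transhydrogenase) form such cycles, but disabling them
outright would be wrong when both isozymes are genuinely active. The
cycle-elimination constraint instead demands, for each cycle's marker
metabolite $i$ (a species unique to the cycle, e.g. hydrogen) and each
cycle reaction $j^\*$,

$$\Bigl|\sum_{j \notin J_i} S_{ij} v_j\Bigr| \;\ge\; |v_{j^\*}|,$$

i.e. no cycle member may carry more flux than the metabolite's net
turnover through non-cycle reactions. With exchanges closed the right-hand
side collapses to zero and the cycle dies; with exchanges open all
isozymes can be active at once. The left absolute value is disjunctive:
`applyCycleConstraint()` solves it exactly by enumerating the sign of each
cycle's non-cycle sum (one binary decision per cycle, so $2^{N_c}$ LPs —
the MILP route), or as a single LP when direction hints pin the sign down.
The "sum of all fluxes involving the metabolite" is interpreted as the
signed stoichiometric sum $\sum_{j \notin J_i} S_{ij} v_j$, matching the
formula rather than a sum of magnitudes. Marker selection is user input;
`suggestCycleMarkers()` proposes, per detected cycle, the shared metabolite
with the fewest appearances outside the cycle.

### Yield ranges

`yieldRange()` fixes substrate uptake at one unit (yields are
scale-invariant under the LP), converts measurement bounds given in
mol/mol into flux bounds, and reports the FVA interval of the product
exchange. No objective fraction is fixed by default — measurements, not an
assumed optimum, constrain the range. An infeasible measurement box is
surfaced as a mass-imbalance diagnostic naming, where identifiable, the
binding measurement.

## Kinetic layer

### Elementary decomposition

`decomposeNetwork()` expands each net reaction into an ordered sequential
mechanism: one binding step per substrate molecule (in declared order,
repeated for stoichiometric coefficients above one), one central
conversion, one release step per product molecule. An A + B ↔ C + D
reaction therefore has 5 steps and 5 enzyme forms; a uni-uni reaction 3.
Reactions with more than four substrate or four product participants are
refused with a hint to lump parallel chemistry first — at core-model scale
nothing legitimate exceeds that. Substrate-level regulation enters as
dead-end binding: competitive inhibitors (and product inhibitors) bind the
free enzyme, uncompetitive inhibitors the fully loaded substrate complex.

### Reference anchoring

All concentrations are nondimensionalized to the reference (wild-type)
state: every metabolite pool and the total enzyme of every reaction equal
1 there, and fluxes are reported as fold of the substrate uptake.
`sampleEnsemble()` draws, per reaction, (i) the distribution of total
enzyme across its forms from a flat simplex and (ii) one reversibility
$R \in (0,1)$ per step, uniformly. Rate constants are then back-computed
so each step's net rate equals the reaction's reference net flux at
reference concentrations: for forward reference flux $v$, the step's
forward and reverse velocities are $v/(1-R)$ and $vR/(1-R)$; for negative
$v$ the roles swap. Dead-end regulatory steps and zero-flux reactions are
anchored at equilibrium with an exchange velocity sampled log-uniformly
over one decade around the reference flux scale, so they remain
perturbable. Anchoring is exact by construction: the reference state is a
steady state of every sampled member, which is what makes mixing members
reaction-wise (the GA's move set) legitimate.

### Steady states

The state vector holds every free metabolite pool and every enzyme form;
rates are bilinear, so the Jacobian is analytic. Conserved totals (enzyme
per reaction, cofactor moieties threading through complexes) make the
Jacobian structurally singular; Newton polishing therefore solves the
stacked system of the rate equations and the conservation relations (the
left nullspace of the step-stoichiometry matrix) in least squares.

`steadyState()` integrates with `deSolve::lsoda` (analytic Jacobian,
rtol 1e-8, atol 1e-12) over expanding horizons up to $10^6$ normalized
time units, stops when the residual max-norm falls below 1e-9, then
polishes with damped Newton. Divergence — a pool exceeding $10^6$ or
falling below $10^{-9}$ while still moving monotonically, or monotone
motion away from reference at the horizon — is reported per species rather
than raised, because that signal is exactly what robustness analysis
consumes. The `"newton"` method tries the polish directly and falls back
to integration; inside fitting loops it is an order of magnitude faster
and agrees with the dynamic route to ~1e-10 on converged cases (asserted
in the tests).

Enzyme levels enter as multiplicative factors on a reaction's total
enzyme: $\tilde e_{tot} = 1$ is the reference, 0 a deletion, bands
$[0.1, 1]$ and $[1, 10]$ encode down- and upregulation of unreported
magnitude, following the convention that unquantified enzyme-level changes
span at most tenfold.

### Derived Michaelis–Menten constants

`deriveKmKcat()` computes the quasi-steady-state saturation curve implied
by the elementary constants (the enzyme-form distribution is linear in the
forms at fixed metabolite concentrations) and reports kcat as the limiting
rate per total enzyme and Km per substrate as the half-saturating
concentration with co-substrates saturating and products absent, in both
directions. Dead-end regulatory steps are excluded so the constants
describe the catalytic chain the way an in-vitro assay would. The balance
system is row-equilibrated before solving because saturating
concentrations spread row magnitudes over ~10 orders; the net rate is
evaluated at the central conversion step, which carries no metabolite
factor and is safe from cancellation.

## Parameterization

The objective is the CV-scaled relative deviation

$$\frac{1}{M}\sum_{m=1}^{M} \frac{1}{N_m} \sum_{i=1}^{N_m}
  \frac{1}{CV_i}\,\frac{|v_i - v_i^{exp}|}{|v_i^{exp}|},$$

averaged within and then across datasets. The absolute value is
deliberate: without it, signed residuals cancel and a badly wrong model
can score well; the signed variant remains available behind
`signed = TRUE` for comparison. Measured values below 1e-9 in magnitude
(numerically silent exchanges) are scored on the CV-scaled absolute
difference and flagged — a relative error against a zero measurement is
undefined. Unreported CVs default to 0.5, a typical fermentation-panel
measurement error.

`gaFit()` encodes an individual as one pool index per reaction — choosing
which ensemble member supplies that reaction's elementary constants — plus
one continuous gene per free enzyme level (a down/upregulated mutant whose
level was not measured), bounded by its band. Selection is binary
tournament, crossover uniform at rate 0.8, mutation per-gene at 0.05,
with one elite individual preserved, so the best objective is monotone
non-increasing by construction. Non-convergent steady states incur a
penalty of $10^3$ per dataset rather than exclusion, keeping fitness
total. Fitness evaluations are memoized per chromosome. The run stops on
the generation budget, 20 stagnant generations (configurable), or an
objective below 1e-12, and then polishes the elite individual by
deterministic coordinate descent (every alternative pool index per
reaction, 1-D refinement of each free level) — a memetic step that
finishes the last few gene flips far faster than waiting for the right
mutations. Because compensating parameter choices at coupled reactions
make the landscape multi-modal, `nStarts` independent restarts (seeds
derived deterministically, fitness cache shared) can be requested; the
best run wins and the reported trace is the best-so-far sequence, still
monotone. Every stochastic entry point takes an explicit
seed and restores the global random state afterwards.

`crossValidate()` refits with one dataset held out (same seed and
configuration per fold for comparability), evaluates the held-out dataset
under the fold fit, and reports the accuracy reduction against the
all-data fit. Free enzyme levels of the held-out genotype that were never
fit are set to the geometric midpoint of their band.

## Perturbation analyses

`scanEnzymeLevel()` walks an enzyme level through a sequence (e.g. an
ammonium-transporter scan in 10% steps to emulate nitrogen limitation),
warm-starting each solve from the previous level's state.
`applyStressProfile()` applies multiplicative enzyme fold-changes and
clamps listed pools as fixed boundary species at scaled values — the two
act on independent model fields, so their order cannot matter. Pool
upscaling given as "increased by 670%" is read as ×7.7 (percent increase);
the plain-multiplier reading is what the API takes directly, so either
interpretation is a one-line change at the call site.
`robustnessScan()` perturbs each enzyme by folds 0.5 and 2 and classifies
each run; a divergent run names the runaway species and the adjacent
non-robust node — the saturated consumer of an accumulating species or the
limiting producer of a depleting one.

## The synthetic ground truth

`generateToyNetwork()` builds a branched fermentation topology: substrate
uptake, a lumped glycolysis producing pyruvate and NADH, competing
terminal branches (ethanol, acetate+formate, lactate, amino-acid families
consuming ammonium and NADPH), two redox pairs bridged by a
transhydrogenase, and two alternate-cofactor hydrogenases that deliberately
close an infeasible cycle with the transhydrogenase (marker: hydrogen).
With 7 branches the network has 30 reactions and 19 measured exchange
metabolites — the shape of a 19-mutant × 19-measurement fermentation
panel; the default genotype panel has 19 mutants concentrated around the
pyruvate node, including two unique-phenotype knockouts (transhydrogenase,
NADH hydrogenase) whose information no other mutant replicates, mirroring
the situation where single mutants carry irreplaceable flux information.
All formulas are synthetic (pseudo-elements `R`/`Q` label cofactor
backbones) and every internal reaction is balanced by construction.

Reference fluxes use seeded branch weights drawn uniformly from
[0.5, 1.5] before normalization to the substrate's pyruvate supply; spare
NADH splits 60/40 between the NADH hydrogenase and the transhydrogenase.
Sampled true kinetics are accepted only if the reference state is
dynamically stable (all Jacobian eigenvalues non-positive up to conserved
modes); unstable draws are discarded deterministically.

`generateMutantLibrary()` simulates each genotype's true steady state and
applies multiplicative lognormal noise with the configured CV (default
0.5, matching a typical ~50% fermentation measurement error;
`sdlog = sqrt(log(1 + cv^2))`, so the noise is unbiased in log space and
has exactly the requested CV). It can also emit one
intracellular-concentration dataset for an amino-acid-pathway knockout
(up to 18 metabolites) and one noisy Km/kcat dataset (up to 10
parameters), completing the three dataset shapes the fitting layer
consumes.

What the generator does *not* emulate: real fermentation data have
correlated errors across metabolites (shared cellobiose-uptake
normalization), secondary mutations, and model-mismatch (the true
in-vivo mechanism is not an ordered elementary chain). Passing the
recovery tests therefore demonstrates that the estimator is consistent
under its own assumptions — identifiability of the pool selection given
the data — not that real panels are fit to the same accuracy.

## Problem sizes and numerical choices

The test and acceptance runs use the 2-branch network (14 reactions) for
fitting studies — 5 mutants, a pool of 4 ensemble members with the truth
injected, GA population 24 over at most 100 generations — and the 7-branch
network for the stoichiometric, shape and perturbation checks. These sizes
give clean convergence of the GA search space (4^14 combinations) within
about a minute while exercising every code path; larger panels scale
linearly in datasets and pool size. Other defaults: simplex feasibility
1e-9, reported-flux rounding 1e-6, steady-state residual 1e-9,
integration horizon 1e6 (1e4 in robustness scans, where divergence is the
point), divergence thresholds 1e6/1e-9 with monotone-trend classification
at the horizon.

## Known limitations

* The cycle-constraint enumeration is exponential in the number of
  simultaneously constrained cycles; fine for core models (a handful of
  cycles), not for genome-scale collections.
* Newton-first steady states may in principle land on an unstable branch;
  the dynamic route is the arbiter and is what the library generator and
  robustness scans use.
* Cross-validation of mutants with free (unfit) enzyme levels evaluates
  them at band midpoints, which biases their held-out deviation upward.
* The GA selects among sampled parameter sets; it does not refine
  continuous elementary constants beyond the free enzyme-level genes.
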