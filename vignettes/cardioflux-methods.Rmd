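---
title: "Methods: flux-minimization analysis of cardiomyocyte substrate utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flux-minimization analysis of cardiomyocyte substrate utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioflux)
```

## The modelling question

Cardiomyocytes meet a continuous ATP demand from whatever mixture of
substrates the coronary blood offers — glucose, lactate, ketone bodies,
acetate and a spectrum of fatty acids. Which mixtures let the cell satisfy
its metabolic targets with the least oxygen and the least total substrate
uptake? `cardioflux` answers this with constraint-based modelling: a
stoichiometric network at steady state, a linear program that minimizes
uptake, a systematic scan over substrate compositions, and a multi-criteria
closeness index to rank the scanned compositions.

## Flux balance with a two-stage flux-minimization objective

A metabolic network with stoichiometric matrix $N$ (metabolites x
reactions) is analysed at steady state, $N v = 0$, with flux bounds
$v_{\min} \le v \le v_{\max}$ in mmol·min⁻¹·(l cell)⁻¹. The demanded
metabolic target is a set of pinned fluxes: at minimum a fixed ATP
hydrolysis rate $v_\mathrm{ATPase}$ (baseline 21.6 mmol·min⁻¹·(l cell)⁻¹,
the contractile plus maintenance expenditure of a working cardiomyocyte),
optionally extended by fixed synthesis rates for membrane lipids and a
minimum NADPH production rate.

Substrate availability enters through the coupling
$v_m = \beta_m \, v_s$, where $v_m$ is the uptake of substrate $m$, $v_s =
\sum_m v_m$ the total substrate uptake, and $\beta$ a point on the unit
simplex ($\sum_m \beta_m = 1$, $0 \le \beta_m \le 1$). The share of a
substrate in the medium dictates its share of total uptake, mirroring
perfused-heart experiments in which measured uptake rates track the
composition of the perfusate.

`minimize_uptake()` solves, for each composition:

* **Stage 1** — minimize $v_s + v_{O_2}$ subject to $N v = 0$, the bounds,
  the pinned targets and the composition coupling.
* **Stage 2** — among the stage-1 optima, minimize $\sum_j |v_j|$
  (reversible fluxes split into nonnegative forward/backward parts), with
  the stage-1 optimum pinned as a constraint with absolute slack $10^{-7}$.

Stage order was a genuinely open design choice: the printed optimization is
the uptake minimization, while the flux-minimization principle asks for a
parsimonious total flux. We made the lexicographic order explicit — uptake
first, total flux as a tiebreak — because the uptake sum is the quantity
the efficiency analysis consumes, and the tiebreak only selects among
degenerate stage-1 optima. `minimize_total_flux = FALSE` disables stage 2.

Solver choices: the LP backend is a two-phase dense primal simplex with
Bland's anti-cycling rule (`lp_solve()`), adequate and fully deterministic
at the problem sizes this package targets (tens to a few hundred columns).
Feasibility and optimality tolerances are $10^{-9}$; every returned
distribution satisfies $\max |N v| \le 10^{-6}$ (asserted in tests).
Unbounded problems signal a missing bound; fluxes without explicit bounds
are capped at ±1000 mmol·min⁻¹·(l cell)⁻¹, the conventional cap of
constraint-based modelling toolboxes.

## The generated core network

`build_core_network()` produces a lumped "cardiomyocyte core" model so that
every downstream method is exercisable on a fully specified fixture. Per
substrate it contains an uptake exchange and a single lumped oxidation
reaction

$$ \text{substrate} + s_{O_2} \cdot O_2 + y \cdot ADP \rightarrow y \cdot ATP $$

with $y$ the ATP yield per mole fully oxidized and $s_{O_2}$ the oxygen
stoichiometry of complete combustion of the molecular formula (CO₂ and
water are boundary species and not balanced). The default yield table
(`default_yield_table()`) uses the standard beta-oxidation bookkeeping for
the six fatty acids — 120 (palmitate), 136 (stearate), 134 (oleate),
132 (alpha-linoleate), 142 (EPA), 156 (DHA) mol ATP — and combustion
oxygen 23, 26, 25.5, 24.5, 26.5 and 29 mol O₂. Glucose is taken at 36
ATP / 6 O₂ (glycerophosphate-shuttle convention), lactate at 17 / 3,
acetoacetate at 22 / 4 and acetate at 9 / 2. These non-fatty-acid yields
are conventions chosen so that the baseline demand reproduces the uptake
rates reported for perfused hearts (21.6/36 = 0.60 for sole glucose,
6·0.60 = 3.60 oxygen; sole oleate 21.6/134 with 25.5 O₂ per mole gives
4.11); published tables disagree at the third decimal between their own
panels for lactate (total uptake 1.2701 vs 1.17), which we document rather
than resolve — our 17 ATP convention gives 1.2706.

Because the oxidation reactions are lumped, sole-substrate scenarios have
closed forms that serve as oracles: $v_s = \text{demand} / \sum_m \beta_m
y_m$ and $v_{O_2} = v_s \sum_m \beta_m s_{O_2,m}$. The test suite checks
these identities on a thousand random compositions.

Optional components:

* **Glycogen store** (`include_glycogen`). The store is a boundary pool:
  `glycogenolysis` is a capped endogenous glucose source (default cap 0.9
  mmol·min⁻¹·(l cell)⁻¹, just above the maximal observed cardiac glycogen
  synthesis rate of ~0.887 so that behaviour is representable) and
  `glycogen_synthesis` an ATP-costing sink (default 2 ATP per glucosyl
  unit: hexokinase plus UDP-glucose activation). Treating the store as a
  boundary pool rather than a mass-balanced intermediate lets the model
  show *net* storage (excess mandated glucose is parked) and *net*
  mobilization (endogenous glucose substitutes for uptake) at steady
  state, the behaviour reported for working hearts. A consequence worth
  knowing: under pure uptake minimization the capped endogenous source is
  drawn before external carbon whenever it is energy-limiting, which is
  exactly why glycogenolysis is carried as its own efficiency criterion
  (below) rather than suppressed in the LP.
* **Lipid targets** (`include_lipid_targets`). Five drains — ceramide,
  cardiolipin, phosphatidylcholine, phosphatidylethanolamine,
  sphingomyelin — each consume a recipe of acyl units from a generic pool
  (fed by any `lipid_usable` substrate) plus named alpha-linoleate and DHA
  units and an ATP activation cost. Because the named units can only come
  from uptake, alpha-linoleate and DHA are *essential*: any composition
  with a zero share of either is infeasible once lipid targets are
  demanded. The recipes and the default target rates (0.001–0.005
  mmol·min⁻¹·(l cell)⁻¹) are synthetic placeholders of realistic
  magnitude — real acyl-composition measurements can be supplied through
  `core_options(lipid_recipes = ...)` and `target_fluxes`. A
  triglyceride-storage sink absorbs acyl units mandated by the
  composition coupling beyond what the targets consume.
* **NADPH branch** (`include_nadph`). A lumped oxidative
  pentose-phosphate reaction (12 NADPH per glucosyl unit from the glucose
  pool) and a drain with a minimum flux, default 1.42e-5
  mmol·min⁻¹·(l cell)⁻¹ — the basal cardiomyocyte NADPH production rate.
  Glucose-free media remain feasible through the capped glycogenolysis
  route.

What the generator does *not* emulate: pathway-resolved glycolysis, TCA
cycle and beta-oxidation (so intracellular flux patterns, P/O-ratio
effects and anaerobic ATP production are outside its reach), compartmental
transport, the carnitine shuttle, and amino-acid metabolism. Tests passing
on this fixture demonstrate the correctness of the *methods* — the LP, the
scanner, the ranking, the alternate-optima procedure — not the biology of
any genome-scale reconstruction; user-supplied SBML models are first-class
inputs for the real thing.

## Scanning the composition simplex

`enumerate_compositions(n_s, step)` generates every lattice point
$(a_1/k, \dots, a_{n_s}/k)$, $\sum a_i = k = 1/\text{step}$, in
lexicographic order — $\binom{k+n_s-1}{n_s-1}$ points; four substrates at
step 0.01 give $\binom{103}{3} = 176{,}851$ compositions. `run_scan()`
solves one flux minimization per composition, records oxygen demand, total
substrate uptake, glycogenolysis and glycogen synthesis per row, keeps
infeasible rows with their status, and checkpoints to TSV every 1000 rows
so long scans resume deterministically. For nine substrates no uniform
step reproduces published non-uniform grids (shares like 0.0167 suggest
twelfths of 0.2); the scanner therefore accepts explicit composition
matrices, and the default step for exploratory nine-substrate scans is
0.05.

## Efficiency index

For criteria that are all costs (oxygen demand $v_{O_2}$, total substrate
uptake $v_s$, glycogenolysis $v_{GL}$), the per-criterion ideal $q^+_j$ is
the column minimum over the scanned cohort and the anti-ideal $q^-_j$ the
maximum. With Euclidean distances $S^+_i$, $S^-_i$ of row $i$ to the ideal
and anti-ideal points, the efficiency index is the TOPSIS closeness
coefficient

$$ C^+_i = \frac{S^-_i}{S^+_i + S^-_i} \in [0, 1], $$

computed on **raw units** — no prior normalization. This was validated
empirically: recomputing the published four-substrate indices from the raw
(oxygen, uptake) pairs matches the printed values to 3–4 decimals
(glucose 0.6577 vs 0.6576, oleate 0.6850 vs 0.6849, lactate 0.2089 vs
0.2091), whereas normalized variants do not. One printed value
(acetoacetate 0.2791) reproduces only to ~0.002 (we obtain 0.280, stably);
we attribute this to rounding of the published inputs and do not chase the
third decimal. Classic vector normalization is available behind
`normalize = TRUE`. The index is cohort-relative: rescoring a subset moves
the ideals and every $C^+$ value, which is intended and tested. Criteria
are unweighted by design; benefit criteria are unsupported.

Degenerate case: if a row has $S^+ + S^- = 0$ (all criteria constant
across the cohort) its index is defined as 1 with a warning.

## Alternate optima and flux uniqueness

Linear programs over degenerate polytopes admit multiple optima.
`enumerate_alternates()` probes them flux by flux: each reaction carrying
flux in the original optimum $v_0$ is pinned, one at a time, to $1.01 v_0$
and $0.99 v_0$ (as an added equality constraint, so that perturbing a
pinned target flux is infeasible by construction) and the problem is
re-solved. Perturbed solutions matching the original objective within a
relative $10^{-6}$ are alternates; fluxes infeasible in both directions
are *dependent* on the target function. Zero fluxes are skipped —
rescaling zero is no perturbation; the published procedure is silent on
them. Per-flux sample variance is computed over the original plus all
retained alternates; the share of zero-variance fluxes is the uniqueness
fraction, and every flux reported unique is cross-checked against a
zero-width `flux_range()` at the optimum. A one-way ANOVA across
distributions (groups = distributions, observations = per-reaction
fluxes) summarizes whether alternates differ from the original; with zero
within-group variance and differing means the F statistic is reported as
infinite with a warning rather than silently capped.

## Units

All rates are mmol·min⁻¹·(l cell)⁻¹. Experimental rates quoted per cell
convert through the cylinder volume $V = \frac{\pi}{4} d^2 l$;
`cardiomyocyte_volume(14, 140)` = 2.16e-11 l with the standard human
cardiomyocyte dimensions. Volumes are displayed at 3 significant figures
and fluxes at 4 decimals; full precision is retained internally.

## Problem sizes and determinism

The shipped analyses are deliberately desk-scale: the core network has 22
reactions (38 with all options), scans in the examples and tests use steps
of 0.2–0.25 (10–35 compositions), and the property tests run a thousand
random compositions — the full test suite completes in well under a
minute. Published results that depend on a 1793-reaction reconstruction
and its constraint files (nine-substrate scan values, basal NADPH split
across isoenzymes, the 90.70% uniqueness figure) are not reproducible from
the printed record and are explicitly out of scope; the package reproduces
the *method* and the desk-scale quantities (yield recovery, sole-substrate
uptake rates, efficiency indices of the printed criteria tables) exactly
or to the stated tolerances.

Everything is deterministic: the generator emits byte-identical JSON for
equal inputs, scans are sequential with a fixed row order, and the simplex
solver uses Bland's rule, so repeated runs agree bit for bit.

## Known limitations

* The simplex backend is dense and unsuited to genome-scale models
  (thousands of reactions); it is honest about this and targets the
  desk-scale networks the package generates or small user SBML models.
* The SBML reader covers the constraint-based core subset (species,
  reactions, stoichiometries, boundary conditions, fbc or COBRA-style
  bounds); kinetic laws, rules and events are ignored with a log message.
* Lumped oxidation hides intracellular flux structure; alternate-optima
  analyses on the core fixture probe method behaviour, not cardiomyocyte
  pathway redundancy.
* The glycogen boundary-pool convention makes `v_GL`/`v_GS` interpretable
  as net mobilization/storage, but a strictly mass-balanced storage cycle
  (synthesis = degradation at steady state) is not representable at
  nonzero net rates.
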