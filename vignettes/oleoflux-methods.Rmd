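---
title: "Constraint-based analysis of lipid accumulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of lipid accumulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleoflux)
```

# The problem

Oleaginous yeasts such as *Yarrowia lipolytica* accumulate neutral lipid
(triacylglycerol, TAG) to well over 20 % of their dry weight, but only
under nutrient limitations that arrest growth — typically nitrogen
starvation. In that state the cells keep importing glucose, and the carbon
that the lipid-synthesis machinery cannot absorb overflows as excreted
citrate, because cytosolic acetyl-CoA for fatty acids is produced from
citrate by ATP:citrate lyase (Acl). Lipid yield and citrate yield
therefore compete for the same intermediate. `oleoflux` implements the
constraint-based machinery needed to quantify this competition on a
genome-scale metabolic model (GSM) and to derive fermentation strategies —
a fed-batch feed rate that starves the overflow, and an aeration level
that arrests growth before it slows lipid synthesis.

# Flux balance analysis and its resolution

All analyses reduce to linear programs over the flux polytope
$\{v : S v = 0,\ lb \le v \le ub\}$. Reversibility is encoded purely by
the bounds; exchange reactions are written `species ->`, so uptake is a
negative flux, while every user-facing function takes and reports uptake
magnitudes as positive numbers. Flux couplings (used for maintenance, see
below) add homogeneous rows $v_t - r\,v_s = 0$ to $S$ rather than
rewriting bounds, so they remain valid under any objective.

**Alternate optima.** FBA objective values are unique but flux vectors
are usually degenerate. Whenever fluxes are reported (scan reporters,
Acl/PPP rates, NADPH production), the package fixes the objective at its
optimum and minimises total absolute flux (parsimonious FBA via a
$v = p - q$ split). Headline objective values are degeneracy-free either
way.

**Solver.** The LP kernel is a dense bounded-variable two-phase revised
simplex (`src/simplex.cpp`): signed artificial variables in phase 1 (so
rank-deficient steady-state systems are handled), Dantzig pricing with a
Bland fallback after long degenerate streaks, eta-updates of the basis
inverse with periodic refactorisation, and a re-verification refactor
before optimality is declared. Tolerances: reduced costs and pivots at
$10^{-9}$; the API contract asserts $\|S v\|_\infty \le 10^{-6}$ on every
optimal solution and the test suite checks it throughout. Bounds are
finite by construction (the conventional $\pm 1000$ mmol gDW$^{-1}$
h$^{-1}$ stands for "unconstrained"); infinite user input is clamped to
$\pm 10^6$.

**The independent oracle.** `enumerate_vertices()` recomputes optima by
brute force: a vertex of the bounded polytope is a basic solution, so
enumerating all rank-sized column subsets and all lower/upper assignments
of the nonbasic variables visits every vertex. FBA maxima and FVA ranges
(after augmenting the system with the fraction-of-optimum constraint and a
slack column) follow by taking extrema over vertices. This is exact,
shares no code with the simplex, and is tractable for the synthetic
models' handful of degrees of freedom; the test suite demands agreement to
$10^{-8}$ across a battery of more than 50 generated networks.

# Maintenance energy, split in two

Because lipogenesis is modelled at zero growth, a biomass-embedded
maintenance term alone would vanish exactly when it matters. Maintenance
ATP is therefore split:

* **GAM** (growth-associated, default 17.05 mmol ATP per gDW) is
  hydrolysed inside the biomass equation and scales with growth;
* **NGAM** (non-growth-associated) is a separate ATP-hydrolysis flux
  coupled to carbon uptake with a substrate-specific ratio — 5.0 mmol ATP
  per mmol glucose, 2.28 per mmol glycerol in the reference
  parameterisation — so energy is still dissipated when $\mu = 0$.

The coupling is an equality, matching the arithmetic one expects (uptake
4.0 at ratio 5.0 gives an NGAM flux of exactly 20). Increasing either term
can never increase growth; this is asserted as a property test.

# Variable-lipid biomass equations

`biomass_spec()` / `build_biomass()` construct biomass pseudo-reactions
parameterised by the neutral-lipid mass fraction $f \in [0.004, 0.80]$.
TAG is a lumped pseudo-species (glycerol backbone + three acyl chains from
a mole-fraction profile, minus three waters); its coefficient delivers
exactly $f$ grams per gDW, and all non-lipid components are rescaled by
$(1-f)/(1-f_\mathrm{ref})$. This simultaneously reduces the protein
fraction as lipid rises, keeps the relative amounts of the non-lipid
components constant, and preserves the 1 g/gDW total (checked to 0.5 %
for every $f$ in the series). The default four-species acyl profile
(C16:0, C16:1, C18:1, C18:2) is a placeholder for experimentally
determined phase- and substrate-specific compositions, which users should
supply when available. Two reference presets matter in practice: the
exponential-phase lipid content (0.4 %) and the measured validation
content (1.3 % TAG); the package exposes `reference_f` explicitly rather
than guessing which applies. For GSMs whose biomass composition lives in
the model file, `rescale_biomass_lipid()` performs the same surgery on
the existing equation, reading the reference fraction off the current TAG
coefficient.

A `cofactors` field carries the redox/energy bookkeeping of biosynthesis
— the net NADH released while polymerising the non-lipid fraction — scaled
with the non-lipid components and excluded from the mass balance. It
exists because growth is the oxygen-hungry process: anabolism from
glucose releases reducing equivalents (the respiratory quotient of growth
exceeds one), whereas TAG synthesis consumes NADPH that the oxidative PPP
supplies without respiration.

# Dynamic FBA

`simulate_batch()` is static-optimization dynamic FBA: at each step the
uptake bound of every tracked exchange is the smaller of its kinetic cap
and what the remaining pool can supply over `dt`; an FBA solve yields
$\mu$ and the exchange fluxes; biomass is updated exponentially
($X \leftarrow X e^{\mu\,dt}$) and concentrations with the exact
exponential weight $X(e^{\mu dt}-1)/\mu$, with last-step partial uptake so
concentrations never go negative. Uptake kinetics are a hard cap — no
Michaelis–Menten term — because the only kinetic input the analyses use is
the measured uptake rate. Molecular weights come from metabolite formulas,
with glucose (180.16) and glycerol (92.09 g/mol) as fallbacks.

A consequence worth knowing: for a single substrate under a binding cap
the LP response is piecewise constant and the integrator is *exact* — the
endpoint does not depend on `dt` at all. Step-size error, first order in
`dt`, appears when several substrate bounds interact; the convergence test
uses a glucose + citrate co-consumption batch for that reason. Default
`dt` is 0.1 h.

# Scenario analyses

* **Lipogenesis optimum** (`lipogenesis_fba`): growth pinned at the
  measured (zero) rate, glucose uptake fixed at the starved-phase
  measurement (0.35 mmol gDW$^{-1}$ h$^{-1}$), citrate excretion fixed
  either as mol per mol glucose (0.55, the measured overflow) or as an
  absolute flux — both entry modes exist because measured excretion can be
  reported either way. The TAG demand is maximised and Acl, PPP entry,
  NADPH and acetyl-CoA production rates are reported from the
  parsimonious solution.
* **Feed calculation** (`compute_feed_uptake`): with the citrate exchange
  closed and growth at zero, the minimal uptake sustaining the
  lipogenesis-phase lipid flux is found by maximising the (negative)
  substrate exchange flux under a lipid lower bound. `feed_schedule()`
  converts the result into a pump rate (dimensional identity:
  rate = uptake × biomass × MW / feed concentration).
* **Lipid-content scans** (`lipid_content_scan`): either fixed uptake with
  growth maximisation, or fixed growth with uptake minimisation, across an
  $f$ grid; records $\mu$/uptake, O$_2$ uptake, CO$_2$ output, respiratory
  quotient, Acl flux and NADPH production.
* **Oxygen thresholds** (`robustness_scan` + `o2_thresholds`): the O$_2$
  uptake bound is scanned on a 0.25 mmol gDW$^{-1}$ h$^{-1}$ grid and each
  response's threshold is the largest bound at which it has dropped below
  99 % of its unconstrained value — a fixed operational criterion, since
  round thresholds reported for such scans rarely state one. Growth
  should starve before lipid synthesis does; on the synthetic model at the
  growth-phase uptake the thresholds come out 6 (growth) versus 5 (lipid).
  Anaerobically the model predicts pyruvate excretion, which the scan
  exposes through reporter fluxes.
* **NADPH sources** (`restrict_nadph_source`, `nadph_yield_comparison`):
  every reaction able to net-produce NADPH is found from the
  stoichiometry; restricting to one named source bounds the producing
  directions of all others to zero (original bounds kept for exact
  inversion). Yields are reported relative to the PPP baseline. Source
  sets are identifier patterns, editable per model, because reaction
  naming differs across reconstructions.
* **Theoretical yields** (`theoretical_yield`): product maximisation at
  zero growth, optionally without NGAM, uptake fixed at 1 mmol — the
  optimum is the mol/mol yield, converted to g/g via formula weights, with
  a `percent_of_theoretical` closure for observed yields.
* **Substrate screen** (`substrate_screen`): each candidate carbon source
  is opened in turn on an otherwise minimal medium (free inorganic
  exchanges only); predicted growth is $\mu > 10^{-6}$ h$^{-1}$ — a
  numerically robust cutoff — and the report carries the confusion matrix
  and accuracy against observed growth calls.
* **Gene deletions** (`single_gene_deletions`): GPR rules are re-evaluated
  with each gene false; reactions whose rule fails are closed. The
  essentiality cutoff is a wild-type-relative growth ratio below 0.01 — a
  conservative choice stated in the report, since no standard exists.

# The synthetic core model

`build_toy_model()` emits a deterministic, carbon-balanced caricature of
oleaginous central metabolism (22 reactions in the default configuration):
glucose exchange and transport, a redox-neutral glycolytic lump, an
oxidative PPP cycle (12 NADPH per glucose), citrate synthesis
(glucose → citrate + 2 ATP + 3 NADH), Acl, fatty-acid synthesis (C16 from
8 acetyl-CoA, 14 NADPH, 7 ATP), TAG assembly, full pyruvate oxidation,
oxidative phosphorylation with a tunable P/O ratio plus a
non-phosphorylating alternative oxidase (AOX — *Y. lipolytica* really has
one; it decouples NADH reoxidation from ATP synthesis so the respiratory
ATP yield is an upper bound), citrate/pyruvate exporters, the
variable-lipid biomass drain, the coupled ATPM maintenance reaction and an
explicit futile ATP cycle (genome-scale networks can always dissipate
surplus ATP through substrate cycles; a lumped model must provide the
valve explicitly, since the NGAM coupling pins ATPM itself). All carbon
metabolites carry real elemental formulas and every enzymatic reaction is
carbon-balanced; hydrogen, oxygen, phosphate and water are deliberately
not tracked in the lumps, so balance validation defaults to carbon.

Stoichiometry is never randomised: a `seed` only permutes identifier
order, to catch order-dependence bugs. The generation manifest records
what was emitted and carries optima computed by the enumeration oracle at
build time, never typed in.

What the toy reproduces about oleaginous physiology: the citrate-overflow
split at the lipogenesis optimum, the reduction of the required uptake
when the overflow is closed (28 mmol glucose per mmol TAG with the PPP as
NADPH source — a number you can derive by hand from the lumped
stoichiometry), the growth-before-lipid oxygen-starvation order, the
PPP-versus-transhydrogenase yield ranking, and anaerobic pyruvate
overflow. What it does not reproduce: the magnitudes of a genome-scale
reconstruction (growth rates, absolute O$_2$ rates), the monotone decline
of O$_2$ uptake with lipid fraction (which needs the full
amino-acid-synthesis oxygen demand), isoenzyme redundancy beyond the one
planted pair, and any nitrogen bookkeeping — nitrogen limitation enters
only as the growth-arrest constraint. Passing tests on the toy therefore
validate the *machinery* (LP correctness, couplings, biomass
construction, scan logic), not genome-scale numbers; those are checked
separately when the iMK735 SBML is supplied.

# Numerical choices and degenerate inputs

* Feasibility/optimality $10^{-9}$ at the solver, $10^{-6}$ at the API.
* Missing SBML bounds default to $(-1000, 1000)$ for reversible and
  $(0, 1000)$ for irreversible reactions, with a message.
* Infeasible scan points are recorded with their status and scans
  continue; infeasible FBA never raises, it returns a status.
* Elemental-balance validation of network edits is advisory
  (`balance = "warn"`/`"none"`) for reconstructions with incomplete
  formula annotation, and strict by default.
* Ties in the simplex ratio test prefer the larger pivot; a degenerate
  streak switches pricing to Bland's rule, guaranteeing termination.
* Zero-consumption trajectories and empty substrate lists are errors, not
  NaNs.

# Problem sizes used by the test suite

The property battery runs the full oracle comparison on 52 generated
models of 13–22 reactions (larger configurations are exercised against
the simplex only), FVA on every reaction of each, a 49-point oxygen grid
for thresholds and four-point lipid grids for monotonicity — sizes chosen
so the exhaustive oracle stays exact and the whole suite runs in a couple
of minutes on a laptop core. The genome-scale acceptance checks
(1336-reaction iMK735) run in seconds per solve with the dense simplex.

# Known limitations

* SBML support targets the COBRA Level-2 dialect (kinetic-law bound
  parameters, note-encoded gene rules); Level-3/FBC-only features are out
  of scope.
* No MILP extensions (loopless FBA, MOMA/ROOM) and no quadratic
  objectives.
* The dense simplex is comfortable at the 10^3-reaction scale but is not
  meant for models an order of magnitude larger.
* dFBA models no pH, oxygen-transfer or stirring dynamics; aeration acts
  only through the O$_2$ uptake bound.
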