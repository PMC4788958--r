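---
title: "Horizontal integration of kinetic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Horizontal integration of kinetic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kimerge)
```

## The problem

Signal-transduction biology is modeled one pathway at a time, and the
resulting kinetic ODE models accumulate in repositories such as the
BioModels Database. Answering questions that span pathways means combining
two such models into one. When the models share formalism and scale
("horizontal" integration), the task splits into two distinct problems:

1. **Structural integration** — find the *overlap* (species, reactions,
   parameters, compartments present in both models) and build a merged
   network in which every element appears exactly once.
2. **Behavioral integration** — choose parameter values for the merged
   model so that it still explains the data each original model explained.

The second problem is the subtle one. For every overlap element two
parameterizations exist, one per source model, and whichever is chosen, the
merged model will typically reproduce that source's behavior and *not* the
other's. `kimerge` implements the full semi-automatic workflow: prepare
(validate, harmonize units), match (annotation-based, with manual
post-editing), merge (under an explicit parameter-source policy), test
consistency, and reparameterize a minimal, goal-compatible set of
parameters.

## Element identity

Database annotations alone under-identify signaling species: "ERK
phosphorylated on T188" and "ERK phosphorylated on Y190" carry the same
UniProt URI. `kimerge` therefore fingerprints every element by three
ingredients (`extract_identity()`):

* the set of MIRIAM RDF resource URIs,
* the SBO term, and
* a *structured name* parsed from the display name.

The naming convention (`parse_name_record()`) is: base name, then
underscore-separated modification tokens (type letters + residue and
position, e.g. `ERK_pT188`), complex components joined by `:` with `×n`
counts (e.g. `STAT5×2_pY694`), and an optional compartment tag after `@`.
The exact convention the original workflow used is not published in
machine-readable form, so this one — chosen to capture precisely the
modification-site failure case — is isolated behind the `name_record`
parser and can be swapped.

Equality of identities (`identity_equal()`) is deterministic, symmetric and
reflexive:

* When **both** sides carry URIs, URI-set equality is necessary. Display
  names may then be aliases (`ERK` vs `ERK2`), but must not *contradict*
  the identity: differing modification sets or differing complex
  composition veto the match.
* When **either** side lacks URIs, the structured name is the sole
  criterion.
* Compartment tags are excluded from equality; species that agree except
  for the compartment are matched and flagged `different-compartment`
  downstream.
* SBO terms, when present on both sides, must not disagree.

## Matching and conflicts

`auto_match()` computes the initial matching purely from these identities,
class by class. Reactions are matched structurally: all
reactant/product/modifier species must match pairwise with equal
stoichiometries. Kinetic parameters rarely carry database annotations, so
they are matched positionally through their owning reactions. Matching is a
partial one-to-one map; an element with several equally good candidates is
*never* silently resolved — it stays unmatched and is flagged
`annotation-name-disagreement` for manual post-editing (`apply_edits()`
supports `add-match`, `remove-match`, `confirm-match`, `flag-match`).

`classify_conflicts()` annotates the result with the recurring challenge
cases: `modification-site` and `different-state` (URI-equal species whose
names differ in modifications), `different-compartment`,
`different-kinetics` (matched reactions whose laws are not symbolically
equivalent after id translation and canonical reordering of commutative
operands — no numerical equivalence probing), and `modifier-vs-reactant`
(same products, a species switching role). `level-of-detail` (a reaction
chain lumped on one side) is deliberately never auto-assigned: recognizing
it requires biological judgment, so it can only be attached manually.

## Merging

`merge_models()` keeps model A's ids for the overlap, copies both models'
exclusive parts unchanged, and applies a `merge_policy()` to the overlap:
one default source (A or B) for kinetic parameters *and* initial amounts,
with per-element overrides. Matched entries still flagged
`different-kinetics` or `modifier-vs-reactant` block the merge until a
per-element decision is supplied — inventing a rate law automatically would
be fabrication. Species matched across different compartments or states are
kept as both species; adding a transport or interconversion reaction is the
user's decision, since no kinetics for it exist in either model. Counts are
conserved: `|merged| = |A| + |B| − |matches|` per element class, and the
merged model must pass `validate_model()`.

## Consistency

Consistency is judged through input/output relations. Writing `ů_A` for a
step input applied to model A's inputs and `v̈_A` for the corresponding
outputs, the merged model is simulated with `(ů_A, 0)` — model B's inputs
silenced — and its A-originating outputs compared with `v̈_A`; likewise with
roles swapped. The comparison statistic is the χ² merit function per data
point,

$$\frac{\chi^2}{N} \;=\; \frac{1}{N}\sum_{i=1}^{N}
  \left(\frac{y_i - y(t_i;\,p)}{\sigma_i}\right)^{2},$$

pooled per side over all of that side's datasets, outputs and time points.
The merged model is **consistent** iff χ²_A/N_A < 1 *and* χ²_B/N_B < 1
(strict). An `integration_goal()` declares target relations on the two
values — e.g. preserve side A exactly (strict-below-one) and bring side B
to approximately one (≤ 1.05 by default; the tolerance is configurable
because "approximately" is not quantified anywhere authoritative).

When the original experimental data are unavailable, each original model's
own simulations are reinterpreted as synthetic data
(`make_synthetic_dataset()`): the central values are the simulated outputs
(no noise is added), and the standard deviation is the sum of a 10 %
relative term and an absolute term of 5 % of the per-curve maximum,
σᵢ = 0.10·|yᵢ| + 0.05·maxₜ|y(t)|. Design notes:

* The two σ terms are **added**, not combined in quadrature — the plainest
  reading of the error model, and the one that gives round values such as
  σ = 1.5 for yᵢ = 10 on a curve with maximum 10.
* The 5 % term uses the **per-curve** maximum (per-dataset would couple
  unrelated outputs' error scales).
* Identically zero curves get a floored σ (10⁻⁶ × the largest curve
  maximum in the dataset, or 1 if all curves are silent) to keep χ² finite,
  with a warning.
* N pools per side: every (dataset, output, time point) triple of that
  side counts once.
* Outputs exclusive to the *silent* side are excluded from a check (they
  are unconstrained "?" components); shared outputs count for the side
  whose input is active.

## Reparameterization

If the merged model is inconsistent, parameters must be re-estimated — but
as few as possible, and none that the integration goal forbids.
`candidate_free_parameters()` returns exactly the quantities whose
perturbation *cannot* change the preserved side's outputs under that side's
isolated inputs: kinetic parameters appearing only in the non-preserved
model's exclusive reactions, initial amounts of its exclusive (non-input)
species, and scaling factors of outputs exclusive to it. Overlap parameters
and preserved-side parameters are excluded; freeing a *shared* output's
scaling factor is allowed only as an explicit user choice, because it
trades preserved-side exactness for fit quality.

`fit_parameters()` minimizes the pooled χ² over all datasets simultaneously
(one parameter vector, per-dataset inputs) with a hand-rolled
Levenberg–Marquardt iteration on **log-transformed** parameters — all
fitted quantities are positive rates, amounts or scales — with
forward-difference Jacobians, bound clipping (default bounds
value/1000 … value×1000), and multi-start: the current values plus
log-uniform draws within the bounds, deterministic given the recorded
`seed`. No environment-provided least-squares package was available, and
the reference tooling for this kind of multi-experiment fitting publishes
no optimizer settings, so printed post-refit statistics are matched as
stochastic outcomes, not bit-exact ones.

## Simulation engine

Kinetic laws are parsed from content MathML into R expressions, compiled to
a small stack-machine bytecode, and integrated in C++ (`src/ode.cpp`).
Two integrators are provided:

* `dopri5` (default): the Dormand–Prince 5(4) embedded pair with adaptive
  step control. At this model scale (tens of states, rate constants up to
  ~10 s⁻¹) its stability-bounded steps are cheap, and its high order keeps
  the global error far below the synthetic-data σ.
* `rosenbrock`: a linearly implicit Rosenbrock 2(3) method
  (Shampine–Reichelt coefficients) with finite-difference Jacobians and LU
  solves, for genuinely stiff systems. Because the controlled solution is
  second-order, its per-step tolerances are internally tightened ×100 so
  the global error stays comparable to the default path.

Default tolerances are rtol = 10⁻⁸, atol = 10⁻¹⁰: pre-refit χ²/N values of
interest reach down to ~10⁻⁴, so integration error must sit several orders
below the data error. Step stimuli are implemented as initial amounts of
boundary+constant input species — `input_signal()` applies the assignments
and sets every *unassigned* input species to zero, which is what "(ů_A, 0)"
means operationally. There are no events, dosing schedules, or time-varying
inputs; SBML constructs outside the plain-ODE subset (events, rules,
constraints, initial assignments, time delays) are rejected at load time by
name rather than silently ignored.

Both integrators are cross-checked in the test suite against closed forms,
conservation laws, each other, and an independent fixed-step RK4 oracle
that evaluates the kinetic laws by plain R `eval()` — a second code path
sharing nothing with the bytecode compiler.

## What the synthetic fixtures emulate

`generate_toy_pair()` builds the canonical two-branch topology: each model
owns a step-input species and an exclusive upstream chain (only the first
transition is stimulus-driven; downstream chain species start empty, so the
branch is provably silent at zero input), both feeding a shared linear
cascade — the planted overlap, with identical annotations and names in both
models and model B's overlap rate constants equal to model A's times a
`divergence` factor. Rate constants are log-uniform in [10⁻³, 10¹] s⁻¹ and
initial amounts uniform in [0.1, 10], reproducible from the seed. The
observables are the *consumed* cascade species: their quasi-steady-state
levels scale as flux/k and are therefore sensitive to the overlap
parameters, whereas the terminal species merely integrates the flux and
would hide the divergence.

`synthetic_case_study_pair()` is a deterministic, hand-parameterized pair
with the published case study's *shape* — 11 reactions and 11 species per
model, an overlap of 4 reactions and 5 species (a downstream
phosphorylation cascade with conserved pools), one exclusive receptor
output per model and two shared outputs, divergence 10 between the two
overlap parameterizations. It is labelled synthetic everywhere: it stands
in for the BioModels accession files (BIOMD0000000262/263), which cannot be
redistributed and are not downloadable in the build environment.
`build_case_study()` consumes local copies of the real files when present
and otherwise fails with an explicit "accession files required" error. Its
upstream kinetics were chosen slower than the overlap kinetics so that,
as in the published example, output dynamics are driven by the (refittable)
upstream branch and steady-state gains through the cascade are
compensable from the exclusive side — the constants were fixed once, at
design time, from this timescale argument.

What a green test on these fixtures does establish: the matching recovers
planted overlaps exactly; merging conserves counts and policy fidelity;
the consistency statistic exposes the A/B asymmetry and the refit machinery
repairs it. What it does not establish: agreement with the printed
case-study χ² values (0.0004/1689.3 pre-refit; 0.289/0.899/0.594 and the
failed 2.291 attempt post-refit), which depend on the real models, real
stimulus series and the original study's time grid — none of which are
printed in usable form. With local accession files, the structural claims
(11/11 elements, 4+5 overlap, 18/17 merged) and the consistency *verdicts*
are the reproducible surface; the stand-in reproduces the full qualitative
pattern (pre-refit ~10⁻¹⁶ vs ~300; post-refit both sides < 1 with the
minimal free set; restricted upstream-only fit stuck > 1).

## Numerical and degenerate-input choices

* Simulation grids must start at 0 (step stimuli are applied at t = 0) and
  increase strictly.
* χ² evaluation refuses mismatched grids or missing output labels rather
  than interpolating silently.
* A fitted quantity whose current value is 0 (e.g. an empty downstream
  pool) gets default bounds [10⁻⁹, 10³] instead of the multiplicative
  window, since log-scaling around 0 is undefined.
* Kinetic-law equivalence canonicalizes commutative operands by
  deparse-sorting; `k*S` and `S*k` are equivalent, `k*S` and `k*S*S` are
  not. Non-equivalent forms that are algebraically equal (e.g. distributed
  products) are conservatively flagged for a human decision.
* Merged-model id collisions among unmatched elements are resolved by
  suffixing `_B`; overlap elements keep model A's ids, and the provenance
  map records every element's origin.
* Workflow iteration: refit/check cycles repeat up to `max_iterations`
  (default 3) — the workflow literature says iterations "may be necessary"
  without bounding them.

## Known limitations

* No CellML/BioPAX import, no database lookups, no hierarchical (SBML
  comp) composition, no automatic lumped-vs-detailed chain resolution —
  these are out of scope by design.
* Parameters are matched only through matched reactions; annotated global
  parameters shared across unmatched reactions stay unmatched.
* The unit harmonizer converts quantities whose declared units resolve to
  substance/time/volume dimensions; parameters without declared units are
  left untouched (and logged), which is the honest default for models that
  omit them.
* The Rosenbrock method uses dense finite-difference Jacobians — adequate
  for tens of states, wasteful beyond.
* `simulate_model()` is the operation named "simulate" in the workflow
  description; the R generic `stats::simulate` has an incompatible
  signature, so the package uses the explicit name.
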