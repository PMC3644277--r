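---
title: "Computing all minimal nutrient sets: models, solver, and enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing all minimal nutrient sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minnut)
```

## The problem

Given a metabolic network — a set R of stoichiometric reactions, an ordered
set T of *transportable* metabolites the organism can import, and a set B of
*biomass* compounds that must be produced for growth — which subsets N of T
support growth? A *minimal nutrient set* is a nutrient set no proper subset
of which still supports growth; the full collection of minimal nutrient sets
is a complete, assumption-free answer to "what media could this organism
grow on?", in contrast to strategies that vary one element source at a time
from a seed medium and therefore presuppose that element sources substitute
independently. minnut computes that collection exhaustively, compresses it
losslessly into nutrient equivalence classes, and scores it against
phenotype-microarray growth calls.

## The two growth models

Let M be the stoichiometric matrix (rows compounds, columns reactions,
entries net production) and r the vector of reaction rates (fluxes), so
p = M r is the vector of net production rates. Fix a putative nutrient set
N and let A = N plus the model's auxiliary compounds (always-available
prerequisites; see below).

**Steady state.** N is a steady-state nutrient set when some r satisfies

* r_j >= 0 for every unidirectional reaction (reversible reactions keep a
  sign-unconstrained variable, or may be split into a non-negative pair);
* p_i > 0 for biomass compounds i not in A;
* p_i >= 0 for all other compounds i not in A;
* no constraint for i in A.

Note the inequality p >= 0 rather than the flux-balance convention M r = 0:
over-production of a by-product is allowed, which removes the need for
curated dummy export reactions when a compound has no consumer.

**Machinery duplication.** A population of dividing cells must duplicate the
metabolic intermediates its active pathways use, otherwise division dilutes
them away; a solution that merely cycles a fixed pool of an intermediate is
not sustainable growth. For every compound i outside A and B that is
mentioned by at least one reaction, the machinery-duplicating model
therefore adds the disjunctive clause

    p_i > 0   OR   r_j = 0 for every reaction j mentioning i.

The conjunction of such clauses with the steady-state constraints is a
monotone Boolean combination of linear atoms — no longer a linear program.
A "use it" variant scopes the clause to reactions consuming i as a
reactant; for unidirectional systems the two scopes decide the same nutrient
sets, and the package defaults to the symmetric "mention" scope with
sign-free reversible variables (one variable per reversible reaction), which
is also the form its clause printer produces. Both scopes and both
direction encodings are available and are checked against each other in the
test suite over every nutrient subset of seeded random models.

Every machinery-satisfiable N is steady-satisfiable (the machinery system
only adds constraints). The two-reaction worked example `example1_model()`
(A+B -> C+D, C+F -> B+E, biomass E) separates the models: {A, F} runs the
internal B/C cycle at steady state, but cannot duplicate the cycle's own
carriers, so machinery growth requires seeding the cycle, e.g. {A, B, F}.

## Exact satisfiability

All decisions are made in exact rational arithmetic; no floating-point
value ever influences a truth value. Rationals are reduced
numerator/denominator pairs of doubles, with a guard that aborts rather
than exceed the 2^53 exact-integer range (never observed at the problem
sizes below; reduced simplex tableau entries are ratios of small
subdeterminants).

* **Linear cores** are decided by phase-1 simplex with Bland's rule on an
  exact rational tableau, so termination is unconditional. Every system
  here is homogeneous (all right-hand sides zero), so the feasible set is a
  cone and each strict atom `p > 0` can be decided as `p >= 1`: any point
  of the open cone scales onto that slab. Witnesses are basic solutions,
  returned as exact fractions and re-verified against every clause before
  being released.
* **Disjunctive systems** use one of two backends. The default,
  `"iterative"`, exploits a structural fact about machinery-type systems:
  the solution set is closed under addition. (If r and r' are solutions,
  consider a clause for compound i in the sum: any mentioning reaction
  active in r + r' is active in r or in r', whose clause then forces that
  solution's p_i > 0, and the other solution contributes p_i >= 0 by its
  steady constraints — so the sum satisfies the clause.) The backend
  therefore alternates two steps: if some clause's positive branch
  p_i >= 1 is unachievable even under the relaxed conjunctive system
  (strict atoms weakened to >=, reactions already forced off pinned to
  zero), then *every* solution must take the clause's zero branch, and its
  mentioning reactions are pinned; when every remaining clause's positive
  branch is individually achievable, the per-clause witnesses plus a
  biomass witness sum to a solution of the full disjunctive system. The
  relaxation only ever over-approximates the solution set, so pinning is
  sound, and the pinned set grows monotonically, so the loop terminates.
* The `"branch"` backend is generic DPLL-style case splitting, guided by
  the relaxation's witness: it only branches on clauses the current
  witness violates, and accepts as soon as a witness satisfies every
  remaining clause. It exists for systems without the machinery clause
  shape and as an independent cross-check; the tests assert both backends
  agree on every subset of random models.

The rejected alternative of enforcing `p_j >= alpha * s_j` with a fudge
factor alpha is not implemented: any fixed alpha can wrongly exclude
feasible fluxes, and the exact disjunctive treatment makes it unnecessary.

## Enumerating all minimal nutrient sets

`nutset(N)` — satisfiability of the system built for N — is monotone:
adding a nutrient only removes constraints. Minimal nutrient sets are
exactly the *prime implicants* of this monotone Boolean function, and they
are found by evaluation only, with no assumption about the oracle's inner
structure:

1. If the full set T fails, the collection is empty. Otherwise *minimize*
   the all-true vector: sweep components left to right in T's order,
   flipping each true component to false whenever the oracle stays true.
   The sweep provably lands on a prime implicant, deterministically.
2. Keep a *choice function* g: the conjunction, over known primes v, of
   the disjunction of v's true variables. Any vector sharing a true
   component with every known prime is a choice vector (an implicant of
   g); a new prime exists if and only if some choice vector u has
   nutset(not u) true, and then minimal choice vectors suffice.
3. g lives in a reduced ordered BDD with variable order fixed to T's
   listed order (determinism is valued over node count; there is no
   dynamic reordering). The BDD for pi_g — the prime implicants of g,
   i.e. the minimal choice vectors — is built by standard restrict /
   negate / conjoin operations: pi_g(x) = g(x) AND, for each variable i,
   (NOT x_i OR NOT g(x with x_i := false)).
4. Satisfying assignments of pi_g are traced depth-first, false branch
   first; variables a path skips are expanded to both values with false
   preferred. (For pi_g of a monotone function no variable can be skipped,
   but the traversal handles don't-cares anyway rather than relying on
   that argument.) The first candidate u with nutset(not u) true yields
   the next prime by minimization; g is updated and the search restarts.
   When no candidate survives, the collection is complete.

The oracle memoizes every distinct subset queried and counts evaluations —
the oracle is the cost centre, and the pipeline manifest reports the count.
`brute_force_minimal_sets()` (all 2^|T| subsets, guarded to |T| <= 16) is
kept as the reference implementation; the test suite asserts exact
agreement with the BDD-driven loop on both growth models across 100 seeded
random models, and `limit` permits truncated runs on models too large to
finish.

## Simplification

Two reductions shrink a model without changing any nutset value, applied on
the split-unidirectional form, alternating to a joint fixed point, after
which surviving complementary pairs are merged back:

* **Impossible** compounds — not potential nutrients (transportable or
  auxiliary) and produced by no reaction — are deleted with every reaction
  mentioning them; deletions can expose further impossible compounds, so
  the removal iterates.
* **Useless** compounds — no downstream path to biomass, computed as the
  complement of the least fixed point of "biomass is useful; reactants of
  reactions with a useful product are useful" — are struck from reaction
  sides, and reactions whose whole product side was struck are deleted. A
  reaction may survive unbalanced: losing a dead-end product merely drops a
  redundant non-negativity constraint.

A biomass compound flagged impossible is a hard error naming the compound
(the model cannot grow under any medium and likely has a gap).
Transportables are never removed from T, and auxiliaries stay in the
compound table, even when unused — the enumeration indexes Boolean vectors
by T's order, which must survive simplification. Invariance of the oracle
under simplification is tested exhaustively (every subset, both modes) on
random models.

## Equivalence classes and lossless compression

Compounds c1, c2 are equivalent with respect to a collection when each can
substitute for the other in every set where it occurs (the result staying
in the collection). The relation is an equivalence; the implementation
verifies transitivity on every computed partition and would fail loudly on
a violation. Rewriting every set over class representatives and removing
duplicates yields the reduced collection; expansion (all substitutions of
class members for representatives) regenerates the source exactly, so the
compression loses nothing — a property the tests assert literally on every
enumerated collection. The reduced count is invariant under which
representative is chosen; representatives default to the lexicographically
smallest member id (a deterministic stand-in for "the most familiar
compound"), overridable by a preference list. Per-class element annotations
(which of C/N/P/S members contain) are computed from formulas when present
and are annotation only.

## Instantiation of generic reactions

Generic reactions mention compound classes (broad-specificity enzymes). Each
class slot is substituted independently with every instance; a combination
is kept only when the resulting equation balances elementally (hydrogen
included; charge is out of scope, being a curation-time protonation
concern), and a slot whose class has several instances with the same
formula is ambiguous — combinations through those instances are skipped, as
the formula cannot tell the intended substrate apart. Accepted reactions
get traceable ids `<generic>/<instances>`; classes with no instances drop
their reaction with a report entry. Per-slot independence also covers
classes appearing on both sides: the balance filter discards mismatched
pairings, which resolves the co-variation question without extra ontology.

## Evaluating predictions

A phenotype-microarray record is a tested nutrient set with a growth /
no-growth / low-growth call. A predicted set matches a well when it equals
or is a proper subset of the well's set — a prediction may source several
elements from one compound, making an explicit supplement redundant.
Growth+match is a true positive, growth without match a false negative,
no-growth without match a true negative, no-growth with match a false
positive; low-growth calls are inconclusive upstream labels and are
excluded (the package never re-derives them from respiration curves).
Accuracy is reported as an exact fraction. Name reconciliation between PM
tables and model ids goes through an explicit synonym map; there is no
fuzzy matching, since a silent mismatch would corrupt the confusion matrix.

## Auxiliary compounds

Models may declare auxiliaries: prerequisites (e.g. macromolecular
carriers) that the network does not synthesize. They are treated as
unconditionally available — exempt from production constraints in every
query, exactly like nutrients — but are never candidate nutrients and never
enter equivalence classes. Modelling them as free inputs (rather than via
pseudo-reactions) is this package's choice; it matches their description as
non-synthesized prerequisites and keeps T clean.

## The synthetic-data generator

`random_model()` emulates the input shapes of a curated network: a compound
pool, a designated transportable prefix and biomass suffix, and reactions
with small integer stoichiometry and a configurable reversible fraction.
One linear pathway from some transportable to each biomass compound is
planted so that the full nutrient pool is always steady-feasible;
machinery feasibility is deliberately *not* guaranteed, so draws populate
both sides of the gap between the models. Defaults (8 compounds, 7
reactions, |T| = 4, one biomass compound, reversible fraction 0.25,
coefficients <= 2) are sized so that the exhaustive 2^|T| brute-force
reference remains cheap; the acceptance checks run 100 such models per
sweep and every subset of each. What passing these tests shows is exact
agreement between the enumeration machinery and its definition on networks
of that character; it does not certify behaviour on genome-scale networks
(thousands of reactions, |T| about a hundred), whose runtimes are dominated
by oracle calls and whose BDDs can grow large. The `limit` argument and the
oracle-call counters are the operational tools for that regime.

## Numerical and design notes

* Stoichiometric coefficients are integers in the canonical formats;
  rational coefficients are accepted on read and cleared per reaction by
  uniform rescaling (a change of flux units — feasibility is unaffected).
* Compartment tags, if any, are opaque id suffixes; no compartment
  semantics are modelled.
* Empty biomass means the empty set is the unique minimal nutrient set;
  a constant-false oracle yields the empty collection. Both degenerate
  cases are tested.
* Discovery order of minimal sets is deterministic given T's order (BDD
  variable order, false-first path tracing, left-to-right minimization);
  collections are order-normalized (size, then lexicographic) before
  comparison and serialization.
* The oracle exposes cache and call counters rather than solver push/pop;
  memoization across the subset lattice is the reuse mechanism, and
  correctness never depends on it.
* No objective function exists anywhere: every question is pure
  feasibility.

## Limitations

Negative effects — toxicity, regulation, competition, quorum signalling —
are deliberately outside the model, which is exactly why nutset is monotone
and the enumeration applies; consequently predictions over-approximate
growth (false positives possible, false negatives impossible under
complete-reactions/required-biomass assumptions on the inputs). Relative
nutrient concentrations are not predicted. FBA-style `M r = 0` analysis
with an objective is out of scope, as is any random sampling or
seed-and-vary search of media space — exhaustiveness is the point.
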