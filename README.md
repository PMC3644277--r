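# minnut — exhaustive minimal nutrient set prediction from metabolic networks

Given an organism's metabolic network — a set **R** of stoichiometric
reactions, an ordered set **T** of transportable metabolites (potential
nutrients, inferred from its transporter complement), and a set **B** of
biomass compounds that must be produced for growth — `minnut` computes **all
minimal nutrient sets**: the subsets N ⊆ T from which B is producible, such
that no proper subset still suffices. It is aimed at researchers asking "what
media could this organism grow on?" from genome-derived models, where
seed-and-vary strategies (swap the carbon source, keep the rest) silently
assume that element sources substitute independently — an assumption that is
easy to violate and that exhaustive enumeration does not need.

## The model and the algorithm

With stoichiometric matrix M and flux vector r, net production is p = M r.
For a putative nutrient set N (plus declared auxiliary compounds), the
**steady-state** growth definition asks for fluxes with

- r_j ≥ 0 for unidirectional reactions (reversible fluxes are sign-free),
- p_i > 0 for biomass compounds outside N,
- p_i ≥ 0 for every other compound outside N.

The **machinery-duplicating** definition — the default — additionally demands
that dividing cells replicate the intermediates their active pathways use:
for every non-nutrient, non-biomass compound i mentioned by some reaction,

```
p_i > 0   ∨   ( r_j = 0 for every reaction j mentioning i )
```

This disjunction of linear constraints is beyond linear programming; `minnut`
decides such systems **exactly** (rational arithmetic end to end, witnesses
re-verified symbolically) with a specialised iterative procedure plus a
case-splitting fallback, both built on an exact phase-1 simplex.

`nutset(N)` is monotone — adding a nutrient only removes constraints — so the
minimal nutrient sets are precisely the **prime implicants** of a monotone
Boolean oracle. They are enumerated by the minimize / choice-vector / BDD
loop: minimization of the all-true vector yields the first prime implicant;
a binary decision diagram over the found primes exposes the minimal choice
vectors, exactly the places a new prime implicant can hide; the loop stops
when none of them works, which certifies completeness. The collection is then
compressed **losslessly** into nutrient equivalence classes (compounds
mutually substitutable across the whole collection) plus a reduced collection
of canonical sets, and can be scored against phenotype-microarray growth
calls (exact/subset matching, TP/TN/FP/FN and exact-fraction accuracy).

## A worked example

The two-reaction network `A+B → C+D`, `C+F → B+E` with biomass `{E}`
separates the two growth definitions:

```r
library(minnut)
m <- example1_model()
stoich_matrix(m)
#>   R1 R2
#> A -1  0
#> B -1  1
#> C  1 -1
#> D  1  0
#> E  0  1
#> F  0 -1

nutset(m, c("A", "F"), "steady")     #> TRUE
nutset(m, c("A", "F"), "machinery")  #> FALSE
```

At steady state `{A, F}` works: the internal B/C cycle turns over (r1 = r2),
consuming A and F and producing E. But a growing, dividing population must
also make *more* B and C, and the clauses printed by

```r
build_constraints(m, c("A", "F"), "machinery")
#> <constraint_system> mode=machinery, 2 flux variables (0 free), 7 clauses
#>  B: -R1+R2 >= 0
#>  B: -R1+R2 > 0 | R1 = 0 & R2 = 0
#>  C: R1-R2 >= 0
#>  C: R1-R2 > 0 | R1 = 0 & R2 = 0
#>  D: R1 >= 0
#>  D: R1 > 0 | R1 = 0
#>  E: R2 > 0
```

force r1 = r2 (rows B, C) while demanding strictly more C than is consumed —
a contradiction, hence no growth. Seeding the cycle fixes it, and the
enumeration finds exactly one machinery-minimal set:

```r
enumerate_minimal_nutrient_sets(m, "machinery")
#> <prime_implicant_set> 1 minimal nutrient set(s), mode=machinery, oracle calls: 4
#>   {A, B, F}

is_satisfiable(build_constraints(m, c("A", "B", "F"), "machinery"),
               witness = TRUE)$witness
#> $R1  "3"
#> $R2  "1"
```

(r1 = 3, r2 = 1 nets two C, three D and one E per unit time — exact
rationals, verified against every clause.) The cross-feeding fixture
`crossfeed_model()` (C1+N1 → M, C2+N2 → M) shows why exhaustiveness matters:
its minimal sets are `{C1, N1}` and `{C2, N2}`, all four equivalence classes
are singletons, and a seed-and-vary search from `{C1, N1}` would test
`{C1, N2}`, find it dead, and wrongly conclude N2 is never a nitrogen source.

A shell interface mirrors the library (`exec/minnut`):

```sh
minnut enumerate model.json --mode machinery -o sets.json
minnut classes sets.json -o classes.json
minnut check model.json --nutrients A,B,F --witness
minnut pipeline run.cfg          # load → instantiate → simplify → enumerate
                                 # → classes → reduce → evaluate, + manifest
```

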