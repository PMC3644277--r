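# Constraint construction and exact satisfiability of the two growth models.

test_that("steady constraints for the worked example match the derivation", {
  m <- example1_model()
  sys <- build_constraints(m, c("A", "F"), mode = "steady")
  rendered <- vapply(sys$clauses, format_clause, "")
  names(rendered) <- sys$provenance
  expect_identical(rendered[["B"]], "-R1+R2 >= 0")
  expect_identical(rendered[["C"]], "R1-R2 >= 0")
  expect_identical(rendered[["D"]], "R1 >= 0")
  expect_identical(rendered[["E"]], "R2 > 0")
  expect_false(any(sys$vars$free))
})

test_that("machinery clauses for B, C, D take the published disjunctive form", {
  m <- example1_model()
  sys <- build_constraints(m, c("A", "F"), mode = "machinery")
  rendered <- split(vapply(sys$clauses, format_clause, ""), sys$provenance)
  expect_true("-R1+R2 > 0 | R1 = 0 & R2 = 0" %in% rendered[["B"]])
  expect_true("R1-R2 > 0 | R1 = 0 & R2 = 0" %in% rendered[["C"]])
  expect_true("R1 > 0 | R1 = 0" %in% rendered[["D"]])
  # biomass keeps its strict constraint, no machinery clause
  expect_identical(unname(rendered[["E"]]), "R2 > 0")
  # nutrients A, F are exempt entirely
  expect_false("A" %in% sys$provenance)
  expect_false("F" %in% sys$provenance)
})

test_that("{A,F} grows at steady state but not under machinery duplication", {
  m <- example1_model()
  st <- is_satisfiable(build_constraints(m, c("A", "F"), "steady"),
                       witness = TRUE)
  expect_true(st$satisfiable)
  # the published flux r1 = r2 = 1 satisfies the system
  expect_true(verify_witness(build_constraints(m, c("A", "F"), "steady"),
                             c(R1 = 1, R2 = 1)))
  mach <- build_constraints(m, c("A", "F"), "machinery")
  expect_false(is_satisfiable(mach)$satisfiable)
  expect_false(is_satisfiable(mach, method = "branch")$satisfiable)
  # seeding the internal cycle restores machinery growth: r1=2, r2=1
  sys_b <- build_constraints(m, c("A", "B", "F"), "machinery")
  expect_true(is_satisfiable(sys_b)$satisfiable)
  expect_true(verify_witness(sys_b, c(R1 = 2, R2 = 1)))
  expect_true(nutset(m, c("A", "F"), "steady"))
  expect_false(nutset(m, c("A", "F"), "machinery"))
  expect_true(nutset(m, c("A", "B", "F"), "machinery"))
})

test_that("degenerate systems behave as defined", {
  m <- example1_model()
  expect_error(build_constraints(m, "Z", "steady"), "outside T")
  # all compounds exempt and no biomass: only sign constraints remain
  m2 <- metabolic_model(
    compounds = lapply(c("A", "B"), compound),
    reactions = list(parse_reaction_equation("R", "A -> B")),
    transportables = c("A", "B"), biomass = character())
  sys <- build_constraints(m2, c("A", "B"), "machinery")
  expect_length(sys$clauses, 0)
  ans <- is_satisfiable(sys, witness = TRUE)
  expect_true(ans$satisfiable)
  expect_identical(unname(unlist(ans$witness)), "0")
})

test_that("witnesses re-verify exactly and bad fluxes are rejected", {
  m <- example1_model()
  sys <- build_constraints(m, c("A", "B", "F"), "machinery")
  ans <- is_satisfiable(sys, witness = TRUE)
  expect_true(ans$satisfiable)
  expect_true(verify_witness(sys, ans$witness_rational))
  expect_false(verify_witness(sys, c(R1 = 1, R2 = 1)))  # violates C's clause
  expect_false(verify_witness(sys, c(R1 = -1, R2 = -2)))  # sign constraint
})

test_that("nutset is monotone and machinery implies steady", {
  for (seed in c(1, 4, 7)) {
    m <- small_random_model(seed, reversible_fraction = 0.3)
    tset <- m$transportables
    orc_m <- nutset_oracle(m, "machinery")
    orc_s <- nutset_oracle(m, "steady")
    asg <- all_assignments(length(tset))
    for (v in asg) {
      fm <- orc_m$f(v)
      fs <- orc_s$f(v)
      expect_true(!fm || fs, info = paste("Lemma-1, seed", seed))
      # monotone: supersets by one element
      for (i in which(!v)) {
        v2 <- v
        v2[i] <- TRUE
        expect_true(!fm || orc_m$f(v2))
        expect_true(!fs || orc_s$f(v2))
      }
    }
  }
})

test_that("the split and free-variable encodings decide nutset identically", {
  for (seed in c(3, 6, 8)) {
    m <- small_random_model(seed, reversible_fraction = 0.5)
    has_rev <- any(vapply(m$reactions, `[[`, TRUE, "reversible"))
    tset <- m$transportables
    for (v in all_assignments(length(tset))) {
      N <- tset[v]
      a <- nutset(m, N, "machinery", direction = "free-variable",
                  machinery_scope = "mention")
      b <- nutset(m, N, "machinery", direction = "split-unidirectional",
                  machinery_scope = "use")
      expect_identical(a, b,
                       info = paste("seed", seed, "reversible:", has_rev,
                                    "N:", paste(N, collapse = ",")))
    }
  }
})

test_that("the iterative and branching backends agree", {
  for (seed in c(2, 10)) {
    m <- small_random_model(seed, reversible_fraction = 0.3)
    tset <- m$transportables
    for (v in all_assignments(length(tset))) {
      sys <- build_constraints(m, tset[v], "machinery")
      expect_identical(is_satisfiable(sys, method = "iterative")$satisfiable,
                       is_satisfiable(sys, method = "branch")$satisfiable)
    }
  }
})

test_that("constraint systems export to SMT-LIB 2", {
  m <- example1_model()
  sys <- build_constraints(m, c("A", "F"), "machinery")
  lines <- export_smtlib(sys)
  expect_identical(lines[1], "(set-logic QF_LRA)")
  expect_identical(lines[length(lines)], "(check-sat)")
  expect_true(any(grepl("declare-const R1 Real", lines, fixed = TRUE)))
  expect_true(any(grepl("(or ", lines, fixed = TRUE)))
})
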