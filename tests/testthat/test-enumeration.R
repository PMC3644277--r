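# Prime-implicant enumeration of the growth oracle.

test_that("minimization follows the left-to-right single-pass contract", {
  f <- tt_oracle(list(c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE)))
  expect_identical(minimize_implicant(f, rep(TRUE, 3)),
                   c(FALSE, FALSE, TRUE))
  expect_identical(minimize_implicant(function(v) TRUE, rep(TRUE, 3)),
                   rep(FALSE, 3))
  all_true_only <- function(v) all(v)
  expect_identical(minimize_implicant(all_true_only, rep(TRUE, 3)),
                   rep(TRUE, 3))
  expect_error(minimize_implicant(function(v) FALSE, rep(TRUE, 3)),
               "f\\(v\\) = TRUE")
  # the result is always a prime implicant (Theorem-level property)
  set.seed(7)
  for (k in 1:10) {
    mins <- lapply(1:3, function(i) {
      v <- logical(4)
      v[sample(4, sample(1:3, 1))] <- TRUE
      v
    })
    f2 <- tt_oracle(mins)
    out <- minimize_implicant(f2, rep(TRUE, 4))
    expect_true(is_prime_implicant(f2, out))
  }
})

test_that("choice-function updates match truth-table minimal choice vectors", {
  n <- 3
  # primes {100, 010}: minimal choice vectors must pick one true from each
  m <- bdd_manager(n)
  g <- update_choice_function(m, bdd_const(m, TRUE),
                              c(TRUE, FALSE, FALSE))
  g <- update_choice_function(m, g, c(FALSE, TRUE, FALSE))
  choice_oracle <- function(v) v[1] && v[2]
  pig <- prime_implicant_bdd(m, g)
  mins <- tt_minimal_true(choice_oracle, n)
  expect_identical(mins, list(c(TRUE, TRUE, FALSE)))
  for (v in all_assignments(n)) {
    expect_identical(bdd_eval(m, g, v), choice_oracle(v))
    expect_identical(bdd_eval(m, pig, v),
                     any(vapply(mins, function(u) identical(u, v), TRUE)))
  }
  # single prime (1,1,0): minimal choice vectors {100, 010}
  m2 <- bdd_manager(n)
  g2 <- update_choice_function(m2, bdd_const(m2, TRUE),
                               c(TRUE, TRUE, FALSE))
  pig2 <- prime_implicant_bdd(m2, g2)
  mins2 <- tt_minimal_true(function(v) v[1] || v[2], n)
  for (v in all_assignments(n)) {
    expect_identical(bdd_eval(m2, pig2, v),
                     any(vapply(mins2, function(u) identical(u, v), TRUE)))
  }
  # zero primes: g constant true, pi_g's sole implicant is all-false
  m3 <- bdd_manager(n)
  pig3 <- prime_implicant_bdd(m3, bdd_const(m3, TRUE))
  for (v in all_assignments(n)) {
    expect_identical(bdd_eval(m3, pig3, v), !any(v))
  }
})

test_that("the worked examples enumerate to their known minimal sets", {
  m <- example1_model()
  mach <- enumerate_minimal_nutrient_sets(m, "machinery")
  expect_same_collection(mach$sets, list(c("A", "B", "F")))
  expect_true(mach$complete)
  st <- enumerate_minimal_nutrient_sets(m, "steady")
  expect_same_collection(st$sets, list(c("A", "F")))
  cf <- crossfeed_model()
  for (mode in c("steady", "machinery")) {
    r <- enumerate_minimal_nutrient_sets(cf, mode)
    expect_same_collection(r$sets, list(c("C1", "N1"), c("C2", "N2")))
  }
})

test_that("brute force handles degenerate oracles", {
  # no biomass: the empty set is the unique minimal nutrient set
  m <- metabolic_model(
    compounds = lapply(c("A", "B"), compound),
    reactions = list(parse_reaction_equation("R", "A -> B")),
    transportables = "A", biomass = character())
  bf <- brute_force_minimal_sets(m, "steady")
  expect_identical(bf$sets, list(character(0)))
  en <- enumerate_minimal_nutrient_sets(m, "steady")
  expect_same_collection(en$sets, list(character(0)))
  # unsatisfiable even on full T: empty result
  m2 <- metabolic_model(
    compounds = lapply(c("A", "E"), compound),
    reactions = list(),
    transportables = "A", biomass = "E")
  expect_length(brute_force_minimal_sets(m2, "machinery")$sets, 0)
  expect_length(enumerate_minimal_nutrient_sets(m2, "machinery")$sets, 0)
  big <- example1_model()
  big$transportables <- sprintf("T%02d", 1:17)  # guard only; not validated
  expect_error(brute_force_minimal_sets(big, "steady"), "refused")
})

test_that("BDD enumeration equals brute force on random models", {
  for (seed in 11:22) {
    m <- small_random_model(seed, reversible_fraction = 0.25)
    for (mode in c("steady", "machinery")) {
      orc <- nutset_oracle(m, mode)
      bf <- brute_force_minimal_sets(m, mode, oracle = orc)
      en <- enumerate_minimal_nutrient_sets(m, mode, oracle = orc)
      expect_same_collection(bf$sets, en$sets)
    }
  }
})

test_that("every emitted vector is a verified prime implicant, pairwise incomparable", {
  for (seed in c(13, 17)) {
    m <- small_random_model(seed)
    for (mode in c("steady", "machinery")) {
      orc <- nutset_oracle(m, mode)
      en <- enumerate_minimal_nutrient_sets(m, mode, oracle = orc)
      vs <- en$vectors
      for (v in vs) expect_true(is_prime_implicant(orc$f, v))
      if (length(vs) > 1) {
        for (a in seq_along(vs)) {
          for (b in seq_along(vs)) {
            if (a != b) expect_false(all(vs[[a]] <= vs[[b]]))
          }
        }
      }
      # monotone closure spot check: the union of any two results grows
      if (length(vs) >= 2) {
        expect_true(orc$f(vs[[1]] | vs[[2]]))
      }
    }
  }
})

test_that("each machinery minimal set contains a steady minimal set", {
  for (seed in c(14, 19)) {
    m <- small_random_model(seed)
    mach <- enumerate_minimal_nutrient_sets(m, "machinery")
    st <- enumerate_minimal_nutrient_sets(m, "steady")
    for (v in mach$vectors) {
      expect_true(any(vapply(st$vectors, function(u) all(u <= v), TRUE)))
    }
  }
})

test_that("the limit flag truncates and flags incompleteness", {
  cf <- crossfeed_model()
  r <- enumerate_minimal_nutrient_sets(cf, "machinery", limit = 1)
  expect_length(r$sets, 1)
  expect_false(r$complete)
})

test_that("discovery order is deterministic", {
  cf <- crossfeed_model()
  a <- enumerate_minimal_nutrient_sets(cf, "machinery")
  b <- enumerate_minimal_nutrient_sets(cf, "machinery")
  expect_identical(a$sets, b$sets)
})
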