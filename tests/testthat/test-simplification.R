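# Impossible/Useless compound removal and the joint fixed point.

test_that("impossible compounds cascade through reaction deletion", {
  # X (not transportable) has no producer; deleting X -> Y leaves Y
  # producerless, so Y goes on the next iteration
  m <- metabolic_model(
    compounds = lapply(c("A", "B", "C", "D", "E", "F", "X", "Y"), compound),
    reactions = list(parse_reaction_equation("R1", "A + B -> C + D"),
                     parse_reaction_equation("R2", "C + F -> B + E"),
                     parse_reaction_equation("R3", "X -> Y")),
    transportables = c("A", "F"), biomass = "E")
  out <- remove_impossible(m)
  expect_setequal(out$trace$removed_impossible, c("X", "Y"))
  expect_identical(out$trace$deleted_reactions, "R3")
  expect_false("X" %in% names(out$model$compounds))
  expect_true(out$trace$iterations >= 2L)
})

test_that("the worked example is already impossible-free", {
  m <- example1_model(transportables = c("A", "F"))
  out <- remove_impossible(m)
  expect_length(out$trace$removed_impossible, 0)
  expect_identical(names(out$model$reactions), c("R1", "R2"))
})

test_that("useless compounds are pruned from reaction sides", {
  # D has no downstream biomass: eliminated from R1's product list
  m <- example1_model(transportables = c("A", "F"))
  out <- remove_useless(m)
  expect_identical(out$trace$removed_useless, "D")
  expect_identical(names(out$model$reactions[["R1"]]$products), "C")
  # a dead-end branch D -> G disappears entirely
  m2 <- metabolic_model(
    compounds = lapply(c("A", "B", "C", "D", "E", "F", "G"), compound),
    reactions = list(parse_reaction_equation("R1", "A + B -> C + D"),
                     parse_reaction_equation("R2", "C + F -> B + E"),
                     parse_reaction_equation("R3", "D -> G")),
    transportables = c("A", "F"), biomass = "E")
  out2 <- remove_useless(m2)
  expect_setequal(out2$trace$removed_useless, c("D", "G"))
  expect_identical(out2$trace$deleted_reactions, "R3")
})

test_that("models whose compounds all reach biomass are untouched", {
  m <- crossfeed_model()
  out <- remove_useless(m)
  expect_length(out$trace$removed_useless, 0)
  expect_identical(names(out$model$reactions), names(m$reactions))
  empty <- metabolic_model(compounds = list(compound("A")),
                           reactions = list(), transportables = "A",
                           biomass = character())
  res <- remove_impossible(empty)
  expect_identical(res$trace$iterations, 1L)
})

test_that("simplification is idempotent and preserves T and B", {
  m <- small_random_model(3, reversible_fraction = 0.4)
  s1 <- simplify_model(m)
  s2 <- simplify_model(s1$model)
  expect_identical(names(s2$model$reactions), names(s1$model$reactions))
  expect_length(s2$trace$removed_impossible, 0)
  expect_length(s2$trace$removed_useless, 0)
  expect_identical(s1$model$transportables, m$transportables)
  expect_identical(s1$model$biomass, m$biomass)
})

test_that("an unproducible biomass compound is a hard error", {
  m <- metabolic_model(
    compounds = lapply(c("A", "B", "E"), compound),
    reactions = list(parse_reaction_equation("R1", "A -> B")),
    transportables = "A", biomass = "E")
  expect_error(simplify_model(m), "biomass unproducible: E")
})

test_that("simplification never changes the growth oracle", {
  for (seed in c(2, 5, 9, 12)) {
    m <- small_random_model(seed, reversible_fraction = 0.3)
    simp <- simplify_model(m)$model
    tset <- m$transportables
    for (v in all_assignments(length(tset))) {
      N <- tset[v]
      for (mode in c("steady", "machinery")) {
        expect_identical(nutset(simp, N, mode), nutset(m, N, mode),
                         info = paste("seed", seed, mode,
                                      paste(N, collapse = ",")))
      }
    }
  }
})
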