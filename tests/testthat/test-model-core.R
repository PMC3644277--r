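# Model types, canonical I/O, stoichiometric matrices, direction handling.

test_that("the worked-example model has the published stoichiometric matrix", {
  m <- example1_model()
  expect_length(m$compounds, 6)
  expect_length(m$reactions, 2)
  M <- stoich_matrix(m)
  expected <- matrix(c(-1, -1, 1, 1, 0, 0,
                       0, 1, -1, 0, 1, -1),
                     nrow = 6,
                     dimnames = list(c("A", "B", "C", "D", "E", "F"),
                                     c("R1", "R2")))
  expect_identical(M[rownames(expected), ], expected)
})

test_that("model save/load round trips in both canonical formats", {
  m <- example1_model()
  m$compounds[["A"]]$formula <- "C6H12O6"
  for (fmt in c("json", "tsv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(m2$transportables, m$transportables)
    expect_identical(m2$biomass, m$biomass)
    expect_identical(names(m2$reactions), names(m$reactions))
    expect_identical(m2$reactions[["R1"]]$reactants,
                     m$reactions[["R1"]]$reactants)
    expect_identical(m2$compounds[["A"]]$formula, "C6H12O6")
    expect_identical(stoich_matrix(m2), stoich_matrix(m))
  }
})

test_that("dangling compound references are rejected by name", {
  expect_error(
    metabolic_model(
      compounds = lapply(c("A", "B"), compound),
      reactions = list(parse_reaction_equation("R1", "A -> Q")),
      transportables = "A", biomass = "B"),
    "Q")
})

test_that("reaction equations parse coefficients, fractions and arrows", {
  rx <- parse_reaction_equation("R", "2 A + B -> C + 3 D")
  expect_identical(rx$reactants, c(A = 2, B = 1))
  expect_identical(rx$products, c(C = 1, D = 3))
  expect_false(rx$reversible)
  rev <- parse_reaction_equation("R", "A <-> B")
  expect_true(rev$reversible)
  # rational coefficients are cleared by uniform rescaling
  half <- parse_reaction_equation("R", "1/2 A -> B")
  expect_identical(half$reactants, c(A = 1))
  expect_identical(half$products, c(B = 2))
  expect_error(parse_reaction_equation("R", "A B C"), "arrow")
})

test_that("duplicate mentions on one side merge by summing", {
  rx <- reaction("R", reactants = c(A = 1, A = 2), products = c(B = 1))
  expect_identical(rx$reactants, c(A = 3))
})

test_that("stoichiometric matrix handles degenerate and reversible cases", {
  m0 <- metabolic_model(compounds = list(compound("A")),
                        reactions = list(), transportables = "A",
                        biomass = character())
  expect_identical(ncol(stoich_matrix(m0)), 0L)
  mrev <- metabolic_model(
    compounds = lapply(c("A", "B"), compound),
    reactions = list(parse_reaction_equation("R", "A <-> B")),
    transportables = "A", biomass = "B")
  M <- stoich_matrix(mrev, "split-unidirectional")
  expect_identical(colnames(M), c("R__f", "R__r"))
  expect_identical(M[, "R__f"], -M[, "R__r"])
  Mf <- stoich_matrix(mrev, "free-variable")
  expect_identical(ncol(Mf), 1L)
})

test_that("split then merge is the identity when nothing is deleted", {
  m <- metabolic_model(
    compounds = lapply(c("A", "B", "C"), compound),
    reactions = list(parse_reaction_equation("R1", "A <-> B"),
                     parse_reaction_equation("R2", "B -> C")),
    transportables = "A", biomass = "C")
  s <- split_directions(m)
  expect_identical(names(s$reactions), c("R1__f", "R1__r", "R2"))
  back <- merge_directions(s)
  expect_identical(names(back$reactions), names(m$reactions))
  expect_identical(back$reactions[["R1"]]$reversible, TRUE)
  expect_identical(back$reactions[["R1"]]$reactants,
                   m$reactions[["R1"]]$reactants)
  # already-unidirectional models pass through split unchanged
  ex1 <- example1_model()
  expect_identical(names(split_directions(ex1)$reactions),
                   names(ex1$reactions))
})

test_that("merge keeps a lone surviving direction as unidirectional", {
  m <- metabolic_model(
    compounds = lapply(c("A", "B"), compound),
    reactions = list(parse_reaction_equation("R1", "A <-> B")),
    transportables = "A", biomass = "B")
  s <- split_directions(m)
  s$reactions <- s$reactions[names(s$reactions) != "R1__r"]
  back <- merge_directions(s)
  expect_identical(names(back$reactions), "R1")
  expect_false(back$reactions[["R1"]]$reversible)
  expect_identical(back$reactions[["R1"]]$reactants, c(A = 1))
  expect_identical(back$reactions[["R1"]]$products, c(B = 1))
})

test_that("mass-balanced reactions have zero elemental column sums", {
  cps <- list(compound("glc", "C6H12O6"), compound("lac", "C3H6O3"))
  names(cps) <- c("glc", "lac")
  rx <- parse_reaction_equation("R", "glc -> 2 lac")
  m <- metabolic_model(cps, list(rx), transportables = "glc",
                       biomass = "lac")
  M <- stoich_matrix(m)
  for (el in c("C", "H", "O")) {
    contrib <- vapply(rownames(M), function(cid) {
      f <- parse_formula(m$compounds[[cid]]$formula)
      if (el %in% names(f)) f[[el]] else 0L
    }, 0L)
    expect_identical(sum(contrib * M[, "R"]), 0)
  }
})

test_that("SBML species and reversibility import", {
  sbml <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
 <model id="toy">
  <listOfSpecies>
   <species id="A"/><species id="B"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="true">
    <listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>
    <listOfProducts><speciesReference species="B"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- load_model(path, transportables = "A", biomass = "B")
  expect_identical(names(m$compounds), c("A", "B"))
  expect_true(m$reactions[["R1"]]$reversible)
  expect_identical(m$reactions[["R1"]]$reactants, c(A = 2))
})

test_that("formula parser validates element counts", {
  expect_identical(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_identical(parse_formula("CH4"), c(C = 1L, H = 4L))
  expect_identical(parse_formula("NaCl2"), c(Cl = 2L, Na = 1L))
  expect_error(parse_formula("C0"), "positive")
  expect_error(parse_formula("6C"), "malformed")
})
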