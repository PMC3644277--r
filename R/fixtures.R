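# Programmatic fixture models: the two worked examples and a seeded random
# generator with a planted pathway, so every pipeline stage is testable
# without external data.

#' The two-reaction worked example
#'
#' Reactions A+B -> C+D and C+F -> B+E with biomass {E}. With nutrients
#' {A, F} the steady-state system is satisfiable (the internal B/C cycle can
#' run) but the machinery-duplicating system is not: the cycle cannot
#' duplicate its own intermediates.
#'
#' @param transportables candidate nutrient order; default `c("A","B","F")`.
#' @return a `metabolic_model`.
#' @export
example1_model <- function(transportables = c("A", "B", "F")) {
  metabolic_model(
    compounds = lapply(c("A", "B", "C", "D", "E", "F"), compound),
    reactions = list(
      parse_reaction_equation("R1", "A + B -> C + D"),
      parse_reaction_equation("R2", "C + F -> B + E")
    ),
    transportables = transportables,
    biomass = "E"
  )
}

#' The cross-feeding counterexample to single-element variation
#'
#' Reactions C1+N1 -> M and C2+N2 -> M with biomass {M}: the carbon sources
#' cannot substitute for one another, so varying one element at a time from a
#' seed medium misses {C2, N2} entirely.
#'
#' @return a `metabolic_model` with T = (C1, C2, N1, N2).
#' @export
crossfeed_model <- function() {
  metabolic_model(
    compounds = lapply(c("C1", "C2", "N1", "N2", "M"), compound),
    reactions = list(
      parse_reaction_equation("R1", "C1 + N1 -> M"),
      parse_reaction_equation("R2", "C2 + N2 -> M")
    ),
    transportables = c("C1", "C2", "N1", "N2"),
    biomass = "M"
  )
}

#' Simulate single-element variation from a seed medium
#'
#' Starting from a seed nutrient set, varies the sources of one designated
#' slot only (the strategy whose blind spot motivates exhaustive
#' enumeration), and returns the nutrient sets it would ever test.
#'
#' @param seed_set character vector, the seed nutrient set.
#' @param vary_slot the compound in `seed_set` to vary.
#' @param alternatives candidate replacements for `vary_slot`.
#' @return list of nutrient sets tested by the strategy.
#' @export
single_element_variation <- function(seed_set, vary_slot, alternatives) {
  stopifnot(vary_slot %in% seed_set)
  out <- list(sort(seed_set))
  for (alt in setdiff(alternatives, vary_slot)) {
    out[[length(out) + 1L]] <- sort(union(setdiff(seed_set, vary_slot), alt))
  }
  normalize_collection(out)
}

#' Seeded random model with a planted pathway
#'
#' Generates a reproducible random metabolic model in which every biomass
#' compound is reachable through a planted linear pathway from some
#' transportable (so biomass is producible from the full nutrient pool in the
#' steady-state sense); the remaining reactions are random. Machinery-level
#' feasibility is deliberately not guaranteed: infeasible draws exercise the
#' gap between the two growth definitions.
#'
#' @param n_compounds total number of compounds (>= 3).
#' @param n_reactions total number of reactions (at least enough to hold the
#'   planted chains).
#' @param n_transportables number of candidate nutrients (>= 1).
#' @param n_biomass number of biomass compounds (>= 1).
#' @param reversible_fraction probability a random (non-planted) reaction is
#'   reversible.
#' @param max_coefficient stoichiometric coefficients are drawn uniformly
#'   from 1..max_coefficient.
#' @param seed integer seed; the same seed yields a byte-identical model.
#' @return a `metabolic_model`.
#' @export
random_model <- function(n_compounds = 8, n_reactions = 7,
                         n_transportables = 4, n_biomass = 1,
                         reversible_fraction = 0.2, max_coefficient = 2,
                         seed = 1) {
  if (n_biomass < 1 || n_transportables < 1) {
    stop("need at least one biomass compound and one transportable")
  }
  if (n_transportables + n_biomass > n_compounds) {
    stop("n_compounds too small for the requested T and B")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  ids <- sprintf("c%02d", seq_len(n_compounds))
  tset <- ids[seq_len(n_transportables)]
  bset <- ids[n_transportables + seq_len(n_biomass)]
  inner <- setdiff(ids, c(tset, bset))
  reactions <- list()
  k <- 0L
  # planted linear pathway to each biomass compound
  for (b in bset) {
    src <- sample(tset, 1)
    via <- if (length(inner) > 0 && stats::runif(1) < 0.7) {
      sample(inner, 1)
    } else NULL
    chain <- c(src, via, b)
    for (s in seq_len(length(chain) - 1)) {
      k <- k + 1L
      reactions[[k]] <- reaction(
        sprintf("P%02d", k),
        reactants = stats::setNames(1, chain[s]),
        products = stats::setNames(1, chain[s + 1]))
    }
  }
  while (k < n_reactions) {
    k <- k + 1L
    nr <- sample(1:2, 1)
    np <- sample(1:2, 1)
    lhs <- sample(ids, nr)
    rhs <- sample(setdiff(ids, lhs), np)
    reactions[[k]] <- reaction(
      sprintf("R%02d", k),
      reactants = stats::setNames(sample(seq_len(max_coefficient), nr,
                                         replace = TRUE), lhs),
      products = stats::setNames(sample(seq_len(max_coefficient), np,
                                        replace = TRUE), rhs),
      reversible = stats::runif(1) < reversible_fraction)
  }
  metabolic_model(
    compounds = lapply(ids, compound),
    reactions = reactions,
    transportables = tset,
    biomass = bset
  )
}
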