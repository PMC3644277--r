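# Model simplification: removal of Impossible and Useless compounds.
#
# Both removals are defined on the split-unidirectional form and are iterated
# to a joint fixed point; complementary direction pairs that survive are
# merged back into reversible reactions afterwards. Neither removal changes
# the satisfiability of the growth constraint systems for any nutrient set
# (a property the test suite checks exhaustively on small random models).

.new_trace <- function() {
  list(removed_impossible = character(), removed_useless = character(),
       stripped_transportables = character(),
       deleted_reactions = character(), iterations = 0L)
}

#' Remove Impossible compounds
#'
#' A compound is Impossible when it is not a potential nutrient (neither
#' transportable nor auxiliary) and no reaction produces it; it is deleted
#' together with every reaction mentioning it, iterating until no change,
#' since reaction deletion can expose further Impossible compounds.
#'
#' @param model a split-unidirectional `metabolic_model`.
#' @return list with `model` and a trace
#'   (`removed_impossible`, `deleted_reactions`, `iterations`).
#' @export
remove_impossible <- function(model) {
  trace <- .new_trace()
  exempt <- union(model$transportables, model$auxiliaries)
  repeat {
    trace$iterations <- trace$iterations + 1L
    produced <- unique(unlist(lapply(model$reactions,
                                     function(rx) names(rx$products))))
    impossible <- setdiff(setdiff(names(model$compounds), exempt), produced)
    if (length(impossible) == 0) break
    drop_rx <- vapply(model$reactions, function(rx) {
      any(c(names(rx$reactants), names(rx$products)) %in% impossible)
    }, TRUE)
    trace$removed_impossible <- c(trace$removed_impossible, impossible)
    trace$deleted_reactions <- c(trace$deleted_reactions,
                                 names(model$reactions)[drop_rx])
    model$reactions <- model$reactions[!drop_rx]
    model$compounds <- model$compounds[
      !names(model$compounds) %in% impossible]
  }
  list(model = model, trace = trace)
}

#' Remove Useless compounds
#'
#' Useful compounds are the least fixed point of: biomass compounds are
#' useful; a compound is useful when it is a reactant of a reaction with at
#' least one useful product. All other compounds are Useless: they are
#' eliminated from reaction sides, and reactions whose products have all
#' become useless are deleted (losing a product this way merely removes a
#' redundant non-negativity constraint). Transportables and auxiliaries stay
#' in the compound table so vector indexing over T is stable; their stripped
#' mentions are recorded separately.
#'
#' @param model a split-unidirectional `metabolic_model`.
#' @return list with `model` and a trace
#'   (`removed_useless`, `stripped_transportables`, `deleted_reactions`,
#'   `iterations`).
#' @export
remove_useless <- function(model) {
  trace <- .new_trace()
  useful <- intersect(model$biomass, names(model$compounds))
  repeat {
    trace$iterations <- trace$iterations + 1L
    grew <- FALSE
    for (rx in model$reactions) {
      if (any(names(rx$products) %in% useful)) {
        new <- setdiff(names(rx$reactants), useful)
        if (length(new) > 0) {
          useful <- c(useful, new)
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  useless <- setdiff(names(model$compounds), useful)
  keep_always <- union(model$transportables, model$auxiliaries)
  mentioned <- unique(unlist(lapply(model$reactions, function(rx) {
    c(names(rx$reactants), names(rx$products))
  })))
  if (length(useless) > 0) {
    out <- list()
    for (rx in model$reactions) {
      rx$reactants <- rx$reactants[!names(rx$reactants) %in% useless]
      rx$products <- rx$products[!names(rx$products) %in% useless]
      if (length(rx$products) == 0) {
        trace$deleted_reactions <- c(trace$deleted_reactions, rx$id)
      } else {
        out[[rx$id]] <- rx
      }
    }
    model$reactions <- out
    trace$removed_useless <- setdiff(useless, keep_always)
    trace$stripped_transportables <- intersect(intersect(useless, keep_always),
                                               mentioned)
    model$compounds <- model$compounds[
      !names(model$compounds) %in% trace$removed_useless]
  }
  list(model = model, trace = trace)
}

#' Simplify a model before constraint construction
#'
#' Splits reversible reactions, alternates Impossible and Useless removal to
#' a joint fixed point, then merges surviving complementary pairs back into
#' reversible reactions. Transportable and biomass memberships are never
#' altered.
#'
#' @param model a `metabolic_model`.
#' @return list with `model` (simplified) and a combined trace.
#' @export
simplify_model <- function(model) {
  work <- split_directions(model)
  trace <- .new_trace()
  fingerprint <- function(m) {
    list(length(m$compounds), length(m$reactions),
         sum(vapply(m$reactions, function(rx) {
           length(rx$reactants) + length(rx$products)
         }, 0L)))
  }
  repeat {
    trace$iterations <- trace$iterations + 1L
    before <- fingerprint(work)
    a <- remove_impossible(work)
    gone_biomass <- intersect(a$trace$removed_impossible, model$biomass)
    if (length(gone_biomass) > 0) {
      stop("biomass unproducible: ", paste(gone_biomass, collapse = ", "))
    }
    b <- remove_useless(a$model)
    work <- b$model
    changed <- !identical(before, fingerprint(work))
    trace$removed_impossible <- c(trace$removed_impossible,
                                  a$trace$removed_impossible)
    trace$removed_useless <- c(trace$removed_useless,
                               b$trace$removed_useless)
    trace$stripped_transportables <- unique(c(
      trace$stripped_transportables, b$trace$stripped_transportables))
    trace$deleted_reactions <- c(trace$deleted_reactions,
                                 a$trace$deleted_reactions,
                                 b$trace$deleted_reactions)
    if (!changed) break
  }
  out <- merge_directions(work)
  out$transportables <- model$transportables
  out$biomass <- model$biomass
  out$auxiliaries <- model$auxiliaries
  list(model = out, trace = trace)
}
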