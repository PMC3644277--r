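# Domain types: compounds, reactions, metabolic models; stoichiometric
# matrices; splitting and merging of reversible reactions.

#' Create a compound
#'
#' A compound is a metabolite or a compound class (an ontology node whose
#' instances are concrete metabolites). Formulas are elemental composition
#' strings such as `"C6H12O6"`; macromolecule placeholders may omit them.
#'
#' @param id unique compound identifier.
#' @param formula elemental formula string, or `NA` when unknown.
#' @param is_class `TRUE` for a compound class.
#' @param instances character vector of instance compound ids (classes only).
#' @return a `compound` object.
#' @export
compound <- function(id, formula = NA_character_, is_class = FALSE,
                     instances = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.na(formula)) parse_formula(formula)  # validates
  structure(
    list(id = id, formula = formula, is_class = isTRUE(is_class),
         instances = as.character(instances)),
    class = "compound"
  )
}

#' Parse an elemental formula
#'
#' @param formula string such as `"C6H12O6"` or `"CH4"`.
#' @return named integer vector of strictly positive element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || !nzchar(formula)) {
    stop("empty formula")
  }
  m <- gregexpr("([A-Z][a-z]*)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (paste(toks, collapse = "") != formula) {
    stop("malformed formula: ", formula)
  }
  elem <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  if (any(cnt <= 0L)) stop("formula counts must be strictly positive: ", formula)
  out <- tapply(cnt, elem, sum)
  stats::setNames(as.integer(out), names(out))
}

# Clear denominators so stoichiometry is held as exact integers; a uniform
# positive rescaling of one reaction only changes the unit of its flux
# variable, so feasibility questions are unaffected.
.clear_denominators <- function(reactants, products) {
  v <- c(reactants, products)
  if (length(v) == 0) return(list(reactants = reactants, products = products))
  dens <- vapply(v, function(x) {
    if (x == trunc(x)) return(1)
    for (q in 2:10000) if (abs(x * q - round(x * q)) < 1e-9) return(q)
    stop("cannot represent coefficient exactly: ", x)
  }, numeric(1))
  l <- Reduce(function(a, b) a * b / rq_gcd(a, b), dens, accumulate = FALSE)
  r <- round(reactants * l)
  p <- round(products * l)
  list(reactants = r, products = p)
}

#' Create a reaction
#'
#' Duplicate mentions of a compound on the same side are merged by summing
#' coefficients. Rational coefficients are accepted and cleared to integers
#' by uniformly rescaling the reaction (a change of flux units).
#'
#' @param id reaction identifier.
#' @param reactants named numeric vector of positive coefficients
#'   (names are compound ids); may be empty only for exchange stubs.
#' @param products as `reactants`.
#' @param reversible can the reaction run in either direction?
#' @param is_transport annotation flag, carried but without semantics.
#' @param is_exchange explicitly flagged exchange stub (may have an empty
#'   side).
#' @return a `reaction` object.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     reversible = FALSE, is_transport = FALSE,
                     is_exchange = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  merge_side <- function(x) {
    if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("reaction ", id, ": coefficients must be named by compound id")
    }
    if (any(x <= 0)) stop("reaction ", id, ": coefficients must be positive")
    v <- tapply(x, names(x), sum)[unique(names(x))]
    stats::setNames(as.numeric(v), names(v))
  }
  reactants <- merge_side(reactants)
  products <- merge_side(products)
  if (!isTRUE(is_exchange) && (length(reactants) == 0 || length(products) == 0)) {
    stop("reaction ", id, ": empty side on a non-exchange reaction")
  }
  sides <- .clear_denominators(reactants, products)
  structure(
    list(id = id, reactants = sides$reactants, products = sides$products,
         reversible = isTRUE(reversible), is_transport = isTRUE(is_transport),
         is_exchange = isTRUE(is_exchange), pair = NA_character_),
    class = "reaction"
  )
}

#' Create a metabolic model
#'
#' @param compounds list of [compound()] objects.
#' @param reactions list of [reaction()] objects (the set R).
#' @param transportables ordered character vector of potential nutrients
#'   (the set T; its order fixes the Boolean-vector components used by the
#'   enumeration module).
#' @param biomass character vector of compounds that must be produced at a
#'   strictly positive rate for growth (the set B).
#' @param auxiliaries compounds assumed unconditionally available (never
#'   candidate nutrients, exempt from production constraints).
#' @return a validated `metabolic_model`.
#' @export
metabolic_model <- function(compounds, reactions, transportables,
                            biomass, auxiliaries = character()) {
  names(compounds) <- vapply(compounds, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  model <- structure(
    list(compounds = compounds, reactions = reactions,
         transportables = as.character(transportables),
         biomass = as.character(biomass),
         auxiliaries = as.character(auxiliaries)),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, that every reference (reaction sides, transportables,
#' biomass, auxiliaries, class instances) names a declared compound, and that
#' class instances are themselves non-class compounds.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly usable in pipelines; errors describe every
#'   dangling reference found.
#' @export
validate_model <- function(model) {
  cids <- vapply(model$compounds, `[[`, "", "id")
  if (anyDuplicated(cids)) {
    stop("duplicate compound ids: ",
         paste(unique(cids[duplicated(cids)]), collapse = ", "))
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  dangling <- character()
  for (rx in model$reactions) {
    ref <- c(names(rx$reactants), names(rx$products))
    dangling <- c(dangling, setdiff(ref, cids))
  }
  for (who in c("transportables", "biomass", "auxiliaries")) {
    dangling <- c(dangling, setdiff(model[[who]], cids))
  }
  for (cp in model$compounds) {
    bad <- setdiff(cp$instances, cids)
    dangling <- c(dangling, bad)
    inst <- intersect(cp$instances, cids)
    isclass <- vapply(model$compounds[inst], `[[`, TRUE, "is_class")
    if (any(isclass)) {
      stop("class ", cp$id, " lists class compounds as instances: ",
           paste(inst[isclass], collapse = ", "))
    }
    if (length(cp$instances) > 0 && !cp$is_class) {
      stop("compound ", cp$id, " has instances but is not a class")
    }
  }
  if (length(dangling) > 0) {
    stop("undeclared compound reference(s): ",
         paste(unique(dangling), collapse = ", "))
  }
  if (anyDuplicated(model$transportables)) {
    stop("duplicate transportables")
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$compounds), " compounds, ",
      length(x$reactions), " reactions (",
      sum(vapply(x$reactions, `[[`, TRUE, "reversible")), " reversible), |T| = ",
      length(x$transportables), ", |B| = ", length(x$biomass),
      ", auxiliaries = ", length(x$auxiliaries), "\n", sep = "")
  invisible(x)
}

#' Build the stoichiometric matrix
#'
#' Rows are compounds, columns reactions; entries are net production
#' (negative for net consumption). In `"split-unidirectional"` mode each
#' reversible reaction contributes a forward and a negated reverse column;
#' in `"free-variable"` mode it contributes one column whose flux variable
#' is unconstrained in sign.
#'
#' @param model a `metabolic_model`.
#' @param direction_mode `"free-variable"` or `"split-unidirectional"`.
#' @return integer matrix with compound/reaction dimnames.
#' @export
stoich_matrix <- function(model,
                          direction_mode = c("free-variable",
                                             "split-unidirectional")) {
  direction_mode <- match.arg(direction_mode)
  if (direction_mode == "split-unidirectional") {
    model <- split_directions(model)
  }
  cids <- unname(vapply(model$compounds, `[[`, "", "id"))
  rids <- unname(vapply(model$reactions, `[[`, "", "id"))
  M <- matrix(0, nrow = length(cids), ncol = length(rids),
              dimnames = list(cids, rids))
  for (k in seq_along(model$reactions)) {
    rx <- model$reactions[[k]]
    M[names(rx$reactants), k] <- M[names(rx$reactants), k] - rx$reactants
    M[names(rx$products), k] <- M[names(rx$products), k] + rx$products
  }
  M
}

#' Split reversible reactions into unidirectional pairs
#'
#' Each reversible reaction `id` becomes a complementary pair `id__f` /
#' `id__r` linked through their `pair` field; unidirectional reactions pass
#' through unchanged.
#'
#' @param model a `metabolic_model`.
#' @return model in split-unidirectional form.
#' @export
split_directions <- function(model) {
  out <- list()
  for (rx in model$reactions) {
    if (!rx$reversible) {
      out[[rx$id]] <- rx
    } else {
      fwd <- rx
      fwd$id <- paste0(rx$id, "__f")
      fwd$reversible <- FALSE
      fwd$pair <- rx$id
      rev <- rx
      rev$id <- paste0(rx$id, "__r")
      rev$reversible <- FALSE
      rev$reactants <- rx$products
      rev$products <- rx$reactants
      rev$pair <- rx$id
      out[[fwd$id]] <- fwd
      out[[rev$id]] <- rev
    }
  }
  model$reactions <- out
  model
}

#' Merge complementary unidirectional pairs back into reversible reactions
#'
#' Pairs created by [split_directions()] whose two directions are still exact
#' mirrors are recombined under the original id; a pair with a single
#' survivor is kept unidirectional under the original id.
#'
#' @param model a split-unidirectional `metabolic_model`.
#' @return model with reversible reactions restored.
#' @export
merge_directions <- function(model) {
  out <- list()
  done <- character()
  mirrors <- function(a, b) {
    identical(a$reactants[order(names(a$reactants))],
              b$products[order(names(b$products))]) &&
      identical(a$products[order(names(a$products))],
                b$reactants[order(names(b$reactants))])
  }
  for (rx in model$reactions) {
    if (is.na(rx$pair)) {
      out[[rx$id]] <- rx
      next
    }
    if (rx$pair %in% done) next
    done <- c(done, rx$pair)
    fid <- paste0(rx$pair, "__f")
    rid <- paste0(rx$pair, "__r")
    fwd <- model$reactions[[fid]]
    rev <- model$reactions[[rid]]
    if (!is.null(fwd) && !is.null(rev) && mirrors(fwd, rev)) {
      mrg <- fwd
      mrg$id <- rx$pair
      mrg$reversible <- TRUE
      mrg$pair <- NA_character_
      out[[mrg$id]] <- mrg
    } else {
      # lone survivor (or directions no longer mirrored): keep as
      # unidirectional under the original id when unambiguous
      for (surv in Filter(Negate(is.null), list(fwd, rev))) {
        surv$pair <- NA_character_
        surv$id <- if (is.null(fwd) || is.null(rev)) rx$pair else surv$id
        out[[surv$id]] <- surv
      }
    }
  }
  model$reactions <- out
  model
}
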