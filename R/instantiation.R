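# Instantiation of generic reactions over compound classes.
#
# Pathway/genome databases describe broad-specificity enzymes with generic
# reactions whose substrates are compound classes (e.g. "sugar phosphate" ->
# "sugar"). Before constraint construction every generic reaction is expanded
# into instance-level reactions by substituting, independently per class
# slot, all combinations of class instances; a combination is kept only when
# the resulting equation is mass balanced, and a slot is skipped as ambiguous
# when several instances of its class share one chemical formula.

#' Check elemental mass balance of a reaction
#'
#' @param rx a [reaction()] object.
#' @param compounds named list of [compound()] objects covering every
#'   mentioned compound; all must carry formulas.
#' @return `TRUE` iff coefficient-weighted element counts agree on both sides.
#' @export
is_mass_balanced <- function(rx, compounds) {
  tally <- function(side) {
    tot <- integer(0)
    for (cid in names(side)) {
      cp <- compounds[[cid]]
      if (is.null(cp) || is.na(cp$formula)) {
        stop("balance indeterminate: compound ", cid, " has no formula")
      }
      f <- parse_formula(cp$formula) * side[[cid]]
      for (el in names(f)) {
        tot[el] <- (if (el %in% names(tot)) tot[el] else 0L) + f[el]
      }
    }
    tot
  }
  lhs <- tally(rx$reactants)
  rhs <- tally(rx$products)
  els <- union(names(lhs), names(rhs))
  get <- function(v, el) if (el %in% names(v)) v[[el]] else 0L
  all(vapply(els, function(el) get(lhs, el) == get(rhs, el), TRUE))
}

#' Expand generic reactions into mass-balanced instances
#'
#' Generic reactions (those mentioning class compounds) are removed from the
#' model and replaced by every accepted instantiation. Substitution is
#' independent per class slot; a combination is rejected when unbalanced and
#' a slot is ambiguous when more than one instance of its class has the same
#' chemical formula (such combinations are skipped). Instantiated reaction
#' ids are `<generic-id>/<instance ids>` for traceability.
#'
#' @param model a `metabolic_model` whose compound table carries the
#'   class/instance ontology.
#' @return list with `model` (instance-only reactions) and `reports`, a
#'   data.frame with one row per generic reaction
#'   (`generic_reaction_id`, `attempted`, `accepted`, `rejected_unbalanced`,
#'   `rejected_ambiguous`, `accepted_ids`).
#' @export
instantiate_generic_reactions <- function(model) {
  is_class <- vapply(model$compounds, `[[`, TRUE, "is_class")
  class_ids <- names(model$compounds)[is_class]
  reports <- list()
  out <- list()
  for (rx in model$reactions) {
    slots_r <- names(rx$reactants)[names(rx$reactants) %in% class_ids]
    slots_p <- names(rx$products)[names(rx$products) %in% class_ids]
    if (length(slots_r) + length(slots_p) == 0) {
      out[[rx$id]] <- rx
      next
    }
    rep0 <- list(generic_reaction_id = rx$id, attempted = 0L,
                 accepted_ids = character(), rejected_unbalanced = 0L,
                 rejected_ambiguous = 0L)
    # per-slot candidate instances; a slot with an ambiguous-formula clash
    # marks the clashing instances, combinations touching them are skipped
    slot_ids <- c(slots_r, slots_p)
    choices <- lapply(slot_ids, function(cid) model$compounds[[cid]]$instances)
    if (any(lengths(choices) == 0)) {
      # class without instances: reaction dropped, recorded
      reports[[rx$id]] <- rep0
      next
    }
    ambiguous <- lapply(choices, function(inst) {
      fml <- vapply(model$compounds[inst], `[[`, "", "formula")
      inst[fml %in% fml[duplicated(fml)] & !is.na(fml)]
    })
    grid <- expand.grid(choices, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    for (k in seq_len(nrow(grid))) {
      combo <- as.character(grid[k, ])
      rep0$attempted <- rep0$attempted + 1L
      if (any(mapply(function(c, amb) c %in% amb, combo, ambiguous))) {
        rep0$rejected_ambiguous <- rep0$rejected_ambiguous + 1L
        next
      }
      subst <- function(side, slots, offset) {
        nm <- names(side)
        for (s in seq_along(slots)) {
          nm[nm == slots[s]] <- combo[offset + s]
        }
        stats::setNames(as.numeric(side), nm)
      }
      new_rx <- tryCatch(
        reaction(paste0(rx$id, "/", paste(combo, collapse = ",")),
                 reactants = subst(rx$reactants, slots_r, 0L),
                 products = subst(rx$products, slots_p, length(slots_r)),
                 reversible = rx$reversible, is_transport = rx$is_transport,
                 is_exchange = rx$is_exchange),
        error = function(e) NULL)
      ok <- !is.null(new_rx) &&
        tryCatch(is_mass_balanced(new_rx, model$compounds),
                 error = function(e) FALSE)
      if (ok && !new_rx$id %in% names(out)) {
        out[[new_rx$id]] <- new_rx
        rep0$accepted_ids <- c(rep0$accepted_ids, new_rx$id)
      } else if (!ok) {
        rep0$rejected_unbalanced <- rep0$rejected_unbalanced + 1L
      }
    }
    reports[[rx$id]] <- rep0
  }
  reports_df <- if (length(reports) == 0) {
    data.frame(generic_reaction_id = character(),
               attempted = integer(), accepted = integer(),
               rejected_unbalanced = integer(),
               rejected_ambiguous = integer(),
               accepted_ids = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(lapply(reports, function(r) {
      data.frame(generic_reaction_id = r$generic_reaction_id,
                 attempted = r$attempted,
                 accepted = length(r$accepted_ids),
                 rejected_unbalanced = r$rejected_unbalanced,
                 rejected_ambiguous = r$rejected_ambiguous,
                 accepted_ids = paste(r$accepted_ids, collapse = ","),
                 stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  }
  model$reactions <- out
  list(model = validate_model(model), reports = reports_df)
}
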