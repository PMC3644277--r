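# Growth constraint systems and their exact satisfiability.
#
# For a putative nutrient set N the steady-state model requires non-negative
# net production of every compound outside A = N + auxiliaries and strictly
# positive net production of biomass compounds outside A. The
# machinery-duplicating model adds, for every non-exempt non-biomass compound
# mentioned by a reaction, the disjunctive clause
#     p_i > 0  OR  r_j = 0 for every reaction j mentioning i,
# so a dividing cell cannot dilute metabolites its active machinery uses.
# All systems are homogeneous, so strict atoms are decided as ">= 1" rows
# (any point of the open cone scales onto that slab).

#' Build the growth constraint system for a nutrient set
#'
#' @param model a `metabolic_model`.
#' @param nutrients character vector, subset of `model$transportables`.
#' @param mode `"steady"` or `"machinery"`.
#' @param direction reversible-reaction handling: `"free-variable"` keeps one
#'   sign-unconstrained flux per reversible reaction; `"split-unidirectional"`
#'   splits them into non-negative pairs.
#' @param machinery_scope which reactions trigger a compound's machinery
#'   clause: `"mention"` (reactant or product; the uniform default) or
#'   `"use"` (reactant only, the split-unidirectional formulation).
#' @return a `constraint_system` object: flux variables with sign
#'   constraints, clauses (each a non-empty disjunction of conjunctions of
#'   homogeneous linear atoms), and per-clause compound provenance.
#' @export
build_constraints <- function(model, nutrients,
                              mode = c("steady", "machinery"),
                              direction = c("free-variable",
                                            "split-unidirectional"),
                              machinery_scope = c("mention", "use")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  machinery_scope <- match.arg(machinery_scope)
  prep <- .prep_constraints(model, mode, direction, machinery_scope)
  .assemble_system(prep, nutrients)
}

.prep_constraints <- function(model, mode, direction, machinery_scope) {
  if (direction == "split-unidirectional") {
    model <- split_directions(model)
  }
  M <- stoich_matrix(model)
  rids <- vapply(model$reactions, `[[`, "", "id")
  free <- vapply(model$reactions, `[[`, TRUE, "reversible") &
    direction == "free-variable"
  mentions <- lapply(names(model$compounds), function(cid) {
    which(vapply(model$reactions, function(rx) {
      if (machinery_scope == "use") {
        cid %in% names(rx$reactants) ||
          (rx$reversible && cid %in% names(rx$products))
      } else {
        cid %in% names(rx$reactants) || cid %in% names(rx$products)
      }
    }, TRUE))
  })
  names(mentions) <- names(model$compounds)
  list(model = model, M = M, rids = rids, free = free, mentions = mentions,
       mode = mode, direction = direction, machinery_scope = machinery_scope)
}

.assemble_system <- function(prep, nutrients) {
  model <- prep$model
  bad <- setdiff(nutrients, model$transportables)
  if (length(bad) > 0) {
    stop("nutrients outside T: ", paste(bad, collapse = ", "))
  }
  exempt <- union(nutrients, model$auxiliaries)
  clauses <- list()
  provenance <- character()
  for (cid in names(model$compounds)) {
    if (cid %in% exempt) next
    coef <- prep$M[cid, ]
    in_b <- cid %in% model$biomass
    if (in_b) {
      clauses[[length(clauses) + 1L]] <-
        list(list(list(coef = coef, rel = ">")))
      provenance <- c(provenance, cid)
    } else if (any(coef != 0)) {
      clauses[[length(clauses) + 1L]] <-
        list(list(list(coef = coef, rel = ">=")))
      provenance <- c(provenance, cid)
    }
    if (prep$mode == "machinery" && !in_b) {
      men <- prep$mentions[[cid]]
      if (length(men) > 0) {
        zero_atoms <- lapply(men, function(j) {
          z <- numeric(ncol(prep$M))
          names(z) <- colnames(prep$M)
          z[j] <- 1
          list(coef = z, rel = "==")
        })
        clauses[[length(clauses) + 1L]] <-
          list(list(list(coef = coef, rel = ">")), zero_atoms)
        provenance <- c(provenance, cid)
      }
    }
  }
  structure(
    list(vars = data.frame(id = prep$rids, free = prep$free,
                           stringsAsFactors = FALSE),
         clauses = clauses, provenance = provenance,
         mode = prep$mode, nutrients = nutrients),
    class = "constraint_system"
  )
}

#' @export
print.constraint_system <- function(x, ...) {
  cat("<constraint_system> mode=", x$mode, ", ", nrow(x$vars),
      " flux variables (", sum(x$vars$free), " free), ",
      length(x$clauses), " clauses\n", sep = "")
  for (k in seq_along(x$clauses)) {
    cat(" ", x$provenance[k], ": ", format_clause(x$clauses[[k]]), "\n",
        sep = "")
  }
  invisible(x)
}

#' Render a clause as text
#' @param clause one element of a `constraint_system`'s clause list.
#' @return a string such as `"-r1+r2 > 0 | r1 = 0 & r2 = 0"`.
#' @export
format_clause <- function(clause) {
  atom_str <- function(a) {
    nz <- which(a$coef != 0)
    if (length(nz) == 0) {
      lhs <- "0"
    } else {
      parts <- vapply(nz, function(i) {
        c0 <- a$coef[i]
        s <- if (c0 > 0) "+" else "-"
        m <- if (abs(c0) == 1) "" else paste0(abs(c0), "*")
        paste0(s, m, names(a$coef)[i])
      }, "")
      lhs <- sub("^\\+", "", paste(parts, collapse = ""))
    }
    rel <- c(">" = "> 0", ">=" = ">= 0", "==" = "= 0")[[a$rel]]
    paste(lhs, rel)
  }
  disj <- vapply(clause, function(d) {
    paste(vapply(d, atom_str, ""), collapse = " & ")
  }, "")
  paste(disj, collapse = " | ")
}

# Build lp_feasible() input from a list of atoms. Strict atoms become ">= 1"
# rows; exact by homogeneity of the whole system.
.atoms_to_lp <- function(atoms, nvar) {
  m <- length(atoms)
  A <- matrix(0, nrow = m, ncol = nvar)
  rel <- character(m)
  b <- numeric(m)
  for (i in seq_len(m)) {
    A[i, ] <- atoms[[i]]$coef
    if (atoms[[i]]$rel == ">") {
      rel[i] <- ">="
      b[i] <- 1
    } else if (atoms[[i]]$rel == ">=") {
      rel[i] <- ">="
      b[i] <- 0
    } else {
      rel[i] <- "=="
      b[i] <- 0
    }
  }
  list(A = A, rel = rel, b = b)
}

.lp_atoms <- function(atoms, free, witness = FALSE) {
  lp <- .atoms_to_lp(atoms, length(free))
  lp_feasible(lp$A, lp$rel, lp$b, free = free, witness = witness)
}

# Recognize the machinery clause shape: exactly two disjuncts, one a single
# strict atom, the other a conjunction of single-variable zero equalities.
.machinery_shape <- function(clause) {
  if (length(clause) != 2) return(NULL)
  for (ord in list(c(1, 2), c(2, 1))) {
    pos <- clause[[ord[1]]]
    zer <- clause[[ord[2]]]
    if (length(pos) == 1 && pos[[1]]$rel == ">" &&
        all(vapply(zer, function(a) {
          a$rel == "==" && sum(a$coef != 0) == 1
        }, TRUE))) {
      zv <- vapply(zer, function(a) which(a$coef != 0), 1L)
      return(list(pos = pos[[1]], zero_vars = zv))
    }
  }
  NULL
}

#' Decide satisfiability of a constraint system exactly
#'
#' Two exact backends are available. `"iterative"` exploits the fact that the
#' feasible set of a machinery-type system is closed under addition of
#' solutions: a clause whose positive branch is unachievable (given the
#' reactions already forced off) forces its mentioning reactions to zero, and
#' when every remaining clause's positive branch is individually achievable
#' their witnesses and a biomass witness sum to a solution of the full
#' disjunctive system. `"branch"` is generic per-clause case splitting with
#' infeasibility pruning. `"auto"` uses `"iterative"` when every disjunctive
#' clause has the machinery shape, else `"branch"`.
#'
#' @param system a `constraint_system`.
#' @param witness return an exact rational flux witness when satisfiable?
#'   Witnesses are re-verified against every clause before being returned.
#' @param method `"auto"`, `"iterative"`, or `"branch"`.
#' @return list with `satisfiable` (logical) and `witness` (named list of
#'   `"p/q"` strings, or `NULL`).
#' @export
is_satisfiable <- function(system, witness = FALSE,
                           method = c("auto", "iterative", "branch")) {
  method <- match.arg(method)
  free <- system$vars$free
  nvar <- length(free)
  conj <- list()
  disj <- list()
  for (cl in system$clauses) {
    if (length(cl) == 1) {
      conj <- c(conj, cl[[1]])
    } else {
      disj[[length(disj) + 1L]] <- cl
    }
  }
  shapes <- lapply(disj, .machinery_shape)
  if (method == "auto") {
    method <- if (all(!vapply(shapes, is.null, TRUE))) "iterative" else "branch"
  }
  res <- if (method == "iterative") {
    if (any(vapply(shapes, is.null, TRUE))) {
      stop("iterative backend requires machinery-shaped clauses")
    }
    .solve_iterative(conj, shapes, free, witness)
  } else {
    .solve_branch(conj, disj, free, witness)
  }
  if (res$satisfiable && witness) {
    ok <- verify_witness(system, res$x)
    if (!ok) stop("internal: witness failed exact re-verification")
    w <- as.list(rq_format(res$x))
    names(w) <- system$vars$id
    return(list(satisfiable = TRUE, witness = w, witness_rational = res$x))
  }
  list(satisfiable = res$satisfiable, witness = NULL)
}

.zero_atoms_for <- function(idx, nvar) {
  lapply(idx, function(j) {
    z <- numeric(nvar)
    z[j] <- 1
    list(coef = z, rel = "==")
  })
}

.solve_iterative <- function(conj, shapes, free, witness) {
  nvar <- length(free)
  # relaxation used by the per-clause achievability checks and the summed
  # witness parts: strict atoms weaken to ">=" so every part contributes
  # non-negatively to every constrained production rate
  nonstrict <- lapply(conj, function(a) {
    if (a$rel == ">") list(coef = a$coef, rel = ">=") else a
  })
  zero <- rep(FALSE, nvar)
  repeat {
    zatoms <- .zero_atoms_for(which(zero), nvar)
    base <- .lp_atoms(c(conj, zatoms), free, witness = FALSE)
    if (!base$feasible) return(list(satisfiable = FALSE))
    active <- Filter(function(s) !all(zero[s$zero_vars]), shapes)
    failed <- NULL
    for (s in active) {
      pos <- s$pos
      chk <- .lp_atoms(c(nonstrict, zatoms, list(pos)), free, witness = FALSE)
      if (!chk$feasible) {
        failed <- s
        break
      }
    }
    if (is.null(failed)) {
      if (!witness) return(list(satisfiable = TRUE))
      zatoms <- .zero_atoms_for(which(zero), nvar)
      total <- .lp_atoms(c(conj, zatoms), free, witness = TRUE)$x
      for (s in active) {
        part <- .lp_atoms(c(nonstrict, zatoms, list(s$pos)), free,
                          witness = TRUE)$x
        total <- rq_add(total, part)
      }
      return(list(satisfiable = TRUE, x = total))
    }
    zero[failed$zero_vars] <- TRUE
  }
}

.solve_branch <- function(conj, disj, free, witness) {
  atom_holds <- function(a, x) {
    val <- rq_dot(a$coef, x)
    switch(a$rel,
           ">" = rq_sign(val) > 0,
           ">=" = rq_sign(val) >= 0,
           "==" = rq_sign(val) == 0)
  }
  clause_holds <- function(cl, x) {
    any(vapply(cl, function(d) all(vapply(d, atom_holds, TRUE, x)), TRUE))
  }
  rec <- function(fixed, remaining) {
    probe <- .lp_atoms(fixed, free, witness = TRUE)
    if (!probe$feasible) return(NULL)
    # branch only on clauses the relaxation's witness violates; when it
    # satisfies them all it solves the whole disjunctive system
    ok <- vapply(remaining, clause_holds, TRUE, probe$x)
    if (all(ok)) return(probe$x)
    pick <- which(!ok)[1]
    rest <- remaining[-pick]
    for (d in remaining[[pick]]) {
      got <- rec(c(fixed, d), rest)
      if (!is.null(got)) return(got)
    }
    NULL
  }
  x <- rec(conj, disj)
  if (is.null(x)) return(list(satisfiable = FALSE))
  list(satisfiable = TRUE, x = x)
}

#' Re-verify a rational flux witness against every clause
#'
#' @param system a `constraint_system`.
#' @param x rational vector (`list(n, d)`) over the system's variables, or a
#'   named numeric/character vector of fluxes (`"p/q"` strings allowed).
#' @return `TRUE` iff every clause holds under exact rational evaluation,
#'   including sign constraints.
#' @export
verify_witness <- function(system, x) {
  if (!is.list(x) || is.null(x$n)) {
    v <- x[system$vars$id]
    parse1 <- function(s) {
      if (is.numeric(s)) return(c(s, 1))
      p <- as.numeric(strsplit(as.character(s), "/", fixed = TRUE)[[1]])
      if (length(p) == 1) c(p, 1) else p
    }
    parts <- vapply(v, parse1, numeric(2))
    x <- rq(parts[1, ], parts[2, ])
  }
  sgn <- rq_sign(x)
  if (any(sgn < 0 & !system$vars$free)) return(FALSE)
  atom_ok <- function(a) {
    val <- rq_dot(a$coef, x)
    switch(a$rel,
           ">" = rq_sign(val) > 0,
           ">=" = rq_sign(val) >= 0,
           "==" = rq_sign(val) == 0)
  }
  for (cl in system$clauses) {
    sat <- any(vapply(cl, function(d) all(vapply(d, atom_ok, TRUE)), TRUE))
    if (!sat) return(FALSE)
  }
  TRUE
}

#' Growth oracle: is N a nutrient set?
#'
#' Builds the constraint system for `nutrients` and decides it exactly.
#' `nutset` is monotone in its nutrient argument: adding a transportable only
#' removes constraints.
#'
#' @inheritParams build_constraints
#' @param ... passed to [build_constraints()].
#' @return `TRUE` iff the system is satisfiable.
#' @export
nutset <- function(model, nutrients, mode = c("steady", "machinery"), ...) {
  sys <- build_constraints(model, nutrients, mode = mode, ...)
  is_satisfiable(sys)$satisfiable
}

#' Memoizing growth oracle over Boolean nutrient vectors
#'
#' Returns an oracle closure for the enumeration machinery: it accepts either
#' a logical vector over the model's transportable order or a character
#' vector of compound ids, memoizes every distinct query, and counts oracle
#' evaluations (the cost centre of the whole pipeline).
#'
#' @inheritParams build_constraints
#' @return list with `f` (the oracle function), `n` (number of
#'   transportables), `transportables`, `calls()` (evaluation counter,
#'   cache misses), and `lookups()` (total queries).
#' @export
nutset_oracle <- function(model, mode = c("steady", "machinery"),
                          direction = c("free-variable",
                                        "split-unidirectional"),
                          machinery_scope = c("mention", "use")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  machinery_scope <- match.arg(machinery_scope)
  prep <- .prep_constraints(model, mode, direction, machinery_scope)
  tset <- model$transportables
  cache <- new.env(parent = emptyenv())
  misses <- 0L
  total <- 0L
  f <- function(v) {
    if (is.character(v)) {
      v <- tset %in% v
    }
    stopifnot(is.logical(v), length(v) == length(tset))
    key <- paste(as.integer(v), collapse = "")
    total <<- total + 1L
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    misses <<- misses + 1L
    sys <- .assemble_system(prep, tset[v])
    res <- is_satisfiable(sys)$satisfiable
    assign(key, res, envir = cache)
    res
  }
  list(f = f, n = length(tset), transportables = tset,
       calls = function() misses, lookups = function() total)
}

#' Export a constraint system in SMT-LIB 2 syntax
#'
#' @param system a `constraint_system`.
#' @param path output file; when `NULL` the lines are returned.
#' @return the SMT-LIB 2 lines, invisibly when written to a file.
#' @export
export_smtlib <- function(system, path = NULL) {
  esc <- function(id) gsub("[^A-Za-z0-9_]", "_", id)
  lines <- c("(set-logic QF_LRA)")
  for (i in seq_len(nrow(system$vars))) {
    lines <- c(lines, sprintf("(declare-const %s Real)",
                              esc(system$vars$id[i])))
    if (!system$vars$free[i]) {
      lines <- c(lines, sprintf("(assert (>= %s 0))",
                                esc(system$vars$id[i])))
    }
  }
  term <- function(coef) {
    nz <- which(coef != 0)
    if (length(nz) == 0) return("0")
    parts <- vapply(nz, function(k) {
      v <- esc(names(coef)[k])
      c0 <- coef[k]
      if (c0 == 1) v
      else if (c0 == -1) sprintf("(- %s)", v)
      else if (c0 < 0) sprintf("(* (- %s) %s)", abs(c0), v)
      else sprintf("(* %s %s)", c0, v)
    }, "")
    if (length(parts) == 1) parts else sprintf("(+ %s)",
                                               paste(parts, collapse = " "))
  }
  atom <- function(a) {
    op <- c(">" = ">", ">=" = ">=", "==" = "=")[[a$rel]]
    sprintf("(%s %s 0)", op, term(a$coef))
  }
  for (cl in system$clauses) {
    ds <- vapply(cl, function(d) {
      as_ <- vapply(d, atom, "")
      if (length(as_) == 1) as_ else sprintf("(and %s)",
                                             paste(as_, collapse = " "))
    }, "")
    body <- if (length(ds) == 1) ds else sprintf("(or %s)",
                                                 paste(ds, collapse = " "))
    lines <- c(lines, sprintf("(assert %s)", body))
  }
  lines <- c(lines, "(check-sat)")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
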