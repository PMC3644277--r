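# Enumeration of all minimal nutrient sets as prime implicants of the
# monotone growth oracle.
#
# The loop: minimize the all-true vector for the first prime implicant; keep
# a BDD g = AND over found primes v of (OR of v's true components), whose
# prime implicants are the minimal choice vectors; build pi_g from g by
# standard BDD operations; trace pi_g's satisfying assignments u until one
# has f(!u) = true, minimize !u into a fresh prime, update g, restart;
# finish when no candidate u works.

#' Minimize an implicant of a monotone oracle
#'
#' Single left-to-right pass: each true component is flipped to false when
#' the oracle stays true, yielding a prime implicant. Deterministic given the
#' component order.
#'
#' @param f monotone oracle, function(logical vector) -> logical.
#' @param v logical vector with `f(v)` true.
#' @return a prime implicant of `f`.
#' @export
minimize_implicant <- function(f, v) {
  if (!isTRUE(f(v))) {
    stop("minimize_implicant requires f(v) = TRUE")
  }
  u <- v
  for (i in seq_along(u)) {
    if (u[i]) {
      u2 <- u
      u2[i] <- FALSE
      if (isTRUE(f(u2))) u <- u2
    }
  }
  u
}

#' Conjoin a new prime implicant into the choice function
#'
#' The choice function g is the conjunction, over known primes v, of the
#' disjunction of v's true variables; its implicants are the choice vectors.
#'
#' @param m a [bdd_manager()].
#' @param g node id of the current choice function.
#' @param prime logical vector (the new prime implicant).
#' @return node id of the updated g.
#' @export
update_choice_function <- function(m, g, prime) {
  d <- bdd_const(m, FALSE)
  for (i in which(prime)) {
    d <- bdd_apply(m, "or", d, bdd_var(m, i))
  }
  bdd_apply(m, "and", g, d)
}

#' BDD of the prime implicants of a monotone g
#'
#' pi_g(x) = g(x) AND, for every variable i, (NOT x_i OR NOT g(x with
#' x_i := false)): x satisfies g and no single true component can be dropped.
#'
#' @param m a [bdd_manager()].
#' @param g node id of a monotone function.
#' @return node id of pi_g.
#' @export
prime_implicant_bdd <- function(m, g) {
  acc <- g
  for (i in seq_len(m$n)) {
    gi0 <- bdd_restrict(m, g, i, FALSE)
    cl <- bdd_apply(m, "or",
                    bdd_not(m, bdd_var(m, i)),
                    bdd_not(m, gi0))
    acc <- bdd_apply(m, "and", acc, cl)
  }
  acc
}

.as_id_sets <- function(vectors, tset) {
  lapply(vectors, function(v) tset[v])
}

#' Enumerate all minimal nutrient sets
#'
#' @param model a `metabolic_model` (simplification first is recommended but
#'   not required).
#' @param mode `"steady"` or `"machinery"`.
#' @param limit optional cap on the number of sets returned (for truncated
#'   runs on large models); the result is then flagged incomplete.
#' @param oracle optional pre-built [nutset_oracle()] (reused cache).
#' @param ... passed to [nutset_oracle()] (`direction`, `machinery_scope`).
#' @return object of class `prime_implicant_set`: list with `sets` (list of
#'   character vectors in discovery order), `vectors` (logical vectors over
#'   T), `transportables`, `complete` flag, and `oracle_calls`.
#' @export
enumerate_minimal_nutrient_sets <- function(model,
                                            mode = c("steady", "machinery"),
                                            limit = NULL, oracle = NULL,
                                            ...) {
  mode <- match.arg(mode)
  if (is.null(oracle)) oracle <- nutset_oracle(model, mode, ...)
  f <- oracle$f
  n <- oracle$n
  tset <- oracle$transportables
  done <- function(vectors, complete) {
    structure(list(sets = .as_id_sets(vectors, tset), vectors = vectors,
                   transportables = tset, mode = mode, complete = complete,
                   oracle_calls = oracle$calls()),
              class = "prime_implicant_set")
  }
  if (!isTRUE(f(rep(TRUE, n)))) {
    return(done(list(), complete = TRUE))
  }
  primes <- list(minimize_implicant(f, rep(TRUE, n)))
  m <- bdd_manager(n)
  g <- update_choice_function(m, bdd_const(m, TRUE), primes[[1]])
  repeat {
    if (!is.null(limit) && length(primes) >= limit) {
      return(done(primes, complete = FALSE))
    }
    pig <- prime_implicant_bdd(m, g)
    u <- bdd_find_implicant(m, pig, function(cand) isTRUE(f(!cand)))
    if (is.null(u)) {
      return(done(primes, complete = TRUE))
    }
    new_prime <- minimize_implicant(f, !u)
    primes[[length(primes) + 1L]] <- new_prime
    g <- update_choice_function(m, g, new_prime)
  }
}

#' @export
print.prime_implicant_set <- function(x, ...) {
  cat("<prime_implicant_set> ", length(x$sets), " minimal nutrient set(s), ",
      "mode=", x$mode, if (!x$complete) " [INCOMPLETE]", ", oracle calls: ",
      x$oracle_calls, "\n", sep = "")
  for (s in x$sets) {
    cat("  {", paste(s, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Brute-force enumeration of minimal nutrient sets
#'
#' Evaluates the growth oracle on every subset of T and keeps the minimal
#' satisfying subsets. Reference implementation for testing the BDD-driven
#' enumeration; guarded to |T| <= 16.
#'
#' @inheritParams enumerate_minimal_nutrient_sets
#' @return a `prime_implicant_set` (sets ordered by size, then
#'   lexicographically by component).
#' @export
brute_force_minimal_sets <- function(model, mode = c("steady", "machinery"),
                                     oracle = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(oracle)) oracle <- nutset_oracle(model, mode, ...)
  n <- oracle$n
  if (n > 16) stop("brute force refused for |T| > 16 (got ", n, ")")
  f <- oracle$f
  tset <- oracle$transportables
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n),
                                   KEEP.OUT.ATTRS = FALSE))
  truth <- apply(subsets, 1, function(v) isTRUE(f(as.logical(v))))
  imps <- which(truth)
  minimal <- logical(length(imps))
  for (a in seq_along(imps)) {
    va <- as.logical(subsets[imps[a], ])
    dominated <- FALSE
    for (b in seq_along(imps)) {
      if (a == b) next
      vb <- as.logical(subsets[imps[b], ])
      if (all(vb <= va) && any(vb < va)) {
        dominated <- TRUE
        break
      }
    }
    minimal[a] <- !dominated
  }
  vectors <- lapply(imps[minimal], function(k) as.logical(subsets[k, ]))
  ord <- order(vapply(vectors, sum, 0),
               vapply(vectors, function(v) paste(as.integer(v),
                                                 collapse = ""), ""))
  vectors <- vectors[ord]
  structure(list(sets = .as_id_sets(vectors, tset), vectors = vectors,
                 transportables = tset, mode = mode, complete = TRUE,
                 oracle_calls = oracle$calls()),
            class = "prime_implicant_set")
}

#' Verify a vector is a prime implicant of an oracle
#'
#' @param f monotone oracle over logical vectors.
#' @param v logical vector.
#' @return `TRUE` iff `f(v)` holds and every single true-to-false flip
#'   falsifies `f`.
#' @export
is_prime_implicant <- function(f, v) {
  if (!isTRUE(f(v))) return(FALSE)
  for (i in which(v)) {
    v2 <- v
    v2[i] <- FALSE
    if (isTRUE(f(v2))) return(FALSE)
  }
  TRUE
}
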