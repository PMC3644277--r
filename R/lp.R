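# Exact feasibility of conjunctive linear systems.
#
# Decides whether {x : A x (>=|==) b, x_j >= 0 for non-free j} is non-empty,
# by phase-1 simplex on an exact rational tableau. Bland's anti-cycling rule
# makes termination unconditional; no floating point enters any decision.
# All the systems this package generates are homogeneous cones, so strict
# inequalities are presented here already rescaled to ">= 1" rows.

#' Decide feasibility of a linear system exactly
#'
#' @param A numeric matrix (integer-valued entries), one row per constraint.
#' @param rel character vector, one of `">="` or `"=="` per row.
#' @param b integer right-hand sides, all non-negative.
#' @param free logical vector, `TRUE` for sign-unconstrained variables;
#'   remaining variables are constrained non-negative.
#' @param witness if `TRUE`, return an exact rational witness on feasibility.
#' @return list with `feasible` (logical) and `x` (rational vector as a
#'   `list(n, d)` pair over the original variables, or `NULL`).
#' @noRd
lp_feasible <- function(A, rel, b, free = rep(FALSE, ncol(A)),
                        witness = FALSE) {
  m <- nrow(A)
  p <- ncol(A)
  stopifnot(length(rel) == m, length(b) == m, length(free) == p)
  if (any(b < 0)) stop("internal: lp_feasible requires non-negative rhs")
  if (any(A != trunc(A)) || any(b != trunc(b))) {
    stop("internal: lp_feasible requires integral input")
  }
  if (m == 0) {
    x <- if (witness) rq(rep(0, p)) else NULL
    return(list(feasible = TRUE, x = x))
  }

  # Structural columns: one per non-negative variable, a +/- pair per free
  # variable (x = x_plus - x_minus).
  cols <- list()
  colvar <- integer(0)   # original variable index
  colsgn <- integer(0)   # +1 / -1
  for (j in seq_len(p)) {
    cols[[length(cols) + 1L]] <- A[, j]
    colvar <- c(colvar, j)
    colsgn <- c(colsgn, 1L)
    if (free[j]) {
      cols[[length(cols) + 1L]] <- -A[, j]
      colvar <- c(colvar, j)
      colsgn <- c(colsgn, -1L)
    }
  }
  nstruct <- length(cols)
  nge <- sum(rel == ">=")
  # surplus columns for ">=" rows
  ge_rows <- which(rel == ">=")
  for (k in seq_along(ge_rows)) {
    s <- rep(0, m)
    s[ge_rows[k]] <- -1
    cols[[length(cols) + 1L]] <- s
  }
  # artificial columns (initial basis)
  for (i in seq_len(m)) {
    a <- rep(0, m)
    a[i] <- 1
    cols[[length(cols) + 1L]] <- a
  }
  ncols <- nstruct + nge + m
  art0 <- nstruct + nge  # artificial columns are art0+1 .. art0+m

  Tn <- cbind(do.call(cbind, cols), b)
  # objective row: reduced costs of minimizing the artificial sum,
  # with the artificial basis priced out
  obj <- c(colSums(Tn[, seq_len(nstruct + nge), drop = FALSE]),
           rep(0, m), sum(b))
  Tn <- rbind(Tn, obj)
  Td <- matrix(1, nrow = m + 1L, ncol = ncols + 1L)
  objr <- m + 1L
  rhsc <- ncols + 1L
  basis <- art0 + seq_len(m)

  repeat {
    # entering column: Bland -- smallest non-artificial index with a
    # strictly positive reduced cost
    enter <- 0L
    for (j in seq_len(art0)) {
      if (Tn[objr, j] > 0) { enter <- j; break }
    }
    if (enter == 0L) break
    # ratio test over rows with a positive pivot entry, exact comparison
    leave <- 0L
    bn <- bd <- 0
    for (i in seq_len(m)) {
      if (Tn[i, enter] > 0) {
        # ratio = rhs_i / T[i, enter]
        rn <- Tn[i, rhsc] * Td[i, enter]
        rd <- Td[i, rhsc] * Tn[i, enter]
        if (leave == 0L || rn * bd < bn * rd ||
            (rn * bd == bn * rd && basis[i] < basis[leave])) {
          leave <- i
          bn <- rn
          bd <- rd
        }
      }
    }
    if (leave == 0L) {
      stop("internal: unbounded phase-1 objective")
    }
    # pivot at (leave, enter)
    pn <- Tn[leave, enter]
    pd <- Td[leave, enter]
    prow <- rq(Tn[leave, ] * pd, Td[leave, ] * pn)
    Tn[leave, ] <- prow$n
    Td[leave, ] <- prow$d
    for (i in seq_len(m + 1L)) {
      if (i != leave && Tn[i, enter] != 0) {
        # scaled pivot row, reduced before subtraction to bound magnitudes
        t <- rq(prow$n * Tn[i, enter], prow$d * Td[i, enter])
        upd <- rq(Tn[i, ] * t$d - t$n * Td[i, ], Td[i, ] * t$d)
        Tn[i, ] <- upd$n
        Td[i, ] <- upd$d
      }
    }
    basis[leave] <- enter
  }

  feasible <- Tn[objr, rhsc] == 0
  x <- NULL
  if (feasible && witness) {
    xn <- rep(0, p)
    xd <- rep(1, p)
    acc <- rq(xn, xd)
    for (i in seq_len(m)) {
      bv <- basis[i]
      if (bv <= nstruct && Tn[i, rhsc] != 0) {
        j <- colvar[bv]
        term <- rq(colsgn[bv] * Tn[i, rhsc], Td[i, rhsc])
        cur <- rq(acc$n[j], acc$d[j])
        upd <- rq_add(cur, term)
        acc$n[j] <- upd$n
        acc$d[j] <- upd$d
      }
    }
    x <- acc
  }
  list(feasible = feasible, x = x)
}
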