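# A small reduced ordered binary decision diagram (ROBDD) engine.
#
# Nodes are hash-consed, variables are 1..n in the model's transportable
# order (determinism first; dynamic reordering is deliberately absent), and
# the only operations needed by the enumeration algorithm are provided:
# AND, OR, NOT, restriction, and short-circuiting path traversal with the
# low (false) branch visited first.

#' Create a BDD manager over n variables
#'
#' @param n number of Boolean variables.
#' @return a manager environment; node 1 is the FALSE terminal, node 2 TRUE.
#' @export
bdd_manager <- function(n) {
  m <- new.env(parent = emptyenv())
  m$n <- n
  size <- 256L
  m$var <- rep(NA_integer_, size)
  m$lo <- rep(NA_integer_, size)
  m$hi <- rep(NA_integer_, size)
  m$var[1:2] <- n + 1L  # terminals sort after every variable
  m$count <- 2L
  m$unique <- new.env(parent = emptyenv())
  m$memo <- new.env(parent = emptyenv())
  m
}

#' @noRd
.bdd_mk <- function(m, v, lo, hi) {
  if (lo == hi) return(lo)
  key <- paste(v, lo, hi)
  hit <- get0(key, envir = m$unique, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (m$count == length(m$var)) {
    grow <- length(m$var) * 2L
    length(m$var) <- grow
    length(m$lo) <- grow
    length(m$hi) <- grow
  }
  id <- m$count + 1L
  m$count <- id
  m$var[id] <- v
  m$lo[id] <- lo
  m$hi[id] <- hi
  assign(key, id, envir = m$unique)
  id
}

#' The BDD for a single variable
#' @param m a [bdd_manager()].
#' @param i variable index in 1..n.
#' @return node id.
#' @export
bdd_var <- function(m, i) {
  stopifnot(i >= 1, i <= m$n)
  .bdd_mk(m, as.integer(i), 1L, 2L)
}

#' Boolean constants
#' @param m a [bdd_manager()].
#' @param value logical scalar.
#' @return terminal node id (1 for FALSE, 2 for TRUE).
#' @export
bdd_const <- function(m, value) if (isTRUE(value)) 2L else 1L

#' Combine two BDDs
#' @param m a [bdd_manager()].
#' @param op `"and"` or `"or"`.
#' @param f,g node ids.
#' @return node id of `f op g`.
#' @export
bdd_apply <- function(m, op, f, g) {
  if (op == "and") {
    if (f == 1L || g == 1L) return(1L)
    if (f == 2L) return(g)
    if (g == 2L) return(f)
  } else if (op == "or") {
    if (f == 2L || g == 2L) return(2L)
    if (f == 1L) return(g)
    if (g == 1L) return(f)
  } else {
    stop("unknown op: ", op)
  }
  if (f == g) return(f)
  key <- paste(op, min(f, g), max(f, g))
  hit <- get0(key, envir = m$memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  v <- min(m$var[f], m$var[g])
  flo <- if (m$var[f] == v) m$lo[f] else f
  fhi <- if (m$var[f] == v) m$hi[f] else f
  glo <- if (m$var[g] == v) m$lo[g] else g
  ghi <- if (m$var[g] == v) m$hi[g] else g
  r <- .bdd_mk(m, v, bdd_apply(m, op, flo, glo), bdd_apply(m, op, fhi, ghi))
  assign(key, r, envir = m$memo)
  r
}

#' Negate a BDD
#' @param m a [bdd_manager()].
#' @param f node id.
#' @return node id of NOT f.
#' @export
bdd_not <- function(m, f) {
  if (f == 1L) return(2L)
  if (f == 2L) return(1L)
  key <- paste("not", f)
  hit <- get0(key, envir = m$memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  r <- .bdd_mk(m, m$var[f], bdd_not(m, m$lo[f]), bdd_not(m, m$hi[f]))
  assign(key, r, envir = m$memo)
  r
}

#' Restrict a variable to a constant
#' @param m a [bdd_manager()].
#' @param f node id.
#' @param i variable index.
#' @param value logical value substituted for variable `i`.
#' @return node id of `f[x_i := value]`.
#' @export
bdd_restrict <- function(m, f, i, value) {
  if (f <= 2L || m$var[f] > i) return(f)
  key <- paste("res", f, i, value)
  hit <- get0(key, envir = m$memo, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  r <- if (m$var[f] == i) {
    if (isTRUE(value)) m$hi[f] else m$lo[f]
  } else {
    .bdd_mk(m, m$var[f],
            bdd_restrict(m, m$lo[f], i, value),
            bdd_restrict(m, m$hi[f], i, value))
  }
  assign(key, r, envir = m$memo)
  r
}

#' Evaluate a BDD on a full assignment
#' @param m a [bdd_manager()].
#' @param f node id.
#' @param x logical vector of length n.
#' @return logical scalar.
#' @export
bdd_eval <- function(m, f, x) {
  while (f > 2L) {
    f <- if (x[m$var[f]]) m$hi[f] else m$lo[f]
  }
  f == 2L
}

#' Visit the satisfying assignments of a BDD until one is accepted
#'
#' Depth-first traversal of root-to-TRUE paths, false branch first; variables
#' skipped along a path (don't-cares) are expanded to both values with false
#' preferred. `visit` receives each complete logical assignment and the
#' traversal stops at the first assignment for which it returns `TRUE`.
#'
#' @param m a [bdd_manager()].
#' @param f node id.
#' @param visit function(logical vector) -> logical.
#' @return the accepted assignment, or `NULL` when `visit` accepted none.
#' @export
bdd_find_implicant <- function(m, f, visit) {
  n <- m$n
  assign_ <- logical(n)
  rec <- function(node, i) {
    if (node == 1L) return(NULL)
    if (i > n) {
      # complete assignment; node must be a terminal here
      if (node == 2L && isTRUE(visit(assign_))) return(assign_)
      return(NULL)
    }
    if (node == 2L || m$var[node] > i) {
      # don't-care at variable i: false first
      assign_[i] <<- FALSE
      got <- rec(node, i + 1L)
      if (!is.null(got)) return(got)
      assign_[i] <<- TRUE
      return(rec(node, i + 1L))
    }
    assign_[i] <<- FALSE
    got <- rec(m$lo[node], i + 1L)
    if (!is.null(got)) return(got)
    assign_[i] <<- TRUE
    rec(m$hi[node], i + 1L)
  }
  rec(f, 1L)
}
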