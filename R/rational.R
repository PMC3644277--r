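# Exact rational arithmetic on parallel numerator/denominator vectors.
#
# Rationals are held as reduced pairs of doubles (den > 0). All model
# stoichiometry is integral, so numerators/denominators stay well below the
# 2^53 exact-integer range of a double at the problem sizes this package
# targets; every operation reduces by the gcd and an explicit guard aborts
# rather than silently losing exactness.

.RQ_MAX <- 2^52

#' @noRd
rq_gcd <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (any(b > 0)) {
    keep <- b > 0
    t <- b[keep]
    b[keep] <- a[keep] %% t
    a[keep] <- t
  }
  a[a == 0] <- 1
  a
}

#' Construct a reduced rational vector
#' @noRd
rq <- function(n, d = rep(1, length(n))) {
  stopifnot(length(n) == length(d), all(d != 0))
  if (any(n != trunc(n)) || any(d != trunc(d))) {
    stop("rational components must be integral")
  }
  neg <- d < 0
  n[neg] <- -n[neg]
  d[neg] <- -d[neg]
  g <- rq_gcd(n, d)
  n <- n / g
  d <- d / g
  if (any(abs(n) > .RQ_MAX) || any(d > .RQ_MAX)) {
    stop("exact rational overflow: values exceed the exact double range")
  }
  list(n = n, d = d)
}

#' @noRd
rq_add <- function(x, y) rq(x$n * y$d + y$n * x$d, x$d * y$d)

#' @noRd
rq_sub <- function(x, y) rq(x$n * y$d - y$n * x$d, x$d * y$d)

#' @noRd
rq_mul <- function(x, y) rq(x$n * y$n, x$d * y$d)

#' @noRd
rq_div <- function(x, y) {
  if (any(y$n == 0)) stop("rational division by zero")
  rq(x$n * y$d, x$d * y$n)
}

#' Exact sign of each component
#' @noRd
rq_sign <- function(x) sign(x$n)

#' Exact comparison x < y (componentwise)
#' @noRd
rq_lt <- function(x, y) (x$n * y$d) < (y$n * x$d)

#' @noRd
rq_eq <- function(x, y) x$n == y$n & x$d == y$d

#' Subset of a rational vector
#' @noRd
rq_slice <- function(x, i) list(n = x$n[i], d = x$d[i])

#' Exact sum of the components of a rational vector
#' @noRd
rq_sum <- function(x) {
  acc <- rq(0)
  for (i in seq_along(x$n)) {
    acc <- rq_add(acc, rq(x$n[i], x$d[i]))
  }
  acc
}

#' Exact dot product of integer coefficients with a rational vector
#' @noRd
rq_dot <- function(coef, x) {
  nz <- which(coef != 0)
  acc <- rq(0)
  for (i in nz) {
    acc <- rq_add(acc, rq(coef[i] * x$n[i], x$d[i]))
  }
  acc
}

#' Render rationals as "p/q" strings
#' @noRd
rq_format <- function(x) {
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  ifelse(x$d == 1, fmt(x$n), paste0(fmt(x$n), "/", fmt(x$d)))
}
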