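# Shared helpers: truth-table oracles and set-collection comparison.

# Monotone Boolean function from an explicit list of minimal true vectors
# (truth by superset of any listed vector). Independent of the BDD machinery.
tt_oracle <- function(minimal_vectors) {
  function(v) {
    any(vapply(minimal_vectors, function(m) all(v[m]), TRUE))
  }
}

# All 2^n assignments as a list of logical vectors, lexicographic with FALSE
# first in the lowest-index position.
all_assignments <- function(n) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.logical(grid[i, ]))
}

# Minimal true vectors of an arbitrary oracle by exhaustive truth-table
# enumeration (the reference for choice-function and BDD tests).
tt_minimal_true <- function(f, n) {
  vs <- Filter(function(v) isTRUE(f(v)), all_assignments(n))
  keep <- vapply(seq_along(vs), function(a) {
    !any(vapply(seq_along(vs), function(b) {
      a != b && all(vs[[b]] <= vs[[a]]) && any(vs[[b]] < vs[[a]])
    }, TRUE))
  }, TRUE)
  vs[keep]
}

expect_same_collection <- function(a, b) {
  expect_identical(normalize_collection(a), normalize_collection(b))
}

# Small random model shared across property tests; parameters chosen so the
# exhaustive 2^|T| brute force stays fast.
small_random_model <- function(seed, reversible_fraction = 0.25) {
  random_model(n_compounds = 8, n_reactions = 7, n_transportables = 4,
               n_biomass = 1, reversible_fraction = reversible_fraction,
               seed = seed)
}
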