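# Equivalence classes of nutrients over a collection of minimal nutrient
# sets, and the lossless reduced representation.
#
# Two compounds are equivalent when each can substitute for the other in
# every set of the collection where it occurs. Rewriting every set over class
# representatives and deduplicating compresses the collection with zero
# information loss: expansion over the classes regenerates it exactly.

.set_key <- function(s) paste0("k:", paste(sort(s), collapse = "\r"))

.collection_index <- function(collection) {
  idx <- new.env(parent = emptyenv())
  for (s in collection) assign(.set_key(s), TRUE, envir = idx)
  idx
}

#' Canonicalize a collection of nutrient sets
#'
#' @param collection list of character vectors.
#' @return list of sorted character vectors with duplicates removed,
#'   deterministic order (size, then lexicographic).
#' @export
normalize_collection <- function(collection) {
  sets <- lapply(collection, function(s) sort(unique(as.character(s))))
  keys <- vapply(sets, .set_key, "")
  sets <- sets[!duplicated(keys)]
  ord <- order(lengths(sets), vapply(sets, .set_key, ""))
  sets[ord]
}

#' Are two compounds equivalent with respect to a collection?
#'
#' @param c1,c2 compound ids occurring in the collection.
#' @param collection list of character-vector nutrient sets.
#' @return `TRUE` iff for every set containing `c1` the set with `c2`
#'   substituted is also in the collection, and symmetrically.
#' @export
are_equivalent <- function(c1, c2, collection) {
  if (identical(c1, c2)) return(TRUE)
  idx <- .collection_index(collection)
  sub_ok <- function(a, b) {
    for (s in collection) {
      if (a %in% s) {
        t <- union(setdiff(s, a), b)
        if (!isTRUE(get0(.set_key(t), envir = idx, inherits = FALSE))) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  sub_ok(c1, c2) && sub_ok(c2, c1)
}

#' Partition nutrient compounds into equivalence classes
#'
#' @param collection list of character-vector nutrient sets (duplicates are
#'   removed first).
#' @param representatives optional preference order: the first member of a
#'   class appearing in this character vector becomes its representative;
#'   classes with no preferred member fall back to the lexicographically
#'   smallest id.
#' @param compounds optional named list of [compound()] objects; when given,
#'   per-class element annotations (which of C, N, P, S the members contain)
#'   are attached.
#' @return object of class `equivalence_classification`: `classes` (list of
#'   character vectors), `representative` (one id per class), `class_of`
#'   (named lookup), optional `elements` annotation.
#' @export
compute_classes <- function(collection, representatives = NULL,
                            compounds = NULL) {
  collection <- normalize_collection(collection)
  occurring <- sort(unique(unlist(collection)))
  k <- length(occurring)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  idx <- .collection_index(collection)
  equiv_pair <- function(a, b) {
    sub_ok <- function(x, y) {
      for (s in collection) {
        if (x %in% s) {
          t <- union(setdiff(s, x), y)
          if (!isTRUE(get0(.set_key(t), envir = idx, inherits = FALSE))) {
            return(FALSE)
          }
        }
      }
      TRUE
    }
    sub_ok(a, b) && sub_ok(b, a)
  }
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (find(i) != find(j) && equiv_pair(occurring[i], occurring[j])) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  classes <- split(occurring, roots)
  names(classes) <- NULL
  classes <- classes[order(vapply(classes, min, ""))]
  # the relation is provably transitive; verify every within-class pair
  for (cl in classes) {
    if (length(cl) > 1) {
      for (i in 1:(length(cl) - 1)) {
        for (j in (i + 1):length(cl)) {
          if (!equiv_pair(cl[i], cl[j])) {
            stop("internal: computed relation is not transitive on class {",
                 paste(cl, collapse = ", "), "}")
          }
        }
      }
    }
  }
  rep_of <- vapply(classes, function(cl) {
    pref <- intersect(representatives, cl)
    if (length(pref) > 0) pref[1] else min(cl)
  }, "")
  class_of <- stats::setNames(
    rep(seq_along(classes), lengths(classes)), unlist(classes))
  elements <- NULL
  if (!is.null(compounds)) {
    elements <- vapply(classes, function(cl) {
      els <- unique(unlist(lapply(cl, function(cid) {
        cp <- compounds[[cid]]
        if (is.null(cp) || is.na(cp$formula)) return(character())
        intersect(c("C", "N", "P", "S"), names(parse_formula(cp$formula)))
      })))
      paste(intersect(c("C", "N", "P", "S"), els), collapse = ",")
    }, "")
  }
  structure(list(classes = classes, representative = rep_of,
                 class_of = class_of, elements = elements),
            class = "equivalence_classification")
}

#' @export
print.equivalence_classification <- function(x, ...) {
  cat("<equivalence_classification> ", length(x$classes), " class(es)\n",
      sep = "")
  for (i in seq_along(x$classes)) {
    cat("  [", x$representative[i], "]",
        if (!is.null(x$elements) && nzchar(x$elements[i])) {
          paste0(" (", x$elements[i], ")")
        },
        ": ", paste(x$classes[[i]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Reduce a collection to canonical forms
#'
#' Every set is rewritten over class representatives and duplicates are
#' removed; the count of canonical sets does not depend on which
#' representatives were chosen.
#'
#' @param collection list of character-vector nutrient sets.
#' @param classification an [compute_classes()] result for this collection.
#' @return object of class `reduced_collection`: `canonical_sets` and the
#'   `classification`.
#' @export
reduce_collection <- function(collection, classification) {
  collection <- normalize_collection(collection)
  rep_map <- stats::setNames(
    classification$representative[classification$class_of],
    names(classification$class_of))
  canon <- lapply(collection, function(s) sort(unique(rep_map[s])))
  canon <- normalize_collection(canon)
  structure(list(canonical_sets = canon, classification = classification),
            class = "reduced_collection")
}

#' Expand a reduced collection back to the full collection
#'
#' Substitutes every class member for each representative in every canonical
#' set, in all combinations.
#'
#' @param reduced a [reduce_collection()] result.
#' @return normalized list of character-vector nutrient sets.
#' @export
expand_collection <- function(reduced) {
  cls <- reduced$classification
  class_members <- function(cid) {
    cls$classes[[cls$class_of[[cid]]]]
  }
  out <- list()
  for (s in reduced$canonical_sets) {
    if (length(s) == 0) {
      out[[length(out) + 1L]] <- character(0)
      next
    }
    choices <- lapply(s, class_members)
    grid <- expand.grid(choices, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(grid))) {
      out[[length(out) + 1L]] <- as.character(grid[r, ])
    }
  }
  normalize_collection(out)
}

#' Write an equivalence classification as TSV
#'
#' Columns: class id, representative, elements (when annotated), comma-joined
#' member compounds.
#'
#' @param classification a [compute_classes()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_classes_tsv <- function(classification, path) {
  df <- data.frame(
    class = seq_along(classification$classes),
    representative = classification$representative,
    elements = if (is.null(classification$elements)) ""
               else classification$elements,
    compounds = vapply(classification$classes, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a collection of nutrient sets to JSON
#' @param collection list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_collection <- function(collection, path) {
  jsonlite::write_json(lapply(normalize_collection(collection), as.list),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a collection of nutrient sets from JSON
#' @param path a JSON file holding a list of lists of compound ids.
#' @return normalized list of character vectors.
#' @export
load_collection <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  normalize_collection(lapply(doc, function(s) unlist(s)))
}
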