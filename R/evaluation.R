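# Scoring predicted minimal nutrient sets against phenotype-microarray (PM)
# growth calls.
#
# Each PM well is a tested nutrient set with a growth / no-growth /
# low-growth call. A prediction matches a well when some predicted set equals
# the well's set or is a proper subset of it (a predicted compound may source
# several elements at once, making an explicit supplement redundant).
# Low-growth wells are inconclusive and excluded from the confusion matrix.

#' Read a phenotype-microarray table
#'
#' Tab-separated with a header: `well_id`, `nutrients` (comma-joined
#' compound ids), `growth_call` (one of `growth`, `no-growth`, `low-growth`).
#'
#' @param path TSV file.
#' @param synonyms optional two-column data.frame (`pm_name`, `model_id`)
#'   mapping PM compound names onto model ids; unmapped names pass through.
#' @return data.frame with list-column `nutrient_set`.
#' @export
read_pm_table <- function(path, synonyms = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("well_id", "nutrients", "growth_call")
  if (!all(need %in% names(df))) {
    stop("PM table must have columns: ", paste(need, collapse = ", "))
  }
  sets <- lapply(strsplit(df$nutrients, ","), trimws)
  if (!is.null(synonyms)) {
    map <- stats::setNames(synonyms$model_id, synonyms$pm_name)
    sets <- lapply(sets, function(s) {
      unname(ifelse(s %in% names(map), map[s], s))
    })
  }
  data.frame(well_id = df$well_id,
             nutrient_set = I(sets),
             growth_call = df$growth_call,
             stringsAsFactors = FALSE)
}

#' Does a predicted collection match a PM nutrient set?
#'
#' @param pm_set character vector (the well's nutrient set).
#' @param predicted_collection list of character-vector predicted minimal
#'   nutrient sets.
#' @return `TRUE` iff some predicted set equals `pm_set` or is a proper
#'   subset of it.
#' @export
matches <- function(pm_set, predicted_collection) {
  any(vapply(predicted_collection, function(s) all(s %in% pm_set), TRUE))
}

#' Score predictions against PM growth calls
#'
#' growth + match is a true positive; growth without match a false negative;
#' no-growth without match a true negative; no-growth with match a false
#' positive; low-growth wells are excluded as inconclusive.
#'
#' @param pm_records data.frame from [read_pm_table()] (columns `well_id`,
#'   `nutrient_set`, `growth_call`).
#' @param predicted_collection list of character-vector predicted sets.
#' @return object of class `confusion_report`: counts `TP`, `TN`, `FP`,
#'   `FN`, `excluded_low_growth`, exact `accuracy` (`"p/q"` string plus
#'   numeric value, `NA` when no conclusive records), and per-record
#'   `verdicts`.
#' @export
score_predictions <- function(pm_records, predicted_collection) {
  calls <- pm_records$growth_call
  bad <- setdiff(unique(calls), c("growth", "no-growth", "low-growth"))
  if (length(bad) > 0) {
    stop("unknown growth_call value(s): ", paste(bad, collapse = ", "))
  }
  verdict <- character(nrow(pm_records))
  for (i in seq_len(nrow(pm_records))) {
    if (calls[i] == "low-growth") {
      verdict[i] <- "excluded"
      next
    }
    hit <- matches(pm_records$nutrient_set[[i]], predicted_collection)
    verdict[i] <- if (calls[i] == "growth") {
      if (hit) "TP" else "FN"
    } else {
      if (hit) "FP" else "TN"
    }
  }
  tp <- sum(verdict == "TP")
  tn <- sum(verdict == "TN")
  fp <- sum(verdict == "FP")
  fn <- sum(verdict == "FN")
  denom <- tp + tn + fp + fn
  acc_str <- if (denom == 0) NA_character_ else {
    rq_format(rq(tp + tn, denom))
  }
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 excluded_low_growth = sum(verdict == "excluded"),
                 accuracy = acc_str,
                 accuracy_value = if (denom == 0) NA_real_
                                  else (tp + tn) / denom,
                 verdicts = data.frame(well_id = pm_records$well_id,
                                       growth_call = calls,
                                       verdict = verdict,
                                       stringsAsFactors = FALSE)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> TP=", x$TP, " TN=", x$TN, " FP=", x$FP,
      " FN=", x$FN, " excluded=", x$excluded_low_growth, "\n", sep = "")
  if (is.na(x$accuracy)) {
    cat("  accuracy: not applicable (no conclusive records)\n")
  } else {
    cat("  accuracy: ", x$accuracy, " = ",
        sprintf("%.1f%%", 100 * x$accuracy_value), "\n", sep = "")
  }
  invisible(x)
}
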