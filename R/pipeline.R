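# End-to-end pipeline: instantiate -> simplify -> enumerate -> classes ->
# reduce -> (optionally) evaluate, with a run manifest for reproducibility.

#' Read a flat key=value config file
#' @param path config file; `#` starts a comment, values are strings.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  stats::setNames(
    lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
    trimws(vapply(kv, `[[`, "", 1)))
}

#' Run the full prediction pipeline
#'
#' Loads a model, instantiates generic reactions, simplifies, enumerates all
#' minimal nutrient sets, compresses them into equivalence classes and a
#' reduced collection, optionally scores against a PM table, and writes
#' `sets.json`, `classes.json`, `reduced.json`, `report.tsv` (when a PM table
#' is given) and `manifest.json` into the output directory.
#'
#' @param config a named list or a path to a flat key=value file. Keys:
#'   `model` (path, required), `mode` (`machinery` default or `steady`),
#'   `out_dir` (required), `pm_table` (optional TSV), `limit` (optional
#'   integer), `simplify` (`true`/`false`, default true).
#' @return invisibly, a list with the pipeline artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  need <- setdiff(c("model", "out_dir"), names(config))
  if (length(need) > 0) {
    stop("config error: missing key(s): ", paste(need, collapse = ", "))
  }
  mode <- config$mode %||% "machinery"
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  counts <- list()

  model <- stage("load", load_model(config$model))
  counts$reactions_loaded <- length(model$reactions)

  inst <- stage("instantiate", instantiate_generic_reactions(model))
  model <- inst$model
  counts$reactions_after_instantiation <- length(model$reactions)

  simplify <- !identical(tolower(config$simplify %||% "true"), "false")
  if (simplify) {
    simp <- stage("simplify", simplify_model(model))
    model <- simp$model
    counts$reactions_after_simplification <- length(model$reactions)
  }

  oracle <- nutset_oracle(model, mode)
  limit <- if (!is.null(config$limit)) as.integer(config$limit) else NULL
  result <- stage("enumerate",
                  enumerate_minimal_nutrient_sets(model, mode, limit = limit,
                                                  oracle = oracle))
  counts$minimal_nutrient_sets <- length(result$sets)
  counts$oracle_evaluations <- oracle$calls()
  collection <- normalize_collection(result$sets)
  save_collection(collection, file.path(out_dir, "sets.json"))

  classes <- stage("classes",
                   compute_classes(collection, compounds = model$compounds))
  jsonlite::write_json(
    list(classes = lapply(classes$classes, as.list),
         representative = as.list(classes$representative),
         elements = if (is.null(classes$elements)) NULL
                    else as.list(classes$elements)),
    file.path(out_dir, "classes.json"), auto_unbox = TRUE, pretty = TRUE)
  counts$equivalence_classes <- length(classes$classes)

  reduced <- stage("reduce", reduce_collection(collection, classes))
  save_collection(reduced$canonical_sets, file.path(out_dir, "reduced.json"))
  counts$reduced_sets <- length(reduced$canonical_sets)

  report <- NULL
  if (!is.null(config$pm_table)) {
    pm <- stage("evaluate", read_pm_table(config$pm_table))
    report <- stage("evaluate", score_predictions(pm, collection))
    utils::write.table(report$verdicts, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$pm_records <- nrow(pm)
    counts$accuracy <- report$accuracy_value
  }

  manifest <- list(
    tool = "minnut",
    version = as.character(utils::packageVersion("minnut")),
    model_md5 = unname(tools::md5sum(config$model)),
    mode = mode,
    transportable_order = as.list(model$transportables),
    complete = result$complete,
    timestamp = format(Sys.time(), tz = "UTC"),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, sets = collection, classes = classes,
                 reduced = reduced, report = report, manifest = manifest))
}
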