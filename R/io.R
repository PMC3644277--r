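# Canonical model file formats.
#
# Two equivalent on-disk dialects are supported: a JSON document and a
# sectioned TSV. Both preserve transportable order exactly. Reactions may be
# written either with explicit reactant/product coefficient maps or as
# equation strings like "2 A + B -> C + D" ("<->" for reversible). A minimal
# SBML level-3 importer maps species to compounds and honours the
# `reversible` flag.

#' Parse a reaction equation string
#'
#' Accepts forms such as `"2 A + B -> C"`, `"A <-> B"`, with coefficients as
#' integers or fractions (`"1/2 A + ..."`). Compound ids may contain any
#' characters except whitespace and a bare `+` token.
#'
#' @param id reaction id to assign.
#' @param equation the equation string.
#' @param ... passed to [reaction()] (`is_transport`, `is_exchange`).
#' @return a [reaction()] object.
#' @export
parse_reaction_equation <- function(id, equation, ...) {
  arrow <- regmatches(equation, regexpr("<->|<=>|-->|->|=>|=", equation))
  if (length(arrow) == 0) {
    stop("reaction ", id, ": no arrow found in equation: ", equation)
  }
  reversible <- arrow %in% c("<->", "<=>")
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("reaction ", id, ": multiple arrows")
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "(^|\\s)\\+(\\s|$)")[[1]])
    terms <- terms[nzchar(terms)]
    coefs <- numeric(0)
    for (t in terms) {
      toks <- strsplit(t, "\\s+")[[1]]
      coef <- 1
      if (length(toks) > 1 && grepl("^[0-9]+(/[0-9]+)?$", toks[1])) {
        parts <- as.numeric(strsplit(toks[1], "/", fixed = TRUE)[[1]])
        coef <- if (length(parts) == 2) parts[1] / parts[2] else parts[1]
        toks <- toks[-1]
      }
      cid <- paste(toks, collapse = " ")
      coefs <- c(coefs, stats::setNames(coef, cid))
    }
    coefs
  }
  reaction(id, reactants = parse_side(sides[1]),
           products = parse_side(sides[2]), reversible = reversible, ...)
}

#' Render a reaction as an equation string
#' @param rx a [reaction()] object.
#' @return character equation such as `"2 A + B -> C"`.
#' @export
format_reaction_equation <- function(rx) {
  side <- function(v) {
    paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
  }
  paste(side(rx$reactants), if (rx$reversible) "<->" else "->",
        side(rx$products))
}

#' Save a model in a canonical format
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`; `"auto"` picks from the extension.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "json") {
    doc <- list(
      format = "minnut-model",
      version = 1L,
      compounds = lapply(model$compounds, function(cp) {
        list(id = cp$id,
             formula = cp$formula,  # NA serializes as null
             is_class = cp$is_class,
             instances = as.list(cp$instances))
      }),
      reactions = lapply(model$reactions, function(rx) {
        list(id = rx$id,
             reactants = as.list(rx$reactants),
             products = as.list(rx$products),
             reversible = rx$reversible,
             is_transport = rx$is_transport,
             is_exchange = rx$is_exchange)
      }),
      transportables = as.list(model$transportables),
      biomass = as.list(model$biomass),
      auxiliaries = as.list(model$auxiliaries)
    )
    names(doc$compounds) <- NULL
    names(doc$reactions) <- NULL
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# minnut-model\tv1", con)
    for (cp in model$compounds) {
      writeLines(paste("compound", cp$id,
                       ifelse(is.na(cp$formula), "", cp$formula),
                       ifelse(cp$is_class, "class", "instance"),
                       paste(cp$instances, collapse = ","),
                       sep = "\t"), con)
    }
    for (rx in model$reactions) {
      flags <- c(if (rx$is_transport) "transport",
                 if (rx$is_exchange) "exchange")
      writeLines(paste("reaction", rx$id, format_reaction_equation(rx),
                       paste(flags, collapse = ","), sep = "\t"), con)
    }
    for (t in model$transportables) {
      writeLines(paste("transportable", t, sep = "\t"), con)
    }
    for (b in model$biomass) writeLines(paste("biomass", b, sep = "\t"), con)
    for (a in model$auxiliaries) {
      writeLines(paste("auxiliary", a, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Load a model from a canonical (or SBML) file
#'
#' @param path input file.
#' @param format `"json"`, `"tsv"`, `"sbml"`, or `"auto"` (by extension).
#' @param transportables,biomass,auxiliaries optional overrides, mainly for
#'   SBML inputs which carry no such annotations.
#' @return a validated `metabolic_model`, transportable order as listed in
#'   the file.
#' @export
load_model <- function(path, format = c("auto", "json", "tsv", "sbml"),
                       transportables = NULL, biomass = NULL,
                       auxiliaries = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", xml = "sbml", sbml = "sbml", "json")
  }
  model <- switch(format,
                  json = .load_model_json(path),
                  tsv = .load_model_tsv(path),
                  sbml = .load_model_sbml(path))
  if (!is.null(transportables)) model$transportables <- transportables
  if (!is.null(biomass)) model$biomass <- biomass
  if (!is.null(auxiliaries)) model$auxiliaries <- auxiliaries
  metabolic_model(model$compounds, model$reactions, model$transportables,
                  model$biomass, model$auxiliaries)
}

.load_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "minnut-model")) {
    stop("not a minnut-model JSON document: ", path)
  }
  compounds <- lapply(doc$compounds, function(cp) {
    f <- unlist(cp$formula)
    compounds_formula <- if (length(f) != 1 || is.na(f)) NA_character_ else f
    compound(cp$id,
             formula = compounds_formula,
             is_class = isTRUE(cp$is_class),
             instances = unlist(cp$instances) %||% character())
  })
  reactions <- lapply(doc$reactions, function(rx) {
    if (!is.null(rx$equation)) {
      parse_reaction_equation(rx$id, rx$equation,
                              is_transport = isTRUE(rx$is_transport),
                              is_exchange = isTRUE(rx$is_exchange))
    } else {
      reaction(rx$id,
               reactants = unlist(rx$reactants) %||% numeric(),
               products = unlist(rx$products) %||% numeric(),
               reversible = isTRUE(rx$reversible),
               is_transport = isTRUE(rx$is_transport),
               is_exchange = isTRUE(rx$is_exchange))
    }
  })
  list(compounds = compounds, reactions = reactions,
       transportables = unlist(doc$transportables) %||% character(),
       biomass = unlist(doc$biomass) %||% character(),
       auxiliaries = unlist(doc$auxiliaries) %||% character())
}

.load_model_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  compounds <- list()
  reactions <- list()
  transportables <- character()
  biomass <- character()
  auxiliaries <- character()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    rec <- f[1]
    if (rec == "compound") {
      inst <- if (length(f) >= 5 && nzchar(f[5])) {
        strsplit(f[5], ",", fixed = TRUE)[[1]]
      } else character()
      compounds[[length(compounds) + 1L]] <-
        compound(f[2],
                 formula = if (length(f) >= 3 && nzchar(f[3])) f[3]
                           else NA_character_,
                 is_class = length(f) >= 4 && identical(f[4], "class"),
                 instances = inst)
    } else if (rec == "reaction") {
      flags <- if (length(f) >= 4) strsplit(f[4], ",")[[1]] else character()
      reactions[[length(reactions) + 1L]] <-
        parse_reaction_equation(f[2], f[3],
                                is_transport = "transport" %in% flags,
                                is_exchange = "exchange" %in% flags)
    } else if (rec == "transportable") {
      transportables <- c(transportables, f[2])
    } else if (rec == "biomass") {
      biomass <- c(biomass, f[2])
    } else if (rec == "auxiliary") {
      auxiliaries <- c(auxiliaries, f[2])
    } else {
      stop("malformed record at line ", k, " of ", path, ": ", lines[k])
    }
  }
  list(compounds = compounds, reactions = reactions,
       transportables = transportables, biomass = biomass,
       auxiliaries = auxiliaries)
}

.load_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  compounds <- lapply(sp, function(s) {
    compound(xml2::xml_attr(s, "id"))
  })
  rxn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  side <- function(r, which) {
    refs <- xml2::xml_find_all(r, paste0("./", which, "/speciesReference"))
    ids <- xml2::xml_attr(refs, "species")
    st <- xml2::xml_attr(refs, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    stats::setNames(st, ids)
  }
  reactions <- lapply(rxn, function(r) {
    rs <- side(r, "listOfReactants")
    ps <- side(r, "listOfProducts")
    reaction(xml2::xml_attr(r, "id"), reactants = rs, products = ps,
             reversible = identical(xml2::xml_attr(r, "reversible"), "true"),
             is_exchange = length(rs) == 0 || length(ps) == 0)
  })
  list(compounds = compounds, reactions = reactions,
       transportables = character(), biomass = character(),
       auxiliaries = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
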