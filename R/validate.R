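#' Structural validation of a kinetic model
#'
#' Checks the structural well-formedness a merged or hand-built model must
#' satisfy before simulation: unique element ids, resolvable references
#' (species -> compartment, reaction participants -> species, kinetic-law
#' symbols -> declared ids), presence of kinetic laws, positive
#' stoichiometries and nonnegative initial amounts. Problems are reported,
#' not raised.
#'
#' @param model a [kinetic_model].
#' @return a `validation_report`: list with `valid` (TRUE iff no
#'   error-severity issue) and `issues` (data.frame severity/message/element).
#' @export
validate_model <- function(model) {
  issues <- list()
  add <- function(severity, message, element) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, message = message, element = element,
      stringsAsFactors = FALSE)
  }

  ids <- unlist(model_element_ids(model), use.names = FALSE)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add("error", sprintf("duplicate id '%s'", d), d)

  for (sp in model$species) {
    if (!(sp$compartment %in% names(model$compartments))) {
      add("error", sprintf("species '%s' references undeclared compartment '%s'",
                           sp$id, sp$compartment), sp$id)
    }
    if (is.na(sp$initial_amount) || sp$initial_amount < 0) {
      add("error", sprintf("species '%s' has negative or missing initial amount",
                           sp$id), sp$id)
    }
  }

  known <- c(names(model$species), names(model$parameters),
             names(model$compartments), "time", "pi")
  for (rx in model$reactions) {
    for (s in c(rx$reactants$species, rx$products$species, rx$modifiers)) {
      if (!(s %in% names(model$species))) {
        add("error", sprintf("reaction '%s' references undeclared species '%s'",
                             rx$id, s), rx$id)
      }
    }
    if (any(c(rx$reactants$stoichiometry, rx$products$stoichiometry) <= 0)) {
      add("error", sprintf("reaction '%s' has non-positive stoichiometry", rx$id),
          rx$id)
    }
    if (is.null(rx$kinetic_law)) {
      add("error", sprintf("reaction '%s' has no kinetic law", rx$id), rx$id)
    } else {
      for (sym in expr_symbols(rx$kinetic_law)) {
        if (!(sym %in% known)) {
          add("error",
              sprintf("kinetic law of '%s' references undeclared symbol '%s'",
                      rx$id, sym), rx$id)
        }
      }
    }
  }

  for (p in model$parameters) {
    if (is.na(p$value)) {
      add("warning", sprintf("parameter '%s' has no value", p$id), p$id)
    }
  }

  issues <- if (length(issues) == 0) {
    data.frame(severity = character(0), message = character(0),
               element = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
  structure(list(valid = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> valid: %s, %d issue(s)\n", x$valid,
              nrow(x$issues)))
  if (nrow(x$issues) > 0) print(x$issues, row.names = FALSE)
  invisible(x)
}

#' Serialize a validation report as JSON
#' @param report a `validation_report`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
validation_report_json <- function(report, path = NULL) {
  obj <- list(valid = report$valid, issues = report$issues)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
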