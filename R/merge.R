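# Merge engine: build one model from two models and a match set, applying a
# parameter-source policy to the overlap. Overlap elements keep model A's
# ids; model B's exclusive elements are copied (renamed on id collision) and
# their kinetic laws rewritten through the match map.

#' Parameter-source policy for the overlap
#'
#' Decides whose parameter values and initial amounts parameterize the
#' overlap elements of the merged model: model A's or model B's, with
#' per-element overrides. Initial amounts follow the same source as kinetic
#' parameters unless overridden.
#'
#' @param default_source `"A"` or `"B"`.
#' @param per_element named character vector of overrides, names are model A
#'   element ids (the merged ids of overlap elements), values `"A"`/`"B"`.
#' @export
merge_policy <- function(default_source = c("A", "B"), per_element = character(0)) {
  default_source <- match.arg(default_source)
  if (length(per_element) > 0) {
    stopifnot(all(per_element %in% c("A", "B")), !is.null(names(per_element)))
  }
  structure(list(default_source = default_source, per_element = per_element),
            class = "merge_policy")
}

.policy_source <- function(policy, id) {
  if (id %in% names(policy$per_element)) policy$per_element[[id]]
  else policy$default_source
}

#' Merge two models under a match set and a parameter-source policy
#'
#' Every overlap element appears once (with model A's id) carrying the
#' policy-chosen source's parameter values and initial amounts; non-overlap
#' elements are copied unchanged from their original models. Id collisions
#' between unmatched elements are resolved by suffixing the model B copy
#' with `"_B"`. Matched entries flagged `modifier-vs-reactant` or
#' `different-kinetics` require a per-element policy choice; otherwise the
#' merge stops and demands a manual decision. The merged model is validated
#' before it is returned.
#'
#' @param model_a,model_b [kinetic_model] objects with harmonized units.
#' @param matches a `match_set` (after [classify_conflicts()] and manual
#'   editing).
#' @param policy a [merge_policy].
#' @return a `merged_model`: list with `model` (a [kinetic_model]),
#'   `provenance` (named character, `"<class>:<id>"` -> `A-only` / `B-only` /
#'   `overlap`) and `policy_used`.
#' @export
merge_models <- function(model_a, model_b, matches, policy = merge_policy("A")) {
  stopifnot(inherits(matches, "match_set"), inherits(policy, "merge_policy"))

  for (e in matches$entries) {
    # dangling refs fail fast
    model_element(model_a, e$class, e$id_a)
    model_element(model_b, e$class, e$id_b)
    hard <- intersect(e$conflicts$kind, c("modifier-vs-reactant", "different-kinetics"))
    if (length(hard) > 0 && !(e$id_a %in% names(policy$per_element))) {
      stop(sprintf(
        "manual decision required: %s '%s' ~ '%s' is flagged %s; set a per-element policy choice",
        e$class, e$id_a, e$id_b, paste(hard, collapse = "/")), call. = FALSE)
    }
  }

  maps <- lapply(c(compartment = "compartment", species = "species",
                   parameter = "parameter", reaction = "reaction"),
                 function(cl) .entry_map(matches$entries, cl))

  merged <- model_a
  merged$model_id <- paste0(model_a$model_id, "_", model_b$model_id, "_merged")
  merged$name <- sprintf("merge of %s and %s", model_a$name, model_b$name)

  provenance <- character(0)
  for (cl in names(maps)) {
    slot <- switch(cl, species = "species", reaction = "reactions",
                   parameter = "parameters", compartment = "compartments")
    for (id in names(model_a[[slot]])) {
      provenance[[paste0(cl, ":", id)]] <-
        if (id %in% unname(maps[[cl]])) "overlap" else "A-only"
    }
  }

  # apply policy to overlap elements (values from B where chosen)
  for (e in matches$entries) {
    src <- .policy_source(policy, e$id_a)
    if (src != "B") next
    if (e$class == "species") {
      merged$species[[e$id_a]]$initial_amount <-
        model_b$species[[e$id_b]]$initial_amount
    } else if (e$class == "parameter") {
      merged$parameters[[e$id_a]]$value <- model_b$parameters[[e$id_b]]$value
    } else if (e$class == "compartment") {
      merged$compartments[[e$id_a]]$size <- model_b$compartments[[e$id_b]]$size
    }
  }

  # copy model B's exclusive elements, renaming on id collision
  taken <- function() unlist(model_element_ids(merged), use.names = FALSE)
  rename <- character(0)  # B id -> merged id, for all B elements
  for (cl in c("compartment", "species", "parameter", "reaction")) {
    for (id in names(maps[[cl]])) rename[[id]] <- maps[[cl]][[id]]
  }
  fresh_id <- function(id) {
    if (!(id %in% taken())) return(id)
    cand <- paste0(id, "_B")
    while (cand %in% taken()) cand <- paste0(cand, "_B")
    cand
  }

  for (id in setdiff(names(model_b$compartments), names(maps$compartment))) {
    nid <- fresh_id(id)
    el <- model_b$compartments[[id]]
    el$id <- nid
    merged$compartments[[nid]] <- el
    rename[[id]] <- nid
    provenance[[paste0("compartment:", nid)]] <- "B-only"
  }
  for (id in setdiff(names(model_b$species), names(maps$species))) {
    nid <- fresh_id(id)
    el <- model_b$species[[id]]
    el$id <- nid
    el$compartment <- rename[[el$compartment]] %||% el$compartment
    merged$species[[nid]] <- el
    rename[[id]] <- nid
    provenance[[paste0("species:", nid)]] <- "B-only"
  }
  for (id in setdiff(names(model_b$parameters), names(maps$parameter))) {
    nid <- fresh_id(id)
    el <- model_b$parameters[[id]]
    el$id <- nid
    merged$parameters[[nid]] <- el
    rename[[id]] <- nid
    provenance[[paste0("parameter:", nid)]] <- "B-only"
  }
  for (id in setdiff(names(model_b$reactions), names(maps$reaction))) {
    nid <- fresh_id(id)
    el <- model_b$reactions[[id]]
    el$id <- nid
    tr <- function(x) unname(vapply(x, function(s) rename[[s]] %||% s, character(1)))
    if (nrow(el$reactants) > 0) el$reactants$species <- tr(el$reactants$species)
    if (nrow(el$products) > 0) el$products$species <- tr(el$products$species)
    if (length(el$modifiers) > 0) el$modifiers <- tr(el$modifiers)
    if (!is.null(el$kinetic_law)) {
      el$kinetic_law <- substitute_symbols(el$kinetic_law, rename)
    }
    # globalized local parameters follow their owning reaction's new id
    el$local_parameters <- tr(el$local_parameters)
    merged$reactions[[nid]] <- el
    for (lp in el$local_parameters) {
      if (lp %in% names(merged$parameters)) {
        merged$parameters[[lp]]$origin_reaction <- nid
      }
    }
    rename[[id]] <- nid
    provenance[[paste0("reaction:", nid)]] <- "B-only"
  }

  rep <- validate_model(merged)
  if (!rep$valid) {
    stop(sprintf("merged model does not validate:\n%s",
                 paste(rep$issues$message, collapse = "\n")), call. = FALSE)
  }
  structure(list(model = merged, provenance = provenance, policy_used = policy,
                 matches = matches),
            class = "merged_model")
}

#' @export
print.merged_model <- function(x, ...) {
  pv <- table(x$provenance)
  cat(sprintf("<merged_model> %s\n", x$model$model_id))
  cat(sprintf("  provenance: %s\n",
              paste(sprintf("%s: %d", names(pv), pv), collapse = ", ")))
  invisible(x)
}

#' Write merge provenance as a JSON sidecar
#' @param merged a `merged_model`; @param path output path.
#' @export
write_provenance <- function(merged, path) {
  jsonlite::write_json(as.list(merged$provenance), path, auto_unbox = TRUE)
  invisible(path)
}
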