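# Semantic identity of model elements: MIRIAM URIs + SBO term + a structured
# name. Database annotations alone cannot distinguish, e.g., a protein
# phosphorylated on two different residues, so display names are parsed
# against a structured naming convention and take part in the equality
# relation.

#' Parse a structured element name
#'
#' The naming convention encodes what databases cannot: a base name, followed
#' by underscore-separated modification tokens (modification-type letters +
#' residue and position, e.g. `"_pT188"`), complexes as components joined by
#' `":"` with `"×n"` counts, and an optional compartment tag after
#' `"@"`. Examples: `"ERK_pT188"`, `"Shc:Grb2:SOS"`, `"STAT5×2_pY694@nuc"`.
#'
#' Parsing then serializing (via [format_name_record()]) is idempotent.
#'
#' @param name display name of a model element.
#' @return a `name_record`: list with `base_name`, `components`
#'   (data.frame name/count), `modifications` (sorted character vector
#'   `"type:site"`), `compartment_tag` (or `NA`).
#' @export
parse_name_record <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  compartment_tag <- NA_character_
  if (grepl("@", name, fixed = TRUE)) {
    at <- regexpr("@[^@]*$", name)
    compartment_tag <- substring(name, at + 1L)
    name <- substring(name, 1L, at - 1L)
  }
  tokens <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(tokens) == 0) tokens <- ""
  is_mod <- grepl("^[a-z]+[A-Z][0-9]+$", tokens)
  is_mod[1] <- FALSE  # the first token is always part of the base name
  mods <- character(0)
  for (tok in tokens[is_mod]) {
    m <- regmatches(tok, regexec("^([a-z]+)([A-Z][0-9]+)$", tok))[[1]]
    mods <- c(mods, paste0(m[2], ":", m[3]))
  }
  base <- paste(tokens[!is_mod], collapse = "_")
  comp_tokens <- strsplit(base, ":", fixed = TRUE)[[1]]
  comps <- lapply(comp_tokens, function(ct) {
    m <- regmatches(ct, regexec("^(.*)×([0-9]+)$", ct))[[1]]
    if (length(m) == 3) {
      list(name = m[2], count = as.integer(m[3]))
    } else {
      list(name = ct, count = 1L)
    }
  })
  components <- data.frame(
    name = vapply(comps, `[[`, character(1), "name"),
    count = vapply(comps, `[[`, integer(1), "count"),
    stringsAsFactors = FALSE)
  components <- components[order(components$name), , drop = FALSE]
  rownames(components) <- NULL
  structure(list(base_name = base,
                 components = components,
                 modifications = sort(mods),
                 compartment_tag = compartment_tag),
            class = "name_record")
}

#' Serialize a structured name record
#' @param record a `name_record` from [parse_name_record()].
#' @return the canonical display name (components sorted, modifications sorted).
#' @export
format_name_record <- function(record) {
  comps <- record$components
  parts <- ifelse(comps$count > 1L,
                  paste0(comps$name, "×", comps$count), comps$name)
  out <- paste(parts, collapse = ":")
  if (length(record$modifications) > 0) {
    toks <- sub(":", "", record$modifications, fixed = TRUE)
    out <- paste(c(out, toks), collapse = "_")
  }
  if (!is.na(record$compartment_tag)) {
    out <- paste0(out, "@", record$compartment_tag)
  }
  out
}

#' Extract the semantic identity of a model element
#'
#' Combines the element's MIRIAM resource URIs, its SBO term and the
#' structured name parsed from its display name. An element with no
#' annotation yields an identity carrying only the structured name.
#' Extraction is pure: repeated calls on the same element agree.
#'
#' @param element an element record (from a [kinetic_model]'s `species`,
#'   `reactions`, `parameters` or `compartments` list).
#' @return an `element_identity`: list with `rdf_uris` (sorted), `sbo_term`
#'   and `structured_name` (a `name_record`).
#' @export
extract_identity <- function(element) {
  uris <- .norm_uris(element$uris %||% character(0))
  uris <- uris[order(unname(uris))]
  nm <- element$name
  if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- element$id
  structure(list(rdf_uris = uris,
                 sbo_term = element$sbo %||% NA_character_,
                 structured_name = parse_name_record(nm)),
            class = "element_identity")
}

#' Equality of two element identities
#'
#' Deterministic, symmetric, reflexive. URI-set equality is necessary when
#' both sides carry URIs; the structured name is always required to be
#' compatible (equal base components and modification sets) and is the sole
#' criterion when either side has no URIs. Compartment tags are excluded
#' from the comparison: species whose identities agree except for the
#' compartment are matched and flagged downstream. SBO terms, when present
#' on both sides, must not disagree.
#'
#' @param a,b `element_identity` objects.
#' @return TRUE or FALSE.
#' @export
identity_equal <- function(a, b) {
  stopifnot(inherits(a, "element_identity"), inherits(b, "element_identity"))
  if (!is.na(a$sbo_term) && !is.na(b$sbo_term) && a$sbo_term != b$sbo_term) {
    return(FALSE)
  }
  if (length(a$rdf_uris) > 0 && length(b$rdf_uris) > 0) {
    if (!setequal(unname(a$rdf_uris), unname(b$rdf_uris))) return(FALSE)
    # URI-identified elements: display names may be aliases (ERK vs ERK2),
    # but names must not CONTRADICT the identity - differing modification
    # sets, or differing complex composition, veto the match
    na <- a$structured_name; nb <- b$structured_name
    if (!identical(na$modifications, nb$modifications)) return(FALSE)
    complexish <- function(n) nrow(n$components) > 1 || any(n$components$count > 1)
    if (complexish(na) && complexish(nb) &&
        !identical(na$components, nb$components)) {
      return(FALSE)
    }
    return(TRUE)
  }
  .names_compatible(a$structured_name, b$structured_name)
}

.names_compatible <- function(na, nb) {
  identical(na$components, nb$components) &&
    identical(na$modifications, nb$modifications)
}

#' Near-match classification of two species identities
#'
#' For URI-equal species whose structured names disagree: returns
#' `"modification-site"` when both carry modifications but on different
#' sites, `"different-state"` when exactly one side is unmodified, and
#' `NA` otherwise.
#' @noRd
identity_near_conflict <- function(a, b) {
  if (length(a$rdf_uris) == 0 || length(b$rdf_uris) == 0) return(NA_character_)
  if (!setequal(unname(a$rdf_uris), unname(b$rdf_uris))) return(NA_character_)
  if (.names_compatible(a$structured_name, b$structured_name)) return(NA_character_)
  if (!identical(a$structured_name$components, b$structured_name$components)) {
    return(NA_character_)
  }
  ma <- a$structured_name$modifications
  mb <- b$structured_name$modifications
  if (length(ma) == 0 || length(mb) == 0) return("different-state")
  "modification-site"
}

#' @export
print.element_identity <- function(x, ...) {
  cat(sprintf("<element_identity> name: %s\n", format_name_record(x$structured_name)))
  if (length(x$rdf_uris) > 0) {
    cat(sprintf("  %s: %s\n", names(x$rdf_uris), unname(x$rdf_uris)))
  }
  if (!is.na(x$sbo_term)) cat(sprintf("  SBO: %s\n", x$sbo_term))
  invisible(x)
}
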