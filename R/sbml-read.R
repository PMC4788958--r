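#' Read an SBML Level 2/3 model
#'
#' Parses a plain kinetic ODE model from SBML. Reaction-local parameters are
#' globalized with a `<reaction>__<id>` prefix so that merge policies and
#' fitting can address every parameter uniformly; `functionDefinition`s are
#' inlined into the kinetic laws. Constructs outside the plain-ODE subset
#' (events, rules, constraints, initial assignments, time delays) are
#' rejected with an "unsupported construct" error rather than silently
#' ignored.
#'
#' @param path path to an SBML file (Level 2 or 3).
#' @return a [kinetic_model].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("non-SBML content: %s is not well-formed XML (%s)",
                 path, conditionMessage(e)), call. = FALSE)
  })
  root <- xml2::xml_ns_strip(doc)
  if (xml2::xml_name(root) != "sbml") {
    stop(sprintf("non-SBML content: root element is <%s>, expected <sbml>",
                 xml2::xml_name(root)), call. = FALSE)
  }
  level <- as.integer(xml2::xml_attr(root, "level"))
  version <- as.integer(xml2::xml_attr(root, "version"))
  if (is.na(level) || !level %in% c(2L, 3L)) {
    stop(sprintf("unsupported SBML level: %s (need 2 or 3)",
                 xml2::xml_attr(root, "level")), call. = FALSE)
  }
  mnode <- xml2::xml_find_first(root, "./model")
  if (inherits(mnode, "xml_missing")) {
    stop("non-SBML content: no <model> element", call. = FALSE)
  }

  .reject_unsupported(mnode)

  mid <- xml2::xml_attr(mnode, "id")
  if (is.na(mid)) mid <- tools::file_path_sans_ext(basename(path))
  model <- kinetic_model(mid, name = xml2::xml_attr(mnode, "name") %||% mid,
                         level = level, version = if (is.na(version)) 1L else version)

  model$units <- .read_unit_definitions(mnode)
  model$unit_roles <- .read_unit_roles(mnode, model$units, level)

  funs <- .read_function_definitions(mnode)

  for (cn in xml2::xml_find_all(mnode, "./listOfCompartments/compartment")) {
    id <- xml2::xml_attr(cn, "id")
    size <- as.numeric(xml2::xml_attr(cn, "size"))
    if (is.na(size)) size <- 1
    model$compartments[[id]] <- list(
      id = id, name = xml2::xml_attr(cn, "name") %||% id, size = size,
      units = xml2::xml_attr(cn, "units"),
      constant = !identical(xml2::xml_attr(cn, "constant"), "false"),
      sbo = xml2::xml_attr(cn, "sboTerm"), uris = .read_annotation_uris(cn))
  }

  for (sn in xml2::xml_find_all(mnode, "./listOfSpecies/species")) {
    id <- xml2::xml_attr(sn, "id")
    conc <- as.numeric(xml2::xml_attr(sn, "initialConcentration"))
    if (is.na(conc)) {
      amt <- as.numeric(xml2::xml_attr(sn, "initialAmount"))
      if (!is.na(amt)) {
        csize <- model$compartments[[xml2::xml_attr(sn, "compartment")]]$size %||% 1
        conc <- amt / csize
      } else {
        conc <- 0
      }
    }
    model$species[[id]] <- list(
      id = id, name = xml2::xml_attr(sn, "name") %||% id,
      compartment = xml2::xml_attr(sn, "compartment"),
      initial_amount = conc,
      boundary = identical(xml2::xml_attr(sn, "boundaryCondition"), "true"),
      constant = identical(xml2::xml_attr(sn, "constant"), "true"),
      sbo = xml2::xml_attr(sn, "sboTerm"), uris = .read_annotation_uris(sn))
  }

  for (pn in xml2::xml_find_all(mnode, "./listOfParameters/parameter")) {
    id <- xml2::xml_attr(pn, "id")
    model$parameters[[id]] <- list(
      id = id, name = xml2::xml_attr(pn, "name") %||% id,
      value = as.numeric(xml2::xml_attr(pn, "value")),
      units = xml2::xml_attr(pn, "units"),
      constant = !identical(xml2::xml_attr(pn, "constant"), "false"),
      origin_reaction = NA_character_,
      sbo = xml2::xml_attr(pn, "sboTerm"), uris = .read_annotation_uris(pn))
  }

  for (rn in xml2::xml_find_all(mnode, "./listOfReactions/reaction")) {
    model <- .read_reaction(model, rn, funs)
  }

  model
}

.reject_unsupported <- function(mnode) {
  checks <- list(
    c("./listOfEvents/event", "events"),
    c("./listOfRules/algebraicRule", "algebraic rules"),
    c("./listOfRules/assignmentRule", "assignment rules"),
    c("./listOfRules/rateRule", "rate rules"),
    c("./listOfConstraints/constraint", "constraints"),
    c("./listOfInitialAssignments/initialAssignment", "initial assignments"))
  for (ch in checks) {
    if (length(xml2::xml_find_all(mnode, ch[1])) > 0) {
      stop(sprintf("unsupported construct: %s", ch[2]), call. = FALSE)
    }
  }
}

.read_function_definitions <- function(mnode) {
  funs <- list()
  for (fn in xml2::xml_find_all(mnode, "./listOfFunctionDefinitions/functionDefinition")) {
    id <- xml2::xml_attr(fn, "id")
    math <- xml2::xml_find_first(fn, "./math")
    lam <- mathml_to_expr(math)
    if (!is.list(lam) || is.null(lam$args)) {
      stop(sprintf("functionDefinition '%s' does not contain a lambda", id),
           call. = FALSE)
    }
    funs[[id]] <- lam
  }
  funs
}

.read_reaction <- function(model, rn, funs) {
  rid <- xml2::xml_attr(rn, "id")
  part <- function(xpath) {
    refs <- xml2::xml_find_all(rn, xpath)
    data.frame(
      species = vapply(refs, function(x) xml2::xml_attr(x, "species"), character(1)),
      stoichiometry = vapply(refs, function(x) {
        s <- as.numeric(xml2::xml_attr(x, "stoichiometry"))
        if (is.na(s)) 1 else s
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  mods <- vapply(xml2::xml_find_all(rn, "./listOfModifiers/modifierSpeciesReference"),
                 function(x) xml2::xml_attr(x, "species"), character(1))

  kl <- xml2::xml_find_first(rn, "./kineticLaw")
  law <- NULL
  local_ids <- character(0)
  if (!inherits(kl, "xml_missing")) {
    lp_nodes <- c(xml2::xml_find_all(kl, "./listOfParameters/parameter"),
                  xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter"))
    rename <- character(0)
    for (pn in lp_nodes) {
      lid <- xml2::xml_attr(pn, "id")
      gid <- paste0(rid, "__", lid)
      if (gid %in% names(model$parameters)) {
        stop(sprintf("duplicate id after local-parameter globalization: '%s'", gid),
             call. = FALSE)
      }
      model$parameters[[gid]] <- list(
        id = gid, name = xml2::xml_attr(pn, "name") %||% lid,
        value = as.numeric(xml2::xml_attr(pn, "value")),
        units = xml2::xml_attr(pn, "units"), constant = TRUE,
        origin_reaction = rid,
        sbo = xml2::xml_attr(pn, "sboTerm"), uris = .read_annotation_uris(pn))
      rename[[lid]] <- gid
      local_ids <- c(local_ids, gid)
    }
    math <- xml2::xml_find_first(kl, "./math")
    if (!inherits(math, "xml_missing")) {
      law <- mathml_to_expr(math)
      law <- inline_function_calls(law, funs)
      law <- substitute_symbols(law, rename)
    }
  }

  model$reactions[[rid]] <- list(
    id = rid, name = xml2::xml_attr(rn, "name") %||% rid,
    reversible = identical(xml2::xml_attr(rn, "reversible"), "true"),
    reactants = part("./listOfReactants/speciesReference"),
    products = part("./listOfProducts/speciesReference"),
    modifiers = mods,
    kinetic_law = law,
    local_parameters = local_ids,
    sbo = xml2::xml_attr(rn, "sboTerm"), uris = .read_annotation_uris(rn))
  model
}

#' Collect MIRIAM resource URIs from an element's RDF annotation
#'
#' Returns a named character vector: values are resource URIs, names the
#' BioModels qualifier of the enclosing relation element (e.g. `"is"`,
#' `"isVersionOf"`). A malformed RDF block yields a warning and is skipped.
#' @noRd
.read_annotation_uris <- function(node) {
  ann <- xml2::xml_find_first(node, "./annotation")
  if (inherits(ann, "xml_missing")) return(character(0))
  out <- character(0)
  res <- tryCatch({
    # namespace prefixes inside annotations are not resolvable after
    # xml_ns_strip(), so navigate by local names
    descs <- xml2::xml_find_all(
      ann, ".//*[local-name()='RDF']/*[local-name()='Description']")
    for (d in descs) {
      for (qual in xml2::xml_find_all(d, "./*")) {
        qname <- xml2::xml_name(qual)
        lis <- xml2::xml_find_all(qual, ".//*[local-name()='li']")
        for (li in lis) {
          attrs <- xml2::xml_attrs(li)
          hit <- attrs[grepl("(^|:)resource$", names(attrs))]
          if (length(hit) >= 1) {
            out <- c(out, setNames(unname(hit[1]), qname))
          }
        }
      }
    }
    TRUE
  }, error = function(e) {
    warning(sprintf("malformed RDF annotation skipped: %s", conditionMessage(e)),
            call. = FALSE)
    FALSE
  })
  out
}

.read_unit_definitions <- function(mnode) {
  units <- list()
  for (ud in xml2::xml_find_all(mnode, "./listOfUnitDefinitions/unitDefinition")) {
    id <- xml2::xml_attr(ud, "id")
    parts <- lapply(xml2::xml_find_all(ud, "./listOfUnits/unit"), function(u) {
      list(kind = xml2::xml_attr(u, "kind"),
           exponent = {
             e <- as.numeric(xml2::xml_attr(u, "exponent")); if (is.na(e)) 1 else e
           },
           scale = {
             s <- as.numeric(xml2::xml_attr(u, "scale")); if (is.na(s)) 0 else s
           },
           multiplier = {
             m <- as.numeric(xml2::xml_attr(u, "multiplier")); if (is.na(m)) 1 else m
           })
    })
    units[[id]] <- parts
  }
  units
}

.read_unit_roles <- function(mnode, units, level) {
  roles <- list(substance = "mole", time = "second", volume = "litre")
  if (level >= 3L) {
    for (role in c("substance", "time", "volume")) {
      attr_name <- paste0(role, "Units")
      v <- xml2::xml_attr(mnode, attr_name)
      if (!is.na(v)) roles[[role]] <- v
    }
  } else {
    # L2: redefining the built-in unit ids overrides the defaults
    for (role in c("substance", "time", "volume")) {
      if (role %in% names(units)) roles[[role]] <- role
    }
  }
  roles
}
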