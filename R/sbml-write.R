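#' Write a kinetic model as SBML
#'
#' Serializes a [kinetic_model] to SBML at the model's own level/version
#' (L2V4 or L3V1/L3V2). Globalized reaction-local parameters are written back
#' as local parameters of their owning reaction; element annotations are
#' emitted as MIRIAM RDF blocks and `sboTerm` attributes. The writer is the
#' inverse of [load_model()]: re-loading the written file reproduces the
#' model element for element.
#'
#' @param model a [kinetic_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  l3 <- model$level >= 3L
  ns <- if (l3) {
    sprintf("http://www.sbml.org/sbml/level3/version%d/core", model$version)
  } else {
    sprintf("http://www.sbml.org/sbml/level%d/version%d", model$level, model$version)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"%d\" version=\"%d\">", ns,
            model$level, model$version),
    sprintf("  <model id=\"%s\" name=\"%s\"%s>", .xml_escape(model$model_id),
            .xml_escape(model$name),
            if (l3) .l3_role_attrs(model) else "")
  )

  if (length(model$units) > 0) {
    out <- c(out, "    <listOfUnitDefinitions>")
    for (id in names(model$units)) {
      out <- c(out, sprintf("      <unitDefinition id=\"%s\">", .xml_escape(id)),
               "        <listOfUnits>")
      for (u in model$units[[id]]) {
        out <- c(out, sprintf(
          "          <unit kind=\"%s\" exponent=\"%s\" scale=\"%s\" multiplier=\"%s\"/>",
          u$kind, .fmt_num(u$exponent), .fmt_num(u$scale), .fmt_num(u$multiplier)))
      }
      out <- c(out, "        </listOfUnits>", "      </unitDefinition>")
    }
    out <- c(out, "    </listOfUnitDefinitions>")
  }

  if (length(model$compartments) > 0) {
    out <- c(out, "    <listOfCompartments>")
    for (cm in model$compartments) {
      attrs <- sprintf("id=\"%s\" name=\"%s\" size=\"%s\"%s%s",
                       .xml_escape(cm$id), .xml_escape(cm$name), .fmt_num(cm$size),
                       if (l3) " constant=\"true\"" else "",
                       .sbo_attr(cm$sbo))
      out <- c(out, .element_xml("compartment", attrs, cm, indent = "      "))
    }
    out <- c(out, "    </listOfCompartments>")
  }

  if (length(model$species) > 0) {
    out <- c(out, "    <listOfSpecies>")
    for (sp in model$species) {
      attrs <- sprintf(paste0(
        "id=\"%s\" name=\"%s\" compartment=\"%s\" initialConcentration=\"%s\"",
        " boundaryCondition=\"%s\" constant=\"%s\"%s%s"),
        .xml_escape(sp$id), .xml_escape(sp$name), sp$compartment,
        .fmt_num(sp$initial_amount),
        tolower(sp$boundary), tolower(sp$constant),
        if (l3) " hasOnlySubstanceUnits=\"false\"" else "",
        .sbo_attr(sp$sbo))
      out <- c(out, .element_xml("species", attrs, sp, indent = "      "))
    }
    out <- c(out, "    </listOfSpecies>")
  }

  globals <- Filter(function(p) is.na(p$origin_reaction), model$parameters)
  if (length(globals) > 0) {
    out <- c(out, "    <listOfParameters>")
    for (p in globals) {
      attrs <- sprintf("id=\"%s\" name=\"%s\" value=\"%s\"%s%s%s",
                       .xml_escape(p$id), .xml_escape(p$name), .fmt_num(p$value),
                       if (!is.na(p$units)) sprintf(" units=\"%s\"", p$units) else "",
                       if (l3) " constant=\"true\"" else "",
                       .sbo_attr(p$sbo))
      out <- c(out, .element_xml("parameter", attrs, p, indent = "      "))
    }
    out <- c(out, "    </listOfParameters>")
  }

  if (length(model$reactions) > 0) {
    out <- c(out, "    <listOfReactions>")
    for (rx in model$reactions) {
      out <- c(out, .reaction_xml(model, rx, l3))
    }
    out <- c(out, "    </listOfReactions>")
  }

  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

.l3_role_attrs <- function(model) {
  paste0(sprintf(" substanceUnits=\"%s\"", model$unit_roles$substance),
         sprintf(" timeUnits=\"%s\"", model$unit_roles$time),
         sprintf(" volumeUnits=\"%s\"", model$unit_roles$volume))
}

.sbo_attr <- function(sbo) {
  if (is.null(sbo) || is.na(sbo)) "" else sprintf(" sboTerm=\"%s\"", sbo)
}

.annotation_xml <- function(el, indent) {
  if (length(el$uris) == 0) return(character(0))
  quals <- unique(names(el$uris) %||% rep("is", length(el$uris)))
  body <- character(0)
  for (q in quals) {
    uris <- el$uris[names(el$uris) == q]
    body <- c(body,
              sprintf("%s      <bqbiol:%s>", indent, q),
              sprintf("%s        <rdf:Bag>", indent),
              sprintf("%s          <rdf:li rdf:resource=\"%s\"/>", indent,
                      .xml_escape(unname(uris))),
              sprintf("%s        </rdf:Bag>", indent),
              sprintf("%s      </bqbiol:%s>", indent, q))
  }
  c(sprintf("%s<annotation>", indent),
    sprintf(paste0("%s  <rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/",
                   "22-rdf-syntax-ns#\" xmlns:bqbiol=\"http://biomodels.net/",
                   "biology-qualifiers/\">"), indent),
    sprintf("%s    <rdf:Description rdf:about=\"#%s\">", indent, .xml_escape(el$id)),
    body,
    sprintf("%s    </rdf:Description>", indent),
    sprintf("%s  </rdf:RDF>", indent),
    sprintf("%s</annotation>", indent))
}

.element_xml <- function(tag, attrs, el, indent) {
  ann <- .annotation_xml(el, paste0(indent, "  "))
  if (length(ann) == 0) {
    sprintf("%s<%s %s/>", indent, tag, attrs)
  } else {
    c(sprintf("%s<%s %s>", indent, tag, attrs), ann,
      sprintf("%s</%s>", indent, tag))
  }
}

.reaction_xml <- function(model, rx, l3) {
  ind <- "      "
  out <- sprintf("%s<reaction id=\"%s\" name=\"%s\" reversible=\"%s\"%s%s>",
                 ind, .xml_escape(rx$id), .xml_escape(rx$name),
                 tolower(rx$reversible),
                 if (l3) " fast=\"false\"" else "", .sbo_attr(rx$sbo))
  # L3V2 dropped the 'fast' attribute
  if (l3 && model$version >= 2L) {
    out <- sub(" fast=\"false\"", "", out, fixed = TRUE)
  }
  out <- c(out, .annotation_xml(rx, paste0(ind, "  ")))
  refs <- function(df, list_tag, ref_tag) {
    if (nrow(df) == 0) return(character(0))
    c(sprintf("%s  <%s>", ind, list_tag),
      sprintf("%s    <%s species=\"%s\" stoichiometry=\"%s\"%s/>", ind, ref_tag,
              df$species, .fmt_num(df$stoichiometry),
              if (l3) " constant=\"true\"" else ""),
      sprintf("%s  </%s>", ind, list_tag))
  }
  out <- c(out,
           refs(rx$reactants, "listOfReactants", "speciesReference"),
           refs(rx$products, "listOfProducts", "speciesReference"))
  if (length(rx$modifiers) > 0) {
    out <- c(out, sprintf("%s  <listOfModifiers>", ind),
             sprintf("%s    <modifierSpeciesReference species=\"%s\"/>", ind,
                     rx$modifiers),
             sprintf("%s  </listOfModifiers>", ind))
  }
  if (!is.null(rx$kinetic_law)) {
    law <- rx$kinetic_law
    lp <- rx$local_parameters
    rename <- setNames(sub(paste0("^", rx$id, "__"), "", lp), lp)
    law <- substitute_symbols(law, rename)
    out <- c(out, sprintf("%s  <kineticLaw>", ind),
             sprintf("%s    <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
                     ind),
             sprintf("%s      %s", ind, expr_to_mathml(law)),
             sprintf("%s    </math>", ind))
    if (length(lp) > 0) {
      list_tag <- if (l3) "listOfLocalParameters" else "listOfParameters"
      ref_tag <- if (l3) "localParameter" else "parameter"
      out <- c(out, sprintf("%s    <%s>", ind, list_tag))
      for (gid in lp) {
        p <- model$parameters[[gid]]
        out <- c(out, sprintf("%s      <%s id=\"%s\" name=\"%s\" value=\"%s\"%s%s/>",
                              ind, ref_tag, .xml_escape(rename[[gid]]),
                              .xml_escape(p$name), .fmt_num(p$value),
                              if (!is.na(p$units)) sprintf(" units=\"%s\"", p$units) else "",
                              .sbo_attr(p$sbo)))
      }
      out <- c(out, sprintf("%s    </%s>", ind, list_tag))
    }
    out <- c(out, sprintf("%s  </kineticLaw>", ind))
  }
  c(out, sprintf("%s</reaction>", ind))
}
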