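#' Kinetic ODE model container
#'
#' A `kinetic_model` holds everything needed to simulate a plain kinetic ODE
#' model: compartments, species (as concentrations), global and
#' reaction-local parameters (local parameters are globalized with a
#' `<reaction>__<parameter>` id at load time), reactions with kinetic-law
#' expressions, and the unit system (substance / time / volume roles).
#'
#' Models are usually read from SBML with [load_model()]; the constructor and
#' the `km_add_*` builders exist so that fixture models can be assembled
#' programmatically in tests and examples.
#'
#' @param model_id identifier of the model.
#' @param name human-readable name; defaults to `model_id`.
#' @param level,version SBML level/version used when the model is written.
#' @return an object of class `kinetic_model`.
#' @export
kinetic_model <- function(model_id, name = model_id, level = 3L, version = 2L) {
  stopifnot(is.character(model_id), nchar(model_id) > 0)
  structure(list(
    model_id = model_id,
    name = name,
    level = as.integer(level),
    version = as.integer(version),
    compartments = list(),
    species = list(),
    parameters = list(),
    reactions = list(),
    units = list(),
    unit_roles = list(substance = "mole", time = "second", volume = "litre"),
    notes = character(0)
  ), class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %s (SBML L%dV%d)\n", x$model_id, x$level, x$version))
  cat(sprintf("  compartments: %d  species: %d  parameters: %d  reactions: %d\n",
              length(x$compartments), length(x$species),
              length(x$parameters), length(x$reactions)))
  invisible(x)
}

.check_new_id <- function(model, id) {
  if (id %in% c(names(model$species), names(model$parameters),
                names(model$reactions), names(model$compartments))) {
    stop(sprintf("duplicate id '%s'", id), call. = FALSE)
  }
}

#' @rdname kinetic_model
#' @param model a `kinetic_model`.
#' @param id element id (SBML SId).
#' @param size compartment size in volume units.
#' @param uris named character vector of MIRIAM resource URIs (names are
#'   qualifiers such as `"bqbiol:is"`).
#' @param sbo SBO term (e.g. `"SBO:0000252"`) or `NA`.
#' @export
km_add_compartment <- function(model, id, size = 1, name = id,
                               uris = character(0), sbo = NA_character_) {
  .check_new_id(model, id)
  model$compartments[[id]] <- list(id = id, name = name, size = size,
                                   units = NA_character_, constant = TRUE,
                                   sbo = sbo, uris = .norm_uris(uris))
  model
}

#' @rdname kinetic_model
#' @param initial_amount nonnegative initial concentration (model units).
#' @param compartment id of the containing compartment.
#' @param boundary,constant SBML boundaryCondition / constant flags. A species
#'   with both flags set is treated as a step-stimulus input candidate by
#'   [simulate_model()].
#' @export
km_add_species <- function(model, id, initial_amount, compartment,
                           name = id, boundary = FALSE, constant = FALSE,
                           uris = character(0), sbo = NA_character_) {
  .check_new_id(model, id)
  if (is.na(initial_amount) || initial_amount < 0) {
    stop(sprintf("species '%s': initial_amount must be >= 0", id), call. = FALSE)
  }
  model$species[[id]] <- list(id = id, name = name, compartment = compartment,
                              initial_amount = initial_amount,
                              boundary = boundary, constant = constant,
                              sbo = sbo, uris = .norm_uris(uris))
  model
}

#' @rdname kinetic_model
#' @param value parameter value.
#' @param units optional unit-definition id (or base kind) of the parameter;
#'   used by [harmonize_units()] to decide convertibility.
#' @param origin_reaction for globalized reaction-local parameters, the id of
#'   the owning reaction; `NA` for true globals.
#' @export
km_add_parameter <- function(model, id, value, name = id, units = NA_character_,
                             origin_reaction = NA_character_,
                             uris = character(0), sbo = NA_character_) {
  .check_new_id(model, id)
  model$parameters[[id]] <- list(id = id, name = name, value = value,
                                 units = units, constant = TRUE,
                                 origin_reaction = origin_reaction,
                                 sbo = sbo, uris = .norm_uris(uris))
  model
}

#' @rdname kinetic_model
#' @param reactants,products named numeric vectors of stoichiometries
#'   (names are species ids), e.g. `c(A = 1)`.
#' @param modifiers character vector of modifier species ids.
#' @param kinetic_law an R expression (see [str2lang()]) or a string giving
#'   the rate in substance/time units.
#' @param reversible SBML reversible flag (informational).
#' @export
km_add_reaction <- function(model, id, reactants, products,
                            modifiers = character(0), kinetic_law,
                            name = id, reversible = FALSE,
                            uris = character(0), sbo = NA_character_) {
  .check_new_id(model, id)
  as_part <- function(x) {
    if (length(x) == 0) {
      return(data.frame(species = character(0), stoichiometry = numeric(0),
                        stringsAsFactors = FALSE))
    }
    if (is.character(x)) x <- setNames(rep(1, length(x)), x)
    data.frame(species = names(x), stoichiometry = as.numeric(x),
               stringsAsFactors = FALSE)
  }
  if (is.character(kinetic_law)) kinetic_law <- str2lang(kinetic_law)
  model$reactions[[id]] <- list(id = id, name = name, reversible = reversible,
                                reactants = as_part(reactants),
                                products = as_part(products),
                                modifiers = modifiers,
                                kinetic_law = kinetic_law,
                                local_parameters = character(0),
                                sbo = sbo, uris = .norm_uris(uris))
  model
}

#' All element ids of a model, grouped by class
#' @noRd
model_element_ids <- function(model) {
  list(compartment = names(model$compartments),
       species = names(model$species),
       parameter = names(model$parameters),
       reaction = names(model$reactions))
}

#' Fetch an element record by class and id
#' @noRd
model_element <- function(model, class, id) {
  slot <- switch(class,
                 species = "species", reaction = "reactions",
                 parameter = "parameters", compartment = "compartments",
                 stop(sprintf("unknown element class '%s'", class), call. = FALSE))
  el <- model[[slot]][[id]]
  if (is.null(el)) {
    stop(sprintf("no %s with id '%s' in model '%s'", class, id, model$model_id),
         call. = FALSE)
  }
  el
}
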