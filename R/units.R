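# Unit harmonization between two models. SBML expresses units as products of
# base kinds with multiplier/scale/exponent; quantities of model B are
# re-expressed in model A's substance/time/volume system before matching and
# merging.

# SI factor and dimension vector of one SBML base kind.
# Dimensions tracked: substance (mole), time (second), volume (m^3),
# mass (kg), length (m), item (dimensionless counts, NOT convertible to mole).
.BASE_KINDS <- list(
  mole          = list(factor = 1,     dims = c(substance = 1)),
  item          = list(factor = 1,     dims = c(item = 1)),
  second        = list(factor = 1,     dims = c(time = 1)),
  litre         = list(factor = 1e-3,  dims = c(volume = 1)),
  liter         = list(factor = 1e-3,  dims = c(volume = 1)),
  metre         = list(factor = 1,     dims = c(length = 1)),
  meter         = list(factor = 1,     dims = c(length = 1)),
  gram          = list(factor = 1e-3,  dims = c(mass = 1)),
  kilogram      = list(factor = 1,     dims = c(mass = 1)),
  dimensionless = list(factor = 1,     dims = c())
)

#' Resolve a unit reference of a model to (SI factor, dimension vector)
#' @noRd
resolve_unit <- function(model, ref) {
  if (is.null(ref) || is.na(ref)) return(NULL)
  if (ref %in% names(model$units)) {
    parts <- model$units[[ref]]
    factor <- 1
    dims <- c()
    for (u in parts) {
      base <- .BASE_KINDS[[u$kind]]
      if (is.null(base)) {
        stop(sprintf("unsupported unit kind '%s'", u$kind), call. = FALSE)
      }
      factor <- factor * (u$multiplier * 10^u$scale * base$factor)^u$exponent
      for (d in names(base$dims)) {
        cur <- if (d %in% names(dims)) dims[[d]] else 0
        dims[d] <- cur + base$dims[[d]] * u$exponent
      }
      dims <- dims[dims != 0]
    }
    return(list(factor = factor, dims = .norm_dims(dims)))
  }
  base <- .BASE_KINDS[[ref]]
  if (is.null(base)) {
    stop(sprintf("unknown unit reference '%s'", ref), call. = FALSE)
  }
  list(factor = base$factor, dims = .norm_dims(base$dims))
}

.norm_dims <- function(dims) {
  if (length(dims) == 0) return(setNames(numeric(0), character(0)))
  dims[order(names(dims))]
}

.role_unit <- function(model, role) {
  ref <- model$unit_roles[[role]]
  u <- resolve_unit(model, ref)
  if (is.null(u)) stop(sprintf("model '%s' has no %s unit", model$model_id, role),
                       call. = FALSE)
  u
}

.same_dims <- function(a, b) {
  identical(a$dims, b$dims)
}

#' Harmonize the unit systems of two models
#'
#' Rescales model B's quantities to model A's substance/time/volume units:
#' species initial concentrations, compartment sizes, and every parameter
#' whose declared units are dimensionally interpretable in terms of
#' substance/time/volume. Parameters without declared units are left
#' untouched and noted in the log. If the unit systems already agree, both
#' models are returned unchanged with an empty log. Dynamics are preserved:
#' model B simulated after conversion on a rescaled time grid reproduces its
#' original trajectories up to the unit factors.
#'
#' @param model_a,model_b [kinetic_model] objects.
#' @return list with elements `model_a`, `model_b` (converted) and `log`
#'   (data.frame element/role/factor/note).
#' @export
harmonize_units <- function(model_a, model_b) {
  roles <- c("substance", "time", "volume")
  for (m in list(model_a, model_b)) {
    if (length(m$units) == 0) {
      warning(sprintf("model '%s' declares no unit definitions; assuming SBML defaults (mole, second, litre)",
                      m$model_id), call. = FALSE)
    }
  }
  fa <- lapply(roles, function(r) .role_unit(model_a, r))
  fb <- lapply(roles, function(r) .role_unit(model_b, r))
  names(fa) <- names(fb) <- roles

  for (r in roles) {
    if (!.same_dims(fa[[r]], fb[[r]])) {
      stop(sprintf(
        "non-convertible unit pair for role '%s': model '%s' uses %s, model '%s' uses %s",
        r, model_a$model_id, model_a$unit_roles[[r]],
        model_b$model_id, model_b$unit_roles[[r]]), call. = FALSE)
    }
  }
  conv <- vapply(roles, function(r) fb[[r]]$factor / fa[[r]]$factor, numeric(1))

  log <- list()
  note <- function(element, role, factor, msg = "") {
    log[[length(log) + 1L]] <<- data.frame(
      element = element, role = role, factor = factor, note = msg,
      stringsAsFactors = FALSE)
  }

  if (all(abs(conv - 1) < .Machine$double.eps * 8)) {
    return(list(model_a = model_a, model_b = model_b, log = .log_df(log)))
  }

  b <- model_b
  conc_factor <- conv[["substance"]] / conv[["volume"]]
  if (conc_factor != 1) {
    for (id in names(b$species)) {
      b$species[[id]]$initial_amount <- b$species[[id]]$initial_amount * conc_factor
      note(id, "concentration", conc_factor)
    }
  }
  if (conv[["volume"]] != 1) {
    for (id in names(b$compartments)) {
      b$compartments[[id]]$size <- b$compartments[[id]]$size * conv[["volume"]]
      note(id, "volume", conv[["volume"]])
    }
  }

  # parameters: convert those with declared, interpretable units
  ua <- list(substance = fa$substance, time = fa$time, volume = fa$volume)
  for (id in names(b$parameters)) {
    p <- b$parameters[[id]]
    if (is.na(p$units %||% NA_character_)) {
      note(id, "parameter", 1, "no declared units; value not converted")
      next
    }
    pu <- tryCatch(resolve_unit(b, p$units), error = function(e) NULL)
    if (is.null(pu)) {
      note(id, "parameter", 1, sprintf("units '%s' not interpretable", p$units))
      next
    }
    dims <- pu$dims
    if (length(setdiff(names(dims), c("substance", "time", "volume"))) > 0) {
      note(id, "parameter", 1,
           sprintf("units '%s' outside substance/time/volume", p$units))
      next
    }
    # factor of the same unit expression rebuilt from A's role units
    ga <- prod(vapply(names(dims), function(d) ua[[d]]$factor^dims[[d]], numeric(1)))
    if (length(dims) == 0) ga <- 1
    f <- pu$factor / ga
    if (f != 1) {
      b$parameters[[id]]$value <- p$value * f
      note(id, "parameter", f, sprintf("converted from '%s'", p$units))
    }
    # re-point the declared units at A's system so the written model is coherent
    b$parameters[[id]]$units <- NA_character_
  }

  b$unit_roles <- model_a$unit_roles
  b$units <- model_a$units
  list(model_a = model_a, model_b = b, log = .log_df(log))
}

.log_df <- function(log) {
  if (length(log) == 0) {
    return(data.frame(element = character(0), role = character(0),
                      factor = numeric(0), note = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, log)
}
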