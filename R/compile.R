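# Compilation of a kinetic model into the flat structures the C++ integrator
# consumes: a stack-machine bytecode program per reaction rate, a
# stoichiometry triplet list, and parameter / volume vectors. Compartment
# sizes are appended to the parameter vector so kinetic laws may reference
# compartment ids like any other symbol.

.OPS <- c(CONST = 1L, SPECIES = 2L, PARAM = 3L, TIME = 4L,
          ADD = 10L, SUB = 11L, MUL = 12L, DIV = 13L, POW = 14L, NEG = 15L,
          EXP = 20L, LN = 21L, LOG10 = 22L, SQRT = 23L, ABS = 24L,
          FLOOR = 25L, CEIL = 26L, SIN = 27L, COS = 28L, TAN = 29L,
          LT = 30L, LE = 31L, GT = 32L, GE = 33L, EQ = 34L, NE = 35L,
          AND = 36L, OR = 37L, NOT = 38L, SELECT = 40L, MIN = 41L, MAX = 42L)

.FUN_OPS <- c(exp = "EXP", sqrt = "SQRT", abs = "ABS", floor = "FLOOR",
              ceiling = "CEIL", sin = "SIN", cos = "COS", tan = "TAN")
.BIN_OPS <- c(`+` = "ADD", `-` = "SUB", `*` = "MUL", `/` = "DIV", `^` = "POW",
              `<` = "LT", `<=` = "LE", `>` = "GT", `>=` = "GE",
              `==` = "EQ", `!=` = "NE", `&` = "AND", `|` = "OR")

#' Compile a kinetic model for simulation
#' @return list with program, triplets, y0, params, vols, dynamic, ids
#' @noRd
compile_kinetic_model <- function(model) {
  rep_ok <- validate_model(model)
  if (!rep_ok$valid) {
    stop(sprintf("model '%s' does not validate:\n%s", model$model_id,
                 paste(rep_ok$issues$message, collapse = "\n")), call. = FALSE)
  }
  sp_ids <- names(model$species)
  sp_idx <- setNames(seq_along(sp_ids), sp_ids)
  par_ids <- c(names(model$parameters), names(model$compartments))
  par_vals <- c(vapply(model$parameters, `[[`, numeric(1), "value"),
                vapply(model$compartments, `[[`, numeric(1), "size"))
  par_idx <- setNames(seq_along(par_ids), par_ids)

  op <- integer(0); arg <- integer(0); consts <- numeric(0)
  emit <- function(o, a = 0L) {
    op[[length(op) + 1L]] <<- .OPS[[o]]
    arg[[length(arg) + 1L]] <<- as.integer(a)
  }
  emit_const <- function(v) {
    consts[[length(consts) + 1L]] <<- v
    emit("CONST", length(consts) - 1L)
  }
  compile_expr <- function(e) {
    if (is.numeric(e) || is.logical(e)) return(emit_const(as.numeric(e)))
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm == "time") return(emit("TIME"))
      if (nm == "pi") return(emit_const(pi))
      if (nm %in% sp_ids) return(emit("SPECIES", sp_idx[[nm]] - 1L))
      if (nm %in% par_ids) return(emit("PARAM", par_idx[[nm]] - 1L))
      stop(sprintf("undeclared symbol '%s' in kinetic law", nm), call. = FALSE)
    }
    if (!is.call(e)) stop("unsupported kinetic-law construct", call. = FALSE)
    fn <- as.character(e[[1L]])
    args <- as.list(e)[-1L]
    if (fn == "(") return(compile_expr(args[[1L]]))
    if (fn == "-" && length(args) == 1L) {
      compile_expr(args[[1L]]); return(emit("NEG"))
    }
    if (fn %in% names(.BIN_OPS)) {
      compile_expr(args[[1L]]); compile_expr(args[[2L]])
      return(emit(.BIN_OPS[[fn]]))
    }
    if (fn == "!") { compile_expr(args[[1L]]); return(emit("NOT")) }
    if (fn %in% names(.FUN_OPS)) {
      compile_expr(args[[1L]]); return(emit(.FUN_OPS[[fn]]))
    }
    if (fn == "log") {
      if (length(args) == 1L) { compile_expr(args[[1L]]); return(emit("LN")) }
      base <- args[[2L]]
      if (is.numeric(base) && base == 10) {
        compile_expr(args[[1L]]); return(emit("LOG10"))
      }
      compile_expr(args[[1L]]); emit("LN")
      compile_expr(base); emit("LN")
      return(emit("DIV"))
    }
    if (fn %in% c("pmin", "pmax", "min", "max")) {
      compile_expr(args[[1L]])
      for (a in args[-1L]) {
        compile_expr(a)
        emit(if (fn %in% c("pmin", "min")) "MIN" else "MAX")
      }
      return(invisible(NULL))
    }
    if (fn == "ifelse") {
      compile_expr(args[[1L]]); compile_expr(args[[2L]]); compile_expr(args[[3L]])
      return(emit("SELECT"))
    }
    stop(sprintf("unsupported function '%s' in kinetic law", fn), call. = FALSE)
  }

  starts <- integer(length(model$reactions) + 1L)
  starts[1L] <- 0L
  for (i in seq_along(model$reactions)) {
    compile_expr(model$reactions[[i]]$kinetic_law)
    starts[i + 1L] <- length(op)
  }

  trip_i <- integer(0); trip_r <- integer(0); trip_c <- numeric(0)
  for (r in seq_along(model$reactions)) {
    rx <- model$reactions[[r]]
    add <- function(df, sign) {
      for (k in seq_len(nrow(df))) {
        trip_i[[length(trip_i) + 1L]] <<- sp_idx[[df$species[k]]] - 1L
        trip_r[[length(trip_r) + 1L]] <<- r - 1L
        trip_c[[length(trip_c) + 1L]] <<- sign * df$stoichiometry[k]
      }
    }
    add(rx$reactants, -1)
    add(rx$products, 1)
  }

  vols <- vapply(sp_ids, function(s) {
    model$compartments[[model$species[[s]]$compartment]]$size
  }, numeric(1))
  dynamic <- vapply(sp_ids, function(s) {
    sp <- model$species[[s]]
    !(sp$boundary || sp$constant)
  }, logical(1))
  y0 <- vapply(model$species, `[[`, numeric(1), "initial_amount")

  list(prog = list(op = op, arg = arg, starts = starts, consts = consts),
       species_ids = sp_ids, param_ids = par_ids,
       y0 = unname(y0), params = unname(par_vals),
       vols = unname(vols), dynamic = unname(dynamic),
       trip_i = trip_i, trip_r = trip_r, trip_c = trip_c)
}

#' Evaluate the right-hand side of the compiled ODE system (diagnostics)
#' @noRd
compiled_rhs <- function(cm, t, y, params = cm$params) {
  .ode_rates_cpp(cm$prog, as.numeric(y), as.numeric(params), cm$vols,
                 cm$dynamic, cm$trip_i, cm$trip_r, cm$trip_c, t)
}
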