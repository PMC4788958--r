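# Goal-driven reparameterization: selection of refit candidates that cannot
# disturb the preserved side, and multi-start Levenberg-Marquardt estimation
# on log-transformed parameters against multiple datasets simultaneously.

#' Refit-candidate parameters under an integration goal
#'
#' Returns the parameters whose perturbation cannot change the preserved
#' side's outputs under that side's isolated inputs: kinetic parameters of
#' the non-preserved model's exclusive reactions, initial amounts of its
#' exclusive species (as `"init:<species>"` refs), and scaling factors of
#' outputs exclusive to the non-preserved side (as `"scale:<label>"` refs).
#' Overlap parameters and preserved-side parameters are excluded: fitting
#' them would make exact reproduction of the preserved side impossible.
#'
#' With `preserve_exact = "none"` no exclusion is forced; all non-overlap
#' parameters of both sides are returned with a warning.
#'
#' @param merged a `merged_model`.
#' @param matches the `match_set` used for the merge.
#' @param goal an [integration_goal].
#' @param observables optional list of [observable()]s; needed to propose
#'   scale candidates.
#' @return list with components `reaction_parameters`, `initial_amounts`,
#'   `observable_scales` (character vectors of refs); attribute `side` names
#'   the non-preserved side.
#' @export
candidate_free_parameters <- function(merged, matches, goal, observables = NULL) {
  stopifnot(inherits(merged, "merged_model"), inherits(goal, "integration_goal"))
  prov <- merged$provenance
  model <- merged$model

  side_of <- function(class, id) prov[[paste0(class, ":", id)]] %||% NA_character_

  if (goal$preserve_exact == "none") {
    warning("goal names no preserve_exact side; returning all non-overlap parameters",
            call. = FALSE)
    keep <- c("A-only", "B-only")
  } else {
    keep <- if (goal$preserve_exact == "A") "B-only" else "A-only"
  }

  excl_rx <- names(model$reactions)[vapply(names(model$reactions), function(r) {
    side_of("reaction", r) %in% keep
  }, logical(1))]
  # parameters referenced in exclusive reactions and nowhere else
  ref_by <- function(rids) {
    unique(unlist(lapply(rids, function(r) .law_parameters(model, r))))
  }
  pars_excl <- ref_by(excl_rx)
  pars_other <- ref_by(setdiff(names(model$reactions), excl_rx))
  reaction_parameters <- setdiff(pars_excl, pars_other)

  excl_sp <- names(model$species)[vapply(names(model$species), function(s) {
    side_of("species", s) %in% keep
  }, logical(1))]
  # input species are stimulus levels, not fittable initial conditions
  excl_sp <- excl_sp[!vapply(excl_sp, function(s) {
    sp <- model$species[[s]]
    sp$boundary && sp$constant
  }, logical(1))]
  initial_amounts <- paste0("init:", excl_sp)

  observable_scales <- character(0)
  if (!is.null(observables)) {
    for (ob in observables) {
      if (side_of("species", ob$species_ref) %in% keep) {
        observable_scales <- c(observable_scales, paste0("scale:", ob$label))
      }
    }
  }

  structure(list(reaction_parameters = reaction_parameters,
                 initial_amounts = initial_amounts,
                 observable_scales = observable_scales),
            side = keep)
}

#' Assemble a fitting problem
#'
#' @param model a `merged_model` or [kinetic_model].
#' @param free character vector of free-quantity refs: parameter ids,
#'   `"init:<species>"` initial amounts, `"scale:<label>"` observable scales.
#' @param datasets list of `dataset` objects (multi-experiment fit: one
#'   parameter vector, per-dataset inputs).
#' @param observables list of [observable()]s of the model.
#' @param bounds optional named list/vector of `c(low, high)` per ref;
#'   defaults to `[value/1000, value*1000]` around the current value.
#' @param rtol,atol integration tolerances used inside the objective.
#' @return a `fit_problem`.
#' @export
fit_problem <- function(model, free, datasets, observables, bounds = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  if (inherits(model, "merged_model")) model <- model$model
  stopifnot(inherits(model, "kinetic_model"), length(free) > 0)
  cm <- compile_kinetic_model(model)

  ob_labels <- vapply(observables, `[[`, character(1), "label")
  current <- vapply(free, function(ref) {
    if (startsWith(ref, "init:")) {
      sp <- sub("^init:", "", ref)
      if (!(sp %in% cm$species_ids)) {
        stop(sprintf("unknown species in ref '%s'", ref), call. = FALSE)
      }
      model$species[[sp]]$initial_amount
    } else if (startsWith(ref, "scale:")) {
      lab <- sub("^scale:", "", ref)
      if (!(lab %in% ob_labels)) {
        stop(sprintf("unknown observable in ref '%s'", ref), call. = FALSE)
      }
      observables[[which(ob_labels == lab)[1]]]$scale
    } else {
      if (!(ref %in% names(model$parameters))) {
        stop(sprintf("unknown parameter ref '%s'", ref), call. = FALSE)
      }
      model$parameters[[ref]]$value
    }
  }, numeric(1))

  bnds <- matrix(0, nrow = length(free), ncol = 2,
                 dimnames = list(free, c("low", "high")))
  for (i in seq_along(free)) {
    ref <- free[i]
    user <- if (!is.null(bounds) && ref %in% names(bounds)) bounds[[ref]] else NULL
    if (!is.null(user)) {
      bnds[i, ] <- user
    } else if (current[i] > 0) {
      bnds[i, ] <- c(current[i] / 1000, current[i] * 1000)
    } else {
      # zero current value (e.g. an empty pool): wide positive default
      bnds[i, ] <- c(1e-9, 1e3)
    }
  }
  if (any(bnds <= 0)) {
    stop("bounds must be positive (parameters are fitted on a log scale)",
         call. = FALSE)
  }

  structure(list(model = model, free = free, datasets = datasets,
                 observables = observables, current = current, bounds = bnds,
                 cm = cm, rtol = rtol, atol = atol),
            class = "fit_problem")
}

# residual vector of the whole multi-experiment problem at parameter values p
# (natural scale, ordered as problem$free)
.fit_residuals <- function(problem, p) {
  cm <- problem$cm
  model <- problem$model
  params <- cm$params
  y0_base <- cm$y0
  scales <- vapply(problem$observables, `[[`, numeric(1), "scale")
  labs <- vapply(problem$observables, `[[`, character(1), "label")
  par_pos <- setNames(seq_along(cm$param_ids), cm$param_ids)
  sp_pos <- setNames(seq_along(cm$species_ids), cm$species_ids)

  for (i in seq_along(problem$free)) {
    ref <- problem$free[i]
    if (startsWith(ref, "init:")) {
      y0_base[sp_pos[[sub("^init:", "", ref)]]] <- p[i]
    } else if (startsWith(ref, "scale:")) {
      scales[labs == sub("^scale:", "", ref)] <- p[i]
    } else {
      params[par_pos[[ref]]] <- p[i]
    }
  }

  res <- numeric(0)
  for (ds in problem$datasets) {
    y0 <- y0_base
    # step input + input-zero convention
    for (nm in cm$species_ids) {
      sp <- model$species[[nm]]
      if (sp$boundary && sp$constant) {
        y0[sp_pos[[nm]]] <- if (nm %in% names(ds$input$assignments)) {
          ds$input$assignments[[nm]]
        } else 0
      }
    }
    for (nm in names(ds$input$assignments)) y0[sp_pos[[nm]]] <- ds$input$assignments[[nm]]
    vals <- .ode_integrate_cpp(cm$prog, y0, params, cm$vols, cm$dynamic,
                               cm$trip_i, cm$trip_r, cm$trip_c,
                               as.numeric(ds$time_grid), problem$rtol,
                               problem$atol, hmax = diff(range(ds$time_grid)),
                               maxsteps = 2000000L, method = "dopri5")
    for (lab in names(ds$observations)) {
      k <- which(labs == lab)[1]
      if (is.na(k)) {
        stop(sprintf("dataset output '%s' has no observable", lab), call. = FALSE)
      }
      yhat <- scales[k] * vals[, sp_pos[[problem$observables[[k]]$species_ref]]]
      d <- ds$observations[[lab]]
      res <- c(res, (d$value - yhat) / d$sigma)
    }
  }
  res
}

#' Multi-start Levenberg-Marquardt fit
#'
#' Minimizes the pooled chi^2 over all datasets simultaneously.
#' Parameters are optimized on a log scale (all fitted quantities are
#' positive); each start is a log-uniform draw within the bounds, plus one
#' start at the current values. Deterministic given `seed`.
#'
#' @param problem a [fit_problem].
#' @param n_starts number of starts (>= 1; the first is the current value).
#' @param seed integer seed, recorded in the result.
#' @param maxit LM iteration cap per start.
#' @return a `fit_result`: estimates, chi2_over_N_total, per_side (A/B),
#'   per_dataset, n_starts, converged, seed.
#' @export
fit_parameters <- function(problem, n_starts = 5L, seed = 1L, maxit = 60L) {
  stopifnot(inherits(problem, "fit_problem"), n_starts >= 1L)
  set.seed(as.integer(seed))
  lb <- log(problem$bounds[, "low"])
  ub <- log(problem$bounds[, "high"])
  th0 <- pmin(pmax(log(pmax(problem$current, problem$bounds[, "low"])), lb), ub)

  starts <- list(th0)
  if (n_starts > 1L) {
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- lb + runif(length(lb)) * (ub - lb)
    }
  }

  obj <- function(theta) .fit_residuals(problem, exp(theta))
  best <- NULL
  n_fail <- 0L
  for (st in starts) {
    fit <- tryCatch(.lm_minimize(obj, st, lb, ub, maxit = maxit),
                    error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  if (is.null(best)) {
    stop(sprintf("all %d starts failed to integrate", n_starts), call. = FALSE)
  }

  p_hat <- exp(best$theta)
  names(p_hat) <- problem$free
  r <- .fit_residuals(problem, p_hat)
  n_total <- length(r)
  sides <- vapply(problem$datasets, `[[`, character(1), "origin")
  sizes <- vapply(problem$datasets, dataset_size, integer(1))
  # residuals are concatenated dataset by dataset
  idx_end <- cumsum(sizes)
  idx_start <- c(1L, head(idx_end, -1L) + 1L)
  ss_side <- c(A = 0, B = 0); n_side <- c(A = 0L, B = 0L)
  per_dataset <- numeric(length(problem$datasets))
  for (k in seq_along(problem$datasets)) {
    rk <- r[idx_start[k]:idx_end[k]]
    per_dataset[k] <- sum(rk^2) / sizes[k]
    if (sides[k] %in% c("A", "B")) {
      ss_side[[sides[k]]] <- ss_side[[sides[k]]] + sum(rk^2)
      n_side[[sides[k]]] <- n_side[[sides[k]]] + sizes[k]
    }
  }
  names(per_dataset) <- vapply(problem$datasets, `[[`, character(1), "label")

  structure(list(
    estimates = p_hat,
    chi2_over_N_total = sum(r^2) / n_total,
    per_side = c(A = if (n_side[["A"]] > 0) ss_side[["A"]] / n_side[["A"]] else NA_real_,
                 B = if (n_side[["B"]] > 0) ss_side[["B"]] / n_side[["B"]] else NA_real_),
    per_dataset = per_dataset,
    n_starts = n_starts, n_failed_starts = n_fail,
    converged = best$converged, seed = as.integer(seed)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chi2/N = %.4g (sides A: %.4g, B: %.4g), %d starts, seed %d\n",
              x$chi2_over_N_total, x$per_side[["A"]], x$per_side[["B"]],
              x$n_starts, x$seed))
  print(x$estimates)
  invisible(x)
}

#' Apply fitted estimates back to model and observables
#'
#' @param problem the [fit_problem] that was fitted.
#' @param estimates named vector from a `fit_result`.
#' @return list with `model` (updated [kinetic_model]) and `observables`.
#' @export
apply_fit <- function(problem, estimates) {
  model <- problem$model
  observables <- problem$observables
  labs <- vapply(observables, `[[`, character(1), "label")
  for (ref in names(estimates)) {
    v <- estimates[[ref]]
    if (startsWith(ref, "init:")) {
      model$species[[sub("^init:", "", ref)]]$initial_amount <- v
    } else if (startsWith(ref, "scale:")) {
      k <- which(labs == sub("^scale:", "", ref))
      for (i in k) observables[[i]]$scale <- v
    } else {
      model$parameters[[ref]]$value <- v
    }
  }
  list(model = model, observables = observables)
}

#' Serialize a fit result as JSON
#' @param result a `fit_result`; @param path optional output path.
#' @export
fit_result_json <- function(result, path = NULL) {
  obj <- list(estimates = as.list(result$estimates),
              chi2_over_N_total = result$chi2_over_N_total,
              per_side = as.list(result$per_side),
              per_dataset = as.list(result$per_dataset),
              n_starts = result$n_starts, converged = result$converged,
              seed = result$seed)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

# ---- Levenberg-Marquardt on a box --------------------------------------------

#' @noRd
.lm_minimize <- function(resid_fn, theta0, lb, ub, maxit = 60L,
                         ftol = 1e-10, gtol = 1e-8) {
  theta <- pmin(pmax(theta0, lb), ub)
  r <- resid_fn(theta)
  if (any(!is.finite(r))) stop("non-finite residuals at start", call. = FALSE)
  cost <- sum(r^2)
  lambda <- 1e-3
  np <- length(theta)
  converged <- FALSE

  jac <- function(theta, r0) {
    J <- matrix(0, length(r0), np)
    for (j in seq_len(np)) {
      dt <- 1e-6 * max(1, abs(theta[j]))
      tj <- theta
      tj[j] <- min(theta[j] + dt, ub[j])
      if (tj[j] == theta[j]) tj[j] <- theta[j] - dt
      rj <- resid_fn(tj)
      J[, j] <- (rj - r0) / (tj[j] - theta[j])
    }
    J
  }

  for (it in seq_len(maxit)) {
    J <- jac(theta, r)
    g <- crossprod(J, r)
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    improved <- FALSE
    for (tries in 1:12) {
      A <- JtJ + lambda * diag(pmax(diag(JtJ), 1e-12), np)
      step <- tryCatch(-solve(A, g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- pmin(pmax(theta + as.numeric(step), lb), ub)
        rc <- tryCatch(resid_fn(cand), error = function(e) NULL)
        if (!is.null(rc) && all(is.finite(rc)) && sum(rc^2) < cost) {
          rel <- (cost - sum(rc^2)) / max(cost, .Machine$double.eps)
          theta <- cand; r <- rc; cost <- sum(rc^2)
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          if (rel < ftol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved || converged) {
      if (!improved) converged <- TRUE  # no descent direction left
      break
    }
  }
  list(theta = theta, cost = cost, converged = converged)
}
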