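# Consistency testing: synthetic datasets from original-model simulations,
# the chi^2/N statistic, per-side consistency checks of a merged model, and
# integration-goal evaluation.
#
# The error model for synthetic data points is 10 % relative error plus 5 %
# of the per-curve maximum as absolute error, the two terms added (not in
# quadrature): sigma_i = 0.10*|y_i| + 0.05*max_t|y(t)|.

#' Turn simulated outputs into a synthetic dataset
#'
#' Interprets model output values as synthetic data points (no noise is
#' added to the central values) with standard deviations from the 10 %
#' relative + 5 %-of-maximum error model. Identically zero output curves get
#' a floored sigma (1e-6 times the largest curve maximum in the dataset, or
#' 1 if all curves are silent) and a warning.
#'
#' @param outputs a `trajectory` of scaled outputs (from [observe()]).
#' @param input the [input_signal] that produced the outputs.
#' @param origin `"A"`, `"B"` or `"experimental"`.
#' @param label dataset label.
#' @return a `dataset`: list with label, input, time_grid, observations
#'   (per-output data.frame value/sigma), origin.
#' @export
make_synthetic_dataset <- function(outputs, input, origin = c("A", "B", "experimental"),
                                   label = input$label) {
  stopifnot(inherits(outputs, "trajectory"))
  origin <- match.arg(origin)
  if (length(outputs$time) == 0 || ncol(outputs$values) == 0) {
    stop("empty trajectory: cannot build a dataset", call. = FALSE)
  }
  global_max <- max(abs(outputs$values))
  floor_sigma <- 1e-6 * if (global_max > 0) global_max else 1
  obs <- list()
  for (lab in colnames(outputs$values)) {
    y <- outputs$values[, lab]
    curve_max <- max(abs(y))
    sigma <- 0.10 * abs(y) + 0.05 * curve_max
    if (curve_max == 0) {
      warning(sprintf("output '%s' is identically zero; sigma floored", lab),
              call. = FALSE)
      sigma <- rep(floor_sigma, length(y))
    }
    sigma <- pmax(sigma, floor_sigma)
    obs[[lab]] <- data.frame(value = y, sigma = sigma)
  }
  structure(list(label = label, input = input, time_grid = outputs$time,
                 observations = obs, origin = origin),
            class = "dataset")
}

#' Number of observation points in a dataset
#' @param dataset a `dataset`.
#' @export
dataset_size <- function(dataset) {
  sum(vapply(dataset$observations, nrow, integer(1)))
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("<dataset> '%s' (origin %s): %d outputs x %d time points\n",
              x$label, x$origin, length(x$observations), length(x$time_grid)))
  invisible(x)
}

#' Sum of squared weighted residuals of model outputs against a dataset
#' @return list(ss, n, per_output)
#' @noRd
chi2_parts <- function(dataset, model_outputs) {
  stopifnot(inherits(dataset, "dataset"), inherits(model_outputs, "trajectory"))
  if (length(dataset$time_grid) != length(model_outputs$time) ||
      max(abs(dataset$time_grid - model_outputs$time)) > 1e-9) {
    stop("time grid mismatch between dataset and model outputs", call. = FALSE)
  }
  ss <- 0; n <- 0L
  per_output <- numeric(0)
  for (lab in names(dataset$observations)) {
    if (!(lab %in% colnames(model_outputs$values))) {
      stop(sprintf("dataset output '%s' absent from model outputs", lab),
           call. = FALSE)
    }
    d <- dataset$observations[[lab]]
    r <- (d$value - model_outputs$values[, lab]) / d$sigma
    per_output[[lab]] <- sum(r^2)
    ss <- ss + sum(r^2)
    n <- n + nrow(d)
  }
  list(ss = ss, n = n, per_output = per_output)
}

#' The chi^2/N statistic
#'
#' Mean squared weighted residual over every (output, time point) pair of a
#' dataset: `(1/N) * sum_i ((y_i - y(t_i))/sigma_i)^2`. Zero iff the model
#' outputs equal the data at every point; invariant under rescaling an
#' output curve together with its data (sigma is built from the same curve).
#'
#' @param dataset a `dataset`.
#' @param model_outputs a `trajectory` of model outputs on the dataset's
#'   time grid carrying (at least) the dataset's output labels.
#' @return nonnegative scalar.
#' @export
chi2_over_N <- function(dataset, model_outputs) {
  parts <- chi2_parts(dataset, model_outputs)
  parts$ss / parts$n
}

#' Consistency check of a merged model against both sides' datasets
#'
#' For each model A-origin dataset the merged model is simulated with that
#' dataset's input signal (model B's inputs silent, by the input-zero
#' convention of [input_signal()]); likewise with roles swapped for model
#' B-origin datasets. Residuals are pooled per side over all of that side's
#' datasets, outputs and time points. The merged model is consistent iff
#' chi^2_A/N_A < 1 and chi^2_B/N_B < 1 (strict).
#'
#' @param merged a `merged_model` (or plain [kinetic_model]).
#' @param datasets_a,datasets_b lists of `dataset` objects with origins
#'   `"A"` / `"B"`.
#' @param observables list of [observable()]s of the merged model covering
#'   every dataset output label.
#' @param ... passed to [simulate_model()].
#' @return a `consistency_report`: chi2_A_over_N, chi2_B_over_N,
#'   per_dataset, consistent, goal_result (NULL until [evaluate_goal()]).
#' @export
check_consistency <- function(merged, datasets_a, datasets_b, observables, ...) {
  side <- function(datasets) {
    ss <- 0; n <- 0L
    per <- numeric(0)
    for (ds in datasets) {
      traj <- simulate_model(merged, ds$input, ds$time_grid, ...)
      parts <- chi2_parts(ds, observe(traj, observables))
      ss <- ss + parts$ss
      n <- n + parts$n
      per[[ds$label]] <- parts$ss / parts$n
    }
    list(ss = ss, n = n, per = per)
  }
  a <- side(datasets_a)
  b <- side(datasets_b)
  chi2_a <- if (a$n > 0) a$ss / a$n else 0
  chi2_b <- if (b$n > 0) b$ss / b$n else 0
  structure(list(chi2_A_over_N = chi2_a, chi2_B_over_N = chi2_b,
                 per_dataset = c(a$per, b$per),
                 N_A = a$n, N_B = b$n,
                 consistent = (chi2_a < 1) && (chi2_b < 1),
                 goal_result = NULL),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> chi2_A/N = %.4g (N=%d), chi2_B/N = %.4g (N=%d)\n",
              x$chi2_A_over_N, x$N_A, x$chi2_B_over_N, x$N_B))
  cat(sprintf("  consistent: %s\n", x$consistent))
  if (!is.null(x$goal_result)) {
    cat(sprintf("  integration goal: %s\n",
                if (x$goal_result$pass) "achieved" else "NOT achieved"))
  }
  invisible(x)
}

#' Integration goal on the two chi^2/N values
#'
#' A declared target relation guiding policy choice and refit-parameter
#' selection, e.g. "preserve model A exactly, bring model B to approximately
#' one".
#'
#' @param preserve_exact `"A"`, `"B"` or `"none"`.
#' @param relations list of `list(side = "A"|"B", target =
#'   "strict-below-one"|"approx-one")`. Defaults to strict-below-one for the
#'   preserved side and approx-one for the other (both strict when
#'   `preserve_exact = "none"`).
#' @export
integration_goal <- function(preserve_exact = c("A", "B", "none"),
                             relations = NULL) {
  preserve_exact <- match.arg(preserve_exact)
  if (is.null(relations)) {
    relations <- if (preserve_exact == "none") {
      list(list(side = "A", target = "strict-below-one"),
           list(side = "B", target = "strict-below-one"))
    } else {
      other <- if (preserve_exact == "A") "B" else "A"
      list(list(side = preserve_exact, target = "strict-below-one"),
           list(side = other, target = "approx-one"))
    }
  }
  structure(list(preserve_exact = preserve_exact, relations = relations),
            class = "integration_goal")
}

#' Evaluate an integration goal on a consistency report
#'
#' `strict-below-one` relations pass iff the side's chi^2/N < 1;
#' `approx-one` relations pass iff chi^2/N <= 1 + `tol`.
#'
#' @param report a `consistency_report`.
#' @param goal an [integration_goal].
#' @param tol tolerance of the `approx-one` target (default 0.05).
#' @return a `goal_result`: per-relation pass/fail and overall `pass`.
#' @export
evaluate_goal <- function(report, goal, tol = 0.05) {
  stopifnot(inherits(report, "consistency_report"),
            inherits(goal, "integration_goal"))
  per <- lapply(goal$relations, function(rel) {
    value <- if (rel$side == "A") report$chi2_A_over_N else report$chi2_B_over_N
    pass <- if (rel$target == "strict-below-one") value < 1 else value <= 1 + tol
    list(side = rel$side, target = rel$target, value = value, pass = pass)
  })
  structure(list(relations = per,
                 pass = all(vapply(per, `[[`, logical(1), "pass"))),
            class = "goal_result")
}

#' Serialize a consistency report as JSON
#' @param report a `consistency_report`; @param path optional output path.
#' @export
consistency_report_json <- function(report, path = NULL) {
  obj <- list(chi2_A_over_N = report$chi2_A_over_N,
              chi2_B_over_N = report$chi2_B_over_N,
              N_A = report$N_A, N_B = report$N_B,
              per_dataset = as.list(report$per_dataset),
              consistent = report$consistent)
  if (!is.null(report$goal_result)) {
    obj$goal <- list(pass = report$goal_result$pass,
                     relations = report$goal_result$relations)
  }
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Write a dataset as a delimited table plus JSON header
#'
#' The table (tab-separated, columns time / output / value / sigma) goes to
#' `path`; input assignments, origin and label go to `<path>.json`.
#' @param dataset a `dataset`; @param path output path.
#' @export
write_dataset <- function(dataset, path) {
  rows <- do.call(rbind, lapply(names(dataset$observations), function(lab) {
    d <- dataset$observations[[lab]]
    data.frame(time = dataset$time_grid, output = lab,
               value = d$value, sigma = d$sigma, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(label = dataset$label, origin = dataset$origin,
         input = as.list(dataset$input$assignments),
         input_label = dataset$input$label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path path of the delimited table.
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- sort(unique(df$time))
  obs <- list()
  for (lab in unique(df$output)) {
    d <- df[df$output == lab, ]
    d <- d[order(d$time), ]
    obs[[lab]] <- data.frame(value = d$value, sigma = d$sigma)
  }
  structure(list(label = hdr$label,
                 input = input_signal(unlist(hdr$input) %||% numeric(0),
                                      hdr$input_label %||% ""),
                 time_grid = grid, observations = obs, origin = hdr$origin),
            class = "dataset")
}
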