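# Workflow orchestration: prepare -> match -> merge -> check -> refit, with
# serialized artifacts at every stage so any stage can be re-run standalone.

#' Workflow configuration
#'
#' @param model_a,model_b paths to the two SBML files.
#' @param policy a [merge_policy()] (or list coercible to one).
#' @param goal an [integration_goal()].
#' @param experiments list of experiment specs, each a list with `side`
#'   (`"A"`/`"B"`), `stimulus` (named amounts), `label`; observed outputs are
#'   given by `observables`: list of lists (species, scale, label, side).
#' @param time_grid simulation grid (shared by all experiments).
#' @param free_parameters `"auto"` (candidates from the goal) or a character
#'   vector of refs as in [fit_problem()].
#' @param n_starts,seed fitting settings.
#' @param max_iterations refit/check iteration cap.
#' @param out_dir artifact directory.
#' @param edits manual match edits (list of commands, or path to a JSON file).
#' @export
workflow_config <- function(model_a, model_b, policy = merge_policy("A"),
                            goal = integration_goal("A"),
                            experiments = list(),
                            observables = list(),
                            time_grid = seq(0, 3600, length.out = 61),
                            free_parameters = "auto", n_starts = 5L, seed = 1L,
                            max_iterations = 3L, out_dir = tempfile("kimerge_"),
                            edits = list()) {
  structure(list(model_a = model_a, model_b = model_b, policy = policy,
                 goal = goal, experiments = experiments,
                 observables = observables, time_grid = time_grid,
                 free_parameters = free_parameters, n_starts = n_starts,
                 seed = seed, max_iterations = max_iterations,
                 out_dir = out_dir, edits = edits),
            class = "workflow_config")
}

#' Read a workflow configuration from JSON
#'
#' The JSON representation round-trips losslessly through
#' [write_workflow_config()].
#' @param path JSON file.
#' @export
read_workflow_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  workflow_config(
    model_a = x$model_a, model_b = x$model_b,
    policy = merge_policy(x$policy$default_source %||% "A",
                          unlist(x$policy$per_element) %||% character(0)),
    goal = integration_goal(x$goal$preserve_exact %||% "A"),
    experiments = x$experiments %||% list(),
    observables = x$observables %||% list(),
    time_grid = unlist(x$time_grid),
    free_parameters = unlist(x$free_parameters) %||% "auto",
    n_starts = x$n_starts %||% 5L, seed = x$seed %||% 1L,
    max_iterations = x$max_iterations %||% 3L,
    out_dir = x$out_dir %||% tempfile("kimerge_"),
    edits = x$edits %||% list())
}

#' Write a workflow configuration as JSON
#' @param config a [workflow_config()]; @param path output path.
#' @export
write_workflow_config <- function(config, path) {
  obj <- list(model_a = config$model_a, model_b = config$model_b,
              policy = list(default_source = config$policy$default_source,
                            per_element = as.list(config$policy$per_element)),
              goal = list(preserve_exact = config$goal$preserve_exact),
              experiments = config$experiments,
              observables = config$observables,
              time_grid = config$time_grid,
              free_parameters = config$free_parameters,
              n_starts = config$n_starts, seed = config$seed,
              max_iterations = config$max_iterations,
              out_dir = config$out_dir, edits = config$edits)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.wf_observables <- function(config) {
  lapply(config$observables, function(o) {
    ob <- observable(o$species, o$scale %||% 1, o$label %||% o$species)
    attr(ob, "side") <- o$side %||% "shared"
    ob
  })
}

#' Run the integration workflow
#'
#' Executes prepare (load, validate, harmonize units), match (automatic +
#' manual edits), merge, consistency check, and - if the merged model is not
#' consistent and a goal is set - refit/check iterations up to
#' `max_iterations`. Every stage's artifact is written under
#' `config$out_dir`. Any stage error surfaces as an error prefixed with the
#' stage name.
#'
#' @param config a [workflow_config()].
#' @return list with `status` (0 on success), `consistent`, `report_pre`,
#'   `report_post`, `fit`, `merged`, `iterations`, `artifacts`.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)

  # --- stage: prepare -------------------------------------------------------
  prep <- tryCatch({
    model_a <- load_model(config$model_a)
    model_b <- load_model(config$model_b)
    for (m in list(model_a, model_b)) {
      rep <- validate_model(m)
      if (!rep$valid) {
        stop(sprintf("model '%s' invalid: %s", m$model_id,
                     paste(rep$issues$message, collapse = "; ")), call. = FALSE)
      }
    }
    h <- suppressWarnings(harmonize_units(model_a, model_b))
    list(a = h$model_a, b = h$model_b, log = h$log)
  }, error = function(e) .stop_stage("prepare", conditionMessage(e)))
  model_a <- prep$a; model_b <- prep$b

  # --- stage: match ---------------------------------------------------------
  matches <- tryCatch({
    m <- auto_match(model_a, model_b)
    edits <- config$edits
    if (is.character(edits) && length(edits) == 1L) edits <- read_edit_commands(edits)
    if (length(edits) > 0) m <- apply_edits(m, edits, model_a, model_b)
    m <- classify_conflicts(m, model_a, model_b)
    write_match_table(m, model_a, model_b, art("match_table.tsv"))
    match_set_json(m, art("match_set.json"))
    m
  }, error = function(e) .stop_stage("match", conditionMessage(e)))

  # --- stage: merge ---------------------------------------------------------
  merged <- tryCatch({
    mg <- merge_models(model_a, model_b, matches, config$policy)
    write_model(mg$model, art("merged_model.xml"))
    write_provenance(mg, art("provenance.json"))
    mg
  }, error = function(e) .stop_stage("merge", conditionMessage(e)))

  observables <- .wf_observables(config)

  # --- stage: check (build synthetic data from the originals) ---------------
  checked <- tryCatch({
    datasets_a <- list(); datasets_b <- list()
    for (ex in config$experiments) {
      side <- ex$side
      model <- if (side == "A") model_a else model_b
      # observables realized on the original model of this side: exclusive
      # outputs of the other side are the "?" components and are skipped;
      # species_a/species_b give the original-model ids when they differ
      # from the merged id (overlap species keep model A's id in the merge)
      side_obs <- list()
      for (o in config$observables) {
        s <- o$side %||% "shared"
        if (!(s %in% c("shared", side))) next
        sp <- (if (side == "A") o$species_a else o$species_b) %||% o$species
        if (!(sp %in% names(model$species))) next
        side_obs[[length(side_obs) + 1L]] <-
          observable(sp, o$scale %||% 1, o$label %||% o$species)
      }
      inp <- input_signal(unlist(ex$stimulus), label = ex$label)
      traj <- observe(simulate_model(model, inp, config$time_grid), side_obs)
      ds <- make_synthetic_dataset(traj, inp, origin = side)
      write_dataset(ds, art(sprintf("dataset_%s.tsv", ex$label)))
      if (side == "A") datasets_a[[length(datasets_a) + 1L]] <- ds
      else datasets_b[[length(datasets_b) + 1L]] <- ds
    }
    # merged-model observables address merged (A-side) ids for the overlap
    rep0 <- check_consistency(merged, datasets_a, datasets_b, observables)
    rep0$goal_result <- evaluate_goal(rep0, config$goal)
    consistency_report_json(rep0, art("consistency_pre.json"))
    list(report = rep0, datasets_a = datasets_a, datasets_b = datasets_b)
  }, error = function(e) .stop_stage("check", conditionMessage(e)))

  report <- checked$report
  fit <- NULL
  iterations <- 0L
  merged_now <- merged
  observables_now <- observables

  # --- stage: refit (iterate while inconsistent) ----------------------------
  while (!report$consistent && iterations < config$max_iterations) {
    iterations <- iterations + 1L
    refit <- tryCatch({
      free <- config$free_parameters
      if (identical(free, "auto")) {
        cand <- candidate_free_parameters(merged_now, matches, config$goal,
                                          observables_now)
        free <- unlist(cand, use.names = FALSE)
      }
      if (length(free) == 0) {
        stop("no free parameters available for refitting", call. = FALSE)
      }
      datasets <- c(checked$datasets_a, checked$datasets_b)
      prob <- fit_problem(merged_now, free, datasets, observables_now)
      fr <- fit_parameters(prob, n_starts = config$n_starts,
                           seed = config$seed + iterations - 1L)
      upd <- apply_fit(prob, fr$estimates)
      merged_upd <- merged_now
      merged_upd$model <- upd$model
      list(fit = fr, merged = merged_upd, observables = upd$observables)
    }, error = function(e) .stop_stage("refit", conditionMessage(e)))
    fit <- refit$fit
    merged_now <- refit$merged
    observables_now <- refit$observables
    fit_result_json(fit, art(sprintf("fit_result_%d.json", iterations)))
    report <- check_consistency(merged_now, checked$datasets_a,
                                checked$datasets_b, observables_now)
    report$goal_result <- evaluate_goal(report, config$goal)
    consistency_report_json(report, art(sprintf("consistency_post_%d.json",
                                                iterations)))
    write_model(merged_now$model, art("merged_model_refit.xml"))
  }

  list(status = 0L, consistent = report$consistent,
       report_pre = checked$report, report_post = report, fit = fit,
       merged = merged_now, observables = observables_now,
       iterations = iterations, artifacts = config$out_dir)
}
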