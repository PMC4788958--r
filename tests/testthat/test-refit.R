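# Candidate selection and multi-experiment refitting.

refit_ctx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tp <- default_toy()
      pair <- tp$pair
      m <- auto_match(pair$model_a, pair$model_b)
      merged <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
      grid <- short_grid()
      ds_a <- toy_datasets(pair$model_a, tp$spec, "A", levels = c(0.5, 2),
                           time_grid = grid)
      ds_b <- toy_datasets(pair$model_b, tp$spec, "B", levels = c(0.5, 2),
                           time_grid = grid)
      obs <- toy_observables(tp$spec, "merged")
      cache <<- list(tp = tp, pair = pair, matches = m, merged = merged,
                     grid = grid, ds_a = ds_a, ds_b = ds_b, obs = obs)
    }
    cache
  }
})

test_that("candidate parameters cannot disturb the preserved side", {
  ctx <- refit_ctx()
  goal <- integration_goal("A")
  cand <- candidate_free_parameters(ctx$merged, ctx$matches, goal, ctx$obs)
  expect_setequal(cand$reaction_parameters, c("b_kx1", "b_klink"))
  expect_setequal(cand$initial_amounts, c("init:b_X1", "init:b_X2"))
  expect_equal(cand$observable_scales, "scale:out_B")
  expect_equal(attr(cand, "side"), "B-only")
  # overlap and preserved-side parameters are excluded
  all_refs <- unlist(cand, use.names = FALSE)
  expect_false(any(ctx$pair$overlap_parameter_ids %in% all_refs))
  expect_false(any(grepl("^a_", all_refs)))

  # brute-force check: perturbing each candidate leaves A-side outputs
  # unchanged under the isolated A input
  inp <- input_signal(c(a_stim = 1))
  base <- observe(simulate_model(ctx$merged, inp, ctx$grid),
                  toy_observables(ctx$tp$spec, "A"))
  for (ref in cand$reaction_parameters) {
    mod <- ctx$merged$model
    mod$parameters[[ref]]$value <- mod$parameters[[ref]]$value * 10
    pert <- observe(simulate_model(mod, inp, ctx$grid),
                    toy_observables(ctx$tp$spec, "A"))
    expect_equal(pert$values, base$values, tolerance = 1e-9)
  }

  # preserve B mirrors the selection
  cand_b <- candidate_free_parameters(ctx$merged, ctx$matches,
                                      integration_goal("B"), ctx$obs)
  expect_true(all(grepl("^a_|^init:a_|^scale:out_A$",
                        unlist(cand_b, use.names = FALSE))))
  # goal without preserve_exact: everything non-overlap, with a warning
  expect_warning(
    cand_n <- candidate_free_parameters(ctx$merged, ctx$matches,
                                        integration_goal("none"), ctx$obs),
    "no preserve_exact")
  expect_true(all(c("a_kx1", "b_kx1") %in% cand_n$reaction_parameters))
})

test_that("empty overlap makes every non-preserved parameter a candidate", {
  spec <- toy_pair_spec(2, 2, overlap_species = 0, overlap_reactions = 0,
                        seed = 4)
  pair <- generate_toy_pair(spec)
  m <- auto_match(pair$model_a, pair$model_b)
  merged <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
  cand <- candidate_free_parameters(merged, m, integration_goal("A"))
  expect_setequal(cand$reaction_parameters,
                  grep("^b_", names(pair$model_b$parameters), value = TRUE))
})

test_that("parameter recovery: a perturbed parameter is refit to 1%", {
  ctx <- refit_ctx()
  truth <- ctx$merged$model$parameters$b_klink$value
  broken <- ctx$merged
  broken$model$parameters$b_klink$value <- truth * 10
  # data generated from the true merged model; out_A is identically zero
  # under a B stimulus, so only the B-side outputs are observed
  obs <- Filter(function(o) o$label != "out_A", ctx$obs)
  mk_ds <- function(stim, amount, origin) {
    inp <- input_signal(setNames(amount, stim), paste0(origin, amount))
    traj <- observe(simulate_model(ctx$merged, inp, ctx$grid), obs)
    make_synthetic_dataset(traj, inp, origin = origin)
  }
  datasets <- list(mk_ds("b_stim", 0.5, "B"), mk_ds("b_stim", 2, "B"))
  prob <- fit_problem(broken, "b_klink", datasets, obs)
  fr <- fit_parameters(prob, n_starts = 2, seed = 3)
  expect_lt(abs(fr$estimates[["b_klink"]] - truth) / truth, 0.01)
  expect_lt(fr$chi2_over_N_total, 1e-4)
  expect_equal(fr$seed, 3L)
})

test_that("refitting candidates restores side B and leaves side A untouched", {
  ctx <- refit_ctx()
  goal <- integration_goal("A")
  cand <- candidate_free_parameters(ctx$merged, ctx$matches, goal, ctx$obs)
  free <- unlist(cand, use.names = FALSE)
  datasets <- c(ctx$ds_a, ctx$ds_b)
  prob <- fit_problem(ctx$merged, free, datasets, ctx$obs)
  pre <- check_consistency(ctx$merged, ctx$ds_a, ctx$ds_b, ctx$obs)
  expect_false(pre$consistent)
  fr <- fit_parameters(prob, n_starts = 2, seed = 21)
  upd <- apply_fit(prob, fr$estimates)
  post_model <- ctx$merged
  post_model$model <- upd$model
  post <- check_consistency(post_model, ctx$ds_a, ctx$ds_b, upd$observables)
  expect_true(post$consistent)
  expect_lt(post$chi2_B_over_N, 1)
  # preserved side: no shared scale was freed, so A must be bit-comparable
  expect_lt(post$chi2_A_over_N, 1e-6)

  # objective consistency: reported total equals the pooled chi2/N recomputed
  # through the consistency module at the estimates
  ss <- 0; n <- 0
  for (ds in datasets) {
    out <- observe(simulate_model(upd$model, ds$input, ds$time_grid),
                   upd$observables)
    ss <- ss + chi2_over_N(ds, out) * dataset_size(ds)
    n <- n + dataset_size(ds)
  }
  expect_equal(fr$chi2_over_N_total, ss / n, tolerance = 1e-8)
})

test_that("the best objective is non-increasing in the number of starts", {
  ctx <- refit_ctx()
  broken <- ctx$merged
  broken$model$parameters$b_klink$value <-
    broken$model$parameters$b_klink$value * 30
  prob <- fit_problem(broken, c("b_klink", "b_kx1"), ctx$ds_b, ctx$obs)
  f1 <- fit_parameters(prob, n_starts = 1, seed = 99, maxit = 10)
  f3 <- fit_parameters(prob, n_starts = 3, seed = 99, maxit = 10)
  expect_lte(f3$chi2_over_N_total, f1$chi2_over_N_total + 1e-12)
  # determinism given the seed
  f3b <- fit_parameters(prob, n_starts = 3, seed = 99, maxit = 10)
  expect_identical(f3$estimates, f3b$estimates)
  js <- fit_result_json(f3)
  expect_true(jsonlite::validate(js))
})

test_that("fit_problem rejects unknown refs and bad bounds", {
  ctx <- refit_ctx()
  expect_error(fit_problem(ctx$merged, "ghost", ctx$ds_b, ctx$obs),
               "unknown parameter")
  expect_error(fit_problem(ctx$merged, "init:ghost", ctx$ds_b, ctx$obs),
               "unknown species")
  expect_error(fit_problem(ctx$merged, "scale:ghost", ctx$ds_b, ctx$obs),
               "unknown observable")
  expect_error(fit_problem(ctx$merged, "b_klink", ctx$ds_b, ctx$obs,
                           bounds = list(b_klink = c(-1, 1))),
               "bounds must be positive")
})
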