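# Synthetic datasets, chi^2/N, consistency verdicts, integration goals.

mk_flat_traj <- function(vals, labels, time = seq(0, 3, length.out = nrow(vals))) {
  structure(list(time = time,
                 values = matrix(vals, ncol = length(labels),
                                 dimnames = list(NULL, labels)),
                 labels = labels),
            class = "trajectory")
}

test_that("sigma follows the 10% + 5%-of-max error model (hand-checked)", {
  traj <- mk_flat_traj(cbind(c(0, 5, 10)), "y")
  ds <- make_synthetic_dataset(traj, input_signal(), origin = "A", label = "d")
  # y = 10 on a curve with max 10: 0.10*10 + 0.05*10 = 1.5
  expect_equal(ds$observations$y$sigma[3], 1.5)
  # y = 5: 0.5 + 0.5 = 1.0
  expect_equal(ds$observations$y$sigma[2], 1.0)
  # y = 0 on a curve with max 10: only the absolute term remains
  expect_equal(ds$observations$y$sigma[1], 0.5)
  expect_equal(dataset_size(ds), 3)

  # y = 0 on a curve with max 20 -> sigma = 1.0
  traj2 <- mk_flat_traj(cbind(c(0, 20)), "y")
  ds2 <- make_synthetic_dataset(traj2, input_signal(), origin = "A")
  expect_equal(ds2$observations$y$sigma[1], 1.0)

  # identically zero curve: floored sigma plus a warning
  traj3 <- mk_flat_traj(cbind(c(0, 0), c(4, 4)), c("silent", "loud"))
  expect_warning(ds3 <- make_synthetic_dataset(traj3, input_signal(), origin = "A"),
                 "identically zero")
  expect_true(all(ds3$observations$silent$sigma == 1e-6 * 4))

  expect_error(make_synthetic_dataset(
    structure(list(time = numeric(0),
                   values = matrix(numeric(0), 0, 0), labels = character(0)),
              class = "trajectory"),
    input_signal(), origin = "A"), "empty trajectory")
})

test_that("chi2_over_N evaluates the squared weighted residuals", {
  traj <- mk_flat_traj(cbind(c(10, 10)), "y", time = c(0, 1))
  ds <- make_synthetic_dataset(traj, input_signal(), origin = "A")
  # identical model outputs -> 0
  expect_equal(chi2_over_N(ds, traj), 0)
  # hand-built single point: y=10, sigma=2, model 12 -> ((12-10)/2)^2 = 1
  ds1 <- ds
  ds1$observations$y <- data.frame(value = c(10, 10), sigma = c(2, 2))
  model_out <- mk_flat_traj(cbind(c(12, 10)), "y", time = c(0, 1))
  expect_equal(chi2_over_N(ds1, model_out), (1 + 0) / 2)
  # grid mismatch and missing labels are errors
  bad_grid <- mk_flat_traj(cbind(c(12, 10)), "y", time = c(0, 2))
  expect_error(chi2_over_N(ds1, bad_grid), "grid mismatch")
  bad_lab <- mk_flat_traj(cbind(c(12, 10)), "z", time = c(0, 1))
  expect_error(chi2_over_N(ds1, bad_lab), "absent")
})

test_that("chi2/N is scale-equivariant and positive-definite", {
  pair <- default_toy(divergence = 4, seed = 8)$pair
  spec <- default_toy()$spec
  grid <- short_grid(15)
  inp <- input_signal(c(a_stim = 1), "s")
  obs <- toy_observables(spec, "A")
  traj <- observe(simulate_model(pair$model_a, inp, grid), obs)
  ds <- make_synthetic_dataset(traj, inp, origin = "A")
  # perturbed model outputs give chi2 > 0
  pert <- traj
  pert$values <- pert$values * 1.2
  expect_gt(chi2_over_N(ds, pert), 0)
  # multiplying one output curve's data AND model values by c leaves chi2/N
  # unchanged (sigma is rebuilt from the same curve)
  c_ <- 7.3
  traj_scaled <- traj
  traj_scaled$values[, "O1"] <- c_ * traj_scaled$values[, "O1"]
  ds_scaled <- make_synthetic_dataset(traj_scaled, inp, origin = "A")
  pert_scaled <- pert
  pert_scaled$values[, "O1"] <- c_ * pert_scaled$values[, "O1"]
  expect_equal(chi2_over_N(ds_scaled, pert_scaled), chi2_over_N(ds, pert),
               tolerance = 1e-12)
})

test_that("self-consistency: originals against their own synthetic data", {
  tp <- default_toy()
  grid <- short_grid()
  for (side in c("A", "B")) {
    model <- if (side == "A") tp$pair$model_a else tp$pair$model_b
    ds <- toy_datasets(model, tp$spec, side, levels = c(0.5, 2),
                       time_grid = grid)
    obs <- toy_observables(tp$spec, side)
    for (d in ds) {
      out <- observe(simulate_model(model, d$input, grid), obs)
      expect_lt(chi2_over_N(d, out), 1e-6)
    }
  }
})

test_that("check_consistency pools per side and applies the strict rule", {
  tp <- default_toy()
  pair <- tp$pair
  grid <- short_grid()
  m <- auto_match(pair$model_a, pair$model_b)
  merged <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
  ds_a <- toy_datasets(pair$model_a, tp$spec, "A", levels = c(0.5, 2),
                       time_grid = grid)
  ds_b <- toy_datasets(pair$model_b, tp$spec, "B", levels = c(0.5, 2),
                       time_grid = grid)
  obs <- toy_observables(tp$spec, "merged")
  rep <- check_consistency(merged, ds_a, ds_b, obs)
  # the asymmetry of the worked example: A side reproduced, B side far off
  expect_lt(rep$chi2_A_over_N, 1e-6)
  expect_gt(rep$chi2_B_over_N, 10)
  expect_false(rep$consistent)
  expect_equal(rep$N_A, sum(vapply(ds_a, dataset_size, integer(1))))
  # with divergence 1 both sides pass
  tp1 <- default_toy(divergence = 1)
  m1 <- auto_match(tp1$pair$model_a, tp1$pair$model_b)
  mg1 <- merge_models(tp1$pair$model_a, tp1$pair$model_b, m1, merge_policy("A"))
  rep1 <- check_consistency(
    mg1,
    toy_datasets(tp1$pair$model_a, tp1$spec, "A", levels = 1, time_grid = grid),
    toy_datasets(tp1$pair$model_b, tp1$spec, "B", levels = 1, time_grid = grid),
    obs)
  expect_true(rep1$consistent)
  expect_lt(rep1$chi2_B_over_N, 1e-6)
  js <- consistency_report_json(rep)
  expect_true(jsonlite::validate(js))
})

test_that("the consistency verdict is strict at 1", {
  rep <- structure(list(chi2_A_over_N = 0.5, chi2_B_over_N = 1.0,
                        per_dataset = numeric(0), N_A = 1L, N_B = 1L,
                        consistent = (0.5 < 1) && (1.0 < 1),
                        goal_result = NULL),
                   class = "consistency_report")
  expect_false(rep$consistent)
  g <- integration_goal("A")
  res <- evaluate_goal(rep, g)
  # approx-one tolerates exactly-one on the B side
  expect_true(res$pass)
  # but strict-below-one does not
  res2 <- evaluate_goal(rep, integration_goal("none"))
  expect_false(res2$pass)
})

test_that("goal evaluation reproduces the worked decision points", {
  mk_rep <- function(a, b) {
    structure(list(chi2_A_over_N = a, chi2_B_over_N = b,
                   per_dataset = numeric(0), N_A = 1L, N_B = 1L,
                   consistent = a < 1 && b < 1, goal_result = NULL),
              class = "consistency_report")
  }
  goal <- integration_goal("A")  # preserve A, B approximately one
  # post-refit state of the published example: (0.289, 0.899) -> achieved
  expect_true(evaluate_goal(mk_rep(0.289, 0.899), goal)$pass)
  # pre-refit state: (0.0004, 1689.3) -> fails on the B relation
  res <- evaluate_goal(mk_rep(0.0004, 1689.3), goal)
  expect_false(res$pass)
  fails <- Filter(function(r) !r$pass, res$relations)
  expect_equal(vapply(fails, `[[`, character(1), "side"), "B")
  # perfect fit passes any goal
  expect_true(evaluate_goal(mk_rep(0, 0), goal)$pass)
  expect_true(evaluate_goal(mk_rep(0, 0), integration_goal("none"))$pass)
})

test_that("datasets round-trip through table + JSON header", {
  tp <- default_toy()
  ds <- toy_datasets(tp$pair$model_a, tp$spec, "A", levels = 1,
                     time_grid = short_grid(7))[[1]]
  f <- tempfile(fileext = ".tsv")
  write_dataset(ds, f)
  ds2 <- read_dataset(f)
  expect_equal(ds2$origin, "A")
  expect_equal(ds2$time_grid, ds$time_grid)
  expect_equal(sort(names(ds2$observations)), sort(names(ds$observations)))
  expect_equal(ds2$observations$O1$value, ds$observations$O1$value)
  expect_equal(ds2$input$assignments, ds$input$assignments)
})
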