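# Merge engine: count conservation, policy fidelity, behavior preservation.

test_that("count conservation holds over random fixture pairs", {
  for (seed in 1:4) {
    spec <- toy_pair_spec(n_exclusive_a = 1 + seed %% 3,
                          n_exclusive_b = 2,
                          overlap_species = 3 + seed %% 2,
                          overlap_reactions = 1 + seed %% 2,
                          divergence = 3, seed = seed)
    pair <- generate_toy_pair(spec)
    m <- auto_match(pair$model_a, pair$model_b)
    merged <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
    n_sp_match <- sum(vapply(m$entries, function(e) e$class == "species",
                             logical(1)))
    n_rx_match <- sum(vapply(m$entries, function(e) e$class == "reaction",
                             logical(1)))
    expect_equal(length(merged$model$species),
                 length(pair$model_a$species) + length(pair$model_b$species) -
                   n_sp_match)
    expect_equal(length(merged$model$reactions),
                 length(pair$model_a$reactions) + length(pair$model_b$reactions) -
                   n_rx_match)
    expect_true(validate_model(merged$model)$valid)
  }
})

test_that("disjoint merge is the exact sum of the inputs", {
  spec <- toy_pair_spec(2, 2, overlap_species = 0, overlap_reactions = 0,
                        seed = 9)
  pair <- generate_toy_pair(spec)
  m <- auto_match(pair$model_a, pair$model_b)
  merged <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
  expect_equal(length(merged$model$species),
               length(pair$model_a$species) + length(pair$model_b$species))
  expect_equal(length(merged$model$reactions),
               length(pair$model_a$reactions) + length(pair$model_b$reactions))
  expect_false(any(merged$provenance == "overlap"))
})

test_that("policy fidelity: switching source changes exactly the overlap values", {
  tp <- default_toy()
  pair <- tp$pair
  m <- auto_match(pair$model_a, pair$model_b)
  mg_a <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
  mg_b <- merge_models(pair$model_a, pair$model_b, m, merge_policy("B"))
  par_a <- vapply(mg_a$model$parameters, `[[`, numeric(1), "value")
  par_b <- vapply(mg_b$model$parameters, `[[`, numeric(1), "value")
  expect_identical(names(par_a), names(par_b))
  changed <- names(par_a)[par_a != par_b]
  expect_setequal(changed, pair$overlap_parameter_ids)
  # overlap values equal the chosen source's values exactly
  for (k in seq_along(pair$overlap_parameter_ids)) {
    ida <- pair$overlap_parameter_ids[k]
    idb <- sub("^a_", "b_", ida)
    expect_identical(par_a[[ida]], pair$model_a$parameters[[ida]]$value)
    expect_identical(par_b[[ida]], pair$model_b$parameters[[idb]]$value)
  }
  # initial amounts: identical inputs here, so no other field may drift
  init_a <- vapply(mg_a$model$species, `[[`, numeric(1), "initial_amount")
  init_b <- vapply(mg_b$model$species, `[[`, numeric(1), "initial_amount")
  expect_equal(init_a, init_b)
  # per-element override wins over the default
  ov <- pair$overlap_parameter_ids[1]
  mg_mix <- merge_models(pair$model_a, pair$model_b, m,
                         merge_policy("A", setNames("B", ov)))
  expect_identical(mg_mix$model$parameters[[ov]]$value,
                   pair$model_b$parameters[[sub("^a_", "b_", ov)]]$value)
  others <- setdiff(pair$overlap_parameter_ids, ov)
  for (id in others) {
    expect_identical(mg_mix$model$parameters[[id]]$value,
                     pair$model_a$parameters[[id]]$value)
  }
})

test_that("unresolved hard conflicts demand a manual decision", {
  uni <- function(x) c(is = paste0("urn:test:", x))
  mk <- function(id, law) {
    m <- kinetic_model(id)
    m <- km_add_compartment(m, "c", 1, uris = uni("c"))
    m <- km_add_species(m, "S1", 1, "c", name = "S1", uris = uni("s1"))
    m <- km_add_species(m, "S2", 0, "c", name = "S2", uris = uni("s2"))
    m <- km_add_parameter(m, "k", 1)
    km_add_reaction(m, "r1", c(S1 = 1), c(S2 = 1), kinetic_law = law)
  }
  a <- mk("A", "k*S1")
  b <- mk("B", "k*S1*S1")
  m <- classify_conflicts(auto_match(a, b), a, b)
  expect_error(merge_models(a, b, m, merge_policy("A")), "manual decision")
  # an explicit per-element choice resolves it
  mg <- merge_models(a, b, m, merge_policy("A", c(r1 = "A")))
  expect_s3_class(mg, "merged_model")
})

test_that("merged model preserves side A behavior under isolated input", {
  tp <- default_toy()
  pair <- tp$pair
  m <- auto_match(pair$model_a, pair$model_b)
  merged <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
  grid <- short_grid()
  inp <- input_signal(c(a_stim = 1), "A step")
  orig <- simulate_model(pair$model_a, inp, grid)
  comb <- simulate_model(merged, inp, grid)
  for (sp in colnames(orig$values)) {
    expect_equal(comb$values[, sp], orig$values[, sp], tolerance = 1e-7)
  }
  # and the B branch stays silent at zero input
  expect_equal(max(abs(comb$values[, c("b_X2", "b_stim")])), 0)
})

test_that("merged SBML writes, reloads and provenance serializes", {
  pair <- default_toy()$pair
  m <- auto_match(pair$model_a, pair$model_b)
  merged <- merge_models(pair$model_a, pair$model_b, m, merge_policy("A"))
  f <- tempfile(fileext = ".xml")
  write_model(merged$model, f)
  re <- load_model(f)
  expect_equal(sort(names(re$species)), sort(names(merged$model$species)))
  expect_true(validate_model(re)$valid)
  pj <- tempfile(fileext = ".json")
  write_provenance(merged, pj)
  pv <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(sort(unique(unlist(pv))), c("A-only", "B-only", "overlap"))
})
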