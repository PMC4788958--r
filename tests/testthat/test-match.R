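# Automatic matching, manual edits, conflict classification.

mk_pair_for_match <- function() {
  uni <- function(x) c(is = paste0("urn:test:", x))
  a <- kinetic_model("MA")
  a <- km_add_compartment(a, "cyt", 1, uris = uni("cyt"))
  a <- km_add_species(a, "ERK", 1, "cyt", name = "ERK", uris = uni("erk"))
  a <- km_add_species(a, "S1", 1, "cyt", name = "S1", uris = uni("s1"))
  a <- km_add_species(a, "S2", 0, "cyt", name = "S2", uris = uni("s2"))
  a <- km_add_parameter(a, "k1", 0.5)
  a <- km_add_reaction(a, "ra", c(S1 = 1), c(S2 = 1), kinetic_law = "k1*S1")
  b <- kinetic_model("MB")
  b <- km_add_compartment(b, "cytosol", 1, uris = uni("cyt"))
  b <- km_add_species(b, "ERK2", 1, "cytosol", name = "ERK2", uris = uni("erk"))
  b <- km_add_species(b, "S1b", 1, "cytosol", name = "S1", uris = uni("s1"))
  b <- km_add_species(b, "S2b", 0, "cytosol", name = "S2", uris = uni("s2"))
  b <- km_add_parameter(b, "kappa", 5)
  b <- km_add_reaction(b, "rb", c(S1b = 1), c(S2b = 1), kinetic_law = "kappa*S1b")
  list(a = a, b = b)
}

test_that("auto_match pairs annotated elements across naming differences", {
  p <- mk_pair_for_match()
  m <- auto_match(p$a, p$b)
  tab <- as_match_table(m, p$a, p$b)
  # ERK ~ ERK2 via shared UniProt-style URI despite different names/ids
  expect_true(any(tab$class == "species" & tab$id_A == "ERK" & tab$id_B == "ERK2"))
  expect_true(any(tab$class == "reaction" & tab$id_A == "ra" & tab$id_B == "rb"))
  expect_true(any(tab$class == "parameter" & tab$id_A == "k1" & tab$id_B == "kappa"))
  expect_true(any(tab$class == "compartment"))
  # partition invariant: every element is matched xor unmatched
  for (cls in c("species", "reaction", "parameter", "compartment")) {
    slot <- switch(cls, species = "species", reaction = "reactions",
                   parameter = "parameters", compartment = "compartments")
    got <- sort(c(tab$id_A[tab$class == cls], m$unmatched_a[[cls]]))
    expect_equal(got, sort(names(p$a[[slot]])))
  }
})

test_that("disjoint models yield an empty match set", {
  spec <- toy_pair_spec(2, 2, overlap_species = 0, overlap_reactions = 0,
                        seed = 3)
  pair <- generate_toy_pair(spec)
  m <- auto_match(pair$model_a, pair$model_b)
  expect_length(m$entries, 0)
  n_a <- length(pair$model_a$compartments) + length(pair$model_a$species) +
    length(pair$model_a$parameters) + length(pair$model_a$reactions)
  expect_equal(sum(lengths(m$unmatched_a)), n_a)
})

test_that("self-match is complete and conflict-free", {
  pair <- default_toy()$pair
  a <- pair$model_a
  m <- auto_match(a, a)
  # every element matched to itself
  expect_equal(length(m$entries),
               length(a$species) + length(a$reactions) +
                 length(a$parameters) + length(a$compartments))
  for (e in m$entries) expect_identical(e$id_a, e$id_b)
  expect_equal(sum(lengths(m$unmatched_a)), 0)
  m <- classify_conflicts(m, a, a)
  expect_true(all(vapply(m$entries, function(e) nrow(e$conflicts) == 0,
                         logical(1))))
})

test_that("auto_match is symmetric up to role swap", {
  p <- default_toy()$pair
  ab <- auto_match(p$model_a, p$model_b)
  ba <- auto_match(p$model_b, p$model_a)
  key <- function(m, swap = FALSE) {
    sort(vapply(m$entries, function(e) {
      if (swap) paste(e$class, e$id_b, e$id_a) else paste(e$class, e$id_a, e$id_b)
    }, character(1)))
  }
  expect_identical(key(ab), key(ba, swap = TRUE))
})

test_that("ambiguous candidates stay unmatched and are flagged", {
  uni <- c(is = "urn:test:dup")
  a <- kinetic_model("A")
  a <- km_add_compartment(a, "c", 1)
  a <- km_add_species(a, "X", 1, "c", name = "X", uris = uni)
  b <- kinetic_model("B")
  b <- km_add_compartment(b, "c2", 1)
  # two equally plausible candidates in B (same URI, same name)
  b <- km_add_species(b, "X1", 1, "c2", name = "X", uris = uni)
  b <- km_add_species(b, "X2", 2, "c2", name = "X", uris = uni)
  m <- auto_match(a, b)
  expect_false(any(vapply(m$entries, function(e) e$class == "species",
                          logical(1))))
  expect_true("X" %in% m$unmatched_a$species)
  expect_true(all(c("X1", "X2") %in% m$unmatched_b$species))
  cc <- m$candidate_conflicts
  expect_true(all(cc$kind == "annotation-name-disagreement"))
  expect_setequal(cc$id_b, c("X1", "X2"))
})

test_that("apply_edits enforces the one-to-one and class invariants", {
  p <- mk_pair_for_match()
  m <- auto_match(p$a, p$b)
  # remove an auto match -> elements return to the unmatched lists
  m2 <- apply_edits(m, list(list(action = "remove-match", class = "species",
                                 id_a = "ERK", id_b = "ERK2")), p$a, p$b)
  expect_true("ERK" %in% m2$unmatched_a$species)
  expect_true("ERK2" %in% m2$unmatched_b$species)
  # manual re-add carries source = manual
  m3 <- apply_edits(m2, list(list(action = "add-match", class = "species",
                                  id_a = "ERK", id_b = "ERK2")), p$a, p$b)
  e <- Filter(function(x) x$id_a == "ERK", m3$entries)[[1]]
  expect_equal(e$source, "manual")
  expect_equal(e$confidence, "user-asserted")
  # many-to-one rejected
  expect_error(
    apply_edits(m3, list(list(action = "add-match", class = "species",
                              id_a = "S1", id_b = "ERK2")), p$a, p$b),
    "many-to-one")
  # class mismatch rejected (species paired with a reaction id)
  expect_error(
    apply_edits(m3, list(list(action = "add-match", class = "species",
                              id_a = "S1", id_b = "rb")), p$a, p$b),
    "no species")
  # level-of-detail is only ever user-asserted
  m4 <- apply_edits(m3, list(list(action = "flag-match", class = "reaction",
                                  id_a = "ra", id_b = "rb",
                                  kind = "level-of-detail",
                                  detail = "lumped in B")), p$a, p$b)
  e <- Filter(function(x) x$class == "reaction", m4$entries)[[1]]
  expect_true("level-of-detail" %in% e$conflicts$kind)
})

test_that("classify_conflicts flags the structural challenge cases", {
  uni <- function(x) c(is = paste0("urn:test:", x))
  # modifier-vs-reactant: S1 modifies production of S2 in A, consumed in B
  a <- kinetic_model("A")
  a <- km_add_compartment(a, "c", 1, uris = uni("c"))
  a <- km_add_species(a, "S1", 1, "c", name = "S1", uris = uni("s1"))
  a <- km_add_species(a, "S2", 0, "c", name = "S2", uris = uni("s2"))
  a <- km_add_parameter(a, "k", 1)
  a <- km_add_reaction(a, "r1", numeric(0), c(S2 = 1), modifiers = "S1",
                       kinetic_law = "k*S1")
  b <- kinetic_model("B")
  b <- km_add_compartment(b, "c", 1, uris = uni("c"))
  b <- km_add_species(b, "S1", 1, "c", name = "S1", uris = uni("s1"))
  b <- km_add_species(b, "S2", 0, "c", name = "S2", uris = uni("s2"))
  b <- km_add_parameter(b, "k", 1)
  b <- km_add_reaction(b, "r1", c(S1 = 1), c(S2 = 1), kinetic_law = "k*S1")
  m <- classify_conflicts(auto_match(a, b), a, b)
  cc <- m$candidate_conflicts
  expect_true(any(cc$kind == "modifier-vs-reactant" &
                    cc$id_a == "r1" & cc$id_b == "r1"))

  # different-kinetics: same participants, different rate law
  b2 <- b
  b2$reactions$r1 <- a$reactions$r1  # same structure as A now
  b2$reactions$r1$kinetic_law <- str2lang("k*S1*S1")
  m2 <- classify_conflicts(auto_match(a, b2), a, b2)
  rx <- Filter(function(e) e$class == "reaction", m2$entries)
  expect_length(rx, 1)
  expect_true("different-kinetics" %in% rx[[1]]$conflicts$kind)

  # commutation alone is NOT a kinetics conflict
  b3 <- b2
  b3$reactions$r1$kinetic_law <- str2lang("S1*k")
  m3 <- classify_conflicts(auto_match(a, b3), a, b3)
  rx3 <- Filter(function(e) e$class == "reaction", m3$entries)
  expect_false("different-kinetics" %in% rx3[[1]]$conflicts$kind)

  # different-compartment: URI-equal species in unmatched compartments
  a4 <- kinetic_model("A4")
  a4 <- km_add_compartment(a4, "cyt", 1, uris = uni("cyt"))
  a4 <- km_add_species(a4, "P", 1, "cyt", name = "P", uris = uni("p"))
  b4 <- kinetic_model("B4")
  b4 <- km_add_compartment(b4, "nuc", 1, uris = uni("nuc"))
  b4 <- km_add_species(b4, "P", 1, "nuc", name = "P", uris = uni("p"))
  m4 <- classify_conflicts(auto_match(a4, b4), a4, b4)
  sp <- Filter(function(e) e$class == "species", m4$entries)
  expect_length(sp, 1)
  expect_true("different-compartment" %in% sp[[1]]$conflicts$kind)
})

test_that("match tables and JSON round-trip", {
  p <- mk_pair_for_match()
  m <- classify_conflicts(auto_match(p$a, p$b), p$a, p$b)
  f <- tempfile(fileext = ".tsv")
  write_match_table(m, p$a, p$b, f)
  m2 <- read_match_table(f, p$a, p$b)
  key <- function(x) sort(vapply(x$entries, function(e)
    paste(e$class, e$id_a, e$id_b, e$source), character(1)))
  expect_identical(key(m2), key(m))
  js <- match_set_json(m)
  expect_true(jsonlite::validate(js))
})
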