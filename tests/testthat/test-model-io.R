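# SBML reading, validation, writing, round-tripping, unit harmonization.

test_that("load_model parses a minimal SBML file and rejects junk", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '  <model id="mini" name="minimal">',
    '    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>',
    '    <listOfSpecies><species id="X" compartment="c" initialConcentration="2.5"',
    '      boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/></listOfSpecies>',
    '  </model>', '</sbml>'), f)
  m <- load_model(f)
  expect_s3_class(m, "kinetic_model")
  expect_length(m$species, 1)
  expect_length(m$reactions, 0)
  expect_equal(m$species$X$initial_amount, 2.5)

  junk <- tempfile(fileext = ".xml")
  writeLines("this is not SBML at all", junk)
  expect_error(load_model(junk), "non-SBML content")

  notsbml <- tempfile(fileext = ".xml")
  writeLines("<foo><bar/></foo>", notsbml)
  expect_error(load_model(notsbml), "non-SBML content")

  expect_error(load_model(tempfile()), "file not found")
})

test_that("unsupported constructs are rejected by name", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="ev">',
    '    <listOfEvents><event id="e1"/></listOfEvents>',
    '  </model>', '</sbml>'), f)
  expect_error(load_model(f), "unsupported construct: events")

  g <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="ar">',
    '    <listOfRules><algebraicRule/></listOfRules>',
    '  </model>', '</sbml>'), g)
  expect_error(load_model(g), "unsupported construct: algebraic rules")
})

test_that("write/load round trip preserves every element", {
  m <- make_cycle_model()
  m$unit_roles <- list(substance = "mole", time = "second", volume = "litre")
  f <- tempfile(fileext = ".xml")
  write_model(m, f)
  m2 <- load_model(f)
  expect_equal(names(m2$species), names(m$species))
  expect_equal(names(m2$parameters), names(m$parameters))
  expect_equal(names(m2$reactions), names(m$reactions))
  for (id in names(m$species)) {
    expect_equal(m2$species[[id]]$initial_amount, m$species[[id]]$initial_amount)
    expect_equal(m2$species[[id]]$boundary, m$species[[id]]$boundary)
  }
  for (id in names(m$parameters)) {
    expect_equal(m2$parameters[[id]]$value, m$parameters[[id]]$value)
  }
  for (id in names(m$reactions)) {
    expect_equal(deparse(m2$reactions[[id]]$kinetic_law),
                 deparse(m$reactions[[id]]$kinetic_law))
    expect_equal(m2$reactions[[id]]$reactants, m$reactions[[id]]$reactants)
    expect_equal(m2$reactions[[id]]$modifiers, m$reactions[[id]]$modifiers)
  }
})

test_that("annotations, SBO terms and local parameters survive a round trip", {
  m <- kinetic_model("ann", level = 2L, version = 4L)
  m <- km_add_compartment(m, "c", 1)
  m <- km_add_species(m, "E", 1, "c", name = "ERK",
                      uris = c(is = "http://identifiers.org/uniprot/P28482"),
                      sbo = "SBO:0000252")
  m <- km_add_parameter(m, "r1__k", 0.7, origin_reaction = "r1")
  m <- km_add_reaction(m, "r1", c(E = 1), numeric(0), kinetic_law = "r1__k*E",
                       sbo = "SBO:0000179")
  m$reactions$r1$local_parameters <- "r1__k"
  f <- tempfile(fileext = ".xml")
  write_model(m, f)
  m2 <- load_model(f)
  expect_equal(unname(m2$species$E$uris),
               "http://identifiers.org/uniprot/P28482")
  expect_equal(names(m2$species$E$uris), "is")
  expect_equal(m2$species$E$sbo, "SBO:0000252")
  # local parameter re-globalized under the same id
  expect_true("r1__k" %in% names(m2$parameters))
  expect_equal(m2$parameters$r1__k$value, 0.7)
  expect_equal(m2$parameters$r1__k$origin_reaction, "r1")
  expect_equal(deparse(m2$reactions$r1$kinetic_law), "r1__k * E")
})

test_that("validate_model reports dangling references and duplicate ids", {
  good <- make_cycle_model()
  rep <- validate_model(good)
  expect_true(rep$valid)
  expect_equal(nrow(rep$issues), 0)

  bad <- good
  bad$reactions$ph$kinetic_law <- str2lang("kf*K*S*ghost")
  rep2 <- validate_model(bad)
  expect_false(rep2$valid)
  expect_match(paste(rep2$issues$message, collapse = " "), "ghost")

  dup <- good
  dup$parameters[["S"]] <- list(id = "S", name = "S", value = 1,
                                units = NA_character_, constant = TRUE,
                                origin_reaction = NA_character_,
                                sbo = NA_character_, uris = character(0))
  rep3 <- validate_model(dup)
  expect_false(rep3$valid)
  expect_match(paste(rep3$issues$message, collapse = " "), "duplicate id 'S'")

  js <- validation_report_json(rep3)
  expect_true(jsonlite::validate(js))
  expect_false(jsonlite::fromJSON(js)$valid)
})

test_that("MathML corner cases parse and serialize", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mm">',
    '<listOfFunctionDefinitions>',
    '  <functionDefinition id="mm_rate">',
    '    <math xmlns="http://www.w3.org/1998/Math/MathML"><lambda>',
    '      <bvar><ci>Vm</ci></bvar><bvar><ci>Km</ci></bvar><bvar><ci>s</ci></bvar>',
    '      <apply><divide/><apply><times/><ci>Vm</ci><ci>s</ci></apply>',
    '        <apply><plus/><ci>Km</ci><ci>s</ci></apply></apply>',
    '    </lambda></math>',
    '  </functionDefinition>',
    '</listOfFunctionDefinitions>',
    '<listOfCompartments><compartment id="c" size="2"/></listOfCompartments>',
    '<listOfSpecies><species id="S" compartment="c" initialConcentration="1"/></listOfSpecies>',
    '<listOfParameters>',
    '  <parameter id="Vmax" value="0.5"/><parameter id="K" value="0.1"/>',
    '</listOfParameters>',
    '<listOfReactions><reaction id="r1" reversible="false">',
    '  <listOfReactants><speciesReference species="S"/></listOfReactants>',
    '  <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '    <apply><times/>',
    '      <cn type="e-notation">1.5<sep/>-2</cn>',
    '      <apply><ci>mm_rate</ci><ci>Vmax</ci><ci>K</ci><ci>S</ci></apply>',
    '    </apply>',
    '  </math></kineticLaw>',
    '</reaction></listOfReactions>',
    '</model></sbml>'), f)
  m <- load_model(f)
  law <- m$reactions$r1$kinetic_law
  # function definition inlined, e-notation constant folded into a number
  env <- list(Vmax = 0.5, K = 0.1, S = 1)
  expect_equal(eval(law, env), 0.015 * 0.5 * 1 / (0.1 + 1))
  # serialization is stable under a write/load cycle
  g <- tempfile(fileext = ".xml")
  write_model(m, g)
  m2 <- load_model(g)
  expect_equal(eval(m2$reactions$r1$kinetic_law, env), eval(law, env))
})

test_that("harmonize_units rescales amounts and rate constants (hand-checked)", {
  # A in micromole/second, B in millimole/minute
  mk <- function(id, sub_scale, time_mult, k) {
    m <- kinetic_model(id)
    m$units <- list(
      u_sub = list(list(kind = "mole", exponent = 1, scale = sub_scale,
                        multiplier = 1)),
      u_time = list(list(kind = "second", exponent = 1, scale = 0,
                         multiplier = time_mult)),
      u_per_time = list(list(kind = "second", exponent = -1, scale = 0,
                             multiplier = time_mult)))
    m$unit_roles <- list(substance = "u_sub", time = "u_time", volume = "litre")
    m <- km_add_compartment(m, "c", 1)
    m <- km_add_species(m, "S", 1, "c", uris = c(is = "urn:test:S"))
    m <- km_add_parameter(m, "k", k, units = "u_per_time")
    km_add_reaction(m, "r", c(S = 1), numeric(0), kinetic_law = "k*S")
  }
  a <- mk("A", -6, 1, 0.1)     # micromole, second
  b <- mk("B", -3, 60, 6)      # millimole, minute, k = 6/min = 0.1/s
  h <- harmonize_units(a, b)
  # amounts: millimole -> micromole is a factor 1000
  expect_equal(h$model_b$species$S$initial_amount, 1000)
  # first-order rate constant: per minute -> per second is a factor 1/60
  expect_equal(h$model_b$parameters$k$value, 0.1)
  expect_true(nrow(h$log) > 0)

  # identical systems: unchanged, empty log
  h2 <- harmonize_units(a, mk("A2", -6, 1, 0.1))
  expect_identical(h2$model_b$species$S$initial_amount, 1)
  expect_equal(nrow(h2$log), 0)

  # non-convertible: item-based substance vs mole
  cnt <- mk("C", -6, 1, 0.1)
  cnt$units$u_sub <- list(list(kind = "item", exponent = 1, scale = 0,
                               multiplier = 1))
  expect_error(harmonize_units(a, cnt), "non-convertible")
})

test_that("harmonize_units preserves dynamics up to unit factors", {
  mk <- function(id, time_mult, k) {
    m <- kinetic_model(id)
    m$units <- list(
      u_time = list(list(kind = "second", exponent = 1, scale = 0,
                         multiplier = time_mult)),
      u_per_time = list(list(kind = "second", exponent = -1, scale = 0,
                             multiplier = time_mult)))
    m$unit_roles <- list(substance = "mole", time = "u_time", volume = "litre")
    m <- km_add_compartment(m, "c", 1)
    m <- km_add_species(m, "S", 3, "c")
    m <- km_add_parameter(m, "k", k, units = "u_per_time")
    km_add_reaction(m, "r", c(S = 1), numeric(0), kinetic_law = "k*S")
  }
  a <- mk("A", 1, 0.01)          # seconds
  b <- mk("B", 60, 0.6)          # minutes, k = 0.6/min
  h <- harmonize_units(a, b)
  grid_min <- seq(0, 10, length.out = 11)       # minutes
  grid_sec <- grid_min * 60                     # the same instants in seconds
  before <- simulate_model(b, NULL, grid_min)
  after <- simulate_model(h$model_b, NULL, grid_sec)
  expect_equal(after$values[, "S"], before$values[, "S"], tolerance = 1e-8)
})
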