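# Fixture generation: synthetic overlapping model pairs with known ground
# truth, a deterministic stand-in pair with the published case-study shape,
# and the case-study assembler that consumes local copies of the BioModels
# accession files.
#
# Toy topology (emulating two input branches converging on a shared
# cascade): each model owns a step-input species and an exclusive upstream
# chain X1 -> ... -> Xn (only the first transition is stimulus-driven and
# all chain species except X1 start empty, so the branch is silent without
# input). The last chain species drives synthesis of the first species of a
# shared linear cascade O1 -> O2 -> ... (the overlap). Model B's overlap
# rate constants equal model A's times a divergence factor.

#' Specification of a synthetic overlapping model pair
#'
#' @param n_exclusive_a,n_exclusive_b number of exclusive chain species per
#'   model (>= 1; the step-input species comes on top of these).
#' @param overlap_species,overlap_reactions size of the shared cascade;
#'   requires `overlap_reactions <= overlap_species - 1` (a linear chain).
#' @param divergence factor by which model B's overlap kinetic parameters
#'   differ from model A's (1 = identical overlap parameterization).
#' @param seed integer seed; rate constants are log-uniform in [1e-3, 1e1],
#'   initial amounts uniform in [0.1, 10].
#' @export
toy_pair_spec <- function(n_exclusive_a = 2L, n_exclusive_b = 2L,
                          overlap_species = 3L, overlap_reactions = 2L,
                          divergence = 1, seed = 1L) {
  if (overlap_species < 0 || overlap_reactions < 0 ||
      (overlap_species > 0 && overlap_reactions > overlap_species - 1L) ||
      (overlap_species == 0 && overlap_reactions > 0) ||
      n_exclusive_a < 1L || n_exclusive_b < 1L) {
    stop("infeasible toy pair spec", call. = FALSE)
  }
  structure(list(n_exclusive_a = as.integer(n_exclusive_a),
                 n_exclusive_b = as.integer(n_exclusive_b),
                 overlap_species = as.integer(overlap_species),
                 overlap_reactions = as.integer(overlap_reactions),
                 divergence = divergence, seed = as.integer(seed)),
            class = "toy_pair_spec")
}

#' Generate a synthetic overlapping model pair with ground truth
#'
#' Both models validate and are simulatable; overlap elements carry
#' identical annotations and names in both models (different ids), so the
#' planted overlap is exactly what annotation-based matching should recover.
#'
#' @param spec a [toy_pair_spec()].
#' @return list with `model_a`, `model_b`, `ground_truth` (a `match_set`
#'   holding the planted matches) and `overlap_parameter_ids` (A-side ids).
#' @export
generate_toy_pair <- function(spec = toy_pair_spec()) {
  stopifnot(inherits(spec, "toy_pair_spec"))
  set.seed(spec$seed)
  m <- spec$overlap_species
  r <- spec$overlap_reactions
  rate <- function() 10^runif(1, -3, 1)
  amount <- function() runif(1, 0.1, 10)

  k_overlap <- if (r > 0) vapply(seq_len(r), function(i) rate(), numeric(1)) else numeric(0)
  o_init <- if (m > 0) c(amount(), rep(0, m - 1L)) else numeric(0)

  build <- function(side, n_excl, k_ov) {
    pre <- tolower(side)
    mdl <- kinetic_model(paste0("toy_", side), name = paste0("toy model ", side))
    # a fully disjoint pair (m == 0) shares nothing, not even the compartment
    cell_uri <- if (m > 0) "urn:miriam:toy:cell" else {
      paste0("urn:miriam:toy:", side, ":cell")
    }
    mdl <- km_add_compartment(mdl, paste0(pre, "_cell"), size = 1,
                              name = if (m > 0) "cell" else paste0("cell_", side),
                              uris = c(is = cell_uri))
    cellid <- paste0(pre, "_cell")
    stim <- paste0(pre, "_stim")
    mdl <- km_add_species(mdl, stim, amount(), cellid,
                          name = paste0("stimulus_", side),
                          boundary = TRUE, constant = TRUE,
                          uris = c(is = paste0("urn:miriam:toy:", side, ":stim")))
    xs <- paste0(pre, "_X", seq_len(n_excl))
    for (i in seq_len(n_excl)) {
      mdl <- km_add_species(mdl, xs[i], if (i == 1L) amount() else 0, cellid,
                            name = paste0("X", i, "_", side),
                            uris = c(is = paste0("urn:miriam:toy:", side, ":X", i)))
    }
    os <- paste0(pre, "_O", seq_len(m))
    for (j in seq_len(m)) {
      mdl <- km_add_species(mdl, os[j], o_init[j], cellid, name = paste0("O", j),
                            uris = c(is = paste0("urn:miriam:toy:O", j)))
    }
    # exclusive chain: stimulus-driven first step, then spontaneous transfers
    for (i in seq_len(n_excl - 1L)) {
      kid <- paste0(pre, "_kx", i)
      mdl <- km_add_parameter(mdl, kid, rate())
      rid <- paste0(pre, "_RX", i)
      if (i == 1L) {
        mdl <- km_add_reaction(mdl, rid, c(setNames(1, xs[1])), c(setNames(1, xs[2])),
                               modifiers = stim,
                               kinetic_law = sprintf("%s * %s * %s", kid, stim, xs[1]),
                               name = paste0("activation_X1_", side))
      } else {
        mdl <- km_add_reaction(mdl, rid, c(setNames(1, xs[i])),
                               c(setNames(1, xs[i + 1L])),
                               kinetic_law = sprintf("%s * %s", kid, xs[i]),
                               name = paste0("transfer_X", i, "_", side))
      }
    }
    if (m > 0) {
      # exclusive link: synthesis of O1 driven by the last chain species
      klink <- paste0(pre, "_klink")
      mdl <- km_add_parameter(mdl, klink, rate())
      link_law <- if (n_excl == 1L) {
        sprintf("%s * %s * %s", klink, stim, xs[1])
      } else {
        sprintf("%s * %s", klink, xs[n_excl])
      }
      link_mods <- if (n_excl == 1L) c(xs[1], stim) else xs[n_excl]
      mdl <- km_add_reaction(mdl, paste0(pre, "_Rlink"), numeric(0),
                             c(setNames(1, os[1])), modifiers = link_mods,
                             kinetic_law = link_law,
                             name = paste0("O1_synthesis_", side))
    }
    # shared cascade (the overlap): identical structure and annotations
    for (j in seq_len(r)) {
      kid <- paste0(pre, "_ko", j)
      mdl <- km_add_parameter(mdl, kid, k_ov[j])
      mdl <- km_add_reaction(mdl, paste0(pre, "_RO", j), c(setNames(1, os[j])),
                             c(setNames(1, os[j + 1L])),
                             kinetic_law = sprintf("%s * %s", kid, os[j]),
                             name = paste0("cascade_O", j),
                             uris = c(is = paste0("urn:miriam:toy:RO", j)))
    }
    mdl
  }

  model_a <- build("A", spec$n_exclusive_a, k_overlap)
  model_b <- build("B", spec$n_exclusive_b, k_overlap * spec$divergence)

  entries <- list()
  if (m > 0) {
    entries[[1L]] <- .match_entry("compartment", "a_cell", "b_cell", "auto",
                                  "identical-annotation")
  }
  for (j in seq_len(m)) {
    entries[[length(entries) + 1L]] <- .match_entry(
      "species", paste0("a_O", j), paste0("b_O", j), "auto",
      "identical-annotation")
  }
  for (j in seq_len(r)) {
    entries[[length(entries) + 1L]] <- .match_entry(
      "reaction", paste0("a_RO", j), paste0("b_RO", j), "auto",
      "identical-annotation")
    entries[[length(entries) + 1L]] <- .match_entry(
      "parameter", paste0("a_ko", j), paste0("b_ko", j), "auto",
      "identical-annotation")
  }
  ground_truth <- .new_match_set(model_a, model_b, entries)

  list(model_a = model_a, model_b = model_b, ground_truth = ground_truth,
       overlap_parameter_ids = if (r > 0) paste0("a_ko", seq_len(r)) else character(0))
}

#' Default observables of a toy model or toy merged model
#'
#' One exclusive output per side (the end of the exclusive chain, analogous
#' to a phosphorylated receptor) and the end of the shared cascade as the
#' common output.
#'
#' @param spec the [toy_pair_spec()] used for generation.
#' @param side `"A"`, `"B"`, or `"merged"` (both exclusive outputs).
#' @export
toy_observables <- function(spec, side = c("A", "B", "merged")) {
  side <- match.arg(side)
  # observe the *consumed* cascade species: their (quasi-)steady-state levels
  # scale as flux/k and are therefore sensitive to the overlap rate
  # constants, unlike the terminal species, which merely integrates the flux
  n_obs <- max(spec$overlap_reactions, 0L)
  shared <- function(pre) {
    lapply(seq_len(n_obs), function(j) {
      observable(paste0(pre, "_O", j), 1, paste0("O", j))
    })
  }
  out_a <- observable(paste0("a_X", spec$n_exclusive_a), 1, "out_A")
  out_b <- observable(paste0("b_X", spec$n_exclusive_b), 1, "out_B")
  if (side == "A") {
    c(list(out_a), shared("a"))
  } else if (side == "B") {
    c(list(out_b), shared("b"))
  } else {
    c(list(out_a, out_b), shared("a"))  # merged keeps model A's ids
  }
}

#' Build per-side synthetic datasets from an original toy model
#'
#' Simulates the original model under a series of step-stimulus levels and
#' converts the observed outputs into synthetic datasets.
#'
#' @param model an original toy model (side A or B).
#' @param spec the generating [toy_pair_spec()].
#' @param side `"A"` or `"B"`.
#' @param levels stimulus amounts; default a log-spaced series.
#' @param time_grid output grid; default 0-3600 s, 61 points.
#' @export
toy_datasets <- function(model, spec, side = c("A", "B"),
                         levels = 10^seq(-1, 0.5, length.out = 3),
                         time_grid = seq(0, 3600, length.out = 61)) {
  side <- match.arg(side)
  stim <- paste0(tolower(side), "_stim")
  obs <- toy_observables(spec, side)
  lapply(seq_along(levels), function(k) {
    inp <- input_signal(setNames(levels[k], stim),
                        label = sprintf("%s_step_%d", side, k))
    traj <- observe(simulate_model(model, inp, time_grid), obs)
    make_synthetic_dataset(traj, inp, origin = side)
  })
}

# ---- deterministic stand-in with the case-study shape -----------------------

#' Synthetic stand-in for the published EGF/NGF case study
#'
#' A deterministic, hand-parameterized pair of receptor-cascade models with
#' the shape of the published case study: 11 reactions and 11 species per
#' model, an overlap of 4 reactions and 5 species (the downstream
#' phosphorylation cascade), two shared outputs and one exclusive
#' (receptor) output per model. This is a SYNTHETIC stand-in built in code -
#' it is not the BioModels material, whose accession files this package
#' cannot redistribute; use [build_case_study()] with local copies of the
#' accession files for the real thing.
#'
#' Each model: ligand L (step input) activates receptor R -> pR (with
#' dephosphorylation and internalization), pR phosphorylates an adapter
#' I -> pI, and pI drives the shared cascade Akt -> pAkt -> (S6 -> pS6 ->
#' ppS6). Model B's overlap rate constants are model A's times `divergence`.
#'
#' @param divergence factor separating the two models' overlap kinetics
#'   (default 10, a clearly inconsistent pair as in the published example).
#' @return list with `model_a`, `model_b`, `observables_a`, `observables_b`,
#'   `observables_merged`, `stimulus_a`, `stimulus_b`, `output_labels`.
#' @export
synthetic_case_study_pair <- function(divergence = 10) {
  k_overlap <- c(kdeph_akt = 0.02, kph_s6 = 0.01, kph2_s6 = 0.008,
                 krec_s6 = 0.005)
  o_init <- c(Akt = 2, pAkt = 0, S6 = 3, pS6 = 0, ppS6 = 0)

  build <- function(side, k_ov, k_excl) {
    pre <- tolower(side)
    lig <- paste0(pre, "_L")
    ids <- function(x) paste0(pre, "_", x)
    uri_x <- function(x) c(is = paste0("urn:miriam:synthcase:", side, ":", x))
    uri_o <- function(x) c(is = paste0("urn:miriam:synthcase:", x))
    mdl <- kinetic_model(paste0("synthcase_", side),
                         name = paste0("synthetic case-study model ", side))
    mdl <- km_add_compartment(mdl, ids("cell"), 1, name = "cell",
                              uris = uri_o("cell"))
    cell <- ids("cell")
    mdl <- km_add_species(mdl, lig, 1, cell, name = paste0("ligand_", side),
                          boundary = TRUE, constant = TRUE, uris = uri_x("L"))
    for (s in c("R", "pR", "Rd", "I", "pI")) {
      init <- switch(s, R = 5, I = 4, 0)
      mdl <- km_add_species(mdl, ids(s), init, cell,
                            name = paste0(s, "_", side), uris = uri_x(s))
    }
    for (s in names(o_init)) {
      mdl <- km_add_species(mdl, ids(s), o_init[[s]], cell, name = s,
                            uris = uri_o(s))
    }
    for (p in names(k_excl)) mdl <- km_add_parameter(mdl, ids(p), k_excl[[p]])
    for (p in names(k_ov)) mdl <- km_add_parameter(mdl, ids(p), k_ov[[p]])
    law <- function(...) sprintf(...)
    mdl <- km_add_reaction(mdl, ids("r1"), c(setNames(1, ids("R"))),
                           c(setNames(1, ids("pR"))), modifiers = lig,
                           kinetic_law = law("%s * %s * %s", ids("kact"), lig, ids("R")),
                           name = paste0("receptor_activation_", side))
    mdl <- km_add_reaction(mdl, ids("r2"), c(setNames(1, ids("pR"))),
                           c(setNames(1, ids("R"))),
                           kinetic_law = law("%s * %s", ids("kdeact"), ids("pR")),
                           name = paste0("receptor_dephosphorylation_", side))
    mdl <- km_add_reaction(mdl, ids("r3"), c(setNames(1, ids("pR"))),
                           c(setNames(1, ids("Rd"))),
                           kinetic_law = law("%s * %s", ids("kint"), ids("pR")),
                           name = paste0("receptor_internalization_", side))
    mdl <- km_add_reaction(mdl, ids("r4"), numeric(0), c(setNames(1, ids("R"))),
                           kinetic_law = law("%s", ids("ksyn")),
                           name = paste0("receptor_synthesis_", side))
    mdl <- km_add_reaction(mdl, ids("r5"), c(setNames(1, ids("I"))),
                           c(setNames(1, ids("pI"))), modifiers = ids("pR"),
                           kinetic_law = law("%s * %s * %s", ids("kph_i"),
                                             ids("pR"), ids("I")),
                           name = paste0("adapter_phosphorylation_", side))
    mdl <- km_add_reaction(mdl, ids("r6"), c(setNames(1, ids("pI"))),
                           c(setNames(1, ids("I"))),
                           kinetic_law = law("%s * %s", ids("kdeph_i"), ids("pI")),
                           name = paste0("adapter_dephosphorylation_", side))
    mdl <- km_add_reaction(mdl, ids("r7"), c(setNames(1, ids("Akt"))),
                           c(setNames(1, ids("pAkt"))), modifiers = ids("pI"),
                           kinetic_law = law("%s * %s * %s", ids("kph_akt"),
                                             ids("pI"), ids("Akt")),
                           name = paste0("Akt_phosphorylation_", side))
    # the shared downstream cascade: identical structure and annotations
    mdl <- km_add_reaction(mdl, ids("r8"), c(setNames(1, ids("pAkt"))),
                           c(setNames(1, ids("Akt"))),
                           kinetic_law = law("%s * %s", ids("kdeph_akt"), ids("pAkt")),
                           name = "Akt_dephosphorylation", uris = uri_o("r8"))
    mdl <- km_add_reaction(mdl, ids("r9"), c(setNames(1, ids("S6"))),
                           c(setNames(1, ids("pS6"))), modifiers = ids("pAkt"),
                           kinetic_law = law("%s * %s * %s", ids("kph_s6"),
                                             ids("pAkt"), ids("S6")),
                           name = "S6_phosphorylation", uris = uri_o("r9"))
    mdl <- km_add_reaction(mdl, ids("r10"), c(setNames(1, ids("pS6"))),
                           c(setNames(1, ids("ppS6"))), modifiers = ids("pAkt"),
                           kinetic_law = law("%s * %s * %s", ids("kph2_s6"),
                                             ids("pAkt"), ids("pS6")),
                           name = "S6_second_phosphorylation", uris = uri_o("r10"))
    mdl <- km_add_reaction(mdl, ids("r11"), c(setNames(1, ids("ppS6"))),
                           c(setNames(1, ids("S6"))),
                           kinetic_law = law("%s * %s", ids("krec_s6"), ids("ppS6")),
                           name = "S6_recycling", uris = uri_o("r11"))
    mdl
  }

  k_excl_a <- c(kact = 0.01, kdeact = 0.05, kint = 0.002, ksyn = 0.001,
                kph_i = 0.02, kdeph_i = 0.03, kph_akt = 0.015)
  k_excl_b <- c(kact = 0.004, kdeact = 0.03, kint = 0.004, ksyn = 0.0005,
                kph_i = 0.05, kdeph_i = 0.02, kph_akt = 0.03)
  model_a <- build("A", k_overlap, k_excl_a)
  model_b <- build("B", k_overlap * divergence, k_excl_b)

  obs <- function(pre, own_receptor_label) {
    list(observable(paste0(pre, "_pR"), 1.0, own_receptor_label),
         observable(paste0(pre, "_pAkt"), 2.0, "pAkt"),
         observable(paste0(pre, "_ppS6"), 1.5, "pS6sig"))
  }
  list(model_a = model_a, model_b = model_b,
       observables_a = obs("a", "pRec_A"),
       observables_b = obs("b", "pRec_B"),
       observables_merged = c(list(observable("a_pR", 1.0, "pRec_A"),
                                   observable("b_pR", 1.0, "pRec_B")),
                              list(observable("a_pAkt", 2.0, "pAkt"),
                                   observable("a_ppS6", 1.5, "pS6sig"))),
       stimulus_a = "a_L", stimulus_b = "b_L",
       output_labels = c("pRec_A", "pRec_B", "pAkt", "pS6sig"))
}

#' Step-stimulus datasets for the synthetic case-study pair
#'
#' Six step levels per ligand (log-spaced; the published study inherited its
#' levels from the original models, which are configuration here), on a
#' 0-3600 s grid with 61 points.
#'
#' @param pair from [synthetic_case_study_pair()].
#' @param side `"A"` or `"B"`.
#' @param levels stimulus step amounts.
#' @param time_grid output time grid.
#' @export
case_study_datasets <- function(pair, side = c("A", "B"),
                                levels = 10^seq(-1.5, 1, length.out = 6),
                                time_grid = seq(0, 3600, length.out = 61)) {
  side <- match.arg(side)
  model <- if (side == "A") pair$model_a else pair$model_b
  obs <- if (side == "A") pair$observables_a else pair$observables_b
  stim <- if (side == "A") pair$stimulus_a else pair$stimulus_b
  lapply(seq_along(levels), function(k) {
    inp <- input_signal(setNames(levels[k], stim),
                        label = sprintf("%s_step_%d", side, k))
    traj <- observe(simulate_model(model, inp, time_grid), obs)
    make_synthetic_dataset(traj, inp, origin = side)
  })
}

# ---- real case study (requires local accession files) -----------------------

#' Assemble the published EGF/NGF case study from local accession files
#'
#' Loads the two BioModels accession files (BIOMD0000000262, the EGF-Akt
#' model, and BIOMD0000000263, the NGF-Akt model) from local paths and
#' produces the experiment plan of the published integration example: six
#' EGF-step and six NGF-step dataset specifications, each listing the four
#' outputs of the integrated model. The stimulus levels and time grid are
#' inherited from the original study and are configuration here.
#'
#' This function never downloads; if the files are absent it stops with an
#' "accession files required" error naming the accessions.
#'
#' @param path_egf,path_ngf local paths to the two SBML files.
#' @param levels_egf,levels_ngf stimulus concentrations per ligand.
#' @param time_grid simulation/observation grid.
#' @return list with `model_a` (EGF), `model_b` (NGF), `experiment_plan`
#'   (12 dataset specs: label, side, stimulus level, output labels).
#' @export
build_case_study <- function(path_egf, path_ngf,
                             levels_egf = 10^seq(-1.5, 1, length.out = 6),
                             levels_ngf = 10^seq(-1.5, 1, length.out = 6),
                             time_grid = seq(0, 3600, length.out = 61)) {
  missing_files <- c(if (!file.exists(path_egf)) "BIOMD0000000262",
                     if (!file.exists(path_ngf)) "BIOMD0000000263")
  if (length(missing_files) > 0) {
    stop(sprintf(
      "accession files required: local copies of %s must be provided (no downloads are performed)",
      paste(missing_files, collapse = " and ")), call. = FALSE)
  }
  model_a <- load_model(path_egf)
  model_b <- load_model(path_ngf)
  outputs <- c("pEGFR", "pTrkA", "pAkt", "pS6")
  plan <- list()
  for (k in seq_along(levels_egf)) {
    plan[[length(plan) + 1L]] <- list(label = sprintf("EGF_step_%d", k),
                                      side = "A", level = levels_egf[k],
                                      outputs = outputs,
                                      realizable = c("pEGFR", "pAkt", "pS6"))
  }
  for (k in seq_along(levels_ngf)) {
    plan[[length(plan) + 1L]] <- list(label = sprintf("NGF_step_%d", k),
                                      side = "B", level = levels_ngf[k],
                                      outputs = outputs,
                                      realizable = c("pTrkA", "pAkt", "pS6"))
  }
  list(model_a = model_a, model_b = model_b, experiment_plan = plan,
       time_grid = time_grid)
}
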