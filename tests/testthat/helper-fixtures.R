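# Shared fixtures and an independent simulation oracle.

# one-species decay dS/dt = -k S
make_decay_model <- function(k = 1, s0 = 1) {
  m <- kinetic_model("decay")
  m <- km_add_compartment(m, "cell", 1)
  m <- km_add_species(m, "S", s0, "cell")
  m <- km_add_parameter(m, "k", k)
  km_add_reaction(m, "r1", c(S = 1), numeric(0), kinetic_law = "k*S")
}

# closed two-state phosphorylation cycle S <-> Sp driven by a constant kinase
make_cycle_model <- function() {
  m <- kinetic_model("cycle")
  m <- km_add_compartment(m, "cell", 1)
  m <- km_add_species(m, "S", 2, "cell")
  m <- km_add_species(m, "Sp", 0.5, "cell")
  m <- km_add_species(m, "K", 1, "cell", boundary = TRUE, constant = TRUE)
  m <- km_add_parameter(m, "kf", 0.8)
  m <- km_add_parameter(m, "kr", 0.3)
  m <- km_add_reaction(m, "ph", c(S = 1), c(Sp = 1), modifiers = "K",
                       kinetic_law = "kf*K*S")
  km_add_reaction(m, "deph", c(Sp = 1), c(S = 1), kinetic_law = "kr*Sp")
}

# Independent reference simulator: fixed-step classic RK4, rates evaluated by
# plain R eval() of the kinetic-law expressions. Shares no code with the
# compiled bytecode/integrator path.
oracle_simulate <- function(model, input, time_grid, h = NULL) {
  sp_ids <- names(model$species)
  y <- vapply(model$species, `[[`, numeric(1), "initial_amount")
  is_input <- vapply(model$species, function(s) s$boundary && s$constant,
                     logical(1))
  if (!is.null(input)) {
    for (nm in names(input$assignments)) y[[nm]] <- input$assignments[[nm]]
    y[is_input & !(sp_ids %in% names(input$assignments))] <- 0
  }
  dynamic <- !vapply(model$species, function(s) s$boundary || s$constant,
                     logical(1))
  env0 <- c(lapply(model$parameters, `[[`, "value"),
            lapply(model$compartments, `[[`, "size"))
  vols <- vapply(sp_ids, function(s) {
    model$compartments[[model$species[[s]]$compartment]]$size
  }, numeric(1))

  rhs <- function(t, y) {
    env <- c(as.list(y), env0, list(time = t))
    dy <- setNames(numeric(length(y)), sp_ids)
    for (rx in model$reactions) {
      v <- eval(rx$kinetic_law, env)
      for (i in seq_len(nrow(rx$reactants))) {
        s <- rx$reactants$species[i]
        dy[[s]] <- dy[[s]] - rx$reactants$stoichiometry[i] * v
      }
      for (i in seq_len(nrow(rx$products))) {
        s <- rx$products$species[i]
        dy[[s]] <- dy[[s]] + rx$products$stoichiometry[i] * v
      }
    }
    dy <- dy / vols
    dy[!dynamic] <- 0
    dy
  }

  if (is.null(h)) h <- diff(range(time_grid)) / 4000
  out <- matrix(0, length(time_grid), length(y),
                dimnames = list(NULL, sp_ids))
  out[1, ] <- y
  t <- time_grid[1]
  for (k in 2:length(time_grid)) {
    tend <- time_grid[k]
    while (t < tend - 1e-12) {
      hs <- min(h, tend - t)
      k1 <- rhs(t, y)
      k2 <- rhs(t + hs / 2, y + hs / 2 * k1)
      k3 <- rhs(t + hs / 2, y + hs / 2 * k2)
      k4 <- rhs(t + hs, y + hs * k3)
      y <- y + hs / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hs
    }
    out[k, ] <- y
  }
  structure(list(time = time_grid, values = out, labels = sp_ids),
            class = "trajectory")
}

# standard small toy pair used across tests
default_toy <- function(divergence = 10, seed = 42) {
  spec <- toy_pair_spec(2, 2, 3, 2, divergence = divergence, seed = seed)
  pair <- generate_toy_pair(spec)
  list(spec = spec, pair = pair)
}

# short time grid to keep test runtimes down (full-horizon grids are used in
# the acceptance tests)
short_grid <- function(n = 25) seq(0, 600, length.out = n)
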