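# ODE kinetic models of GPCR signaling networks: Michaelis-Menten and
# mass-action rate laws, stiff integration, dose scans and direction
# classification of insulin / cAMP responses.

#' Irreversible Michaelis-Menten rate
#'
#' `V = Vm * S / (Km + S)` in uM/s.
#'
#' @param Vm Limiting rate (uM/s), > 0.
#' @param Km Michaelis constant (uM), > 0.
#' @param S Substrate concentration (uM), >= 0.
#' @return Rate in uM/s.
#' @export
mm_rate <- function(Vm, Km, S) {
  if (Vm <= 0 || Km <= 0) stop("Vm and Km must be positive")
  if (any(S < 0)) stop("substrate concentration must be nonnegative")
  Vm * S / (Km + S)
}

#' Mass-action rate
#'
#' `V = k * prod(S_i)`; the empty product is 1, so a zeroth-order reaction
#' proceeds at rate `k`.
#'
#' @param k Rate constant (units depend on the reaction order).
#' @param substrate_concs Numeric vector of substrate concentrations (uM).
#' @return Rate in uM/s.
#' @export
mass_action_rate <- function(k, substrate_concs = numeric(0)) {
  if (k <= 0) stop("rate constant k must be positive")
  if (any(substrate_concs < 0)) stop("concentrations must be nonnegative")
  k * prod(substrate_concs)
}

#' Build a kinetic model from a network specification
#'
#' The network JSON lists species (name, initial concentration in uM,
#' compartment), reactions (reactants/products with stoichiometries,
#' modifiers acting as catalysts, saturable inhibitors with a Ki, and a rate
#' law of type `mass_action` or `michaelis_menten`) and the readout species.
#' Rates: mass action is `k * prod(reactant^stoich) * prod(modifiers)`;
#' Michaelis-Menten is `Vm * prod(modifiers) * S/(Km + S)` on the first
#' reactant; every law is multiplied by `1/(1 + [I]/Ki)` per inhibitor.
#'
#' @param spec Path to a network JSON file, or an equivalent nested list.
#' @return List of class `phk_model` with `species`, `init` (named uM
#'   vector), `reactions`, `stoich` (species x reactions matrix), `readouts`,
#'   `ligand` (name of the agonist species, when declared) and
#'   `conserved_moieties`.
#' @export
build_model <- function(spec) {
  if (is.character(spec)) {
    if (!file.exists(spec)) stop("network file not found: ", spec)
    spec <- jsonlite::fromJSON(spec, simplifyVector = FALSE)
  }
  sp_names <- vapply(spec$species, `[[`, character(1), "name")
  if (anyDuplicated(sp_names))
    stop("duplicate species name: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  init <- vapply(spec$species, function(s) as.numeric(s$init_um), numeric(1))
  if (any(init < 0)) stop("initial concentrations must be nonnegative")
  names(init) <- sp_names

  check_species <- function(nm, rid) {
    missing <- setdiff(nm, sp_names)
    if (length(missing))
      stop("reaction '", rid, "' references undeclared species: ",
           paste(missing, collapse = ", "))
  }
  parse_side <- function(side, rid) {
    if (is.null(side)) return(list())
    lapply(side, function(x) {
      if (is.character(x)) x <- list(species = x, stoich = 1L)
      st <- if (is.null(x$stoich)) 1L else as.integer(x$stoich)
      if (st < 1L) stop("reaction '", rid, "': stoichiometry must be >= 1")
      list(species = as.character(x$species), stoich = st)
    })
  }
  reactions <- lapply(spec$reactions, function(r) {
    rid <- as.character(r$id)
    reactants <- parse_side(r$reactants, rid)
    products <- parse_side(r$products, rid)
    modifiers <- as.character(unlist(r$modifiers))
    inhibitors <- lapply(r$inhibitors, function(inh)
      list(species = as.character(inh$species), Ki = as.numeric(inh$Ki)))
    check_species(c(vapply(reactants, `[[`, character(1), "species"),
                    vapply(products, `[[`, character(1), "species"),
                    modifiers,
                    vapply(inhibitors, `[[`, character(1), "species")), rid)
    law_type <- as.character(r$law$type)
    params <- lapply(r$law$params, as.numeric)
    if (law_type == "mass_action") {
      if (is.null(params$k) || params$k <= 0)
        stop("reaction '", rid, "': mass_action requires k > 0")
    } else if (law_type == "michaelis_menten") {
      if (is.null(params$Vm) || is.null(params$Km) ||
          params$Vm <= 0 || params$Km <= 0)
        stop("reaction '", rid, "': michaelis_menten requires Vm, Km > 0")
      if (length(reactants) == 0L)
        stop("reaction '", rid, "': michaelis_menten requires a substrate")
    } else stop("reaction '", rid, "': unknown rate law '", law_type, "'")
    for (inh in inhibitors)
      if (is.null(inh$Ki) || inh$Ki <= 0)
        stop("reaction '", rid, "': inhibitor Ki must be positive")
    list(id = rid, reactants = reactants, products = products,
         modifiers = modifiers, inhibitors = inhibitors,
         law_type = law_type, params = params)
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")

  stoich <- matrix(0, length(sp_names), length(reactions),
                   dimnames = list(sp_names,
                                   vapply(reactions, `[[`, character(1),
                                          "id")))
  for (j in seq_along(reactions)) {
    for (x in reactions[[j]]$reactants)
      stoich[x$species, j] <- stoich[x$species, j] - x$stoich
    for (x in reactions[[j]]$products)
      stoich[x$species, j] <- stoich[x$species, j] + x$stoich
  }

  readouts <- as.character(unlist(spec$readouts))
  missing <- setdiff(readouts, sp_names)
  if (length(missing))
    stop("readout species not declared: ", paste(missing, collapse = ", "))

  # indexed runtime table so rate evaluation needs no name lookups
  sp_index <- stats::setNames(seq_along(sp_names), sp_names)
  runtime <- lapply(reactions, function(r) {
    sub_idx <- unlist(lapply(r$reactants, function(x)
      rep(sp_index[[x$species]], x$stoich)))
    list(is_mm = r$law_type == "michaelis_menten",
         k = r$params$k, Vm = r$params$Vm, Km = r$params$Km,
         sub_idx = as.integer(sub_idx),
         S_idx = if (length(r$reactants))
           sp_index[[r$reactants[[1L]]$species]] else NA_integer_,
         mod_idx = as.integer(sp_index[r$modifiers]),
         inh_idx = as.integer(vapply(r$inhibitors, function(i)
           sp_index[[i$species]], numeric(1))),
         inh_Ki = vapply(r$inhibitors, function(i) i$Ki, numeric(1)))
  })

  moieties <- lapply(spec$conserved_moieties, function(m)
    list(name = as.character(m$name),
         species = as.character(unlist(m$species))))

  structure(list(species = sp_names, init = init, reactions = reactions,
                 runtime = runtime, stoich = stoich, readouts = readouts,
                 ligand = if (is.null(spec$ligand)) NULL
                          else as.character(spec$ligand),
                 compartments = vapply(spec$species, function(s)
                   if (is.null(s$compartment)) "cell"
                   else as.character(s$compartment), character(1)),
                 conserved_moieties = moieties),
            class = "phk_model")
}

#' @export
print.phk_model <- function(x, ...) {
  cat(sprintf("<phk_model> %d species, %d reactions; readouts: %s\n",
              length(x$species), length(x$reactions),
              paste(x$readouts, collapse = ", ")))
  invisible(x)
}

# reaction rate vector at state y (positional uM vector)
model_rates <- function(model, y) {
  y <- pmax(y, 0)
  rt <- model$runtime
  v <- numeric(length(rt))
  for (j in seq_along(rt)) {
    r <- rt[[j]]
    val <- if (r$is_mm) {
      S <- y[r$S_idx]
      r$Vm * S / (r$Km + S)
    } else r$k * prod(y[r$sub_idx])
    if (length(r$mod_idx)) val <- val * prod(y[r$mod_idx])
    if (length(r$inh_idx)) val <- val / prod(1 + y[r$inh_idx] / r$inh_Ki)
    v[j] <- val
  }
  v
}

#' Integrate a kinetic model
#'
#' Integrates `dC/dt = N v(C)` with the stiff-capable `lsoda` solver on a
#' uniform output grid, flooring tiny negative concentrations at zero.
#'
#' @param model A [build_model] result.
#' @param t_end End time in seconds (> 0).
#' @param n_out Number of output points (uniform grid including t = 0).
#' @param rtol,atol Solver tolerances.
#' @param init Optional named vector overriding initial concentrations of a
#'   subset of species.
#' @param times Optional explicit output time grid starting at 0 (overrides
#'   `t_end`/`n_out`).
#' @return List of class `phk_trajectory`: `times` (s), `conc` (time x
#'   species matrix, uM) and `solver_stats` (including `steady_state`, TRUE
#'   when `max |dC/dt| < 1e-9` uM/s at the final time).
#' @export
simulate <- function(model, t_end = 600, n_out = 241L, rtol = 1e-8,
                     atol = 1e-10, init = NULL, times = NULL) {
  if (t_end <= 0) stop("t_end must be positive")
  y0 <- model$init
  if (!is.null(init)) {
    missing <- setdiff(names(init), model$species)
    if (length(missing))
      stop("unknown species in init override: ",
           paste(missing, collapse = ", "))
    y0[names(init)] <- init
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  if (times[1] != 0) times <- c(0, times)
  if (any(diff(times) <= 0)) stop("output times must be strictly increasing")
  rhs <- function(t, y, parms) {
    list(as.numeric(model$stoich %*% model_rates(model, y)))
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                        atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ",
         paste(deparse(attr(sol, "istate")), collapse = " "))
  conc <- sol[, -1, drop = FALSE]
  if (min(conc) < -1e-9)
    warning("solver produced concentrations below -1e-9 uM")
  conc[conc < 0 & conc > -1e-9] <- 0
  yT <- conc[nrow(conc), ]
  dT <- as.numeric(model$stoich %*% model_rates(model, yT))
  structure(list(times = times, conc = conc,
                 solver_stats = list(steps = attr(sol, "istate")[3],
                                     steady_state = max(abs(dT)) < 1e-9,
                                     final_max_dcdt = max(abs(dT)))),
            class = "phk_trajectory")
}

#' Readout value of a trajectory
#'
#' @param traj A `phk_trajectory`.
#' @param readout Species name.
#' @param at `"end"` (value at the final time, default) or `"integral"`
#'   (time integral over the trajectory, trapezoidal).
#' @return Numeric scalar.
#' @export
trajectory_readout <- function(traj, readout, at = c("end", "integral")) {
  at <- match.arg(at)
  if (!readout %in% colnames(traj$conc))
    stop("readout species '", readout, "' not in trajectory")
  y <- traj$conc[, readout]
  if (at == "end") return(y[length(y)])
  sum(diff(traj$times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Dose-response scan
#'
#' Simulates the model at each agonist dose and reports the readout at the
#' fixed horizon `t_end`.
#'
#' @param model A `phk_model`.
#' @param ligand_species Species whose initial concentration is scanned.
#' @param doses Nonnegative doses in uM.
#' @param readout Readout species (default: first declared readout).
#' @param t_end,n_out,rtol,atol Passed to [simulate].
#' @return Data frame with columns `dose` and `response`, in input order.
#' @export
dose_response <- function(model, ligand_species, doses,
                          readout = model$readouts[1], t_end = 600,
                          n_out = 121L, rtol = 1e-8, atol = 1e-10) {
  if (any(doses < 0)) stop("doses must be nonnegative")
  if (!ligand_species %in% model$species)
    stop("ligand species '", ligand_species, "' not in model")
  if (!readout %in% model$species)
    stop("readout species '", readout, "' not in model")
  response <- vapply(doses, function(d) {
    init <- stats::setNames(d, ligand_species)
    trajectory_readout(simulate(model, t_end, n_out, rtol, atol, init),
                       readout)
  }, numeric(1))
  data.frame(dose = doses, response = response)
}

#' Read the insulin/glucagon effect table
#'
#' CSV columns: ligand, receptor, insulin_effect, glucagon_effect,
#' g_protein, value_um, min_um, max_um.
#'
#' @param path CSV path; default is the bundled beta-cell secretagogue table.
#' @return Data frame of effect entries.
#' @export
read_effect_table <- function(path = system.file("extdata",
                                                 "insulin_effects.csv",
                                                 package = "phorekin")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "insulin_effect", "glucagon_effect",
            "g_protein", "value_um", "min_um", "max_um")
  if (!all(need %in% names(df)))
    stop("effect table must have columns: ", paste(need, collapse = ", "))
  bad <- with(df, min_um > value_um | value_um > max_um)
  if (any(bad))
    stop("effect table rows violate min <= value <= max: ",
         paste(df$ligand[bad], collapse = ", "))
  df
}

#' Classify the insulin response direction for an effect-table entry
#'
#' Simulates the model with the ligand at the entry's concentration and
#' without it, and compares the insulin readouts: ratio above `1 + epsilon`
#' is stimulatory, below `1 - epsilon` inhibitory, otherwise none.
#'
#' @param model A `phk_model` whose `ligand` species corresponds to the
#'   entry's ligand.
#' @param entry One row of [read_effect_table] (or a list with `ligand` and
#'   `value_um`).
#' @param epsilon Relative dead band (default 0.05).
#' @param readout Insulin readout species (default `"Insulin_secreted"`).
#' @param t_end Simulation horizon in seconds.
#' @param ligand_species Optional explicit mapping of the entry's ligand to a
#'   model species; by default the entry's ligand must equal the model's
#'   declared ligand species.
#' @return `"stimulatory"`, `"inhibitory"` or `"none"`, with attributes
#'   `ratio`, `with_ligand` and `baseline`.
#' @export
classify_effect <- function(model, entry, epsilon = 0.05,
                            readout = "Insulin_secreted", t_end = 600,
                            ligand_species = NULL) {
  if (!is.null(ligand_species)) {
    if (!ligand_species %in% model$species)
      stop("ligand species '", ligand_species, "' not in model")
    model$ligand <- ligand_species
  }
  if (is.null(model$ligand))
    stop("model does not declare a ligand species")
  if (!is.null(entry$ligand) && !is.na(entry$ligand) &&
      is.null(ligand_species) &&
      !identical(as.character(entry$ligand), model$ligand))
    stop("ligand '", entry$ligand, "' is not configured in this model ",
         "(model ligand species: '", model$ligand, "')")
  dose <- as.numeric(entry$value_um)
  base <- trajectory_readout(
    simulate(model, t_end, init = stats::setNames(0, model$ligand)), readout)
  with_l <- trajectory_readout(
    simulate(model, t_end, init = stats::setNames(dose, model$ligand)),
    readout)
  ratio <- if (base > 0) with_l / base else Inf
  dir <- if (ratio > 1 + epsilon) "stimulatory"
         else if (ratio < 1 - epsilon) "inhibitory" else "none"
  structure(dir, ratio = ratio, with_ligand = with_l, baseline = base)
}

#' Check conserved moieties of a trajectory
#'
#' @param model A `phk_model` with declared `conserved_moieties`.
#' @param traj A `phk_trajectory` of that model.
#' @return Data frame: moiety name, initial total, maximum absolute drift
#'   (uM) over the trajectory.
#' @export
check_conservation <- function(model, traj) {
  do.call(rbind, lapply(model$conserved_moieties, function(m) {
    tot <- rowSums(traj$conc[, m$species, drop = FALSE])
    data.frame(moiety = m$name, total = tot[1],
               max_drift = max(abs(tot - tot[1])))
  }))
}

#' Perturb all rate constants of a model
#'
#' Multiplies every `k`, `Vm`, `Km` and `Ki` by an independent factor
#' `1 + u`, `u ~ Uniform(-amplitude, amplitude)`.
#'
#' @param model A `phk_model`.
#' @param amplitude Relative perturbation amplitude (default 0.2).
#' @return The perturbed model.
#' @export
perturb_rate_constants <- function(model, amplitude = 0.2) {
  model$reactions <- lapply(model$reactions, function(r) {
    r$params <- lapply(r$params, function(p)
      p * (1 + stats::runif(1, -amplitude, amplitude)))
    r$inhibitors <- lapply(r$inhibitors, function(inh) {
      inh$Ki <- inh$Ki * (1 + stats::runif(1, -amplitude, amplitude))
      inh
    })
    r
  })
  refresh_runtime(model)
}

# re-sync the indexed runtime table after parameter edits
refresh_runtime <- function(model) {
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    model$runtime[[j]]$k <- r$params$k
    model$runtime[[j]]$Vm <- r$params$Vm
    model$runtime[[j]]$Km <- r$params$Km
    model$runtime[[j]]$inh_Ki <- vapply(r$inhibitors, function(i) i$Ki,
                                        numeric(1))
  }
  model
}

#' Path to a bundled network fixture
#'
#' @param name One of `"gpr142_compound2"`, `"gpr142_compound21"`,
#'   `"npy_gi"`.
#' @return File path of the bundled network JSON.
#' @export
network_fixture <- function(name = c("gpr142_compound2", "gpr142_compound21",
                                     "npy_gi")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, "_network.json"),
              package = "phorekin", mustWork = TRUE)
}
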