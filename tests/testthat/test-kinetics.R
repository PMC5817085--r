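# Rate laws, model construction, integration, dose response, direction
# classification, SBML exchange.

test_that("rate laws evaluate their defining formulas", {
  expect_equal(mm_rate(1, 1, 1), 0.5)
  expect_equal(mm_rate(2, 3, 0), 0)
  # first-order limit: S << Km
  Vm <- 2; Km <- 10; S <- Km / 100
  expect_equal(mm_rate(Vm, Km, S), (Vm / Km) * S, tolerance = 0.01)
  expect_error(mm_rate(1, 1, -1), "nonnegative")

  expect_equal(mass_action_rate(2, c(1, 3)), 6)
  expect_equal(mass_action_rate(5, numeric(0)), 5)  # empty product
  expect_equal(mass_action_rate(4, c(2, 0, 7)), 0)
  expect_error(mass_action_rate(-1, 1), "positive")
})

test_that("the bundled GPR142 network builds with its declared structure", {
  spec <- jsonlite::fromJSON(network_fixture("gpr142_compound2"),
                             simplifyVector = FALSE)
  m <- build_model(network_fixture("gpr142_compound2"))
  expect_length(m$species, length(spec$species))
  expect_length(m$reactions, length(spec$reactions))
  expect_equal(dim(m$stoich), c(length(m$species), length(m$reactions)))
  expect_equal(m$ligand, "Compound2")
  expect_true(all(c("Insulin_secreted", "cAMP") %in% m$readouts))
})

test_that("model validation names the offending element", {
  spec <- mm_toy_spec()
  spec$reactions[[1]]$reactants <- list("Gx")
  expect_error(build_model(spec), "Gx")
  spec2 <- mm_toy_spec()
  spec2$species[[2]]$name <- "S"
  expect_error(build_model(spec2), "duplicate species")
  spec3 <- mm_toy_spec()
  spec3$reactions[[1]]$law$type <- "hill"
  expect_error(build_model(spec3), "unknown rate law")
})

test_that("an empty reaction list gives a constant trajectory", {
  spec <- mm_toy_spec()
  spec$reactions <- list()
  m <- build_model(spec)
  tr <- simulate(m, 100, n_out = 11)
  expect_true(all(abs(tr$conc[, "S"] - 10) < 1e-12))
})

test_that("a closed binding system conserves totals and a zero dose stays at baseline", {
  m <- build_model(network_fixture("gpr142_compound2"))
  tr <- simulate(m, 600)
  cons <- check_conservation(m, tr)
  expect_true(all(cons$max_drift < 1e-8))
  expect_true(all(tr$conc >= -1e-9))

  tr0 <- simulate(m, 300, init = c(Compound2 = 0))
  # no stimulus: receptor never engages
  expect_true(all(tr0$conc[, "GPR142_complex"] < 1e-12))
})

test_that("halving the solver tolerances leaves readouts unchanged", {
  m <- build_model(network_fixture("gpr142_compound2"))
  a <- simulate(m, 600, rtol = 1e-8, atol = 1e-10)
  b <- simulate(m, 600, rtol = 5e-9, atol = 5e-11)
  ro <- c("Insulin_secreted", "cAMP")
  rel <- abs(a$conc[-1, ro] - b$conc[-1, ro]) /
    pmax(abs(a$conc[-1, ro]), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("dose scans preserve order and return baselines at zero dose", {
  m <- build_model(network_fixture("gpr142_compound2"))
  doses <- c(0.05, 0, 0.036)
  dr <- dose_response(m, "Compound2", doses, t_end = 200)
  expect_equal(dr$dose, doses)
  base <- trajectory_readout(simulate(m, 200, n_out = 121,
                                      init = c(Compound2 = 0)),
                             "Insulin_secreted")
  expect_equal(dr$response[2], base, tolerance = 1e-9)
  expect_error(dose_response(m, "Compound2", 0.1, readout = "nope"), "nope")
})

test_that("effect classification reproduces the tabulated directions", {
  tab <- read_effect_table()
  m2 <- build_model(network_fixture("gpr142_compound2"))
  e2 <- tab[tab$ligand == "Compound2", ]
  expect_equal(as.character(classify_effect(m2, e2)), "stimulatory")

  mn <- build_model(network_fixture("npy_gi"))
  en <- tab[tab$ligand == "NPY", ]
  expect_equal(as.character(classify_effect(mn, en)), "inhibitory")

  # zero dose: no effect either way
  expect_equal(as.character(classify_effect(m2, list(ligand = "Compound2",
                                                     value_um = 0))),
               "none")
  # a ligand the model does not carry
  expect_error(classify_effect(m2, list(ligand = "GLP-1", value_um = 1)),
               "not configured")
})

test_that("Michaelis-Menten trajectories reduce to first order when S << Km", {
  Km <- 50; Vm <- 1; S0 <- Km / 100
  mm <- build_model(mm_toy_spec(Vm = Vm, Km = Km, S0 = S0))
  ma <- build_model(mass_action_toy_spec(k = Vm / Km, S0 = S0))
  t1 <- simulate(mm, 100, n_out = 51)
  t2 <- simulate(ma, 100, n_out = 51)
  rel <- abs(t1$conc[-1, "P"] - t2$conc[-1, "P"]) /
    pmax(t2$conc[-1, "P"], 1e-12)
  expect_lt(max(rel), 0.01)
})

test_that("SBML export round-trips structure and dynamics", {
  m <- build_model(network_fixture("gpr142_compound2"))
  doc <- export_sbml(m)
  expect_true(validate_sbml(doc))
  m2 <- import_sbml(doc, ligand = "Compound2")
  expect_equal(m2$species, m$species)
  expect_equal(m2$init, m$init)
  t1 <- simulate(m, 300, n_out = 61)
  t2 <- simulate(m2, 300, n_out = 61)
  expect_lt(max(abs(t1$conc - t2$conc[, colnames(t1$conc)])), 1e-9)

  # unknown law on import errors with the reaction named
  txt <- as.character(doc)
  txt <- sub('"type":"michaelis_menten"', '"type":"ping_pong"', txt)
  expect_error(import_sbml(txt), "ping_pong")
})
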