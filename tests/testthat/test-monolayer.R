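lines <- cp506_cell_lines()

test_that("aerobic and anoxic steady-state Ci/Ce match the closed forms", {
  cs <- stable_prodrug_chain()
  ## aerobic: Ci/Ce -> k_in/k_out = 3.7/0.06
  sim <- simulate_monolayer(inf_medium_setup(oxygen = 200), cs,
                            lines$activator)
  fin <- sim[sim$time_min == 6000 & sim$compound == "CP-506", ]
  ratio <- fin$concentration_uM[fin$compartment == "intracellular"] /
    fin$concentration_uM[fin$compartment == "extracellular"]
  expect_equal(ratio, 3.7 / 0.06, tolerance = 1e-3)
  ## anoxic: quasi-steady Ci/Ce -> k_in/(k_out + k_met0)
  sim0 <- simulate_monolayer(inf_medium_setup(oxygen = 0), cs,
                             lines$activator)
  fin0 <- sim0[sim0$time_min == 6000 & sim0$compound == "CP-506", ]
  ratio0 <- fin0$concentration_uM[fin0$compartment == "intracellular"] /
    fin0$concentration_uM[fin0$compartment == "extracellular"]
  expect_equal(ratio0, 3.7 / (0.06 + 0.12), tolerance = 1e-3)
})

test_that("no uptake means constant medium and empty cells", {
  cs <- inert_compound()
  su <- monolayer_setup(C0 = 50, oxygen = 0)
  sim <- simulate_monolayer(su, cs, lines$activator)
  ce <- sim$concentration_uM[sim$compartment == "extracellular"]
  ci <- sim$concentration_uM[sim$compartment == "intracellular"]
  expect_true(all(abs(ce - 50) < 1e-8))
  expect_true(all(abs(ci) < 1e-10))
})

test_that("mass is conserved to 1e-6 with sink tracking over 4 h", {
  su <- monolayer_setup(oxygen = 0, duration = 240,
                        sample_times = seq(10, 240, by = 10))
  sim <- simulate_monolayer(su, cp506_compounds(), lines$activator)
  bal <- mass_balance(sim)
  expect_true(all(abs(bal$balance - 1) <= 1e-6))
})

test_that("without sink tracking the balance of a lossy system decreases", {
  su <- monolayer_setup(oxygen = 0, duration = 240,
                        sample_times = seq(10, 240, by = 10))
  sim <- simulate_monolayer(su, cp506_compounds(), lines$activator)
  naked <- as.data.frame(sim)        # drops the sink attribute
  attr(naked, "sinks") <- NULL
  bal <- mass_balance(naked, setup = su)
  expect_true(all(diff(bal$balance) < 0))
})

test_that("trajectories are linear in the initial concentration", {
  cs <- cp506_compounds()
  base <- monolayer_setup(C0 = 10, oxygen = 0)
  ref <- simulate_monolayer(base, cs, lines$activator)
  for (alpha in c(0.1, 10)) {
    su <- base; su$C0 <- 10 * alpha
    sc <- simulate_monolayer(su, cs, lines$activator)
    expect_equal(sc$concentration_uM, alpha * ref$concentration_uM,
                 tolerance = 1e-6)
  }
})

test_that("mass balance rejects mismatched time grids", {
  su <- monolayer_setup()
  sim <- simulate_monolayer(su, cp506_compounds(), lines$activator)
  broken <- as.data.frame(sim)
  attr(broken, "sinks") <- NULL
  broken <- broken[!(broken$compartment == "intracellular" &
                       broken$time_min == 180), ]
  expect_error(mass_balance(broken, setup = su), "time grid")
})
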