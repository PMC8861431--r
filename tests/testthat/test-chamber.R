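test_that("equal reservoirs equilibrate to C0/2 with exact mass balance", {
  geo <- chamber_geometry(mcl_thickness = 0)
  pp <- transport_params(compounds = inert_compound())
  sim <- solve_chamber(geo, pp, C0 = 20, duration = 6000,
                       times = seq(0, 6000, 200))
  fin <- sim$reservoirs[sim$reservoirs$time_min == 6000, ]
  expect_equal(fin$concentration_uM, c(10, 10), tolerance = 0.02)
  expect_true(all(abs(sim$balance$balance - 1) <= 1e-5))
})

test_that("bare-membrane flux matches the analytic slab permeation", {
  geo <- chamber_geometry(mcl_thickness = 0)
  pp <- transport_params(compounds = inert_compound())
  sim <- solve_chamber(geo, pp, C0 = 20, duration = 1500,
                       times = seq(0, 1500, 15))
  D <- haptk:::.cm2s_to_um2min(pp$D_sup)
  A <- haptk:::.cm2_to_um2(geo$exposed_area)
  L <- geo$support_thickness
  Vd <- haptk:::.ml_to_um3(geo$donor_volume)
  k <- (D * A / L) * (2 / Vd)
  lag <- L^2 / (6 * D)
  rec <- sim$reservoirs[sim$reservoirs$compartment == "receiver", ]
  sel <- rec$time_min > max(3 * lag, 15)
  pred <- 10 * (1 - exp(-k * (rec$time_min[sel] - lag)))
  expect_lt(max(abs(rec$concentration_uM[sel] - pred) / pred), 0.01)
})

test_that("cellular uptake in the MCL shows up as a reservoir mass deficit", {
  geo <- chamber_geometry()
  pp <- transport_params(compounds = compound_set(
    compound_params("CP-506", k_in = 3.7, k_out = 0.06,
                    k_met0 = c(default = 0.12), oxygen_gated = TRUE)))
  sim <- solve_chamber(geo, pp, C0 = 17.4, duration = 300,
                       condition = "supraoxic")
  res <- sim$reservoirs
  don <- res$concentration_uM[res$compartment == "donor"]
  rec <- res$concentration_uM[res$compartment == "receiver"]
  expect_true(all(diff(don) < 0))
  expect_true(all(diff(rec[-1]) > 0))
  ## reservoir deficit equals the in-layer extracellular + cell-bound
  ## mass plus the (small) chemical-loss sink
  expect_true(all(abs(sim$balance$balance - 1) <= 1e-5))
  Vd <- haptk:::.ml_to_um3(geo$donor_volume)
  deficit <- 17.4 * Vd - (tail(don, 1) + tail(rec, 1)) * Vd
  A <- haptk:::.cm2_to_um2(geo$exposed_area)
  widths <- rep(c(geo$mcl_thickness, geo$support_thickness) /
                  geo$grid_nodes_per_layer,
                each = geo$grid_nodes_per_layer)
  prof <- sim$profiles
  in_layer <- sum(prof$Ce_uM * widths) * A +
    sum(prof$Ci_uM[!is.na(prof$Ci_uM)] *
          widths[seq_len(geo$grid_nodes_per_layer)]) * A
  expect_equal(deficit, in_layer, tolerance = 0.05)
})

test_that("halving the grid step changes reservoir output by <0.5%", {
  pp <- transport_params()
  sims <- lapply(c(25L, 50L), function(n) {
    solve_chamber(chamber_geometry(grid_nodes_per_layer = n), pp,
                  C0 = 17.4, duration = 300, condition = "anoxic")
  })
  for (cmp in unique(sims[[1]]$reservoirs$compound)) {
    a <- sims[[1]]$reservoirs[sims[[1]]$reservoirs$compound == cmp, ]
    b <- sims[[2]]$reservoirs[sims[[2]]$reservoirs$compound == cmp, ]
    scale <- max(b$concentration_uM)
    expect_lt(max(abs(a$concentration_uM - b$concentration_uM)) / scale,
              0.005)
  }
})

test_that("receiver accumulation is ordered in D, uptake and phi", {
  geo <- chamber_geometry()
  rec_at_end <- function(pp, condition = "supraoxic") {
    sim <- solve_chamber(geo, pp, C0 = 17.4, duration = 300,
                         condition = condition,
                         times = c(0, 150, 300))
    r <- sim$reservoirs
    r$concentration_uM[r$compartment == "receiver" & r$time_min == 300 &
                         r$compound == names(pp$compounds)[1]]
  }
  mk <- function(k_in, phi = 0.3, D_mcl = 1.93e-7) {
    transport_params(D_mcl = D_mcl, phi = phi, compounds = compound_set(
      compound_params("CP-506", k_in = k_in, k_out = 0.06,
                      k_met0 = c(default = 0.12), oxygen_gated = TRUE)))
  }
  ## monotone increasing in D
  expect_gt(rec_at_end(mk(3.7, D_mcl = 4e-7)), rec_at_end(mk(3.7)))
  ## monotone decreasing in k_in (uptake sink)
  expect_gt(rec_at_end(mk(1.0)), rec_at_end(mk(3.7)))
  ## monotone decreasing in phi * k_met0 under anoxia
  expect_gt(rec_at_end(mk(3.7, phi = 0.3), "anoxic"),
            rec_at_end(mk(3.7, phi = 1.0), "anoxic"))
})

test_that("thin-MCL limit approaches the bare membrane and drop scales with L", {
  urea <- compound_set(compound_params("urea"))
  pp <- transport_params(D_sup = 3.0e-6, D_mcl = 3.67e-7, compounds = urea)
  bare <- solve_chamber(chamber_geometry(mcl_thickness = 0), pp, C0 = 20,
                        duration = 300)
  ## a layer thin enough to contribute <2% of the total resistance
  thin <- solve_chamber(chamber_geometry(mcl_thickness = 0.5), pp, C0 = 20,
                        duration = 300)
  rb <- bare$reservoirs$concentration_uM[
    bare$reservoirs$compartment == "receiver"]
  rt <- thin$reservoirs$concentration_uM[
    thin$reservoirs$compartment == "receiver"]
  expect_equal(tail(rt, 1), tail(rb, 1), tolerance = 0.05)
  ## when the support membrane dominates the series resistance the flux
  ## is nearly fixed, so the quasi-steady concentration drop across the
  ## MCL doubles when its thickness doubles
  pp_slow <- transport_params(D_sup = 1e-7, D_mcl = 3.67e-7,
                              compounds = urea)
  drop_for <- function(L) {
    sim <- solve_chamber(chamber_geometry(mcl_thickness = L), pp_slow,
                         C0 = 20, duration = 300, times = c(0, 150, 300))
    mcl <- sim$profiles[seq_len(50), ]
    mcl$Ce_uM[1] - mcl$Ce_uM[50]
  }
  expect_equal(drop_for(100) / drop_for(50), 2, tolerance = 0.2)
})
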