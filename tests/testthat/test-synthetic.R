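test_that("generators are byte-reproducible under a fixed seed", {
  su <- monolayer_setup()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_hap_csv(gen_monolayer_dataset(su, "anoxic",
                                      noise = noise_model(seed = 9)), f1)
  write_hap_csv(gen_monolayer_dataset(su, "anoxic",
                                      noise = noise_model(seed = 9)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ## a different seed gives different bytes
  write_hap_csv(gen_monolayer_dataset(su, "anoxic",
                                      noise = noise_model(seed = 10)), f2)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f2, "raw", file.size(f2))))
})

test_that("no uncensored value below the LLOQ leaves any generator", {
  su <- monolayer_setup()
  d1 <- gen_monolayer_dataset(su, "anoxic", noise = noise_model(seed = 3))
  expect_true(all(d1$concentration_uM[!d1$censored] >= 0.01))
  d2 <- gen_flux_dataset(chamber_geometry(), transport_params(),
                         condition = "anoxic",
                         noise = noise_model(seed = 3))
  expect_true(all(d2$concentration_uM[!d2$censored] >= 0.01))
  ## the slowest-forming downstream metabolite starts below the LLOQ in
  ## the extracellular medium and is flagged accordingly
  early <- d1[d1$compound == "CP-506M-Cl2" &
                d1$compartment == "extracellular" & d1$time_min <= 5, ]
  expect_true(all(early$censored))
})

test_that("provenance survives the CSV round trip", {
  d <- gen_stability_dataset(noise = noise_model(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hap_csv(d, path)
  d2 <- read_hap_csv(path)
  prov <- attr(d2, "provenance")
  expect_identical(prov$kind, "media_stability")
  expect_equal(prov$truth[["CP-506M-Cl2"]], 271.1)
  expect_equal(prov$noise$seed, 2L)
  expect_equal(nrow(d2), nrow(d))
})

test_that("stability decays follow their half-lives and refit correctly", {
  clean <- gen_stability_dataset(times = c(0, 7.6, 15.2, 180),
                                 noise = noise_model(cv_proportional = 0,
                                                     replicates = 1))
  m <- clean[clean$compound == "CP-506M", ]
  expect_equal(m$concentration_uM[m$time_min == 7.6], 50)
  expect_equal(m$concentration_uM[m$time_min == 15.2], 25)
  p <- clean[clean$compound == "CP-506", ]
  expect_true(all(p$concentration_uM == 100))
  ## noisy refit of the dichloro-amine decay recovers its half-life
  noisy <- gen_stability_dataset(times = seq(0, 360, 20),
                                 noise = noise_model(seed = 4))
  mc <- noisy[noisy$compound == "CP-506M-Cl2", ]
  est <- fit_halflife(mc$time_min, mc$concentration_uM, mc$censored)
  expect_equal(est$halflife_min, 271.1, tolerance = 0.1)
})

test_that("flux generation conserves reservoir mass before noise", {
  geo <- chamber_geometry(mcl_thickness = 0)
  d <- gen_flux_dataset(geo, transport_params(compounds = inert_compound()),
                        C0 = 20, condition = "supraoxic",
                        noise = noise_model(cv_proportional = 0,
                                            replicates = 1, seed = 1),
                        urea = FALSE)
  tot <- tapply(d$concentration_uM, d$time_min, sum)
  ## donor + receiver leaves out only the small in-membrane transit mass
  expect_true(all(tot <= 20 + 1e-9))
  expect_true(all(tot >= 20 * 0.98))
})

test_that("clonogenic generator respects the kill model and its nulls", {
  d0 <- gen_survival_dataset(c(1, 5), mode = "monolayer", k_d = 0,
                             noise = noise_model(seed = 5))
  expect_true(all(abs(d0$surviving_fraction - 1) < 0.15))
  d <- gen_survival_dataset(c(0.2, 1), mode = "monolayer",
                            noise = noise_model(seed = 5))
  prov <- attr(d, "provenance")
  expect_true(all(c("line", "C0_uM", "colonies") %in% names(d)))
  ## binomial counts scatter around the generating truth
  tr <- prov$truth$true_sf
  m <- aggregate(surviving_fraction ~ line + C0_uM, d, mean)
  for (k in seq_len(nrow(m))) {
    truth_sf <- tr$surviving_fraction[tr$line == m$line[k] &
                                        tr$C0_uM == m$C0_uM[k]]
    expect_equal(m$surviving_fraction[k], truth_sf, tolerance = 0.2)
  }
})
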