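test_that("exact 4PL data is recovered and the midpoint identity holds", {
  x <- 10^seq(-1, 3, length.out = 9)
  y <- 0 + (1 - 0) / (1 + (x / 10)^1)
  fit <- fit_4pl(x, y)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$ec50, 10, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(predict(fit, 10), 0.5, tolerance = 1e-6)
  expect_error(fit_4pl(x[1:3], y[1:3]), "4 distinct")
  expect_error(fit_4pl(x, rep(0.8, 9)), "transition")
})

test_that("IC50 is the 50%-of-control crossing, not the 4PL midpoint", {
  c1 <- structure(list(top = 1, bottom = 0, ec50 = 10, hill = 1,
                       r_squared = 1), class = "curve_4pl")
  expect_equal(interpolate_ic50(c1), 10, tolerance = 1e-6)
  ## bottom = 0.4, hill = 2: 0.4 + 0.6/(1+(x/10)^2) = 0.5 -> x = 10*sqrt(5)
  c2 <- structure(list(top = 1, bottom = 0.4, ec50 = 10, hill = 2,
                       r_squared = 1), class = "curve_4pl")
  expect_equal(interpolate_ic50(c2), 10 * sqrt(5), tolerance = 1e-6)
  ## a curve floored above 50% never crosses: greater-than-range sentinel
  c3 <- structure(list(top = 1, bottom = 0.6, ec50 = 10, hill = 1,
                       r_squared = 1), class = "curve_4pl")
  ic <- interpolate_ic50(c3)
  expect_identical(as.numeric(ic), Inf)
  expect_identical(attr(ic, "censored"), ">max")
})

test_that("IC50 interpolation is scale-equivariant after refitting", {
  x <- 10^seq(-1, 2, length.out = 8)
  y <- 0.05 + 0.9 / (1 + (x / 3)^1.4)
  base <- interpolate_ic50(fit_4pl(x, y))
  for (alpha in c(0.1, 10)) {
    ic <- interpolate_ic50(fit_4pl(alpha * x, y))
    expect_equal(ic, alpha * base, tolerance = 1e-3)
  }
})

test_that("surviving fraction is the ratio of plating efficiencies", {
  expect_equal(surviving_fraction(50, 100, 1000), 0.5)
  expect_equal(surviving_fraction(100, 100, 1000), 1)
  expect_equal(surviving_fraction(20, 400, 10000, 1000), 0.005)
  expect_error(surviving_fraction(10, 0, 1000), "control")
})

test_that("fold ratios reproduce the worked aerobic/anoxic comparisons", {
  expect_equal(fold_ratio(257, 12.8), 20.1)
  expect_equal(fold_ratio(240, 33.1), 7.25)
  expect_equal(fold_ratio(5, 5), 1)
})

test_that("4PL-interpolated IC50 agrees with the kill model's own crossing", {
  ## clonogenic curve generated from the monolayer kill model, then
  ## 4PL-fitted; the interpolated IC50 must sit within 10% of the direct
  ## 50% crossing of the generating model (root-finding oracle)
  line <- cp506_cell_lines()$activator
  C0s <- 0.05 * 3^(0:5)
  sf <- monolayer_survival(C0s, line = line, k_d = 0.01)
  fit <- fit_4pl(sf$C0_uM, sf$surviving_fraction)
  ic_4pl <- interpolate_ic50(fit)
  direct <- uniroot(function(c0)
    monolayer_survival(c0, line = line, k_d = 0.01)$surviving_fraction - 0.5,
    c(0.05, 5), tol = 1e-4)$root
  expect_equal(ic_4pl, direct, tolerance = 0.1)
})
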