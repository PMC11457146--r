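test_that("atomization energies follow the 0 K formation-enthalpy bookkeeping", {
  expect_equal(atomization_energy(1, 4, 0), 711.185 + 4 * 216.035)
  # D0 = 0 when the molecular enthalpy equals the atomic sum
  expect_equal(atomization_energy(3, 8, 3 * 711.185 + 8 * 216.035), 0)
  # isomer differences: the atomic constants cancel
  d <- atomization_energy(10, 22, c(-249.5, -270.1))
  expect_equal(diff(d), -(diff(c(-249.5, -270.1))))
  expect_error(atomization_energy(2, 5, 0), "2\\*a_C \\+ 2")
  # constants are overridable
  expect_equal(atomization_energy(1, 4, 0, dHf0_C = 700, dHf0_H = 200), 1500)
})

test_that("gas-phase distributions match closed-form two-isomer cases", {
  # identical properties: 50/50
  g <- gas_distribution(c("n-C4", "2-m-C3"), c(-100, -100), c(-60, -60), 500)
  expect_equal(g$y, c(0.5, 0.5))
  # exponent gap of RT ln 2 gives a 2:1 ratio
  T <- 500
  gap <- R_KJ * T * log(2)
  g <- gas_distribution(c("n-C4", "2-m-C3"), c(-100 - gap, -100), c(-60, -60), T)
  expect_equal(g$y[1] / g$y[2], 2, tolerance = 1e-12)
  expect_equal(sum(g$y), 1, tolerance = 1e-12)
})

test_that("distributions are normalized and shift/scale invariant", {
  withr::with_seed(21, {
    ids <- vapply(enumerate_isomers(7)$members, `[[`, character(1), "label")
    dhf <- rnorm(length(ids), -200, 15)
    gmh <- rnorm(length(ids), -150, 10)
    g <- gas_distribution(ids, dhf, gmh, 500)
    expect_equal(sum(g$y), 1, tolerance = 1e-12)
    expect_true(all(g$y > 0))
    # invariance to a uniform exponent shift (the log-sum-exp guard)
    g2 <- gas_distribution(ids, dhf + 1e4, gmh, 500)
    expect_equal(g2$y, g$y, tolerance = 1e-12)
    # adsorbed phase: uniform Henry scaling drops out
    h <- data.frame(isomer = ids, zeolite = "MTW", T = 500,
                    KH = exp(rnorm(length(ids), -12, 1)))
    a1 <- adsorbed_distribution(g, h, "MTW")
    h2 <- h; h2$KH <- h2$KH * 3.7e5
    a2 <- adsorbed_distribution(g, h2, "MTW")
    expect_equal(a1$y, a2$y, tolerance = 1e-12)
    expect_equal(sum(a1$y), 1, tolerance = 1e-12)
    # equal Henry coefficients reproduce the gas distribution
    h$KH <- 1e-6
    expect_equal(adsorbed_distribution(g, h, "MTW")$y, g$y, tolerance = 1e-12)
  })
})

test_that("two-component adsorbed case splits as the Henry ratio", {
  g <- gas_distribution(c("n-C4", "2-m-C3"), c(-100, -100), c(-60, -60), 500)
  h <- data.frame(isomer = c("n-C4", "2-m-C3"), zeolite = "MTW", T = 500,
                  KH = c(3e-6, 1e-6))
  a <- adsorbed_distribution(g, h, "MTW")
  expect_equal(a$y, c(0.75, 0.25))
  # missing coefficients are a named error
  expect_error(adsorbed_distribution(g, h[1, ], "MTW"), "2-m-C3")
})

test_that("gas_distribution rejects bad input rather than guessing", {
  expect_error(gas_distribution(c("n-C4", "2-m-C3"), c(-100, -100),
                                c(-60, -60), -1), "T must be > 0")
  expect_error(gas_distribution(c("n-C4", "n-C5"), c(-100, -100),
                                c(-60, -60), 500), "molecular formula")
  expect_error(gas_distribution(c("n-C4", "2-m-C3"), c(-Inf, -100),
                                c(-60, -60), 500), "non-finite")
  expect_error(gas_distribution(c("n-C4", "n-C4"), c(-100, -100),
                                c(-60, -60), 500), "duplicate")
})

test_that("selectivities follow s = y/(1-y) and normalize at the reference", {
  g <- gas_distribution(c("n-C4", "2-m-C3"), c(-100, -100), c(-60, -60), 500)
  g$y <- c(0.2, 0.8)
  expect_equal(unname(selectivity(g)), c(0.25, 4))
  expect_equal(unname(relative_selectivity(g, "n-C4")), c(1, 16))
  expect_equal(relative_selectivity(g, "2-m-C3")[["2-m-C3"]], 1)
  expect_error(relative_selectivity(g, "n-C10"), "absent")
  # monotone in y
  withr::with_seed(31, {
    y <- sort(runif(10))
    y <- y / sum(y)
    gg <- g[rep(1, 0), ]
    res <- structure(data.frame(isomer = paste0("i", 1:10), y = y),
                     phase = "gas", T = 500,
                     class = c("equilibrium_result", "data.frame"))
    expect_true(all(diff(selectivity(res)) > 0))
  })
})

test_that("the full ideal-gas chemical potential reduces to exponent differences", {
  # at equal density the mu difference between isomers equals the
  # reference-exponent difference, so the distribution depends on nothing else
  e1 <- reference_exponent(-150, -200)
  e2 <- reference_exponent(-140, -215)
  mu1 <- ideal_gas_mu(e1, rho = 1e-7, T = 500)
  mu2 <- ideal_gas_mu(e2, rho = 1e-7, T = 500)
  expect_equal(mu1 - mu2, e1 - e2)
  expect_error(ideal_gas_mu(0, rho = -1, T = 500), "rho")
})

test_that("gas ranking from table values agrees with LR-predicted values", {
  syn <- generate_synthetic_table(17, n_max = 10,
                                  temperatures = c(0, 400, 500),
                                  properties = c("dHf", "G_minus_H0"),
                                  sigma = 0.1)
  fit_h <- fit_gc_model(syn$table, "dHf")
  fit_g <- fit_gc_model(syn$table, "G_minus_H0")
  ids <- names(Filter(function(m) carbon_count(m) == 10,
                      training_molecules(syn$table)))
  tab_h0 <- training_values(syn$table, "dHf", 0, ids)
  tab_g500 <- training_values(syn$table, "G_minus_H0", 500, ids)
  lr_h0 <- predict(fit_h, ids, T = 0, coefficients = "per_temperature")
  lr_g500 <- predict(fit_g, ids, T = 500, coefficients = "per_temperature")
  g_tab <- gas_distribution(ids, tab_h0, tab_g500, 500)
  g_lr <- gas_distribution(ids, lr_h0, lr_g500, 500)
  rho <- cor(g_tab$y, g_lr$y, method = "spearman")
  expect_gt(rho, 0.99)
})
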