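test_that("noiseless group-additive data is recovered exactly", {
  syn <- generate_synthetic_table(2, n_max = 7,
                                  temperatures = seq(0, 1000, by = 200))
  for (p in GC_PROPERTIES) {
    fit <- fit_gc_model(syn$table, p)
    expect_lt(max(abs(fit$residuals)), 1e-8)
    expect_lt(gc_mae(fit), 1e-8)
    expect_lt(gc_mae(fit, syn$table), 1e-8)
  }
})

test_that("second-order MAE never exceeds first-order MAE", {
  # the first-order design is nested in the second-order design (first-order
  # counts are center-marginals of second-order counts), so this ordering is
  # expected for fitted residuals
  syn <- generate_synthetic_table(4, n_max = 8, temperatures = c(300, 500),
                                  sigma = 0.5)
  for (p in GC_PROPERTIES) {
    m2 <- fit_gc_model(syn$table, p)
    m1 <- fit_gc_model(syn$table, p, order = "first")
    expect_lte(m2$mae, m1$mae + 1e-12, label = paste(p, "MAE ordering"))
  }
})

test_that("adding a constant shifts the intercept only (affine equivariance)", {
  syn <- generate_synthetic_table(6, n_max = 6, temperatures = c(300, 400, 500),
                                  properties = "dGf", sigma = 0.3)
  shift <- 17.5
  shifted <- as.data.frame(syn$table)
  shifted$value <- shifted$value + shift
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(shifted, tmp, row.names = FALSE)
  tab2 <- read_training_table(tmp)
  f1 <- fit_gc_model(syn$table, "dGf")
  f2 <- fit_gc_model(tab2, "dGf")
  expect_equal(unname(f2$coefficients["(Intercept)", ] -
                        f1$coefficients["(Intercept)", ]),
               rep(shift, 3), tolerance = 1e-7)
  expect_equal(f2$coefficients[-1, ], f1$coefficients[-1, ], tolerance = 1e-7)
})

test_that("temperature polynomials recover planted quadratics and flag cubics", {
  syn <- generate_synthetic_table(8, n_max = 6,
                                  temperatures = seq(100, 900, by = 200),
                                  properties = "H_minus_H0")
  fit <- fit_gc_model(syn$table, "H_minus_H0")
  pm <- syn$planted$H_minus_H0
  # identifiable check: polynomial-evaluated coefficients reproduce the
  # per-temperature fit (which itself reproduces the data exactly)
  for (T in fit$temperatures) {
    a_poly <- fit$polynomials %*% c(1, T, T^2)
    expect_equal(as.numeric(a_poly), unname(fit$coefficients[, as.character(T)]),
                 tolerance = 1e-6)
  }
  expect_lt(max(fit$polynomial_residual), 1e-6)

  # constant coefficients give B = C = 0
  cm <- fit
  cm$coefficients[] <- 3.25
  tp <- fit_temperature_polynomials(cm)
  expect_equal(unname(tp$coefficients[, "A"]),
               rep(3.25, nrow(tp$coefficients)), tolerance = 1e-9)
  expect_equal(max(abs(tp$coefficients[, c("B", "C")])), 0, tolerance = 1e-12)

  # a cubic temperature dependence must surface as a nonzero refit residual
  cub <- fit
  Ts <- cub$temperatures
  cub$coefficients[1, ] <- 1e-7 * Ts^3
  tp <- fit_temperature_polynomials(cub)
  direct <- 1e-7 * Ts^3
  quad_fit <- as.numeric(cbind(1, Ts, Ts^2) %*% tp$coefficients[1, ])
  expect_gt(tp$residual_max[["(Intercept)"]], 1e-4)
  expect_equal(max(abs(quad_fit - direct)), unname(tp$residual_max[1]),
               tolerance = 1e-9)
  expect_error(fit_temperature_polynomials(
    fit_gc_model(syn$table, "H_minus_H0", temperatures = c(100, 300))),
    ">= 3")
})

test_that("prediction routes unseen groups through the approximation map", {
  syn <- generate_synthetic_table(9, n_max = 10,
                                  temperatures = c(300, 400, 500),
                                  properties = "dHf")
  fit <- fit_gc_model(syn$table, "dHf")
  # 3-ethyl-3-tert-butylpentane (C11) contains C(C)(CH2)(CH2)(CH2), a group
  # absent from any C1-C10 isomer
  m14 <- name_to_molecule("3-e-3-tb-C5")
  x <- count_groups(m14)
  unseen <- setdiff(names(x), fit$keys)
  expect_true(group_key("C", c("C", "CH2", "CH2", "CH2")) %in% unseen)
  amap <- stats::setNames(fit$approximation$in_key, fit$approximation$out_key)
  x_mapped <- x
  names(x_mapped)[names(x_mapped) %in% names(amap)] <-
    amap[names(x_mapped)[names(x_mapped) %in% names(amap)]]
  folded <- tapply(x_mapped, names(x_mapped), sum)
  a <- fit$polynomials %*% c(1, 400, 400^2)
  manual <- a["(Intercept)", ] + sum(a[names(folded), ] * folded)
  expect_equal(unname(predict(fit, list(m14), T = 400)), unname(manual),
               tolerance = 1e-9)
  # a methane-free model cannot predict methane
  nometh <- syn$table[syn$table$isomer != "n-C1", ]
  attr(nometh, "molecules") <- training_molecules(syn$table)
  class(nometh) <- class(syn$table)
  fit2 <- fit_gc_model(nometh, "dHf")
  expect_error(predict(fit2, "n-C1", T = 400), "CH4")
})

test_that("prediction warns on extrapolation and errors off-grid per-T", {
  syn <- generate_synthetic_table(10, n_max = 5, temperatures = c(300, 400, 500))
  fit <- fit_gc_model(syn$table, "dGf")
  expect_warning(predict(fit, "n-C5", T = 1200), "outside the fitted range")
  expect_error(predict(fit, "n-C5", T = 450, coefficients = "per_temperature"),
               "not a fitted temperature")
  expect_error(fit_gc_model(syn$table, "dGf", temperatures = 999),
               "not in the table grid")
  expect_error(fit_gc_model(syn$table, "nope"), "absent")
})

test_that("models serialize to JSON and back without losing predictions", {
  syn <- generate_synthetic_table(12, n_max = 6, temperatures = c(300, 400, 500),
                                  properties = "dHf", sigma = 0.1)
  fit <- fit_gc_model(syn$table, "dHf")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_gc_model(fit, tmp)
  back <- read_gc_model(tmp)
  probe <- list(name_to_molecule("2,2,5-m-C7"), name_to_molecule("n-C10"))
  expect_equal(predict(back, probe, T = 400), predict(fit, probe, T = 400),
               tolerance = 1e-12)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_coefficient_csv(fit, csv)
  exported <- read.csv(csv)
  expect_setequal(exported$key, c("(Intercept)", fit$keys))
})
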