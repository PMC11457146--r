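test_that("training tables validate schema, grids and isomer ids", {
  df <- data.frame(isomer = c("n-C4", "2-m-C3"), T = 400,
                   property = "dHf", value = c(-130.5, -141.2))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE)
  tab <- read_training_table(tmp)
  expect_s3_class(tab, "training_table")
  expect_equal(nrow(tab), 2L)
  expect_equal(carbon_count(training_molecules(tab)[["2-m-C3"]]), 4L)
  expect_equal(unname(training_values(tab, "dHf", 400, "n-C4")), -130.5)

  # empty file errors
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("isomer,T,property,value", empty)
  expect_error(read_training_table(empty), "empty")
  # unknown isomer id errors
  bad <- df; bad$isomer[1] <- "definitely-not-an-alkane"
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_training_table(tmp), "neither a shorthand name nor a SMILES")
  # inconsistent temperature grid errors
  bad <- rbind(df, data.frame(isomer = "n-C4", T = 500, property = "dHf",
                              value = -128))
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_training_table(tmp), "inconsistent temperature grid")
  # non-numeric cells error
  bad <- df; bad$value <- c("x", "y")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_training_table(tmp), "non-numeric")
})

test_that("xlsx worksheets in Scott layout are read when readxl is present", {
  skip_if_not_installed("readxl")
  py <- Sys.which("python")
  skip_if(py == "", "python (for building the xlsx fixture) not on PATH")
  tmp <- withr::local_tempfile(fileext = ".xlsx")
  script <- sprintf('
import openpyxl
wb = openpyxl.Workbook()
ws = wb.active; ws.title = "dHf"
ws.append(["isomer", 300, 400])
ws.append(["n-C4", -126.1, -130.5])
ws.append(["2-m-C3", -134.9, -141.2])
ws2 = wb.create_sheet("G_minus_H0")
ws2.append(["isomer", 300, 400])
ws2.append(["n-C4", -64.1, -92.3])
ws2.append(["2-m-C3", -60.8, -88.5])
wb.save(%s)
', deparse(tmp))
  res <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(tmp), "openpyxl unavailable to build the fixture")
  tab <- read_training_table(tmp)
  expect_setequal(unique(tab$property), c("dHf", "G_minus_H0"))
  expect_equal(unname(training_values(tab, "dHf", 400, "2-m-C3")), -141.2)
  expect_equal(unname(training_values(tab, "G_minus_H0", 300, "n-C4")), -64.1)
  expect_error(read_training_table("no-such-file.xlsx"), "no such file")
})

test_that("write/read round trip is lossless to 12 significant digits", {
  syn <- generate_synthetic_table(3, n_max = 5, temperatures = c(300, 400))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_training_table(syn$table, tmp)
  back <- read_training_table(tmp)
  a <- as.data.frame(syn$table)
  b <- as.data.frame(back)
  expect_identical(a[c("isomer", "T", "property")], b[c("isomer", "T", "property")])
  expect_true(all(abs(a$value - b$value) <= 1e-12 * pmax(abs(a$value), 1)))
})

test_that("synthetic tables are exactly group-additive when noiseless", {
  syn <- generate_synthetic_table(5, n_max = 6,
                                  temperatures = c(200, 400, 600),
                                  properties = "dHf")
  X <- build_descriptor_matrix(syn$molecules)
  pm <- syn$planted$dHf
  for (T in c(200, 400, 600)) {
    tv <- c(1, T, T^2)
    manual <- sum(pm["(Intercept)", ] * tv) +
      as.numeric(X[, rownames(pm)[-1], drop = FALSE] %*%
                   (pm[-1, , drop = FALSE] %*% tv))
    vals <- training_values(syn$table, "dHf", T)
    expect_equal(unname(vals[rownames(X)]), manual, tolerance = 1e-12)
  }
})

test_that("an all-equal planted model makes every value proportional to n", {
  keys <- union("CH4", enumerate_group_universe()$key)
  pm <- rbind("(Intercept)" = c(A = 0, B = 0, C = 0),
              matrix(rep(c(-5, 0, 0), each = length(keys)), ncol = 3,
                     dimnames = list(keys, c("A", "B", "C"))))
  syn <- generate_synthetic_table(1, n_max = 5, temperatures = c(300, 500),
                                  properties = "dHf",
                                  planted = list(dHf = pm))
  nn <- vapply(training_molecules(syn$table), carbon_count, integer(1))
  for (T in c(300, 500)) {
    vals <- training_values(syn$table, "dHf", T)
    expect_equal(unname(vals), unname(-5 * nn[names(vals)]), tolerance = 1e-12)
  }
})

test_that("noisier tables degrade coefficient recovery monotonically", {
  rmse_at <- function(sigma, seed) {
    syn <- generate_synthetic_table(seed, n_max = 8, temperatures = 400,
                                    properties = "dHf", sigma = sigma)
    fit <- fit_gc_model(syn$table, "dHf", temperatures = 400)
    # in-sample prediction error against the noise-free planted values
    mols <- training_molecules(syn$table)
    pm <- syn$planted$dHf
    X <- build_descriptor_matrix(mols)
    keys <- intersect(colnames(X), rownames(pm))
    truth <- sum(pm["(Intercept)", ] * c(1, 400, 400^2)) +
      as.numeric(X[, keys] %*% (pm[keys, ] %*% c(1, 400, 400^2)))
    pred <- predict(fit, mols, T = 400, coefficients = "per_temperature")
    sqrt(mean((pred - truth)^2))
  }
  seeds <- 1:4
  lo <- vapply(seeds, function(s) rmse_at(0.05, s), numeric(1))
  hi <- vapply(seeds, function(s) rmse_at(0.4, s), numeric(1))
  expect_true(all(lo < hi))
  # the fit is linear in the data, so for a fixed seed the error against the
  # planted truth scales exactly with the noise level (0.4 / 0.05 = 8)
  expect_equal(unname(hi / lo), rep(8, length(seeds)), tolerance = 1e-6)
})

test_that("Henry tables must be positive and complete", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(isomer = c("n-C4", "2-m-C3"), zeolite = "MTW",
                       T = 500, KH = c(1e-6, 2e-6)), tmp, row.names = FALSE)
  h <- read_henry_table(tmp)
  expect_s3_class(h, "henry_table")
  write.csv(data.frame(isomer = "n-C4", zeolite = "MTW", T = 500, KH = -1),
            tmp, row.names = FALSE)
  expect_error(read_henry_table(tmp), "positive")
})
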