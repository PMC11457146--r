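# Group-contribution linear regression.
#
# For each thermochemical property and each temperature separately,
#   y = alpha0 + sum_k x_k alpha_k
# is fitted by least squares over the training isomers, x_k being the
# occurrence count of group k. The per-temperature coefficients are then
# refitted to quadratic temperature polynomials alpha(T) = A + B T + C T^2.

# minimum-norm least squares via SVD with a relative singular-value cutoff;
# deterministic under rank deficiency (the intercept and the count-sum
# direction can be near-collinear).
.lsq_minnorm <- function(X, y, rcond = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > rcond * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dinv * crossprod(sv$u, y)))
}

#' Fit a group-contribution property model
#'
#' Performs one least-squares fit per temperature (minimum-norm solution
#' under rank deficiency; no regularization or weighting) and, when at
#' least three temperatures are fitted, refits every coefficient to a
#' quadratic polynomial in T. An approximation map covering the out-of-
#' training groups of the full 69-group universe is attached so the model
#' can predict isomers beyond the training range.
#'
#' @param table A \code{training_table}.
#' @param property One of \code{GC_PROPERTIES}.
#' @param order \code{"second"} (default) or \code{"first"} order groups.
#' @param temperatures Temperatures to fit (default: the table's full grid
#'   for this property).
#' @param approximation Optional user map (data frame \code{out_key,in_key})
#'   overriding the built-in demotion rule.
#' @param rcond Relative singular-value cutoff of the solver.
#' @return An object of class \code{gc_model}: per-temperature intercepts
#'   and coefficients, residuals and MAE diagnostics, quadratic temperature
#'   polynomials, and the approximation map.
#' @examples
#' syn <- generate_synthetic_table(1, n_max = 5, temperatures = c(300, 400, 500))
#' fit <- fit_gc_model(syn$table, "dHf")
#' fit$mae
#' @export
fit_gc_model <- function(table, property, order = c("second", "first"),
                         temperatures = NULL, approximation = NULL,
                         rcond = 1e-10) {
  stopifnot(inherits(table, "training_table"))
  order <- match.arg(order)
  if (!property %in% unique(table$property))
    stop("property ", property, " absent from the training table")
  sub <- table[table$property == property, , drop = FALSE]
  grid <- sort(unique(sub$T))
  if (is.null(temperatures)) temperatures <- grid
  if (length(bad <- setdiff(temperatures, grid)))
    stop("temperature(s) not in the table grid: ", paste(bad, collapse = ", "))
  mols <- training_molecules(table)
  ids <- sort(unique(sub$isomer), method = "radix")
  X <- build_descriptor_matrix(mols[ids], order = order)
  rownames(X) <- ids
  keys <- colnames(X)
  coefs <- matrix(NA_real_, nrow = ncol(X) + 1L, ncol = length(temperatures),
                  dimnames = list(c("(Intercept)", keys),
                                  as.character(temperatures)))
  resid <- matrix(NA_real_, nrow = length(ids), ncol = length(temperatures),
                  dimnames = list(ids, as.character(temperatures)))
  # the intercept is fitted by centering; group coefficients are the
  # minimum-norm solution on the centered design. Centering pins the
  # intercept even when count identities (e.g. the CH3/CH/C leaf relation)
  # make the constant direction non-identifiable, so adding c to every
  # training value shifts the intercept by exactly c.
  xm <- colMeans(X)
  for (j in seq_along(temperatures)) {
    y <- training_values(table, property, temperatures[j], ids)
    b <- .lsq_minnorm(sweep(X, 2, xm), y - mean(y), rcond)
    a0 <- mean(y) - sum(xm * b)
    coefs[, j] <- c(a0, b)
    resid[, j] <- a0 + as.numeric(X %*% b) - y
  }
  mae_t <- colMeans(abs(resid))
  model <- structure(list(
    property = property,
    order = order,
    temperatures = temperatures,
    keys = keys,
    coefficients = coefs,
    residuals = resid,
    mae_by_temperature = mae_t,
    mae = mean(abs(resid)),
    polynomials = NULL,
    polynomial_residual = NULL,
    approximation = NULL,
    rcond = rcond), class = "gc_model")
  if (length(temperatures) >= 3L) {
    tp <- fit_temperature_polynomials(model)
    model$polynomials <- tp$coefficients
    model$polynomial_residual <- tp$residual_max
  }
  if (order == "second") {
    model$approximation <- if (is.null(approximation))
      build_approximation_map(keys) else approximation
  }
  model
}

#' @export
print.gc_model <- function(x, ...) {
  cat("<gc_model> property ", x$property, ", ", x$order, "-order groups\n",
      "  ", length(x$keys), " descriptors + intercept, ",
      length(x$temperatures), " temperature(s) ",
      "[", min(x$temperatures), ", ", max(x$temperatures), "] K\n",
      "  training MAE ", format(x$mae, digits = 4), " kJ/mol",
      if (!is.null(x$polynomials))
        paste0("; quadratic T-polynomials fitted (max |resid| ",
               format(max(x$polynomial_residual), digits = 3), " kJ/mol)"),
      "\n", sep = "")
  invisible(x)
}

#' Mean absolute error of a fitted model on a table
#'
#' Mean of |prediction - training value| using the per-temperature
#' coefficients, over all isomers and all fitted temperatures by default
#' (restrict with \code{temperatures}).
#'
#' @param model A \code{gc_model}.
#' @param table A \code{training_table} (default: use the stored training
#'   residuals).
#' @param temperatures Optional subset of fitted temperatures.
#' @return MAE in kJ/mol.
#' @export
gc_mae <- function(model, table = NULL, temperatures = NULL) {
  stopifnot(inherits(model, "gc_model"))
  if (is.null(temperatures)) temperatures <- model$temperatures
  if (length(bad <- setdiff(temperatures, model$temperatures)))
    stop("model was not fitted at: ", paste(bad, collapse = ", "))
  if (is.null(table))
    return(mean(abs(model$residuals[, as.character(temperatures), drop = FALSE])))
  errs <- unlist(lapply(temperatures, function(T) {
    y <- training_values(table, model$property, T)
    pred <- predict(model, names(y), T = T, coefficients = "per_temperature")
    abs(pred - y)
  }))
  if (!length(errs)) stop("empty evaluation scope")
  mean(errs)
}

#' Refit per-temperature coefficients to quadratic temperature polynomials
#'
#' Each coefficient (and the intercept) is independently least-squares
#' fitted to \code{A + B T + C T^2} over the fitted temperatures. The
#' maximum absolute refit residual per coefficient is reported so a
#' non-quadratic temperature dependence is visible rather than silently
#' absorbed.
#'
#' @param model A \code{gc_model} fitted at >= 3 temperatures.
#' @return List with \code{coefficients} (matrix, columns A/B/C, one row per
#'   descriptor plus intercept; units kJ/mol, kJ/mol/K, kJ/mol/K^2) and
#'   \code{residual_max} (named vector, kJ/mol).
#' @export
fit_temperature_polynomials <- function(model) {
  stopifnot(inherits(model, "gc_model"))
  Ts <- model$temperatures
  if (length(Ts) < 3L)
    stop("need >= 3 fitted temperatures for a quadratic polynomial")
  Xt <- cbind(1, Ts, Ts^2)
  qr_t <- qr(Xt)
  co <- t(apply(model$coefficients, 1, function(a) qr.coef(qr_t, a)))
  colnames(co) <- c("A", "B", "C")
  fitted <- Xt %*% t(co)
  res <- abs(t(fitted) - model$coefficients)
  list(coefficients = co,
       residual_max = apply(res, 1, max))
}

# evaluate coefficients at an arbitrary temperature from the polynomials
.poly_coef_at <- function(model, T) {
  if (is.null(model$polynomials))
    stop("model has no temperature polynomials (fitted at < 3 temperatures)")
  as.numeric(model$polynomials %*% c(1, T, T^2)) |>
    stats::setNames(rownames(model$polynomials))
}

#' Predict a thermochemical property for molecules
#'
#' Computes \code{alpha0(T) + sum_k x_k alpha_k(T)}. With
#' \code{coefficients = "poly"} (default) the quadratic temperature
#' polynomials are evaluated at any T in the fitted range (extrapolation
#' warns); with \code{"per_temperature"} the raw per-temperature fit is used
#' and T must be a fitted temperature. Groups absent from the training keys
#' are routed through the model's approximation map.
#'
#' @param object A \code{gc_model}.
#' @param newdata A \code{molecule}, list of molecules, or character vector
#'   of shorthand names / SMILES.
#' @param T Temperature in K.
#' @param coefficients \code{"poly"} or \code{"per_temperature"}.
#' @param ... Unused.
#' @return Named numeric vector of predictions in kJ/mol.
#' @examples
#' syn <- generate_synthetic_table(1, n_max = 5, temperatures = c(300, 400, 500))
#' fit <- fit_gc_model(syn$table, "dHf")
#' predict(fit, "2-m-C4", T = 400)
#' @export
predict.gc_model <- function(object, newdata, T,
                             coefficients = c("poly", "per_temperature"),
                             ...) {
  coefficients <- match.arg(coefficients)
  if (is.character(newdata)) newdata <- lapply(newdata, .resolve_isomer)
  if (is_molecule(newdata)) newdata <- list(newdata)
  amap <- if (!is.null(object$approximation))
    stats::setNames(object$approximation$in_key, object$approximation$out_key)
  else NULL
  if (coefficients == "poly") {
    rng <- range(object$temperatures)
    if (T < rng[1] || T > rng[2])
      warning("T = ", T, " K is outside the fitted range [",
              rng[1], ", ", rng[2], "] K; extrapolating")
    a <- .poly_coef_at(object, T)
  } else {
    j <- match(as.character(T), colnames(object$coefficients))
    if (is.na(j))
      stop("T = ", T, " is not a fitted temperature; use coefficients = \"poly\"")
    a <- object$coefficients[, j]
  }
  vapply(newdata, function(m) {
    x <- count_groups(m, object$order)
    unknown <- setdiff(names(x), object$keys)
    if (length(unknown)) {
      if (is.null(amap) || !all(unknown %in% names(amap)))
        stop("no approximation for group(s): ",
             paste(setdiff(unknown, names(amap)), collapse = ", "))
      hit <- names(x) %in% names(amap)
      names(x)[hit] <- amap[names(x)[hit]]
      x2 <- tapply(x, names(x), sum)
      x <- stats::setNames(as.integer(x2), names(x2))
      still <- setdiff(names(x), object$keys)
      if (length(still))
        stop("approximation map image outside training keys: ",
             paste(still, collapse = ", "))
    }
    a[["(Intercept)"]] + sum(a[names(x)] * x)
  }, numeric(1)) |>
    stats::setNames(vapply(newdata, function(m)
      if (!is.null(m$label)) m$label else write_smiles(m), character(1)))
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model A \code{gc_model}.
#' @param path JSON file path.
#' @rdname gc_model_io
#' @export
write_gc_model <- function(model, path) {
  stopifnot(inherits(model, "gc_model"))
  obj <- list(
    property = model$property, order = model$order,
    temperatures = model$temperatures, keys = model$keys,
    coefficients = model$coefficients,
    mae = model$mae, mae_by_temperature = model$mae_by_temperature,
    polynomials = model$polynomials,
    polynomial_residual = model$polynomial_residual,
    approximation = model$approximation, rcond = model$rcond)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(path)
}

#' @rdname gc_model_io
#' @export
read_gc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- obj$coefficients   # row-major nested arrays simplify back to a matrix
  dimnames(co) <- list(c("(Intercept)", obj$keys), as.character(obj$temperatures))
  poly <- obj$polynomials
  if (!is.null(poly)) {
    dimnames(poly) <- list(c("(Intercept)", obj$keys), c("A", "B", "C"))
  }
  structure(list(
    property = obj$property, order = obj$order,
    temperatures = as.numeric(obj$temperatures), keys = obj$keys,
    coefficients = co,
    residuals = NULL,
    mae_by_temperature = stats::setNames(as.numeric(obj$mae_by_temperature),
                                         as.character(obj$temperatures)),
    mae = obj$mae,
    polynomials = poly,
    polynomial_residual = if (!is.null(obj$polynomial_residual))
      stats::setNames(as.numeric(obj$polynomial_residual),
                      c("(Intercept)", obj$keys)),
    approximation = if (!is.null(obj$approximation) &&
                        length(obj$approximation))
      as.data.frame(obj$approximation, stringsAsFactors = FALSE),
    rcond = obj$rcond), class = "gc_model")
}

#' Export fitted polynomial coefficients as CSV
#'
#' One row per descriptor (plus intercept) with columns key, A, B, C,
#' mirroring per-property coefficient worksheets.
#'
#' @param model A \code{gc_model} with fitted polynomials.
#' @param path Output CSV path.
#' @export
write_coefficient_csv <- function(model, path) {
  stopifnot(inherits(model, "gc_model"))
  if (is.null(model$polynomials)) stop("model has no temperature polynomials")
  df <- data.frame(key = rownames(model$polynomials),
                   A = model$polynomials[, "A"],
                   B = model$polynomials[, "B"],
                   C = model$polynomials[, "C"],
                   max_refit_residual = model$polynomial_residual,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
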