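# Training tables of ideal-gas thermochemical properties and Henry-
# coefficient tables, plus a synthetic group-additive table generator.
#
# Internal units are fixed: energies in kJ/mol, temperatures in K.  The
# Gibbs energy function (G0 - H0(0 K)) is stored signed, exactly as
# tabulated, not as a Giauque function.

#' Supported thermochemical property identifiers
#'
#' \code{dGf} and \code{dHf} are the formation Gibbs energy and enthalpy;
#' \code{G_minus_H0} and \code{H_minus_H0} are (G0 - H0(0 K)) and
#' (H0 - H0(0 K)). All in kJ/mol.
#' @format Character vector of length 4.
#' @export
GC_PROPERTIES <- c("dGf", "dHf", "G_minus_H0", "H_minus_H0")

# resolve an isomer id: shorthand name first, SMILES as fallback
.resolve_isomer <- function(id) {
  m <- tryCatch(name_to_molecule(id), error = function(e) NULL)
  if (is.null(m))
    m <- tryCatch(parse_smiles(id, label = id), error = function(e) NULL)
  if (is.null(m))
    stop("isomer id '", id, "' is neither a shorthand name nor a SMILES")
  m
}

# validate + classify a tidy records data frame into a training_table
.as_training_table <- function(df) {
  need <- c("isomer", "T", "property", "value")
  if (!all(need %in% names(df)))
    stop("training table needs columns ", paste(need, collapse = ","))
  df <- df[need]
  df$isomer <- as.character(df$isomer)
  df$property <- as.character(df$property)
  df$T <- suppressWarnings(as.numeric(df$T))
  df$value <- suppressWarnings(as.numeric(df$value))
  if (!nrow(df)) stop("training table is empty")
  if (anyNA(df$T) || anyNA(df$value))
    stop("training table contains non-numeric temperatures or values")
  if (any(!is.finite(df$value))) stop("training table values must be finite")
  bad <- setdiff(unique(df$property), GC_PROPERTIES)
  if (length(bad))
    stop("unknown property id(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(GC_PROPERTIES, collapse = "/"), ")")
  mols <- lapply(stats::setNames(nm = unique(df$isomer)), .resolve_isomer)
  # identical temperature grid across isomers, per property
  for (p in unique(df$property)) {
    sub <- df[df$property == p, ]
    grids <- tapply(sub$T, sub$isomer, function(x) paste(sort(x), collapse = ","))
    if (length(unique(grids)) != 1L)
      stop("inconsistent temperature grid across isomers for property ", p)
    if (anyDuplicated(sub[c("isomer", "T")]))
      stop("duplicate (isomer, T) records for property ", p)
  }
  df <- df[order(df$property, df$isomer, df$T, method = "radix"), ]
  rownames(df) <- NULL
  structure(df, molecules = mols, class = c("training_table", "data.frame"))
}

#' Read a training table of thermochemical properties
#'
#' Two layouts are supported. CSV: tidy records with columns
#' \code{isomer,T,property,value} (energies kJ/mol, T in K; isomer ids are
#' shorthand names or SMILES). XLSX (requires the readxl package): one
#' worksheet per property in Scott-table layout, first column the isomer id
#' and remaining columns temperatures in K; \code{sheets} maps property ids
#' to worksheet names.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format \code{"csv"} or \code{"xlsx"}.
#' @param sheets Named character vector, property id -> worksheet name
#'   (xlsx only). Defaults to worksheets named like the property ids.
#' @return A \code{training_table} (tidy data frame with resolved molecule
#'   graphs attached).
#' @export
read_training_table <- function(path, format = c("auto", "csv", "xlsx"),
                                sheets = stats::setNames(nm = GC_PROPERTIES)) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(.as_training_table(df))
  }
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading xlsx requires the readxl package")
  avail <- readxl::excel_sheets(path)
  recs <- list()
  for (p in names(sheets)) {
    if (!sheets[[p]] %in% avail) next
    sh <- readxl::read_excel(path, sheet = sheets[[p]])
    if (ncol(sh) < 2L) stop("worksheet ", sheets[[p]], " has no temperature columns")
    temps <- suppressWarnings(as.numeric(names(sh)[-1]))
    if (anyNA(temps))
      stop("worksheet ", sheets[[p]],
           " column headers after the first must be temperatures in K")
    for (j in seq_along(temps)) {
      recs[[length(recs) + 1L]] <- data.frame(
        isomer = as.character(sh[[1]]), T = temps[j], property = p,
        value = as.numeric(sh[[j + 1L]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) stop("no matching worksheets found in ", path)
  .as_training_table(do.call(rbind, recs))
}

#' Write a training table as tidy CSV
#'
#' Values are written with 15 significant digits so a write/read round trip
#' is lossless well beyond 12 significant digits.
#'
#' @param table A \code{training_table}.
#' @param path Output CSV path.
#' @export
write_training_table <- function(table, path) {
  stopifnot(inherits(table, "training_table"))
  df <- as.data.frame(table)
  df$T <- format(df$T, digits = 15, scientific = FALSE, trim = TRUE)
  df$value <- trimws(formatC(df$value, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE)  # names may contain commas
  invisible(path)
}

#' Molecules resolved from a training table
#' @param table A \code{training_table}.
#' @return Named list of \code{molecule} objects keyed by isomer id.
#' @export
training_molecules <- function(table) attr(table, "molecules")

#' Look up training values
#'
#' @param table A \code{training_table}.
#' @param property One of \code{GC_PROPERTIES}.
#' @param T Temperature in K (must be on the table's grid).
#' @param isomers Optional isomer ids (default: all, in table order).
#' @return Named numeric vector of values in kJ/mol.
#' @export
training_values <- function(table, property, T, isomers = NULL) {
  stopifnot(inherits(table, "training_table"))
  sub <- table[table$property == property & table$T == T, , drop = FALSE]
  if (!nrow(sub)) stop("no records for property ", property, " at T = ", T)
  out <- stats::setNames(sub$value, sub$isomer)
  if (!is.null(isomers)) {
    miss <- setdiff(isomers, names(out))
    if (length(miss)) stop("missing isomers: ", paste(miss, collapse = ", "))
    out <- out[isomers]
  }
  out
}

#' Read a Henry-coefficient table
#'
#' CSV with columns \code{isomer,zeolite,T,KH}; coefficients in
#' mol kg^-1 Pa^-1 and strictly positive.
#'
#' @param path CSV path.
#' @return Data frame of class \code{henry_table}.
#' @export
read_henry_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("isomer", "zeolite", "T", "KH")
  if (!all(need %in% names(df)))
    stop("Henry table needs columns ", paste(need, collapse = ","))
  df <- df[need]
  df$T <- as.numeric(df$T)
  df$KH <- as.numeric(df$KH)
  if (anyNA(df$KH) || any(!is.finite(df$KH)) || any(df$KH <= 0))
    stop("Henry coefficients must be finite and strictly positive")
  structure(df, class = c("henry_table", "data.frame"))
}

# deterministic planted quadratic coefficients for one property.
# Base contributions depend on the center type with property-specific
# magnitudes (kJ/mol) mirroring real alkane tables: formation enthalpies
# vary strongly with branching, formation Gibbs energies less so (entropy
# compensation), and the 0 K-referenced G/H functions vary only weakly
# between isomers. Neighbor-dependent perturbations give every property
# genuine second-order structure that a first-order fit cannot represent.
.PLANT_SCALES <- list(
  dHf        = list(base = c(CH4 = -66, CH3 = -42, CH2 = -20.6,
                             CH = -1.2, C = 8.0), sd = 3, nb = 0.8,
                    B0 = 0),
  dGf        = list(base = c(CH4 = -30, CH3 = -12, CH2 = -4.5,
                             CH = 2.0, C = 6.0), sd = 2, nb = 0.4,
                    B0 = 0.05),
  G_minus_H0 = list(base = c(CH4 = -10, CH3 = -8, CH2 = -7,
                             CH = -6.5, C = -6.0), sd = 1, nb = 0.3,
                    B0 = -0.06),
  H_minus_H0 = list(base = c(CH4 = 1.5, CH3 = 2.0, CH2 = 1.6,
                             CH = 1.3, C = 1.1), sd = 0.5, nb = 0.2,
                    B0 = 0.025))

.plant_property_model <- function(property, keys) {
  sc <- .PLANT_SCALES[[property]]
  A <- B <- CC <- numeric(length(keys))
  for (i in seq_along(keys)) {
    g <- .parse_group_key(keys[i])
    nb_rank <- if (length(g$neighbors)) sum(.ua_rank(g$neighbors)) else 0
    A[i] <- sc$base[[g$center]] + stats::rnorm(1, 0, sc$sd) + sc$nb * nb_rank
    B[i] <- sc$B0 + stats::rnorm(1, 0, 0.003)
    CC[i] <- stats::rnorm(1, 0, 3e-6)
  }
  out <- cbind(A = A, B = B, C = CC)
  rownames(out) <- keys
  out
}

#' Generate a synthetic group-additive training table
#'
#' Produces a table whose values are exactly group-additive: for every
#' isomer and temperature,
#' \code{value = a0(T) + sum_k x_k a_k(T) + noise}, with each coefficient a
#' quadratic \code{A + B T + C T^2}. The planted coefficients are returned
#' alongside the table so regression tests can check exact recovery. The
#' defaults emulate the study conditions: all 150 constitutional isomers of
#' C1-C10 on a (0-1000) K grid, all four properties, noiseless.
#'
#' @param seed Integer RNG seed (drives both the planted model and the
#'   noise).
#' @param n_max Largest carbon count; isomers of C1..n_max are included.
#' @param temperatures Temperature grid in K.
#' @param properties Subset of \code{GC_PROPERTIES}.
#' @param sigma Gaussian noise s.d. in kJ/mol (0 = exactly additive).
#' @param planted Optional planted model: named list (per property) of
#'   matrices with rownames = descriptor keys (plus \code{"(Intercept)"})
#'   and columns A, B, C. Built deterministically from the seed when NULL.
#' @return List with elements \code{table} (a \code{training_table}),
#'   \code{planted} (the coefficient matrices) and \code{molecules}.
#' @examples
#' syn <- generate_synthetic_table(seed = 1, n_max = 6,
#'                                 temperatures = c(300, 400, 500))
#' head(syn$table)
#' @export
generate_synthetic_table <- function(seed, n_max = 10,
                                     temperatures = seq(0, 1000, by = 100),
                                     properties = GC_PROPERTIES,
                                     sigma = 0, planted = NULL) {
  stopifnot(n_max >= 1, length(temperatures) >= 1, sigma >= 0)
  properties <- match.arg(properties, GC_PROPERTIES, several.ok = TRUE)
  set.seed(as.integer(seed))
  mols <- list()
  for (n in seq_len(n_max)) mols <- c(mols, enumerate_isomers(n)$members)
  ids <- vapply(mols, function(m) m$label, character(1))
  names(mols) <- ids
  X <- build_descriptor_matrix(mols, order = "second")
  keys <- colnames(X)
  if (is.null(planted)) {
    planted <- lapply(stats::setNames(nm = properties), function(p) {
      rbind("(Intercept)" = c(A = stats::rnorm(1, 0, 2), B = 0, C = 0),
            .plant_property_model(p, keys))
    })
  }
  recs <- list()
  for (p in properties) {
    pm <- planted[[p]]
    miss <- setdiff(keys, rownames(pm))
    if (length(miss))
      stop("planted model for ", p, " lacks keys: ", paste(miss, collapse = ", "))
    for (T in temperatures) {
      tv <- c(1, T, T^2)
      alpha0 <- sum(pm["(Intercept)", ] * tv)
      alpha <- pm[keys, , drop = FALSE] %*% tv
      y <- alpha0 + as.numeric(X %*% alpha)
      if (sigma > 0) y <- y + stats::rnorm(length(y), 0, sigma)
      recs[[length(recs) + 1L]] <- data.frame(
        isomer = ids, T = T, property = p, value = y,
        stringsAsFactors = FALSE)
    }
  }
  tab <- .as_training_table(do.call(rbind, recs))
  list(table = tab, planted = planted, molecules = mols)
}
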