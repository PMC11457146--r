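# Reaction-equilibrium distributions of alkane isomers.
#
# Equating ideal-gas chemical potentials of isomers sharing one molecular
# formula yields Boltzmann weights over the per-isomer exponent
#   e_i = (G0 - H0(0 K))_i(T) + DfH0_i(0 K)      [kJ/mol],
# all density- and atomization-reference terms cancelling between isomers.
# Adsorbed-phase distributions follow from Henry's law at infinite dilution.

#' Gas constant in kJ mol^-1 K^-1
#' @format Length-1 numeric (8.314462618e-3).
#' @export
R_KJ <- 8.314462618e-3

# JANAF 0 K enthalpies of formation of atomic C and H, kJ/mol
.DHF0_ATOM <- c(C = 711.185, H = 216.035)

#' Atomization energy at 0 K
#'
#' \code{D0 = a_C * DfH0(C) + a_H * DfH0(H) - DfH0(molecule)}, with the
#' atomic 0 K formation enthalpies defaulting to the JANAF values
#' 711.185 kJ/mol (C) and 216.035 kJ/mol (H).
#'
#' @param a_C Number of carbon atoms (>= 1).
#' @param a_H Number of hydrogen atoms; must equal \code{2 a_C + 2} for an
#'   alkane.
#' @param dHf0 Molecular enthalpy of formation at 0 K, kJ/mol.
#' @param dHf0_C,dHf0_H Atomic reference constants, kJ/mol (overridable).
#' @return Atomization energy in kJ/mol (vectorized).
#' @examples
#' atomization_energy(1, 4, 0)  # 1575.325 kJ/mol
#' @export
atomization_energy <- function(a_C, a_H, dHf0,
                               dHf0_C = .DHF0_ATOM[["C"]],
                               dHf0_H = .DHF0_ATOM[["H"]]) {
  if (any(a_C < 1)) stop("a_C must be >= 1")
  if (any(a_H != 2 * a_C + 2))
    stop("inconsistent alkane formula: a_H must equal 2*a_C + 2")
  a_C * dHf0_C + a_H * dHf0_H - dHf0
}

#' Ideal-gas chemical potential at number density rho
#'
#' \code{mu = mu_ref + R T log(rho / rho0)} with the reference density
#' \code{rho0 = 1} molecule per cubic Angstrom. For equal-formula isomer
#' equilibria only differences of \code{mu_ref} matter (the density terms
#' cancel), which is what \code{\link{gas_distribution}} uses.
#'
#' @param mu_ref Reference chemical potential, kJ/mol.
#' @param rho Number density, molecules per cubic Angstrom.
#' @param T Temperature in K.
#' @param rho0 Reference density (default 1).
#' @return Chemical potential in kJ/mol.
#' @export
ideal_gas_mu <- function(mu_ref, rho, T, rho0 = 1) {
  if (T <= 0) stop("T must be > 0")
  if (any(rho <= 0)) stop("rho must be > 0")
  mu_ref + R_KJ * T * log(rho / rho0)
}

#' Reference chemical potential exponent of an isomer
#'
#' The part of the ideal-gas chemical potential that differs between
#' isomers of one formula: \code{(G0 - H0(0 K))(T) + DfH0(0 K)} in kJ/mol.
#'
#' @param g_minus_h0 (G0 - H0(0 K)) at the working temperature, kJ/mol.
#' @param dHf0 Enthalpy of formation at 0 K, kJ/mol.
#' @return Exponent in kJ/mol (vectorized).
#' @export
reference_exponent <- function(g_minus_h0, dHf0) g_minus_h0 + dHf0

#' Gas-phase reaction-equilibrium distribution of isomers
#'
#' Boltzmann weights \code{w_i = exp(-e_i / (R T))} over the reference
#' exponents \code{e_i = (G0 - H0(0 K))_i(T) + DfH0_i(0 K)}, normalized to
#' mole fractions. Exponents are shifted by their minimum before
#' exponentiation, so the result is invariant (to ~1e-16) to any uniform
#' shift and never overflows.
#'
#' @param isomer Character vector of isomer ids (shorthand names or SMILES;
#'   used to verify that all isomers share one molecular formula).
#' @param dHf0 Per-isomer enthalpy of formation at 0 K, kJ/mol.
#' @param g_minus_h0 Per-isomer (G0 - H0(0 K)) at \code{T}, kJ/mol.
#' @param T Temperature in K (> 0).
#' @return An \code{equilibrium_result}: data frame with columns
#'   \code{isomer}, \code{y} (mole fraction), with attributes \code{phase}
#'   ("gas") and \code{T}.
#' @examples
#' gas_distribution(c("n-C4", "2-m-C3"), dHf0 = c(-100, -105),
#'                  g_minus_h0 = c(-60, -58), T = 500)
#' @export
gas_distribution <- function(isomer, dHf0, g_minus_h0, T) {
  if (T <= 0) stop("T must be > 0")
  n <- length(isomer)
  if (n < 1L) stop("need at least one isomer")
  if (length(dHf0) != n || length(g_minus_h0) != n)
    stop("dHf0 and g_minus_h0 must match `isomer` in length")
  if (anyDuplicated(isomer)) stop("duplicate isomer ids")
  if (any(!is.finite(dHf0)) || any(!is.finite(g_minus_h0)))
    stop("non-finite thermochemical input (no silent sentinel handling)")
  nc <- vapply(isomer, function(id) carbon_count(.resolve_isomer(id)),
               integer(1))
  if (length(unique(nc)) != 1L)
    stop("isomers do not share one molecular formula (carbon counts ",
         paste(sort(unique(nc)), collapse = ", "), ")")
  e <- reference_exponent(g_minus_h0, dHf0)
  w <- exp(-(e - min(e)) / (R_KJ * T))
  y <- w / sum(w)
  structure(data.frame(isomer = isomer, y = y, stringsAsFactors = FALSE,
                       row.names = NULL),
            phase = "gas", T = T,
            class = c("equilibrium_result", "data.frame"))
}

#' Adsorbed-phase distribution from Henry coefficients
#'
#' At infinite dilution the adsorbed mole fractions follow Henry's law:
#' \code{x_i = KH_i y_i / sum_j KH_j y_j}. The result is invariant to
#' scaling all Henry coefficients by a common constant.
#'
#' @param gas An \code{equilibrium_result} of phase "gas".
#' @param henry A \code{henry_table} (or data frame with columns
#'   \code{isomer,zeolite,T,KH}).
#' @param zeolite Framework id to select (e.g. "MTW").
#' @param T Temperature in K; defaults to the gas result's temperature.
#' @return An \code{equilibrium_result} of phase "adsorbed".
#' @export
adsorbed_distribution <- function(gas, henry, zeolite, T = attr(gas, "T")) {
  stopifnot(inherits(gas, "equilibrium_result"))
  if (!identical(attr(gas, "phase"), "gas"))
    stop("`gas` must be a gas-phase equilibrium_result")
  need <- c("isomer", "zeolite", "T", "KH")
  if (!all(need %in% names(henry)))
    stop("Henry table needs columns ", paste(need, collapse = ","))
  sub <- henry[henry$zeolite == zeolite & henry$T == T, , drop = FALSE]
  kh <- stats::setNames(sub$KH, sub$isomer)
  miss <- setdiff(gas$isomer, names(kh))
  if (length(miss))
    stop("missing Henry coefficient(s) for zeolite ", zeolite, " at ",
         T, " K: ", paste(miss, collapse = ", "))
  kh <- kh[gas$isomer]
  if (any(kh <= 0)) stop("Henry coefficients must be strictly positive")
  w <- kh * gas$y
  structure(data.frame(isomer = gas$isomer, y = as.numeric(w / sum(w)),
                       stringsAsFactors = FALSE, row.names = NULL),
            phase = "adsorbed", T = T, zeolite = zeolite,
            class = c("equilibrium_result", "data.frame"))
}

#' Per-isomer selectivity
#'
#' \code{s_i = y_i / (1 - y_i)}: mole fraction of a component over the sum
#' of all other components in the same phase.
#'
#' @param result An \code{equilibrium_result} with >= 2 components.
#' @return Named numeric vector of selectivities.
#' @export
selectivity <- function(result) {
  stopifnot(inherits(result, "equilibrium_result"))
  if (nrow(result) < 2L) stop("selectivity needs at least 2 components")
  if (any(result$y >= 1))
    stop("selectivity undefined for a pure component (y = 1)")
  stats::setNames(result$y / (1 - result$y), result$isomer)
}

#' Selectivity relative to a reference isomer
#'
#' \code{s_rel,i = s_i / s_ref}; the reference (typically the linear
#' alkane, e.g. n-C10 or n-C14) has relative selectivity 1.
#'
#' @param result An \code{equilibrium_result}.
#' @param reference Isomer id of the reference component.
#' @return Named numeric vector.
#' @export
relative_selectivity <- function(result, reference) {
  s <- selectivity(result)
  if (!reference %in% names(s))
    stop("reference isomer '", reference, "' absent from the result")
  s / s[[reference]]
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("<equilibrium_result> phase ", attr(x, "phase"), ", T = ",
      attr(x, "T"), " K",
      if (!is.null(attr(x, "zeolite"))) paste0(", zeolite ", attr(x, "zeolite")),
      "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
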