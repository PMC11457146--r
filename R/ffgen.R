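# United-atom intramolecular interaction enumeration and RASPA2 file output.
#
# Intramolecular Lennard-Jones applies to site pairs separated by MORE than
# three bonds (1-5 and beyond; no scaled 1-4 LJ). This is the convention
# under which n-tetradecane carries 13 + 12 + 11 + 55 = 91 intramolecular
# interactions.

#' Enumerate intramolecular interactions of an alkane
#'
#' Returns the complete, duplicate-free lists of bonds (site pairs), bends
#' (bonded triples, middle site central), torsions (simple 3-bond paths)
#' and intramolecular Lennard-Jones pairs (graph distance >= 4 bonds).
#'
#' @param m A \code{molecule}.
#' @return An object of class \code{interaction_list} with integer matrices
#'   \code{bonds} (2 cols), \code{bends} (3), \code{torsions} (4),
#'   \code{intra_lj} (2) and a named \code{counts} vector including the
#'   total.
#' @examples
#' enumerate_interactions(name_to_molecule("n-C14"))$counts
#' @export
enumerate_interactions <- function(m) {
  stopifnot(is_molecule(m))
  adj <- .adjacency(m)
  n <- m$n_atoms
  bonds <- m$bonds
  if (nrow(bonds)) {
    bonds <- t(apply(bonds, 1, sort))
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  bends <- list()
  for (v in seq_len(n)) {
    nb <- sort(adj[[v]])
    if (length(nb) >= 2L) {
      prs <- utils::combn(nb, 2)
      for (j in seq_len(ncol(prs)))
        bends[[length(bends) + 1L]] <- c(prs[1, j], v, prs[2, j])
    }
  }
  bends <- if (length(bends)) do.call(rbind, bends) else
    matrix(integer(), ncol = 3)
  if (nrow(bends))
    bends <- bends[order(bends[, 2], bends[, 1], bends[, 3]), , drop = FALSE]
  torsions <- list()
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      b <- bonds[r, 1]; c_ <- bonds[r, 2]
      for (a in adj[[b]]) {
        if (a == c_) next
        for (d in adj[[c_]]) {
          if (d == b) next
          quad <- c(a, b, c_, d)
          if (quad[1] > quad[4]) quad <- rev(quad)
          torsions[[length(torsions) + 1L]] <- quad
        }
      }
    }
  }
  torsions <- if (length(torsions)) unique(do.call(rbind, torsions)) else
    matrix(integer(), ncol = 4)
  if (nrow(torsions))
    torsions <- torsions[order(torsions[, 2], torsions[, 3],
                               torsions[, 1], torsions[, 4]), , drop = FALSE]
  dmat <- do.call(rbind, lapply(seq_len(n), function(v) .bfs_dist(adj, v)$dist))
  lj <- which(upper.tri(dmat) & dmat >= 4L, arr.ind = TRUE)
  lj <- lj[, c("row", "col"), drop = FALSE]
  dimnames(lj) <- NULL
  if (nrow(lj)) lj <- lj[order(lj[, 1], lj[, 2]), , drop = FALSE]
  counts <- c(bonds = nrow(bonds), bends = nrow(bends),
              torsions = nrow(torsions), intra_lj = nrow(lj))
  counts <- c(counts, total = sum(counts))
  structure(list(bonds = bonds, bends = bends, torsions = torsions,
                 intra_lj = lj, counts = counts),
            class = "interaction_list")
}

#' @export
print.interaction_list <- function(x, ...) {
  cat("<interaction_list> ",
      paste(names(x$counts), x$counts, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Load a united-atom force-field parameter set
#'
#' Parameters ship as an editable CSV (sections: \code{lj} with epsilon/kB
#' in K and sigma in Angstrom per pseudo-atom, \code{bond} with k/kB in
#' K/A^2 and r0 in A, \code{bend} with k/kB in K/rad^2 and theta0 in deg,
#' \code{torsion} with the four cosine-series constants in K). The bundled
#' default carries the Dubbeldam et al. alkane united-atom set plus the
#' TraPPE-zeo zeolite atoms; treat the file as nominal published values to
#' be audited or replaced for production simulations.
#'
#' @param path Parameter CSV; defaults to the bundled file.
#' @return An object of class \code{parameter_set} (list of data frames by
#'   section).
#' @export
load_parameter_set <- function(path = system.file("extdata",
                                                  "ff_parameters.csv",
                                                  package = "alkaneGC")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section", "name", "mass", "p1", "p2", "p3", "p4")
  if (!all(need %in% names(df)))
    stop("parameter CSV needs columns ", paste(need, collapse = ","))
  lj <- df[df$section == "lj", ]
  if (any(!is.na(lj$p1) & lj$p1 < 0) || any(lj$p2 <= 0, na.rm = TRUE))
    stop("Lennard-Jones parameters must satisfy eps >= 0, sigma > 0")
  structure(split(df, df$section), class = "parameter_set")
}

.lookup_lj <- function(params, type) {
  row <- params$lj[params$lj$name == type, ]
  if (nrow(row) != 1L) stop("no LJ parameters for pseudo-atom ", type)
  row
}

.one_of_section <- function(params, section) {
  sec <- params[[section]]
  if (is.null(sec) || nrow(sec) < 1L)
    stop("parameter set lacks a '", section, "' entry")
  sec[1L, ]
}

#' Write RASPA2 molecule and force-field definition files
#'
#' Emits \code{<name>.def} (flexible united-atom molecule definition whose
#' bond/bend/torsion/intra-VDW sections come from
#' \code{\link{enumerate_interactions}}), \code{pseudo_atoms.def} and
#' \code{force_field_mixing_rules.def} (Lennard-Jones, truncated and
#' shifted at 12 A, no tail corrections, Lorentz-Berthelot mixing). Output
#' is byte-deterministic for fixed input.
#'
#' @param m A \code{molecule}.
#' @param params A \code{parameter_set} (default: bundled).
#' @param outdir Output directory (created if absent).
#' @param name Base name of the molecule file; defaults to the molecule
#'   label or shorthand name.
#' @param critical Numeric \code{c(Tc, Pc, omega)} critical constants for
#'   the molecule-file header (RASPA uses them for certain MC moves only);
#'   defaults to zeros.
#' @return Invisibly, the paths written.
#' @export
write_raspa_files <- function(m, params = load_parameter_set(),
                              outdir = ".", name = NULL,
                              critical = c(Tc = 0, Pc = 0, omega = 0)) {
  stopifnot(is_molecule(m), inherits(params, "parameter_set"))
  if (is.null(name))
    name <- if (!is.null(m$label)) m$label else molecule_name(m)
  if (is.na(name)) name <- write_smiles(m)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  types <- atom_types(m)
  for (t in unique(types)) .lookup_lj(params, t)   # fail early
  il <- enumerate_interactions(m)
  bond <- .one_of_section(params, "bond")
  bend <- .one_of_section(params, "bend")
  tors <- .one_of_section(params, "torsion")
  num <- function(x) trimws(formatC(x, format = "g", digits = 10))
  lines <- c(
    "# critical constants: Temperature [K], Pressure [Pa], Acentric factor [-]",
    num(critical[[1]]), num(critical[[2]]), num(critical[[3]]),
    "# Number Of Atoms", m$n_atoms,
    "# Number Of Groups", "1",
    "# Alkane-group", "flexible",
    "# number of atoms", m$n_atoms,
    "# atomic positions",
    paste(seq_len(m$n_atoms) - 1L, types),
    paste("# Chiral centers Bond  BondDipoles Bend  UrayBradley InvBend",
          "Torsion Imp. Torsion Bond/Bond Stretch/Bend Bend/Bend",
          "Stretch/Torsion Bend/Torsion IntraVDW IntraCoulomb"),
    paste(0, il$counts[["bonds"]], 0, il$counts[["bends"]], 0, 0,
          il$counts[["torsions"]], 0, 0, 0, 0, 0, 0,
          il$counts[["intra_lj"]], 0))
  if (il$counts[["bonds"]] > 0L) {
    lines <- c(lines, "# Bond stretch: atom n1-n2, type, parameters",
               apply(il$bonds, 1, function(b)
                 paste(b[1] - 1L, b[2] - 1L, bond$name,
                       num(bond$p1), num(bond$p2))))
  }
  if (il$counts[["bends"]] > 0L) {
    lines <- c(lines, "# Bend: atom n1-n2-n3, type, parameters",
               apply(il$bends, 1, function(b)
                 paste(b[1] - 1L, b[2] - 1L, b[3] - 1L, bend$name,
                       num(bend$p1), num(bend$p2))))
  }
  if (il$counts[["torsions"]] > 0L) {
    lines <- c(lines, "# Torsion: atom n1-n2-n3-n4, type, parameters",
               apply(il$torsions, 1, function(b)
                 paste(b[1] - 1L, b[2] - 1L, b[3] - 1L, b[4] - 1L, tors$name,
                       num(tors$p1), num(tors$p2), num(tors$p3), num(tors$p4))))
  }
  if (il$counts[["intra_lj"]] > 0L) {
    lines <- c(lines, "# Intra VDW: atom n1-n2",
               apply(il$intra_lj, 1, function(b) paste(b[1] - 1L, b[2] - 1L)))
  }
  lines <- c(lines, "# Number of config moves", "0")
  mol_path <- file.path(outdir, paste0(name, ".def"))
  writeLines(lines, mol_path)

  lj <- params$lj[order(params$lj$name, method = "radix"), ]
  pa_path <- file.path(outdir, "pseudo_atoms.def")
  writeLines(c(
    "#number of pseudo atoms", nrow(lj),
    paste("#type print as chem oxidation mass charge polarization B-factor",
          "radii connectivity anisotropic anisotropic-type tinker-type"),
    vapply(seq_len(nrow(lj)), function(i)
      paste(lj$name[i], "yes", substr(lj$name[i], 1, 1), lj$name[i], 0,
            num(lj$mass[i]), 0.0, 0.0, 1.0, 1.0, 0, 0, "relative", 0),
      character(1))), pa_path)

  mix_path <- file.path(outdir, "force_field_mixing_rules.def")
  writeLines(c(
    "# general rule for shifted vs truncated", "shifted",
    "# general rule tailcorrections", "no",
    "# number of defined interactions", nrow(lj),
    "# type interaction, parameters: epsilon/kB [K], sigma [A]",
    vapply(seq_len(nrow(lj)), function(i)
      paste(lj$name[i], "lennard-jones", num(lj$p1[i]), num(lj$p2[i])),
      character(1)),
    "# general mixing rule for Lennard-Jones", "Lorentz-Berthelot"), mix_path)

  invisible(c(molecule = mol_path, pseudo_atoms = pa_path,
              mixing_rules = mix_path))
}
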