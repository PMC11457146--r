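# Constitutional isomer enumeration: free trees on n nodes with max degree 4.
#
# Enumeration is by leaf augmentation with canonical-signature deduplication:
# every tree on k nodes arises from a tree on k-1 nodes by deleting a leaf,
# so attaching a leaf at every site of degree < 4 of every (k-1)-isomer and
# deduplicating canonical signatures is complete. This is fast through C14
# (1858 isomers) and needs no generate-and-test over labeled trees.

#' Enumerate all constitutional alkane isomers of CnH2n+2
#'
#' @param n Carbon count (1 <= n <= 20; enumeration grows steeply past C16).
#' @return An object of class \code{isomer_set}: list with elements \code{n}
#'   and \code{members} (molecules in bytewise canonical-SMILES order, each
#'   labelled with its shorthand name where one exists).
#' @examples
#' length(enumerate_isomers(4)$members)  # 2: butane, isobutane
#' @export
enumerate_isomers <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("`n` must be an integer >= 1")
  if (n > 20L) stop("isomer enumeration is capped at C20")
  level <- list(list(n_atoms = 1L, bonds = matrix(integer(), ncol = 2)))
  if (n > 1L) {
    for (k in 2:n) {
      seen <- new.env(parent = emptyenv())
      nxt <- list()
      for (g in level) {
        deg <- tabulate(c(g$bonds), nbins = g$n_atoms)
        if (g$n_atoms == 1L) deg <- 0L
        for (site in which(deg < 4L)) {
          bonds2 <- rbind(g$bonds, c(site, g$n_atoms + 1L))
          cand <- list(n_atoms = g$n_atoms + 1L, bonds = bonds2)
          sig <- .canonical_sig(structure(cand, class = "molecule"))
          if (!exists(sig, envir = seen, inherits = FALSE)) {
            assign(sig, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- cand
          }
        }
      }
      level <- nxt
    }
  }
  members <- lapply(level, function(g) molecule(g$n_atoms, g$bonds))
  smi <- vapply(members, write_smiles, character(1))
  members <- members[order(smi, method = "radix")]
  members <- lapply(members, function(m) {
    m$label <- suppressWarnings(molecule_name(m))
    if (is.na(m$label)) m$label <- write_smiles(m)
    m
  })
  structure(list(n = n, members = members), class = "isomer_set")
}

#' @export
print.isomer_set <- function(x, ...) {
  cat("<isomer_set> C", x$n, ": ", length(x$members),
      " constitutional isomer(s)\n", sep = "")
  invisible(x)
}

# branch/locant decomposition of one molecule, cached shape for filtering
.filter_features <- function(m) {
  deg <- site_degrees(m)
  if (all(deg <= 2L))
    return(list(branches = 0L, sizes = integer(), locants = integer()))
  d <- .decompose(m)
  list(branches = length(d$locants), sizes = d$sizes, locants = d$locants)
}

#' Filter an isomer set by branch-pattern rules
#'
#' Rules mirror the structural criteria used to prune hydroisomerization
#' networks in constraining-pore zeolites: long branches, geminal
#' substitution and adjacent branches all carry steric penalties, so such
#' isomers can be dropped before computing equilibrium distributions.
#' Each rule is independently toggleable; the default arguments are the
#' identity filter.
#'
#' @param s An \code{isomer_set}.
#' @param max_branch Maximum branch length in carbons (e.g. 2 keeps methyl
#'   and ethyl branches only). \code{Inf} disables the rule.
#' @param no_geminal Drop isomers carrying two branches on the same main-
#'   chain carbon.
#' @param min_locant_distance Minimum separation (in chain positions)
#'   between any two branch locants; 0 disables the rule.
#' @return A filtered \code{isomer_set} preserving member order.
#' @examples
#' s <- enumerate_isomers(8)
#' filter_isomers(s, max_branch = 1, no_geminal = TRUE)
#' @export
filter_isomers <- function(s, max_branch = Inf, no_geminal = FALSE,
                           min_locant_distance = 0L) {
  stopifnot(inherits(s, "isomer_set"))
  keep <- vapply(s$members, function(m) {
    f <- .filter_features(m)
    if (f$branches == 0L) return(TRUE)
    if (any(f$sizes > max_branch)) return(FALSE)
    if (no_geminal && anyDuplicated(f$locants)) return(FALSE)
    if (min_locant_distance > 0L && f$branches >= 2L) {
      dmin <- min(diff(sort(f$locants)))
      if (dmin < min_locant_distance) return(FALSE)
    }
    TRUE
  }, logical(1))
  structure(list(n = s$n, members = s$members[keep]), class = "isomer_set")
}
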