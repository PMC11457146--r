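# United-atom molecular graphs for acyclic alkanes.
#
# A molecule is a free tree on n carbon sites with maximum degree 4; hydrogens
# are implicit (site type CH4/CH3/CH2/CH/C is a pure function of degree).

#' United-atom site types in canonical sort order
#'
#' The fixed ordering \code{CH3 < CH2 < CH < C} used everywhere a neighbor
#' multiset is canonicalized. \code{CH4} is the degree-0 special case and is
#' never a neighbor.
#' @format Character vector of length 4.
#' @export
UA_TYPES <- c("CH3", "CH2", "CH", "C")

#' Construct a united-atom alkane molecule
#'
#' Builds a validated molecule from a carbon count and a bond list. The graph
#' must be a tree (connected, acyclic) with every site of degree at most 4.
#'
#' @param n_atoms Number of carbon (united-atom) sites, >= 1.
#' @param bonds Two-column integer matrix of 1-based site index pairs
#'   (0 rows for methane). A plain vector of length 2 is accepted for a
#'   single bond.
#' @param label Optional display name.
#' @return An object of class \code{molecule} with elements \code{n_atoms},
#'   \code{bonds} and \code{label}.
#' @examples
#' ethane <- molecule(2, c(1, 2))
#' atom_types(ethane)
#' @export
molecule <- function(n_atoms, bonds = matrix(integer(), ncol = 2), label = NULL) {
  n_atoms <- as.integer(n_atoms)
  if (length(n_atoms) != 1L || is.na(n_atoms) || n_atoms < 1L)
    stop("`n_atoms` must be a single integer >= 1")
  if (is.null(dim(bonds))) {
    if (length(bonds) == 0L) bonds <- matrix(integer(), ncol = 2)
    else bonds <- matrix(as.integer(bonds), ncol = 2, byrow = TRUE)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) != n_atoms - 1L)
    stop("a tree on ", n_atoms, " sites needs ", n_atoms - 1L,
         " bonds, got ", nrow(bonds))
  if (nrow(bonds) && (anyNA(bonds) || any(bonds < 1L) || any(bonds > n_atoms)))
    stop("bond indices must lie in 1..n_atoms")
  if (nrow(bonds) && any(bonds[, 1] == bonds[, 2]))
    stop("self-bonds are not allowed")
  m <- structure(list(n_atoms = n_atoms, bonds = bonds, label = label),
                 class = "molecule")
  deg <- site_degrees(m)
  if (any(deg > 4L))
    stop("site degree exceeds 4 (carbon valence violated)")
  if (!.is_connected(.adjacency(m)))
    stop("bond graph is not connected")
  m
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", if (!is.null(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat("  C", x$n_atoms, "H", 2L * x$n_atoms + 2L, "  ", write_smiles(x), "\n",
      sep = "")
  invisible(x)
}

#' Test for the molecule class
#' @param x Object to test.
#' @export
is_molecule <- function(x) inherits(x, "molecule")

#' Number of carbon atoms in a molecule
#' @param m A \code{molecule}.
#' @return Integer carbon count.
#' @export
carbon_count <- function(m) {
  stopifnot(is_molecule(m))
  m$n_atoms
}

#' Per-site degrees
#' @param m A \code{molecule}.
#' @return Integer vector of bond counts per site.
#' @export
site_degrees <- function(m) {
  deg <- integer(m$n_atoms)
  if (nrow(m$bonds)) {
    tb <- tabulate(c(m$bonds[, 1], m$bonds[, 2]), nbins = m$n_atoms)
    deg <- as.integer(tb)
  }
  deg
}

#' United-atom type of every site
#'
#' Types are a pure function of degree: 0 -> CH4, 1 -> CH3, 2 -> CH2,
#' 3 -> CH, 4 -> C.
#'
#' @param m A \code{molecule}.
#' @return Character vector, one of CH4/CH3/CH2/CH/C per site.
#' @export
atom_types <- function(m) {
  deg <- site_degrees(m)
  c("CH4", "CH3", "CH2", "CH", "C")[deg + 1L]
}

# adjacency list (list of integer neighbor vectors)
.adjacency <- function(m) {
  adj <- rep(list(integer()), m$n_atoms)
  b <- m$bonds
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      adj[[b[i, 1]]] <- c(adj[[b[i, 1]]], b[i, 2])
      adj[[b[i, 2]]] <- c(adj[[b[i, 2]]], b[i, 1])
    }
  }
  adj
}

.is_connected <- function(adj) {
  n <- length(adj)
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# BFS distances from a source over an adjacency list
.bfs_dist <- function(adj, src) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  list(dist = dist, parent = parent)
}

# centroid(s) of the tree: 1 or 2 site indices
.centroids <- function(adj) {
  n <- length(adj)
  if (n == 1L) return(1L)
  # iterative post-order over BFS ordering rooted at 1
  bfs <- .bfs_dist(adj, 1L)
  ord <- order(bfs$dist)          # root first
  size <- rep(1L, n)
  for (v in rev(ord)) {
    p <- bfs$parent[v]
    if (!is.na(p)) size[p] <- size[p] + size[v]
  }
  maxcomp <- integer(n)
  for (v in seq_len(n)) {
    comps <- integer()
    for (w in adj[[v]]) {
      comps <- c(comps, if (!is.na(bfs$parent[w]) && bfs$parent[w] == v)
        size[w] else n - size[v])
    }
    maxcomp[v] <- max(comps)
  }
  which(maxcomp == min(maxcomp))
}

# canonical signature of the subtree rooted at v, entered from `parent`
# (0 = none).  Children signatures are sorted bytewise so the string is a
# label-independent invariant; it is also a valid SMILES for the subtree.
.rooted_sig <- function(adj, v, parent) {
  kids <- adj[[v]][adj[[v]] != parent]
  if (!length(kids)) return("C")
  ks <- vapply(kids, function(k) .rooted_sig(adj, k, v), character(1))
  paste0("C", paste0("(", sort(ks, method = "radix"), ")", collapse = ""))
}

# label-independent canonical signature of the whole molecule
.canonical_sig <- function(m, adj = .adjacency(m)) {
  cen <- .centroids(adj)
  sigs <- vapply(cen, function(v) .rooted_sig(adj, v, 0L), character(1))
  sort(sigs, method = "radix")[1L]
}

#' Parse an acyclic carbon-only SMILES string
#'
#' Accepts the daylight subset needed for alkanes: \code{C} atoms and
#' branch parentheses only (implicit hydrogens). Ring-closure digits,
#' heteroatoms, aromatic atoms, charges and explicit hydrogens are rejected.
#'
#' @param s SMILES text; internal whitespace is ignored.
#' @param label Optional display name attached to the result.
#' @return A \code{molecule}.
#' @examples
#' parse_smiles("CC(C)(C)C")  # neopentane
#' @export
parse_smiles <- function(s, label = NULL) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("`s` must be a single character string")
  chars <- strsplit(gsub("[[:space:]]", "", s), "")[[1]]
  if (!length(chars)) stop("empty SMILES string")
  bad <- setdiff(unique(chars), c("C", "(", ")"))
  if (length(bad)) {
    if (any(grepl("[0-9%]", bad)))
      stop("ring-closure digits are not supported (acyclic alkanes only)")
    stop("unsupported SMILES token(s): ", paste(bad, collapse = " "),
         " (carbon-only alkanes)")
  }
  n <- 0L
  prev <- NA_integer_
  stack <- integer()
  bonds <- matrix(integer(), ncol = 2)
  blist <- list()
  for (ch in chars) {
    if (ch == "C") {
      n <- n + 1L
      if (!is.na(prev)) blist[[length(blist) + 1L]] <- c(prev, n)
      prev <- n
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch '(' before any atom")
      stack <- c(stack, prev)
    } else { # ")"
      if (!length(stack)) stop("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES")
  if (length(blist)) bonds <- do.call(rbind, blist)
  molecule(n, bonds, label = label)
}

#' Write a canonical SMILES string
#'
#' The traversal is deterministic: the tree is rooted at its centroid (for a
#' bicentroid, the root with the bytewise-smaller subtree signature), and
#' children are emitted in sorted subtree-signature order. Two molecules give
#' the same string iff they are graph-isomorphic.
#'
#' @param m A \code{molecule}.
#' @return A single SMILES string.
#' @export
write_smiles <- function(m) {
  stopifnot(is_molecule(m))
  adj <- .adjacency(m)
  cen <- .centroids(adj)
  sigs <- vapply(cen, function(v) .rooted_sig(adj, v, 0L), character(1))
  root <- cen[order(sigs, method = "radix")[1L]]
  emit <- function(v, parent) {
    kids <- adj[[v]][adj[[v]] != parent]
    if (!length(kids)) return("C")
    ks <- vapply(kids, function(k) .rooted_sig(adj, k, v), character(1))
    kids <- kids[order(ks, method = "radix")]
    parts <- vapply(kids, function(k) emit(k, v), character(1))
    nk <- length(parts)
    paste0("C",
           if (nk > 1L) paste0("(", parts[-nk], ")", collapse = "") else "",
           parts[nk])
  }
  emit(root, 0L)
}

#' Canonical SMILES (alias for \code{write_smiles})
#' @param m A \code{molecule}.
#' @export
canonical_smiles <- function(m) write_smiles(m)

#' Graph-isomorphism test for two molecules
#' @param a,b Molecules.
#' @return TRUE iff \code{a} and \code{b} have isomorphic bond graphs.
#' @export
same_molecule <- function(a, b) {
  stopifnot(is_molecule(a), is_molecule(b))
  a$n_atoms == b$n_atoms && .canonical_sig(a) == .canonical_sig(b)
}
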