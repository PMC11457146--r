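# Shared fixtures and independent oracles.

# random free tree on n nodes with max degree <= 4 (attachment process)
random_alkane_tree <- function(n) {
  if (n == 1L) return(molecule(1))
  bonds <- matrix(integer(), ncol = 2)
  deg <- integer(n)
  for (k in 2:n) {
    open <- which(deg[seq_len(k - 1L)] < 4L)
    site <- if (length(open) == 1L) open else sample(open, 1L)
    bonds <- rbind(bonds, c(site, k))
    deg[site] <- deg[site] + 1L
    deg[k] <- 1L
  }
  molecule(n, bonds)
}

# permute atom labels of a molecule (graph-isomorphic relabeling)
relabel_molecule <- function(m, perm = sample(m$n_atoms)) {
  b <- m$bonds
  if (nrow(b)) b <- cbind(perm[b[, 1]], perm[b[, 2]])
  molecule(m$n_atoms, b)
}

# Pruefer-sequence brute force: number of unlabeled trees on n nodes with
# max degree <= 4, bucketing labeled trees by igraph canonical permutation.
# Independent of the package's enumeration path.
brute_force_isomer_count <- function(n) {
  if (n <= 2L) return(1L)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  canon <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    if (max(tabulate(pr, nbins = n)) > 3L) next  # degree = count + 1 > 4
    # decode Pruefer sequence
    degree <- tabulate(pr, nbins = n) + 1L
    edges <- matrix(0L, nrow = n - 1L, ncol = 2)
    ptr <- 1L
    avail <- degree
    for (i in seq_len(n - 2L)) {
      leaf <- which(avail == 1L)[1L]
      edges[i, ] <- c(leaf, pr[i])
      avail[leaf] <- 0L
      avail[pr[i]] <- avail[pr[i]] - 1L
    }
    edges[n - 1L, ] <- which(avail == 1L)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    cp <- igraph::canonical_permutation(g)$labeling
    gc <- igraph::permute(g, cp)
    el <- igraph::as_edgelist(gc)
    el <- t(apply(el, 1, sort))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    key <- paste(t(el), collapse = ",")
    assign(key, TRUE, envir = canon)
  }
  length(ls(canon))
}

# brute-force simple-path counter of a given edge length (for torsions)
count_simple_paths <- function(m, nedges) {
  adj <- lapply(seq_len(m$n_atoms), function(v) integer())
  for (r in seq_len(nrow(m$bonds))) {
    a <- m$bonds[r, 1]; b <- m$bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  total <- 0L
  walk <- function(path) {
    if (length(path) == nedges + 1L) {
      total <<- total + 1L
      return(invisible())
    }
    for (w in adj[[path[length(path)]]])
      if (!w %in% path) walk(c(path, w))
  }
  for (v in seq_len(m$n_atoms)) walk(v)
  total %/% 2L  # each path counted from both ends
}

# fixture pairs (shorthand name, SMILES) used across molecule tests
name_smiles_fixture <- function() {
  data.frame(
    name = c("n-C10", "2-m-C3", "2,2-m-C3", "2,2,5-m-C7", "4-e-C8",
             "3-e-2,2,4-m-C5", "4-ip-C7", "4-p-C7", "3,3-e-C6",
             "2,2,3,4,4-m-C5"),
    smiles = c("CCCCCCCCCC", "CC(C)C", "CC(C)(C)C", "CC(C)(C)CCC(C)CC",
               "CCCC(CC)CCCC", "CCC(C(C)C)C(C)(C)C", "CCCC(C(C)C)CCC",
               "CCCC(CCC)CCC", "CCC(CC)(CC)CCC", "CC(C)(C)C(C)C(C)(C)C"),
    stringsAsFactors = FALSE)
}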