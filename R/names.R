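# Compact shorthand alkane names: "n-C10", "2,2,5-m-C7", "3-e-2,2,4-m-C5".
#
# Grammar: dash-separated (locant-list, branch-code) pairs followed by the
# parent "C<n>"; "n-C<n>" (or bare "C<n>") is the linear alkane.  Branch
# codes cover all alkyl substituents up to four carbons plus the common
# pentyl shapes, so branch length never exceeds 5 carbons.

# branch code -> branch SMILES written from the attachment atom
.BRANCH_SMILES <- c(
  m     = "C",          # methyl
  e     = "CC",         # ethyl
  p     = "CCC",        # n-propyl
  ip    = "C(C)C",      # isopropyl
  b     = "CCCC",       # n-butyl
  ib    = "CC(C)C",     # isobutyl
  sb    = "C(C)CC",     # sec-butyl
  tb    = "C(C)(C)C",   # tert-butyl
  pe    = "CCCCC",      # n-pentyl
  ipe   = "CCC(C)C",    # isopentyl (3-methylbutyl)
  spe   = "C(C)CCC",    # sec-pentyl (1-methylbutyl)
  neope = "CC(C)(C)C",  # neopentyl (2,2-dimethylpropyl)
  tpe   = "C(C)(C)CC"   # tert-pentyl (1,1-dimethylpropyl)
)

# lazily built map: rooted-subtree signature -> branch code
.branch_sig_codes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sigs <- vapply(.BRANCH_SMILES, function(s) {
        bm <- parse_smiles(s)
        .rooted_sig(.adjacency(bm), 1L, 0L)
      }, character(1))
      cache <<- stats::setNames(names(sigs), sigs)
    }
    cache
  }
})

#' Build a molecule from a shorthand alkane name
#'
#' Understands the compact style used throughout hydroisomerization studies:
#' a parent chain \code{C<n>} prefixed by dash-separated
#' (locants, branch-code) pairs, e.g. \code{"2,2,5-m-C7"} (2,2,5-trimethyl-
#' heptane) or \code{"3-e-2,2,4-m-C5"} (3-ethyl-2,2,4-trimethylpentane).
#' \code{"n-C10"} and bare \code{"C10"} denote the linear alkane. Supported
#' branch codes: m, e, p, ip, b, ib, sb, tb, pe, ipe, spe, neope, tpe
#' (all alkyl branches of at most 5 carbons).
#'
#' @param name Shorthand name (a single string).
#' @return A \code{molecule} labelled with \code{name}.
#' @examples
#' name_to_molecule("2,2,5-m-C7")
#' name_to_molecule("4-ip-C7")
#' @export
name_to_molecule <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("`name` must be a single string")
  raw <- trimws(name)
  toks <- strsplit(raw, "-", fixed = TRUE)[[1]]
  if (!length(toks)) stop("empty name")
  pm <- regmatches(toks[length(toks)],
                   regexec("^C([0-9]+)$", toks[length(toks)]))[[1]]
  if (length(pm) != 2L)
    stop("cannot parse parent chain in '", raw, "' (expected trailing C<n>)")
  parent_n <- as.integer(pm[2])
  if (parent_n < 1L) stop("parent chain length must be >= 1")
  body <- toks[-length(toks)]
  if (length(body) == 1L && body == "n") body <- character()
  if (length(body) %% 2L != 0L)
    stop("cannot parse '", raw,
         "': expected (locants, branch-code) pairs before C<n>")
  # parent chain
  bonds <- if (parent_n > 1L)
    cbind(seq_len(parent_n - 1L), seq_len(parent_n - 1L) + 1L)
  else matrix(integer(), ncol = 2)
  n <- parent_n
  if (length(body)) {
    loc_tokens <- body[seq(1L, length(body), by = 2L)]
    codes <- body[seq(2L, length(body), by = 2L)]
    for (i in seq_along(codes)) {
      code <- codes[i]
      if (!code %in% names(.BRANCH_SMILES))
        stop("unknown branch code '", code, "' in '", raw, "'")
      if (!grepl("^[0-9]+(,[0-9]+)*$", loc_tokens[i]))
        stop("invalid locant list '", loc_tokens[i], "' in '", raw, "'")
      locs <- as.integer(strsplit(loc_tokens[i], ",", fixed = TRUE)[[1]])
      if (any(locs < 1L | locs > parent_n))
        stop("locant out of range 1..", parent_n, " in '", raw, "'")
      bm <- parse_smiles(.BRANCH_SMILES[[code]])
      for (loc in locs) {
        off <- n
        if (nrow(bm$bonds)) bonds <- rbind(bonds, bm$bonds + off)
        bonds <- rbind(bonds, c(loc, off + 1L))
        n <- n + bm$n_atoms
      }
    }
  }
  molecule(n, bonds, label = raw)
}

# Decompose a molecule into its canonical main chain + branches.
# Returns NULL for methane-like trivial cases handled upstream; otherwise a
# list(chain, locants, sizes, sigs) where `sigs` are rooted branch signatures.
# Candidate chains are all longest paths; the winner maximizes the branch
# count, then minimizes the sorted locant vector, then the concatenated
# (locant, signature) record bytewise -- all label-independent criteria.
.decompose <- function(m) {
  adj <- .adjacency(m)
  n <- m$n_atoms
  dists <- lapply(seq_len(n), function(v) .bfs_dist(adj, v))
  dmat <- do.call(rbind, lapply(dists, `[[`, "dist"))
  diam <- max(dmat)
  ends <- which(dmat == diam, arr.ind = TRUE)
  ends <- ends[ends[, 1] < ends[, 2], , drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(ends))) {
    u <- ends[r, 1]; v <- ends[r, 2]
    # unique u..v path via BFS parents from u
    par <- dists[[u]]$parent
    path <- v
    while (path[1L] != u) path <- c(par[path[1L]], path)
    for (chain in list(path, rev(path))) {
      inchain <- logical(n); inchain[chain] <- TRUE
      locs <- integer(); sigs <- character(); sizes <- integer()
      ok <- TRUE
      for (i in seq_along(chain)) {
        for (w in adj[[chain[i]]]) {
          if (!inchain[w]) {
            sig <- .rooted_sig(adj, w, chain[i])
            locs <- c(locs, i)
            sigs <- c(sigs, sig)
            sizes <- c(sizes, nchar(gsub("[()]", "", sig)))
          }
        }
      }
      cand <- list(chain = chain, locants = locs, sizes = sizes, sigs = sigs)
      if (is.null(best) || .decomp_better(cand, best)) best <- cand
    }
  }
  best
}

.decomp_key <- function(c1) {
  o <- order(c1$locants, c1$sigs, method = "radix")
  paste(sprintf("%03d", c1$locants[o]), c1$sigs[o], collapse = "|")
}

.decomp_better <- function(a, b) {
  if (length(a$locants) != length(b$locants))
    return(length(a$locants) > length(b$locants))
  ka <- paste(sprintf("%03d", sort(a$locants)), collapse = ",")
  kb <- paste(sprintf("%03d", sort(b$locants)), collapse = ",")
  if (ka != kb) return(ka < kb)
  .decomp_key(a) < .decomp_key(b)
}

#' Shorthand name of a molecule
#'
#' Inverse of \code{\link{name_to_molecule}}: selects the canonical main
#' chain (longest path; ties resolved toward more branches, then lower
#' locants) and encodes each branch with its alkyl code. Linear alkanes are
#' named \code{"n-C<n>"}. Returns \code{NA} with a warning when a branch has
#' no code in the supported set (possible only for chains beyond C11 with
#' exotic pentyl shapes).
#'
#' @param m A \code{molecule}.
#' @return A single string, or \code{NA_character_}.
#' @examples
#' molecule_name(parse_smiles("CC(C)CCCC(C)C"))
#' @export
molecule_name <- function(m) {
  stopifnot(is_molecule(m))
  deg <- site_degrees(m)
  if (all(deg <= 2L)) return(paste0("n-C", m$n_atoms))
  d <- .decompose(m)
  codes <- .branch_sig_codes()[d$sigs]
  if (anyNA(codes)) {
    warning("molecule has a branch with no shorthand code; returning NA")
    return(NA_character_)
  }
  ucodes <- sort(unique(unname(codes)), method = "radix")
  parts <- vapply(ucodes, function(cd) {
    paste0(paste(sort(d$locants[codes == cd]), collapse = ","), "-", cd)
  }, character(1))
  paste0(paste(parts, collapse = "-"), "-C", length(d$chain))
}
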