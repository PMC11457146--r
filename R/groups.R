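# Second-order (and first-order) group descriptors.
#
# A second-order group is a central united atom together with the multiset of
# its neighbors' united-atom types, written canonically as
# "center(n1)(n2)..." with neighbors sorted CH3 < CH2 < CH < C.  Methane is
# tracked as the special descriptor "CH4" on top of the 69-group universe.

# number of neighbors a center must carry
.UA_VALENCE <- c(CH3 = 1L, CH2 = 2L, CH = 3L, C = 4L)

# rank in the fixed neighbor sort order
.ua_rank <- function(x) match(x, UA_TYPES)

#' Canonical key of a second-order group
#'
#' @param center Central united-atom type, one of CH3/CH2/CH/C.
#' @param neighbors Character vector of neighbor types (length must equal the
#'   center's valence: 1, 2, 3 or 4).
#' @return Canonical key string, e.g. \code{"CH2(CH3)(CH)"}.
#' @examples
#' group_key("CH2", c("CH", "CH3"))
#' @export
group_key <- function(center, neighbors) {
  if (!center %in% UA_TYPES) stop("invalid center type: ", center)
  if (length(neighbors) != .UA_VALENCE[[center]])
    stop(center, " requires exactly ", .UA_VALENCE[[center]], " neighbor(s)")
  if (!all(neighbors %in% UA_TYPES))
    stop("invalid neighbor type(s): ",
         paste(setdiff(neighbors, UA_TYPES), collapse = " "))
  nb <- neighbors[order(.ua_rank(neighbors))]
  paste0(center, paste0("(", nb, ")", collapse = ""))
}

# parse a canonical key back into center + neighbors
.parse_group_key <- function(key) {
  if (key == "CH4") return(list(center = "CH4", neighbors = character()))
  mres <- regmatches(key, regexec("^(CH3|CH2|CH|C)((?:\\((?:CH3|CH2|CH|C)\\))+)$",
                                  key))[[1]]
  if (length(mres) != 3L) stop("malformed group key: ", key)
  nbs <- regmatches(mres[3], gregexpr("\\((CH3|CH2|CH|C)\\)", mres[3]))[[1]]
  nbs <- gsub("[()]", "", nbs)
  if (length(nbs) != .UA_VALENCE[[mres[2]]])
    stop("group key has wrong neighbor count: ", key)
  list(center = mres[2], neighbors = nbs)
}

# all size-k multisets (non-decreasing index sequences) over UA_TYPES
.multisets <- function(k) {
  idx <- list()
  rec <- function(prefix, start) {
    if (length(prefix) == k) {
      idx[[length(idx) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in start:4) rec(c(prefix, i), i)
  }
  rec(integer(), 1L)
  lapply(idx, function(i) UA_TYPES[i])
}

#' Enumerate the full second-order group universe
#'
#' Every valence-consistent (center, neighbor-multiset) combination over the
#' united-atom types CH3/CH2/CH/C: 4 + 10 + 20 + 35 = 69 groups. The
#' methane descriptor \code{"CH4"} is not part of this universe.
#'
#' @return A data frame with columns \code{center}, \code{neighbors}
#'   (comma-joined, canonical order) and \code{key}, sorted by center type
#'   then key.
#' @examples
#' nrow(enumerate_group_universe())  # 69
#' @export
enumerate_group_universe <- function() {
  rows <- list()
  for (center in UA_TYPES) {
    for (nb in .multisets(.UA_VALENCE[[center]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        center = center,
        neighbors = paste(nb, collapse = ","),
        key = group_key(center, nb),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # deterministic order: center type, then bytewise key
  out <- do.call(rbind, lapply(UA_TYPES, function(ct) {
    sub <- out[out$center == ct, ]
    sub[order(sub$key, method = "radix"), ]
  }))
  rownames(out) <- NULL
  out
}

#' Count first- or second-order group occurrences in a molecule
#'
#' First order counts the united atoms CH4/CH3/CH2/CH/C themselves; second
#' order counts one group per site, keyed by the site's center type and
#' neighbor multiset. Methane contributes the special descriptor
#' \code{"CH4"} in both orders.
#'
#' @param m A \code{molecule}.
#' @param order \code{"second"} (default) or \code{"first"}.
#' @return Named integer vector of occurrence counts; the counts always sum
#'   to the number of carbon sites.
#' @examples
#' count_groups(parse_smiles("CCCC"))              # n-butane, second order
#' count_groups(parse_smiles("CCCC"), "first")
#' @export
count_groups <- function(m, order = c("second", "first")) {
  stopifnot(is_molecule(m))
  order <- match.arg(order)
  types <- atom_types(m)
  if (order == "first") {
    tab <- table(factor(types, levels = c("CH4", UA_TYPES)))
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    return(cnt[cnt > 0L])
  }
  adj <- .adjacency(m)
  keys <- vapply(seq_len(m$n_atoms), function(v) {
    if (types[v] == "CH4") "CH4"
    else group_key(types[v], types[adj[[v]]])
  }, character(1))
  tab <- table(keys)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[order(names(cnt), method = "radix")]
}

#' Map an out-of-training group onto a similar in-training group
#'
#' Groups absent from the training set are approximated by the in-training
#' group reachable by the fewest single-neighbor demotions along
#' C -> CH -> CH2 -> CH3. Ties are broken by demoting the lowest-valence
#' neighbor first (the mildest structural change: it terminates a chain
#' rather than un-branching a substituted neighbor), then by bytewise key.
#' When no demotion sequence lands in the training universe the center's
#' first-order type is returned as a fallback.
#'
#' @param key Canonical key of the out-of-training group.
#' @param training_keys Character vector of in-training canonical keys.
#' @return A single in-training key (or the bare center type as fallback).
#' @examples
#' \dontrun{
#' default_approximation("C(CH2)(CH2)(CH2)(C)", training_keys)
#' }
#' @export
default_approximation <- function(key, training_keys) {
  if (!length(training_keys)) stop("`training_keys` must not be empty")
  if (key %in% training_keys) return(key)
  g <- .parse_group_key(key)
  if (g$center == "CH4") stop("CH4 has no approximation")
  demote <- c(C = "CH", CH = "CH2", CH2 = "CH3")
  state_key <- function(nb) group_key(g$center, nb)
  frontier <- list(g$neighbors)
  seen <- new.env(parent = emptyenv())
  assign(key, TRUE, envir = seen)
  while (length(frontier)) {
    nxt <- list()
    hits <- character()
    for (nb in frontier) {
      # candidate single demotions, lowest-valence neighbor first
      ds <- which(nb %in% names(demote))
      if (!length(ds)) next
      ds <- ds[order(.ua_rank(nb[ds]))]
      for (i in ds) {
        nb2 <- nb
        nb2[i] <- demote[[nb2[i]]]
        k2 <- state_key(nb2)
        if (!exists(k2, envir = seen, inherits = FALSE)) {
          assign(k2, TRUE, envir = seen)
          if (k2 %in% training_keys) hits <- c(hits, k2)
          nxt[[length(nxt) + 1L]] <- nb2
        }
      }
    }
    if (length(hits)) return(hits[1L])
    frontier <- nxt
  }
  g$center
}

#' Build a total approximation map over the group universe
#'
#' @param training_keys In-training canonical keys (e.g. the union of
#'   second-order keys over all C1-C10 isomers).
#' @param universe Optional data frame from
#'   \code{\link{enumerate_group_universe}}.
#' @return A data frame with columns \code{out_key}, \code{in_key} covering
#'   every universe group absent from \code{training_keys}.
#' @export
build_approximation_map <- function(training_keys,
                                    universe = enumerate_group_universe()) {
  missing_keys <- setdiff(universe$key, training_keys)
  data.frame(out_key = missing_keys,
             in_key = vapply(missing_keys, default_approximation,
                             character(1), training_keys = training_keys),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write an approximation map CSV
#'
#' Two-column CSV (\code{out_key,in_key}); lets users supply the published
#' approximation list instead of the built-in demotion rule.
#'
#' @param path File path.
#' @rdname approximation_map_io
#' @export
read_approximation_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("out_key", "in_key") %in% names(df)))
    stop("approximation map CSV needs columns out_key,in_key")
  df[c("out_key", "in_key")]
}

#' @param map Data frame with columns \code{out_key}, \code{in_key}.
#' @rdname approximation_map_io
#' @export
write_approximation_map <- function(map, path) {
  utils::write.csv(map[c("out_key", "in_key")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Descriptor matrix for a set of molecules
#'
#' One row per molecule, one integer column per group key; column order is
#' bytewise-sorted canonical keys. When an approximation map is supplied,
#' counts of out-of-training groups are folded onto their in-training images
#' before the column union is taken.
#'
#' @param molecules List of \code{molecule} objects.
#' @param order \code{"second"} (default) or \code{"first"}.
#' @param approximation Optional data frame (\code{out_key,in_key}) or named
#'   character vector mapping keys.
#' @return Integer matrix with key column names; row names are molecule
#'   labels (canonical SMILES when unlabelled).
#' @export
build_descriptor_matrix <- function(molecules, order = c("second", "first"),
                                    approximation = NULL) {
  order <- match.arg(order)
  if (!length(molecules)) stop("`molecules` must be a nonempty list")
  if (is_molecule(molecules)) molecules <- list(molecules)
  amap <- NULL
  if (!is.null(approximation)) {
    amap <- if (is.data.frame(approximation))
      stats::setNames(approximation$in_key, approximation$out_key)
    else approximation
  }
  counts <- lapply(molecules, function(m) {
    x <- count_groups(m, order)
    if (!is.null(amap)) {
      hit <- names(x) %in% names(amap)
      if (any(hit)) {
        names(x)[hit] <- amap[names(x)[hit]]
        x <- tapply(x, names(x), sum)
        x <- stats::setNames(as.integer(x), names(x))
      }
    }
    x
  })
  keys <- sort(unique(unlist(lapply(counts, names))), method = "radix")
  mat <- matrix(0L, nrow = length(molecules), ncol = length(keys),
                dimnames = list(NULL, keys))
  for (i in seq_along(counts)) mat[i, names(counts[[i]])] <- counts[[i]]
  rownames(mat) <- vapply(molecules, function(m)
    if (!is.null(m$label)) m$label else write_smiles(m), character(1))
  mat
}
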