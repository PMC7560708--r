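#' Admissible single-atom swap types
#'
#' The four unordered element pairs considered as single-atom
#' modifications, rendered with their fixed labels: `"N-C"`, `"O-C"`,
#' `"N-O"`, `"S-O"`.
#'
#' @export
SAM_SWAPS <- c("N-C", "O-C", "N-O", "S-O")

.SWAP_PAIRS <- list(
  "N-C" = c("N", "C"), "O-C" = c("O", "C"),
  "N-O" = c("N", "O"), "S-O" = c("S", "O")
)

# Validate a swap-label vector, returning it normalized.
check_swaps <- function(swaps) {
  if (!length(swaps)) stop("at least one swap type is required")
  bad <- setdiff(swaps, SAM_SWAPS)
  if (length(bad)) {
    stop(sprintf("unknown swap type(s): %s (admissible: %s)",
                 paste(bad, collapse = ", "), paste(SAM_SWAPS, collapse = ", ")))
  }
  unique(swaps)
}

# Directed swaps for a set of labels: data.frame(from, to, label).
directed_swaps <- function(swaps) {
  swaps <- check_swaps(swaps)
  do.call(rbind, lapply(swaps, function(lb) {
    p <- .SWAP_PAIRS[[lb]]
    data.frame(from = c(p[1L], p[2L]), to = c(p[2L], p[1L]),
               label = lb, stringsAsFactors = FALSE)
  }))
}

# Label for an unordered element pair, or NA if inadmissible.
swap_label <- function(x, y) {
  for (lb in SAM_SWAPS) {
    p <- .SWAP_PAIRS[[lb]]
    if ((x == p[1L] && y == p[2L]) || (x == p[2L] && y == p[1L])) return(lb)
  }
  NA_character_
}

#' Mutate a single heavy atom
#'
#' Replaces the element of one heavy atom, re-derives implicit hydrogens
#' and aromaticity, and returns the sanitized mutant, or `NULL` when no
#' valid mutant exists (valence violation at the site, or a charged /
#' otherwise unmutable position). The caller treats `NULL` as "no such
#' analog exists". Mutation operates on the kekulized graph; aromaticity is
#' re-perceived on the mutant, and stereo descriptors are retained where
#' still valid (OpenBabel drops descriptors invalidated by the new
#' symmetry).
#'
#' @param mol a `sam_molecule`.
#' @param atom_index canonical atom rank (1-based) of the atom to mutate.
#' @param new_element target element symbol; together with the current
#'   element it must form one of the admissible swaps ([SAM_SWAPS]).
#' @return a `sam_molecule`, or `NULL`.
#' @export
#' @examples
#' \dontrun{
#' pyr <- standardize("c1ccncc1", "pyridine")
#' i <- which(pyr$graph$atoms$elem == "N")
#' mutate_atom(pyr, i, "C")  # benzene
#' }
mutate_atom <- function(mol, atom_index, new_element) {
  stopifnot(inherits(mol, "sam_molecule"))
  g <- mol$graph
  if (atom_index < 1L || atom_index > nrow(g$atoms)) {
    stop("atom_index out of range")
  }
  from <- g$atoms$elem[atom_index]
  if (from == new_element || is.na(swap_label(from, new_element))) {
    stop(sprintf("%s -> %s is not an admissible single-atom swap", from, new_element))
  }
  if (g$atoms$charge[atom_index] != 0L) return(NULL)
  if (!site_accepts(g, atom_index, new_element)) return(NULL)
  g$atoms$elem[atom_index] <- new_element
  sdf <- write_molblock(g, title = "1")
  key <- ob_can_from_sdf(sdf, 1L)
  if (is.na(key)) return(NULL)
  molecule_from_key(key, id = sprintf("%s[%d:%s>%s]", mol$id, atom_index,
                                      from, new_element))
}

#' Enumerate canonical keys of all valid single-atom mutants
#'
#' Applies every admissible directed swap at every heavy atom, keeps the
#' mutants that sanitize, and deduplicates by (canonical key, directed
#' swap): symmetry-equivalent atoms collapse to one entry, annotated with
#' the lowest canonical site rank.
#'
#' @param mol a `sam_molecule`.
#' @param swaps character vector of swap labels (subset of [SAM_SWAPS]).
#' @return data.frame with columns `parent_id`, `site` (canonical rank in
#'   the parent), `from`, `to`, `label`, `key`.
#' @export
enumerate_mutant_keys <- function(mol, swaps = SAM_SWAPS) {
  tab <- mutant_key_table(list(mol), swaps)
  as.data.frame(tab)
}

# Batched mutant enumeration over a list of molecules: one obabel call.
# Returns data.table(parent_id, site, from, to, label, key), deduplicated
# by (parent_id, from, to, key) keeping the lowest site.
mutant_key_table <- function(mols, swaps = SAM_SWAPS) {
  ds <- directed_swaps(swaps)
  meta <- list()
  blocks <- list()
  k <- 0L
  for (mol in mols) {
    g <- mol$graph
    sums <- bond_order_sums(g)
    for (i in seq_len(nrow(g$atoms))) {
      if (g$atoms$charge[i] != 0L) next
      hits <- which(ds$from == g$atoms$elem[i])
      for (h in hits) {
        if (!site_accepts(g, i, ds$to[h], sums)) next
        g2 <- g
        g2$atoms$elem[i] <- ds$to[h]
        k <- k + 1L
        meta[[k]] <- data.frame(parent_id = mol$id, site = i,
                                from = ds$from[h], to = ds$to[h],
                                label = ds$label[h], stringsAsFactors = FALSE)
        blocks[[k]] <- write_molblock(g2, title = as.character(k))
      }
    }
  }
  empty <- data.table::data.table(parent_id = character(0), site = integer(0),
                                  from = character(0), to = character(0),
                                  label = character(0))
  data.table::set(empty, j = "key", value = character(0))
  if (!k) return(empty)
  meta <- data.table::rbindlist(meta)
  data.table::set(meta, j = "key", value = ob_can_from_sdf(unlist(blocks), k))
  meta <- meta[!is.na(key)]
  if (!nrow(meta)) return(empty)
  data.table::setorder(meta, parent_id, from, to, key, site)
  unique(meta, by = c("parent_id", "from", "to", "key"))
}

#' Exchange the elements of two heavy atoms
#'
#' The positional-exchange primitive behind atom-walk detection: element X
#' at position `i` and Y at position `j` trade places. Returns the
#' canonical key of the exchanged structure, or `NA` when the exchange is
#' not admissible (elements equal, pair not an admissible swap, a charged
#' site, or a valence violation).
#'
#' @param mol a `sam_molecule`.
#' @param i,j atom indices (canonical ranks).
#' @return canonical SMILES of the exchanged structure, or `NA_character_`.
#' @export
exchange_atoms <- function(mol, i, j) {
  g <- mol$graph
  n <- nrow(g$atoms)
  stopifnot(i >= 1L, i <= n, j >= 1L, j <= n, i != j)
  x <- g$atoms$elem[i]; y <- g$atoms$elem[j]
  if (x == y || is.na(swap_label(x, y))) return(NA_character_)
  if (g$atoms$charge[i] != 0L || g$atoms$charge[j] != 0L) return(NA_character_)
  sums <- bond_order_sums(g)
  if (!site_accepts(g, i, y, sums) || !site_accepts(g, j, x, sums)) return(NA_character_)
  g$atoms$elem[i] <- y
  g$atoms$elem[j] <- x
  ob_can_from_sdf(write_molblock(g, title = "1"), 1L)
}

# Batched exchange enumeration (the oracle's atom-walk primitive): all
# ordered position pairs (i, j), i < j, whose elements form an admissible
# swap. Returns data.table(parent_id, i, j, label, key).
exchange_key_table <- function(mols, swaps = SAM_SWAPS) {
  swaps <- check_swaps(swaps)
  meta <- list()
  blocks <- list()
  k <- 0L
  for (mol in mols) {
    g <- mol$graph
    sums <- bond_order_sums(g)
    n <- nrow(g$atoms)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      x <- g$atoms$elem[i]
      if (g$atoms$charge[i] != 0L) next
      for (j in (i + 1L):n) {
        y <- g$atoms$elem[j]
        if (x == y || g$atoms$charge[j] != 0L) next
        lb <- swap_label(x, y)
        if (is.na(lb) || !(lb %in% swaps)) next
        if (!site_accepts(g, i, y, sums) || !site_accepts(g, j, x, sums)) next
        g2 <- g
        g2$atoms$elem[i] <- y
        g2$atoms$elem[j] <- x
        k <- k + 1L
        meta[[k]] <- data.frame(parent_id = mol$id, i = i, j = j, label = lb,
                                stringsAsFactors = FALSE)
        blocks[[k]] <- write_molblock(g2, title = as.character(k))
      }
    }
  }
  empty <- data.table::data.table(parent_id = character(0), i = integer(0),
                                  j = integer(0), label = character(0))
  data.table::set(empty, j = "key", value = character(0))
  if (!k) return(empty)
  meta <- data.table::rbindlist(meta)
  data.table::set(meta, j = "key", value = ob_can_from_sdf(unlist(blocks), k))
  meta[!is.na(key)]
}
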