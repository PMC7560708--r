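#' Standardize a batch of compound structures
#'
#' Runs the curation-grade standardization pipeline over a vector of SMILES
#' strings: parse (OpenBabel), normalize charges to a neutral form where one
#' exists (quaternary ammonium and charge-separated groups such as nitro are
#' kept), clear isotope labels, keep the largest organic fragment
#' (salt/solvent stripping), enforce standard valence rules, and compute the
#' canonical SMILES key. The molecule graph is stored in canonical-SMILES
#' atom order, so atom indices are canonical atom ranks.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids compound identifiers (defaults to names of `smiles` or
#'   sequential ids).
#' @param min_heavy minimum heavy-atom count of the kept fragment; smaller
#'   structures are rejected. The chemistry layer default is 1; record
#'   curation applies its own floor (see [filter_records()]).
#' @param neutralize logical; attempt charge neutralization (default TRUE).
#' @return a list with elements
#'   \describe{
#'     \item{molecules}{named list of `sam_molecule` objects (per id).}
#'     \item{failures}{data.frame (id, smiles, reason) of rejected inputs;
#'       reasons are `unparsable`, `no_organic_fragment`, `too_small`,
#'       `valence`.}
#'   }
#' @export
#' @examples
#' \dontrun{
#' standardize_compounds(c(a = "c1ccncc1", b = "CCO.Cl"))
#' }
standardize_compounds <- function(smiles, ids = NULL, min_heavy = 1L,
                                  neutralize = TRUE) {
  n <- length(smiles)
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  fail <- function(i, reason) data.frame(id = ids[i], smiles = smiles[i],
                                         reason = reason, stringsAsFactors = FALSE)
  failures <- list()
  extra <- if (neutralize) "--neutralize" else character(0)
  ok_in <- !is.na(smiles) & nzchar(trimws(smiles)) &
    !grepl("[\t\n ]", trimws(smiles))
  blocks <- vector("list", n)
  blocks[ok_in] <- ob_sdf_from_smiles(trimws(smiles[ok_in]), extra = extra)

  graphs <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(blocks[[i]])) { failures[[length(failures) + 1L]] <- fail(i, "unparsable"); next }
    g <- parse_molblock(blocks[[i]])
    if (is.null(g) || !nrow(g$atoms)) { failures[[length(failures) + 1L]] <- fail(i, "unparsable"); next }
    comp <- graph_components(g)
    # largest organic fragment: most heavy atoms, then most carbons, then
    # first occurrence (deterministic)
    sizes <- tabulate(comp)
    ncarb <- vapply(seq_along(sizes), function(k) sum(g$atoms$elem[comp == k] == "C"), 0L)
    organic <- which(ncarb > 0L)
    if (!length(organic)) { failures[[length(failures) + 1L]] <- fail(i, "no_organic_fragment"); next }
    best <- organic[order(-sizes[organic], -ncarb[organic], organic)][1L]
    g <- subgraph(g, comp == best)
    if (nrow(g$atoms) < min_heavy) { failures[[length(failures) + 1L]] <- fail(i, "too_small"); next }
    if (!valence_ok(g)) { failures[[length(failures) + 1L]] <- fail(i, "valence"); next }
    graphs[[i]] <- g
  }

  live <- which(!vapply(graphs, is.null, TRUE))
  keys <- rep(NA_character_, n)
  if (length(live)) {
    sdf <- unlist(lapply(seq_along(live), function(j)
      write_molblock(graphs[[live[j]]], title = as.character(j))))
    keys[live] <- ob_can_from_sdf(sdf, length(live))
  }
  for (i in live[is.na(keys[live])]) {
    failures[[length(failures) + 1L]] <- fail(i, "unparsable")
    graphs[i] <- list(NULL)
  }
  live <- which(!is.na(keys) & !vapply(graphs, is.null, TRUE))

  # re-read the canonical SMILES so stored graphs are in canonical atom order
  cgraphs <- vector("list", n)
  if (length(live)) {
    cblocks <- ob_sdf_from_smiles(keys[live])
    for (j in seq_along(live)) {
      g <- if (is.null(cblocks[[j]])) NULL else parse_molblock(cblocks[[j]])
      cgraphs[[live[j]]] <- g
    }
  }
  mols <- list()
  for (i in live) {
    g <- cgraphs[[i]]
    if (is.null(g)) { failures[[length(failures) + 1L]] <- fail(i, "unparsable"); next }
    mols[[ids[i]]] <- new_molecule(ids[i], keys[i], g)
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(id = character(0), smiles = character(0), reason = character(0))
  list(molecules = mols, failures = failures)
}

new_molecule <- function(id, key, graph) {
  structure(
    list(id = id, canonical_key = key, graph = graph,
         formula = heavy_formula(graph), n_heavy = nrow(graph$atoms)),
    class = "sam_molecule"
  )
}

# Build a sam_molecule from an already-canonical SMILES key (used for
# mutants, whose graphs are constructed valid).
molecule_from_key <- function(key, id = key) {
  b <- ob_sdf_from_smiles(key)[[1L]]
  if (is.null(b)) return(NULL)
  g <- parse_molblock(b)
  if (is.null(g)) return(NULL)
  new_molecule(id, key, g)
}

# Batch form of molecule_from_key: one obabel call; failures dropped.
molecules_from_keys <- function(keys, ids = keys) {
  blocks <- ob_sdf_from_smiles(keys)
  out <- list()
  for (i in seq_along(keys)) {
    if (is.null(blocks[[i]])) next
    g <- parse_molblock(blocks[[i]])
    if (is.null(g)) next
    out[[ids[i]]] <- new_molecule(ids[i], keys[i], g)
  }
  out
}

#' Standardize a single structure
#'
#' Single-molecule form of [standardize_compounds()]. Rejected structures
#' raise an `InvalidStructure` error rather than being returned, so callers
#' must count them as curation exclusions.
#'
#' @inheritParams standardize_compounds
#' @param id compound identifier.
#' @return a `sam_molecule`: id, canonical_key (canonical SMILES), graph in
#'   canonical atom order, heavy-atom formula, heavy-atom count.
#' @export
standardize <- function(smiles, id = "mol", min_heavy = 1L, neutralize = TRUE) {
  res <- standardize_compounds(smiles, ids = id, min_heavy = min_heavy,
                               neutralize = neutralize)
  if (nrow(res$failures)) {
    sam_error("InvalidStructure",
              sprintf("structure '%s' rejected (%s)", smiles, res$failures$reason[1L]))
  }
  res$molecules[[1L]]
}

# Heavy-atom formula as a named integer vector, elements sorted.
heavy_formula <- function(graph) {
  t <- table(graph$atoms$elem)
  out <- as.integer(t)
  names(out) <- names(t)
  out[order(names(out))]
}

format_formula <- function(f) {
  paste0(names(f), ifelse(f > 1L, f, ""), collapse = "")
}

#' @export
print.sam_molecule <- function(x, ...) {
  cat(sprintf("<sam_molecule> %s\n  key: %s\n  formula: %s (%d heavy atoms)\n",
              x$id, x$canonical_key, format_formula(x$formula), x$n_heavy))
  invisible(x)
}

#' Stereo-insensitive canonical keys
#'
#' Strips tetrahedral (`@`) and double-bond (`/`, `\`) stereo markers from
#' canonical SMILES and re-canonicalizes, yielding keys under which
#' stereoisomers compare equal. Used for crystallographic ligand matching,
#' where chemical-component records frequently omit or re-derive stereo.
#'
#' @param keys character vector of canonical SMILES.
#' @return character vector of stereo-free canonical SMILES (NA on failure).
#' @export
stereo_free_keys <- function(keys) {
  stripped <- gsub("@{1,2}", "", keys)
  stripped <- gsub("[/\\\\]", "", stripped)
  ob_can_from_smiles(stripped)
}

#' Re-render a molecule's SMILES under a random atom numbering
#'
#' Writes the molecule with its atoms renumbered by a random permutation
#' (stereo descriptors adjusted accordingly) and returns a non-canonical
#' SMILES string following that order. The canonical key of the re-rendered
#' string is identical to the original's; this is the instrument used to
#' demonstrate input-order invariance.
#'
#' @param mol a `sam_molecule`.
#' @return a SMILES string.
#' @export
shuffle_smiles <- function(mol) {
  n <- mol$n_heavy
  perm <- sample.int(n)
  g <- permute_graph(mol$graph, perm)
  sdf <- write_molblock(g, title = "1")
  lines <- ob_run(sdf, c("-isdf", "-osmi"))
  smi <- .ob_collect_smiles(lines, 1L)
  if (is.na(smi)) mol$canonical_key else smi
}
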