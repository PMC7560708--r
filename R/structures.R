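#' @title X-ray structure association
#' @description Associates cliffs with crystallographic complex
#'   structures using local mapping tables only: target id -> UniProt
#'   accession -> PDB entry ids, and PDB entry id -> co-crystallized
#'   ligand SMILES. A cliff is annotated with every PDB entry of its
#'   target whose ligand is one of the cliff's two analogs under
#'   canonical-key comparison.
#' @name structure-matching
NULL

#' Read a target-to-PDB mapping table
#'
#' CSV/TSV with columns `target_chembl_id`, `uniprot`, `pdb_id` (one row
#' per target-PDB pair). PDB ids are validated as 4 alphanumerics
#' (case-insensitive, stored upper-case); invalid rows are dropped with a
#' warning.
#'
#' @param path file path or data.frame.
#' @return data.table (target_chembl_id, uniprot, pdb_id).
#' @export
read_target_mappings <- function(path) {
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path)
  need <- c("target_chembl_id", "uniprot", "pdb_id")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stop(sprintf("mapping table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  dt[, pdb_id := toupper(trimws(pdb_id))]
  bad <- !grepl("^[0-9A-Z]{4}$", dt$pdb_id)
  if (any(bad)) {
    warning(sprintf("dropping %d mapping row(s) with invalid PDB ids", sum(bad)))
    dt <- dt[!bad]
  }
  unique(dt[, .(target_chembl_id, uniprot, pdb_id)])
}

#' Read a PDB ligand table
#'
#' CSV/TSV with columns `pdb_id`, `ligand_code`, `smiles`: the
#' co-crystallized small-molecule component of each PDB entry. Ligands
#' whose SMILES do not standardize are skipped with a message.
#'
#' @param path file path or data.frame.
#' @return data.table (pdb_id, ligand_code, smiles).
#' @export
read_pdb_ligands <- function(path) {
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path)
  need <- c("pdb_id", "ligand_code", "smiles")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stop(sprintf("ligand table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  dt[, pdb_id := toupper(trimws(pdb_id))]
  dt[, .(pdb_id, ligand_code, smiles)]
}

#' Does a PDB ligand match a compound?
#'
#' TRUE iff the two standardized structures have identical canonical keys
#' under the configured stereo mode. The default is stereo-insensitive
#' comparison: chemical-component records frequently omit or re-derive
#' stereo descriptors, so requiring exact stereo would miss genuine
#' matches. Strict comparison is available with `stereo_mode = "strict"`.
#'
#' @param ligand a `sam_molecule` (standardized ligand structure).
#' @param compound a `sam_molecule`.
#' @param stereo_mode `"ignore"` (default) or `"strict"`.
#' @return logical scalar.
#' @export
ligand_matches <- function(ligand, compound, stereo_mode = c("ignore", "strict")) {
  stereo_mode <- match.arg(stereo_mode)
  stopifnot(inherits(ligand, "sam_molecule"), inherits(compound, "sam_molecule"))
  if (stereo_mode == "strict") {
    return(ligand$canonical_key == compound$canonical_key)
  }
  ks <- stereo_free_keys(c(ligand$canonical_key, compound$canonical_key))
  !anyNA(ks) && ks[1L] == ks[2L]
}

#' Annotate cliffs with matching X-ray structures
#'
#' For each cliff, collects every PDB entry mapped to the cliff's target
#' whose co-crystallized ligand matches one of the two analogs, and
#' records which analog is co-crystallized. PDB ids are reported sorted
#' and semicolon-separated. Matches that hold only under stereo-relaxed
#' comparison (not under strict key equality) are flagged. The target
#' UniProt accession is filled in from the mapping table.
#'
#' @param cliffs cliff table from [call_cliffs()].
#' @param mappings mapping table from [read_target_mappings()].
#' @param ligands ligand table from [read_pdb_ligands()].
#' @param stereo_mode `"ignore"` (default) or `"strict"`; see
#'   [ligand_matches()].
#' @return the cliff table with `pdb_ids`, `xray_analog` (`"lower"`,
#'   `"higher"`, `"both"` or empty), `xray_stereo_relaxed` (TRUE when at
#'   least one match needed stereo relaxation) and `target_uniprot`
#'   filled in.
#' @export
annotate_cliffs <- function(cliffs, mappings, ligands,
                            stereo_mode = c("ignore", "strict")) {
  stereo_mode <- match.arg(stereo_mode)
  cl <- data.table::copy(data.table::as.data.table(cliffs))
  map <- data.table::as.data.table(mappings)
  lig <- data.table::as.data.table(ligands)
  if (!nrow(cl)) return(cl)
  cl[, xray_stereo_relaxed := FALSE]
  uni <- unique(map[, .(target_chembl_id, uniprot)], by = "target_chembl_id")
  cl[uni, on = "target_chembl_id", target_uniprot := i.uniprot]
  cl[is.na(target_uniprot), target_uniprot := ""]
  if (!nrow(map) || !nrow(lig)) return(cl[])

  std <- standardize_compounds(unique(lig$smiles), ids = unique(lig$smiles))
  if (nrow(std$failures)) {
    message(sprintf("skipping %d ligand record(s) that do not standardize",
                    nrow(std$failures)))
  }
  lig_key <- vapply(std$molecules, function(m) m$canonical_key, "")
  lig <- lig[smiles %in% names(lig_key)]
  data.table::set(lig, j = "lig_strict", value = unname(lig_key[lig$smiles]))

  # comparison keys for ligands and analogs under the configured mode
  all_strict <- unique(c(lig$lig_strict, cl$smiles_1, cl$smiles_2))
  cmp_of <- if (stereo_mode == "ignore") {
    stats::setNames(stereo_free_keys(all_strict), all_strict)
  } else {
    stats::setNames(all_strict, all_strict)
  }
  data.table::set(lig, j = "lig_cmp", value = unname(cmp_of[lig$lig_strict]))

  pdb_lig <- merge(map[, .(target_chembl_id, pdb_id)], lig, by = "pdb_id",
                   allow.cartesian = TRUE)
  for (r in seq_len(nrow(cl))) {
    cand <- pdb_lig[target_chembl_id == cl$target_chembl_id[r]]
    if (!nrow(cand)) next
    k1 <- cmp_of[[cl$smiles_1[r]]]; k2 <- cmp_of[[cl$smiles_2[r]]]
    m1 <- !is.na(cand$lig_cmp) & cand$lig_cmp == k1
    m2 <- !is.na(cand$lig_cmp) & cand$lig_cmp == k2
    hit <- m1 | m2
    if (!any(hit)) next
    ids <- sort(unique(cand$pdb_id[hit]))
    data.table::set(cl, i = r, j = "pdb_ids", value = paste(ids, collapse = ";"))
    which_analog <- if (any(m1) && any(m2)) "both" else if (any(m2)) "higher" else "lower"
    data.table::set(cl, i = r, j = "xray_analog", value = which_analog)
    if (stereo_mode == "ignore") {
      strict_hit <- (cand$lig_strict == cl$smiles_1[r] & m1) |
                    (cand$lig_strict == cl$smiles_2[r] & m2)
      data.table::set(cl, i = r, j = "xray_stereo_relaxed",
                      value = any(hit & !strict_hit))
    }
  }
  cl[]
}
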