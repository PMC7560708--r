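#' Run the full single-atom-modification cliff pipeline
#'
#' Curates a compound-activity table, enumerates analog pairs related by
#' single-atom replacements and walks, calls activity cliffs at the
#' potency-fold threshold, and (when mapping/ligand tables are supplied)
#' annotates cliffs with matching X-ray complex structures. When two
#' compound ids share one canonical structure, only the lexicographically
#' first id enters pair enumeration (with its own potencies); the rest
#' are dropped with a message.
#'
#' @param activities activity table: CSV/TSV path or data.frame (see
#'   [read_activity_table()]).
#' @param mappings optional target-to-PDB table (path or data.frame).
#' @param ligands optional PDB-ligand table (path or data.frame).
#' @param swaps admissible swap labels (default all four).
#' @param fold_threshold minimum potency ratio for a cliff (default 100).
#' @param max_span replicate-span filter in log units
#'   ([aggregate_potencies()]).
#' @param min_heavy_atoms curation minimum structure size
#'   ([filter_records()]).
#' @param stereo_mode ligand-matching stereo mode ([annotate_cliffs()]).
#' @param out_dir optional output directory; when given, the cliff
#'   dataset, target-based pairs, curated potencies, exclusions and the
#'   two summary tables are written as CSV (plus an aligned-text summary).
#' @return list with elements `potencies`, `pairs_structural`, `pairs`
#'   (target-based), `cliffs`, `summary` (overall), `summary_xray`
#'   (restricted to cliffs with structures), `exclusions`, `tally`,
#'   `discarded_groups`, `molecules`.
#' @export
run_sam_pipeline <- function(activities, mappings = NULL, ligands = NULL,
                             swaps = SAM_SWAPS, fold_threshold = 100,
                             max_span = 1.0, min_heavy_atoms = 4L,
                             stereo_mode = c("ignore", "strict"),
                             out_dir = NULL) {
  stereo_mode <- match.arg(stereo_mode)
  records <- read_activity_table(activities)
  filt <- filter_records(records, min_heavy_atoms = min_heavy_atoms)
  agg <- aggregate_potencies(filt$kept, max_span = max_span)
  tinfo <- target_info_table(filt$kept)

  # pair enumeration needs unique structures; duplicate-structure ids are
  # represented by the first id
  mols <- filt$molecules[names(filt$molecules) %in% agg$potencies$compound_id]
  if (length(mols)) {
    keys <- vapply(mols, function(m) m$canonical_key, "")
    ord <- order(names(mols))
    dup_ids <- names(mols)[ord][duplicated(keys[ord])]
    if (length(dup_ids)) {
      message(sprintf("dropping %d compound id(s) duplicating another id's structure",
                      length(dup_ids)))
      mols <- mols[setdiff(names(mols), dup_ids)]
    }
  }

  pairs_structural <- if (length(mols) >= 2L) find_analog_pairs(mols, swaps)
                      else .empty_pairs()
  pairs <- restrict_to_shared_activity(pairs_structural, agg$potencies)
  cliffs <- call_cliffs(pairs, agg$potencies, fold_threshold = fold_threshold,
                        target_info = tinfo)
  if (!is.null(mappings) && !is.null(ligands)) {
    cliffs <- annotate_cliffs(cliffs,
                              read_target_mappings(mappings),
                              read_pdb_ligands(ligands),
                              stereo_mode = stereo_mode)
  }
  summary_all <- summarize_cliffs(cliffs)
  summary_xray <- summarize_cliffs(cliffs, xray_only = TRUE)

  out <- list(potencies = agg$potencies, pairs_structural = pairs_structural,
              pairs = pairs, cliffs = cliffs, summary = summary_all,
              summary_xray = summary_xray, exclusions = filt$exclusions,
              tally = filt$tally, discarded_groups = agg$discarded,
              molecules = mols)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cliff_dataset(cliffs, file.path(out_dir, "sam_ac_dataset.csv"))
    data.table::fwrite(pairs, file.path(out_dir, "analog_pairs.csv"))
    data.table::fwrite(agg$potencies, file.path(out_dir, "potencies.csv"))
    data.table::fwrite(filt$exclusions, file.path(out_dir, "exclusions.csv"))
    data.table::fwrite(summary_all$targets, file.path(out_dir, "summary_targets.csv"))
    data.table::fwrite(summary_all$types, file.path(out_dir, "summary_types.csv"))
    writeLines(format_summary(summary_all, summary_xray),
               file.path(out_dir, "summary.txt"))
  }
  out
}

# Aligned plain-text rendering of the two summary views.
format_summary <- function(summary_all, summary_xray = NULL) {
  fmt_tab <- function(dt) {
    if (!nrow(dt)) return("  (none)")
    utils::capture.output(print(as.data.frame(dt), row.names = FALSE))
  }
  out <- c("Cliffs by measurement / target class / target group:",
           fmt_tab(summary_all$targets), "",
           "Cliffs by measurement / kind / modification type:",
           fmt_tab(summary_all$types_wide))
  if (!is.null(summary_xray)) {
    out <- c(out, "",
             "Cliffs with X-ray structures, by target group:",
             fmt_tab(summary_xray$targets))
  }
  out
}
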