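#' @title Activity-cliff calling and the dataset schema
#' @name cliff-calling
NULL

# Published field list, in order, of the cliff dataset CSV.
CLIFF_COLUMNS <- c(
  "cpd_id_1", "cpd_id_2", "smiles_1", "smiles_2", "measurement",
  "ppot_1", "ppot_2", "target_name", "target_uniprot", "target_chembl_id",
  "target_class", "target_group", "ac_type", "mod_type", "pdb_ids"
)

#' Call activity cliffs from target-based analog pairs
#'
#' Selects the pairs whose two analogs differ in potency by at least
#' `fold_threshold`-fold on the same target and measurement type
#' (inclusive boundary: a pair at exactly the threshold is a cliff;
#' comparisons are made on log-unit potencies at full precision, so
#' 100-fold corresponds to a difference of exactly 2.0). The less potent
#' analog is reported first.
#'
#' @param pairs target-based pair table from
#'   [restrict_to_shared_activity()].
#' @param potencies potency table from [aggregate_potencies()]; every pair
#'   member must have a potency for the pair's (target, measurement) — a
#'   `MissingPotency` error is raised otherwise.
#' @param fold_threshold minimum potency ratio (default 100).
#' @param target_info optional table (target_id, target_name,
#'   target_class, target_group) used to annotate cliffs; see
#'   [filter_records()].
#' @return data.table of cliffs in the dataset schema (see
#'   [write_cliff_dataset()]) plus `delta_ppot` and `xray_analog`
#'   annotation columns. `pdb_ids` is empty until
#'   [annotate_cliffs()] is applied.
#' @export
call_cliffs <- function(pairs, potencies, fold_threshold = 100,
                        target_info = NULL) {
  stopifnot(fold_threshold > 0)
  pairs <- data.table::as.data.table(pairs)
  pot <- data.table::as.data.table(potencies)
  if (!nrow(pairs)) return(.empty_cliffs())
  if (!all(c("target_id", "measurement") %in% names(pairs))) {
    stop("pairs must be target-based; run restrict_to_shared_activity() first")
  }
  x <- merge(pairs,
             pot[, .(compound_a = compound_id, target_id, measurement,
                     ppot_a = ppot)],
             by = c("compound_a", "target_id", "measurement"), all.x = TRUE)
  x <- merge(x,
             pot[, .(compound_b = compound_id, target_id, measurement,
                     ppot_b = ppot)],
             by = c("compound_b", "target_id", "measurement"), all.x = TRUE)
  if (anyNA(x$ppot_a) || anyNA(x$ppot_b)) {
    miss <- x[is.na(ppot_a) | is.na(ppot_b)]
    sam_error("MissingPotency",
              sprintf("%d pair(s) lack a potency for their target/measurement (e.g. %s/%s on %s)",
                      nrow(miss), miss$compound_a[1L], miss$compound_b[1L],
                      miss$target_id[1L]))
  }
  x[, delta_ppot := abs(ppot_a - ppot_b)]
  x <- x[delta_ppot >= log10(fold_threshold)]
  if (!nrow(x)) return(.empty_cliffs())
  # analog 1 = less potent; ties broken lexicographically by id
  lo_is_a <- x$ppot_a < x$ppot_b | (x$ppot_a == x$ppot_b & x$compound_a <= x$compound_b)
  cl <- data.table::data.table(
    cpd_id_1 = ifelse(lo_is_a, x$compound_a, x$compound_b),
    cpd_id_2 = ifelse(lo_is_a, x$compound_b, x$compound_a),
    smiles_1 = ifelse(lo_is_a, x$smiles_a, x$smiles_b),
    smiles_2 = ifelse(lo_is_a, x$smiles_b, x$smiles_a),
    measurement = x$measurement,
    ppot_1 = ifelse(lo_is_a, x$ppot_a, x$ppot_b),
    ppot_2 = ifelse(lo_is_a, x$ppot_b, x$ppot_a),
    target_name = "", target_uniprot = "",
    target_chembl_id = x$target_id,
    target_class = "", target_group = "",
    ac_type = paste0(x$kind, "_AC"),
    mod_type = x$swap,
    pdb_ids = "",
    delta_ppot = x$delta_ppot,
    xray_analog = ""
  )
  if (!is.null(target_info)) {
    ti <- data.table::as.data.table(target_info)
    cl[ti, on = c(target_chembl_id = "target_id"),
       `:=`(target_name = i.target_name, target_class = i.target_class,
            target_group = i.target_group)]
  }
  data.table::setorder(cl, measurement, target_chembl_id, cpd_id_1, cpd_id_2,
                       mod_type)
  cl[]
}

.empty_cliffs <- function() {
  cl <- data.table::as.data.table(
    stats::setNames(rep(list(character(0)), length(CLIFF_COLUMNS)),
                    CLIFF_COLUMNS))
  cl[, `:=`(ppot_1 = numeric(0), ppot_2 = numeric(0),
            delta_ppot = numeric(0), xray_analog = character(0))]
  data.table::setcolorder(cl, c(CLIFF_COLUMNS, "delta_ppot", "xray_analog"))
  cl[]
}

#' Summarize cliffs by target group and by modification type
#'
#' Reproduces the two standard summary views: (i) cliff counts by
#' measurement type, target class and target group, optionally restricted
#' to cliffs with at least one associated X-ray structure, and (ii)
#' counts by measurement type, cliff kind (ar_AC/aw_AC) and modification
#' type. Rows are ordered by descending count, then label.
#'
#' @param cliffs cliff table from [call_cliffs()].
#' @param xray_only restrict the target-group view to cliffs with a
#'   non-empty `pdb_ids` field (default FALSE).
#' @return list with data.tables `targets` (measurement, target_class,
#'   target_group, n) and `types` (measurement, ac_type, mod_type, n),
#'   plus `types_wide` (one row per modification type, one count column
#'   per measurement/kind).
#' @export
summarize_cliffs <- function(cliffs, xray_only = FALSE) {
  cl <- data.table::as.data.table(cliffs)
  sel <- if (xray_only && nrow(cl)) cl[nzchar(pdb_ids)] else cl
  targets <- if (nrow(sel)) {
    t <- sel[, .(n = .N), by = .(measurement, target_class, target_group)]
    data.table::setorder(t, measurement, -n, target_class, target_group)
    t
  } else {
    data.table::data.table(measurement = character(0),
                           target_class = character(0),
                           target_group = character(0), n = integer(0))
  }
  types <- if (nrow(sel)) {
    t <- sel[, .(n = .N), by = .(measurement, ac_type, mod_type)]
    data.table::setorder(t, measurement, ac_type, -n, mod_type)
    t
  } else {
    data.table::data.table(measurement = character(0), ac_type = character(0),
                           mod_type = character(0), n = integer(0))
  }
  wide <- data.table::data.table(mod_type = SAM_SWAPS)
  for (m in c("IC50", "Ki")) {
    for (k in c("ar_AC", "aw_AC")) {
      cnt <- types[measurement == m & ac_type == k]
      v <- integer(length(SAM_SWAPS))
      names(v) <- SAM_SWAPS
      if (nrow(cnt)) v[cnt$mod_type] <- cnt$n
      data.table::set(wide, j = paste(m, k, sep = "_"), value = unname(v))
    }
  }
  list(targets = targets, types = types, types_wide = wide)
}

#' Write the cliff dataset
#'
#' Writes one CSV row per cliff with the published field list and order:
#' compound ids of both analogs, canonical SMILES of both, measurement
#' type, log-unit potencies of both (less potent analog first), target
#' name/UniProt/ChEMBL id, target class and group, sam_AC type
#' (`ar_AC`/`aw_AC`), modification type, and semicolon-separated PDB
#' id(s) (empty when none).
#'
#' @param cliffs cliff table from [call_cliffs()].
#' @param path output file path; a `WriteFailure` error is raised when the
#'   path is unwritable.
#' @return invisibly, the path.
#' @export
write_cliff_dataset <- function(cliffs, path) {
  cl <- data.table::as.data.table(cliffs)
  out <- cl[, CLIFF_COLUMNS, with = FALSE]
  ok <- tryCatch({
    data.table::fwrite(out, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    sam_error("WriteFailure", sprintf("cannot write '%s': %s",
                                      path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Read a cliff dataset written by [write_cliff_dataset()]
#'
#' @param path CSV file path.
#' @return cliff data.table; `delta_ppot` is recomputed from the two
#'   potencies and `xray_analog` (an in-memory annotation, not part of the
#'   published schema) is empty.
#' @export
read_cliff_dataset <- function(path) {
  # read.csv rather than fread: correct un-escaping of doubled quotes in
  # free-text fields (e.g. target names)
  classes <- stats::setNames(rep("character", length(CLIFF_COLUMNS)),
                             CLIFF_COLUMNS)
  classes[c("ppot_1", "ppot_2")] <- "numeric"
  cl <- data.table::as.data.table(
    utils::read.csv(path, colClasses = classes, check.names = FALSE))
  missing <- setdiff(CLIFF_COLUMNS, names(cl))
  if (length(missing)) {
    stop(sprintf("cliff dataset lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  cl[, `:=`(delta_ppot = abs(ppot_2 - ppot_1), xray_analog = "")]
  for (col in setdiff(CLIFF_COLUMNS, c("ppot_1", "ppot_2"))) {
    data.table::set(cl, i = which(is.na(cl[[col]])), j = col, value = "")
  }
  data.table::setcolorder(cl, c(CLIFF_COLUMNS, "delta_ppot", "xray_analog"))
  cl[]
}
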