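#' @import data.table
NULL

# Canonical activity-table column set (extra columns are tolerated).
ACTIVITY_COLUMNS <- c(
  "compound_id", "smiles", "target_id", "target_name", "target_class",
  "target_group", "organism", "assay_relationship", "assay_confidence",
  "assay_target_type", "measurement", "relation", "value", "units"
)

#' Read a compound-activity table
#'
#' Reads a ChEMBL-style activity table from CSV or TSV (delimiter
#' auto-detected) and checks that the documented columns are present.
#' Extra columns are kept.
#'
#' @param path file path, or a data.frame already in memory.
#' @return a data.table of activity records.
#' @export
read_activity_table <- function(path) {
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path, colClasses = list(character = "compound_id"))
  missing <- setdiff(ACTIVITY_COLUMNS, names(dt))
  if (length(missing)) {
    stop(sprintf("activity table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  dt
}

# Accepted concentration units and their molar log-offset: p = offset - log10(value)
.UNIT_OFFSETS <- c("nM" = 9, "uM" = 6, "µM" = 6, "M" = 0)

#' Convert a potency value to the negative decadic logarithmic scale
#'
#' `to_ppot(10, "nM")` is 8.0: the value is converted to mol/L and
#' `-log10` applied, giving pKi/pIC50 ("pPot") in log units.
#'
#' @param value positive numeric vector.
#' @param units unit string(s): one of `nM`, `uM`/`µM`, `M`.
#' @return numeric vector of log-unit potencies.
#' @export
to_ppot <- function(value, units) {
  off <- .UNIT_OFFSETS[units]
  if (anyNA(off)) {
    sam_error("UnknownUnits",
              sprintf("unknown concentration unit(s): %s",
                      paste(unique(units[is.na(off)]), collapse = ", ")))
  }
  if (any(!is.finite(value) | value <= 0)) {
    stop("potency values must be positive and finite")
  }
  unname(off - log10(value))
}

#' Filter raw activity records to high-confidence data
#'
#' Applies the selection criteria in a fixed order, tallying each removed
#' record under its first failing criterion: human assay organism; single
#' protein target; direct assay relationship ("D"); assay confidence score
#' 9; Ki or IC50 measurement; exact "=" relation; accepted concentration
#' unit; positive value; structure standardizes (see
#' [standardize_compounds()], with a curation-level minimum fragment size).
#' Records whose compound id maps to more than one distinct canonical
#' structure are excluded as `structure`.
#'
#' @param records data.table of activity records ([read_activity_table()]).
#' @param min_heavy_atoms minimum heavy-atom count of the standardized
#'   structure (default 4; smaller fragments are degenerate for analog
#'   analysis).
#' @param organism accepted assay organism (case-insensitive).
#' @return a list:
#'   \describe{
#'     \item{kept}{records passing all criteria, with a `canonical_smiles`
#'       column appended.}
#'     \item{exclusions}{removed records with a `reason` column.}
#'     \item{tally}{named integer vector, reason -> count.}
#'     \item{molecules}{named list of `sam_molecule` for the kept
#'       compounds (names are compound ids).}
#'   }
#' @export
filter_records <- function(records, min_heavy_atoms = 4L,
                           organism = "homo sapiens") {
  dt <- data.table::as.data.table(records)
  n <- nrow(dt)
  reason <- rep(NA_character_, n)
  mark <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  mark(tolower(trimws(dt$organism)) != tolower(organism), "organism")
  mark(toupper(trimws(dt$assay_target_type)) != "SINGLE PROTEIN", "target_type")
  mark(toupper(trimws(dt$assay_relationship)) != "D", "relationship")
  mark(is.na(dt$assay_confidence) | dt$assay_confidence != 9L, "confidence")
  mark(!(dt$measurement %in% c("Ki", "IC50")), "measurement")
  mark(trimws(dt$relation) != "=", "relation")
  mark(!(dt$units %in% names(.UNIT_OFFSETS)), "units")
  mark(is.na(dt$value) | !is.finite(dt$value) | dt$value <= 0, "value")

  # structure criterion: standardize each distinct SMILES once
  cand <- which(is.na(reason))
  mols <- list()
  if (length(cand)) {
    smi <- unique(dt$smiles[cand])
    std <- standardize_compounds(smi, ids = smi, min_heavy = min_heavy_atoms)
    key_of <- vapply(std$molecules, function(m) m$canonical_key, "")
    ok_smi <- names(std$molecules)
    bad <- cand[!(dt$smiles[cand] %in% ok_smi)]
    reason[bad] <- "structure"
    # one compound id, one structure: ids with conflicting keys are excluded
    cand <- which(is.na(reason))
    if (length(cand)) {
      keys <- key_of[dt$smiles[cand]]
      nkey <- tapply(keys, dt$compound_id[cand], function(k) length(unique(k)))
      bad_ids <- names(nkey)[nkey > 1L]
      reason[cand[dt$compound_id[cand] %in% bad_ids]] <- "structure"
      cand <- which(is.na(reason))
      # molecule per compound id, re-keyed to the id
      first <- !duplicated(dt$compound_id[cand])
      for (i in cand[first]) {
        m <- std$molecules[[dt$smiles[i]]]
        m$id <- dt$compound_id[i]
        mols[[dt$compound_id[i]]] <- m
      }
    }
  }

  kept <- dt[is.na(reason)]
  if (nrow(kept)) {
    key_map <- vapply(mols, function(m) m$canonical_key, "")
    data.table::set(kept, j = "canonical_smiles",
                    value = unname(key_map[kept$compound_id]))
  } else {
    data.table::set(kept, j = "canonical_smiles", value = character(0))
  }
  exclusions <- dt[!is.na(reason)]
  data.table::set(exclusions, j = "reason", value = reason[!is.na(reason)])
  tally_levels <- c("organism", "target_type", "relationship", "confidence",
                    "measurement", "relation", "units", "value", "structure")
  tally <- table(factor(exclusions$reason, levels = tally_levels))
  tally <- stats::setNames(as.integer(tally), tally_levels)
  list(kept = kept, exclusions = exclusions, tally = tally, molecules = mols)
}

#' Aggregate filtered records into per-compound potencies
#'
#' One potency per (compound, target, measurement type): records are
#' converted to the log scale and averaged arithmetically (the geometric
#' mean of the molar values). Groups whose per-record log values span more
#' than `max_span` log units are discarded entirely — noisy replicate sets
#' would otherwise contaminate cliff calls. Ki and IC50 records are never
#' mixed.
#'
#' @param records the `kept` table from [filter_records()].
#' @param max_span maximum tolerated within-group range in log units
#'   (default 1.0; the boundary is kept).
#' @return a list:
#'   \describe{
#'     \item{potencies}{data.table (compound_id, target_id, measurement,
#'       ppot, n_records).}
#'     \item{discarded}{data.table of discarded groups with their spans.}
#'   }
#' @export
aggregate_potencies <- function(records, max_span = 1.0) {
  dt <- data.table::as.data.table(records)
  ppot_rec <- to_ppot(dt$value, dt$units)
  data.table::set(dt, j = ".ppot", value = ppot_rec)
  grp <- dt[, .(ppot = mean(.ppot), span = max(.ppot) - min(.ppot),
                n_records = .N),
            by = .(compound_id, target_id, measurement)]
  discarded <- grp[span > max_span]
  potencies <- grp[span <= max_span, .(compound_id, target_id, measurement,
                                       ppot, n_records)]
  data.table::setorder(potencies, compound_id, target_id, measurement)
  list(potencies = potencies, discarded = discarded)
}

# Unique target metadata from kept records (first occurrence wins).
target_info_table <- function(records) {
  dt <- data.table::as.data.table(records)
  unique(dt[, .(target_id, target_name, target_class, target_group)],
         by = "target_id")
}
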