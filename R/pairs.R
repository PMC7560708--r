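#' @title Analog-pair enumeration
#' @description Enumeration of analog pairs related by exactly one
#'   single-atom modification. Two mechanisms are covered: atom
#'   replacement (ar) — one position changes element, the heavy-atom
#'   formula shifts by one swap — and atom walk (aw) — a heteroatom
#'   relocates, the formula is unchanged. Detection is an indexed join
#'   over canonical mutant keys rather than an all-pairs structure
#'   comparison: a molecule's valid single-atom mutants are canonicalized
#'   once, then (i) a mutant key equal to another compound's own key
#'   certifies an ar pair, and (ii) two compounds sharing a mutant key
#'   under the same directed swap at different positions certify an aw
#'   pair (the shared mutant is the structure in which both walk positions
#'   carry the same element, which is equivalent to the positional
#'   exchange definition).
#' @name pair-enumeration
NULL

# Shared input validation: named list of sam_molecule with unique keys.
check_compound_set <- function(compounds) {
  stopifnot(length(compounds) > 0L,
            all(vapply(compounds, inherits, TRUE, "sam_molecule")))
  keys <- vapply(compounds, function(m) m$canonical_key, "")
  dup <- duplicated(keys)
  if (any(dup)) {
    sam_error("DuplicateStructure",
              sprintf("compounds share a canonical structure: %s",
                      paste(unique(keys[dup]), collapse = ", ")))
  }
  keytab <- data.table::data.table(id = vapply(compounds, function(m) m$id, ""))
  data.table::set(keytab, j = "key", value = unname(keys))
  keytab
}

.empty_pairs <- function() {
  data.table::data.table(
    compound_a = character(0), compound_b = character(0),
    kind = character(0), swap = character(0),
    site_a = integer(0), site_b = integer(0),
    smiles_a = character(0), smiles_b = character(0)
  )
}

.finish_pairs <- function(pairs, keytab) {
  pairs <- merge(pairs, keytab[, .(compound_a = id, smiles_a = key)],
                 by = "compound_a")
  pairs <- merge(pairs, keytab[, .(compound_b = id, smiles_b = key)],
                 by = "compound_b")
  data.table::setcolorder(pairs, c("compound_a", "compound_b", "kind", "swap",
                                   "site_a", "site_b", "smiles_a", "smiles_b"))
  data.table::setorder(pairs, compound_a, compound_b, swap)
  pairs[]
}

#' Find atom-replacement (ar) analog pairs
#'
#' Returns every unordered pair of compounds for which a single admissible
#' atom replacement converts one into the other. Each pair is reported
#' once per distinct swap type; `site_a`/`site_b` give the canonical atom
#' rank of the modified position in each compound (lowest rank under
#' symmetry).
#'
#' @param compounds named list of `sam_molecule` with pairwise distinct
#'   canonical keys (a `DuplicateStructure` error is raised otherwise).
#' @param swaps admissible swap labels, a subset of [SAM_SWAPS].
#' @return data.table with columns compound_a, compound_b (lexicographic
#'   order), kind ("ar"), swap, site_a, site_b, smiles_a, smiles_b.
#' @export
find_replacement_pairs <- function(compounds, swaps = SAM_SWAPS) {
  keytab <- check_compound_set(compounds)
  mut <- mutant_key_table(compounds, swaps)
  .ar_pairs_from_mutants(mut, keytab)
}

.ar_pairs_from_mutants <- function(mut, keytab) {
  if (!nrow(mut)) return(.empty_pairs())
  hits <- merge(mut, keytab[, .(key, hit_id = id)], by = "key",
                allow.cartesian = TRUE)
  hits <- hits[parent_id != hit_id]
  if (!nrow(hits)) return(.empty_pairs())
  hits[, `:=`(ca = pmin(parent_id, hit_id), cb = pmax(parent_id, hit_id))]
  sa <- hits[parent_id == ca, .(site_a = min(site)), by = .(ca, cb, label)]
  sb <- hits[parent_id == cb, .(site_b = min(site)), by = .(ca, cb, label)]
  pairs <- merge(sa, sb, by = c("ca", "cb", "label"), all = TRUE)
  data.table::setnames(pairs, c("ca", "cb", "label"),
                       c("compound_a", "compound_b", "swap"))
  pairs[, kind := "ar"]
  .finish_pairs(pairs, keytab)
}

#' Find atom-walk (aw) analog pairs
#'
#' Returns every unordered pair of compounds whose structures are
#' identical except that one heteroatom and one partner atom of an
#' admissible swap have exchanged positions (equal heavy-atom formulas).
#' Detection: two compounds form an aw pair iff they produce the same
#' mutant canonical key under the same directed swap, which is equivalent
#' to the positional-exchange definition. A compound never pairs with
#' itself (symmetric walk sites produce the same canonical key and are
#' screened out by the unique-key precondition).
#'
#' @inheritParams find_replacement_pairs
#' @return data.table as in [find_replacement_pairs()] with kind "aw".
#' @export
find_walk_pairs <- function(compounds, swaps = SAM_SWAPS) {
  keytab <- check_compound_set(compounds)
  mut <- mutant_key_table(compounds, swaps)
  .aw_pairs_from_mutants(mut, keytab)
}

.aw_pairs_from_mutants <- function(mut, keytab) {
  if (!nrow(mut)) return(.empty_pairs())
  j <- merge(mut, mut, by = c("key", "from", "to", "label"),
             allow.cartesian = TRUE, suffixes = c("_a", "_b"))
  j <- j[parent_id_a < parent_id_b]
  if (!nrow(j)) return(.empty_pairs())
  pairs <- j[, .(site_a = min(site_a), site_b = min(site_b)),
             by = .(compound_a = parent_id_a, compound_b = parent_id_b,
                    swap = label)]
  pairs[, kind := "aw"]
  .finish_pairs(pairs, keytab)
}

#' Find all analog pairs (replacements and walks)
#'
#' Convenience wrapper running [find_replacement_pairs()] and
#' [find_walk_pairs()] on one compound set. The two kinds are disjoint by
#' construction (a replacement changes the heavy-atom formula, a walk
#' preserves it).
#'
#' @inheritParams find_replacement_pairs
#' @return combined pair data.table.
#' @export
find_analog_pairs <- function(compounds, swaps = SAM_SWAPS) {
  keytab <- check_compound_set(compounds)
  mut <- mutant_key_table(compounds, swaps)
  out <- rbind(.ar_pairs_from_mutants(mut, keytab),
               .aw_pairs_from_mutants(mut, keytab))
  data.table::setorder(out, compound_a, compound_b, kind, swap)
  out[]
}

#' Restrict structural pairs to shared measured activity
#'
#' Keeps the pairs whose two compounds both have a curated potency for the
#' same target under the same measurement type, expanding a structural
#' pair into one target-based pair per shared (target, measurement). Ki
#' and IC50 potencies never combine.
#'
#' @param pairs pair table from the `find_*_pairs` functions.
#' @param potencies potency table from [aggregate_potencies()].
#' @return the pair table with `target_id` and `measurement` columns
#'   appended, one row per (pair, target, measurement).
#' @export
restrict_to_shared_activity <- function(pairs, potencies) {
  pairs <- data.table::as.data.table(pairs)
  pot <- data.table::as.data.table(potencies)
  if (!nrow(pairs) || !nrow(pot)) {
    out <- pairs[0]
    out[, `:=`(target_id = character(0), measurement = character(0))]
    return(out[])
  }
  a <- merge(pairs, pot[, .(compound_a = compound_id, target_id, measurement)],
             by = "compound_a", allow.cartesian = TRUE)
  ab <- merge(a, pot[, .(compound_b = compound_id, target_id, measurement,
                         .present = TRUE)],
              by = c("compound_b", "target_id", "measurement"))
  ab[, .present := NULL]
  data.table::setcolorder(ab, c(names(pairs), "target_id", "measurement"))
  data.table::setorder(ab, compound_a, compound_b, kind, swap, target_id,
                       measurement)
  ab[]
}
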