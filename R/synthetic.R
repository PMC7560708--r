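#' @title Synthetic benchmark generation and the brute-force oracle
#' @description Generates ChEMBL-like fixture inputs with planted analog
#'   pairs, planted cliffs and decoys, and provides the exhaustive
#'   pairwise oracle that certifies the indexed pair enumeration.
#' @name synthetic-benchmark
NULL

# --- scaffold library (embedded; no downloads) -------------------------

# Substituents, always attached through their first atom (written inside
# parentheses at the attachment site); mutually distinct under that
# convention and free of admissible-swap relations among themselves.
.FIXTURE_RS <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC",
                 "C(C)C", "C(C)CC", "C(C)(C)C", "CC(C)C",
                 "C(F)(F)", "C(F)(F)F", "C(Cl)", "CC(Cl)")

# Series families: each returns the SMILES of one analog series around a
# scaffold. Planted relations (certified by the oracle at generation
# time): azines give ar pairs (ring N <-> C vs the benzene analog) plus
# the pairwise N walks; furan/thiophene gives an S-O replacement and an
# O-C walk; para-substituted benzenes give the N-O/O-C/N-C replacement
# triangle; the acyclic linker gives an N-O replacement and an O-C walk.
.FIXTURE_FAMILIES <- list(
  azine = function(r) c(paste0("c1cc(", r, ")ccc1"),
                        paste0("n1c(", r, ")cccc1"),
                        paste0("n1cc(", r, ")ccc1"),
                        paste0("n1ccc(", r, ")cc1")),
  furanthiophene = function(r) c(paste0("o1c(", r, ")ccc1"),
                                 paste0("o1cc(", r, ")cc1"),
                                 paste0("s1c(", r, ")ccc1")),
  parabenzene = function(r) c(paste0("Oc1ccc(", r, ")cc1"),
                              paste0("Nc1ccc(", r, ")cc1"),
                              paste0("Cc1ccc(", r, ")cc1")),
  linker = function(r) c(paste0("C(", r, ")OCC"), paste0("C(", r, ")NCC"),
                         paste0("C(", r, ")COC"))
)

.FIXTURE_DECOYS <- c("c1ccc2ccccc2c1", "C1CCCCC1", "CC(C)(C)CC(C)(C)C",
                     "C1C2CC3CC1CC(C2)C3", "c1ccc(-c2ccccc2)cc1",
                     "C1CCCCCC1")

.FIXTURE_CLASSES <- list(
  c("Enzyme", "Kinase"), c("Enzyme", "Protease"), c("Enzyme", "Lyase"),
  c("Enzyme", "Phosphodiesterase"), c("Enzyme", "Oxidoreductase"),
  c("Enzyme", "Transferase"),
  c("Membrane receptor", "Family A G protein-coupled receptor"),
  c("Epigenetic regulator", "Writer"), c("Epigenetic regulator", "Eraser"),
  c("Transcription factor", "Nuclear receptor")
)

# Greedy proper coloring of a small pair graph (ids, edge list); returns
# named integer vector of 0-based colors.
.greedy_colors <- function(ids, edges) {
  cols <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$compound_a[k]; b <- edges$compound_b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  for (id in ids) {
    used <- cols[unlist(adj[[id]])]
    used <- used[!is.na(used)]
    c0 <- 0L
    while (c0 %in% used) c0 <- c0 + 1L
    cols[[id]] <- c0
  }
  cols
}

#' Exhaustive brute-force analog-pair oracle
#'
#' Decides, for every unordered pair of compounds, whether the two are
#' related by a single atom replacement (by testing all single mutations
#' of one member against the other's canonical key) or by a single atom
#' walk (by testing all position pairs for an admissible element
#' exchange). This is the definitional truth that the indexed enumeration
#' in [find_replacement_pairs()]/[find_walk_pairs()] must match exactly;
#' it shares only the canonicalization backend, not the join logic.
#'
#' @param compounds named list of `sam_molecule` with distinct canonical
#'   keys.
#' @param swaps admissible swap labels.
#' @param max_heavy exhaustive-size bound; a `SizeLimit` error is raised
#'   when a molecule exceeds it (default 14 heavy atoms).
#' @return data.table (compound_a, compound_b, kind, swap), unordered
#'   pairs with compound_a < compound_b.
#' @export
oracle_pairs <- function(compounds, swaps = SAM_SWAPS, max_heavy = 14L) {
  keytab <- check_compound_set(compounds)
  sizes <- vapply(compounds, function(m) m$n_heavy, 0L)
  if (any(sizes > max_heavy)) {
    sam_error("SizeLimit",
              sprintf("molecule(s) exceed the exhaustive bound of %d heavy atoms: %s",
                      max_heavy, paste(names(sizes)[sizes > max_heavy], collapse = ", ")))
  }
  ds <- directed_swaps(swaps)

  # all single-mutation results per molecule (no deduplication)
  meta <- list(); blocks <- list(); k <- 0L
  for (mol in compounds) {
    g <- mol$graph
    sums <- bond_order_sums(g)
    for (i in seq_len(nrow(g$atoms))) {
      if (g$atoms$charge[i] != 0L) next
      for (h in which(ds$from == g$atoms$elem[i])) {
        if (!site_accepts(g, i, ds$to[h], sums)) next
        g2 <- g
        g2$atoms$elem[i] <- ds$to[h]
        k <- k + 1L
        meta[[k]] <- data.frame(parent_id = mol$id, label = ds$label[h],
                                stringsAsFactors = FALSE)
        blocks[[k]] <- write_molblock(g2, title = as.character(k))
      }
    }
  }
  muts <- if (k) {
    m <- data.table::rbindlist(meta)
    data.table::set(m, j = "key", value = ob_can_from_sdf(unlist(blocks), k))
    m[!is.na(key)]
  } else NULL
  exch <- exchange_key_table(compounds, swaps)

  ids <- sort(keytab$id)
  keys <- stats::setNames(keytab$key, keytab$id)
  mut_by <- if (!is.null(muts) && nrow(muts)) split(muts, by = "parent_id") else list()
  exch_by <- if (nrow(exch)) split(exch, by = "parent_id") else list()
  out <- list()
  for (x in seq_along(ids)) {
    for (y in seq_len(x - 1L)) {
      a <- ids[y]; b <- ids[x]
      ma <- mut_by[[a]]; mb <- mut_by[[b]]
      ar_labels <- sort(unique(c(
        if (!is.null(ma)) ma$label[ma$key == keys[[b]]],
        if (!is.null(mb)) mb$label[mb$key == keys[[a]]]
      )))
      ea <- exch_by[[a]]; eb <- exch_by[[b]]
      aw_labels <- sort(unique(c(
        if (!is.null(ea)) ea$label[ea$key == keys[[b]]],
        if (!is.null(eb)) eb$label[eb$key == keys[[a]]]
      )))
      if (length(ar_labels)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          compound_a = a, compound_b = b, kind = "ar", swap = ar_labels)
      }
      if (length(aw_labels)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          compound_a = a, compound_b = b, kind = "aw", swap = aw_labels)
      }
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(compound_a = character(0), compound_b = character(0),
                           kind = character(0), swap = character(0))
  data.table::setorder(res, compound_a, compound_b, kind, swap)
  res[]
}

#' Generate a ChEMBL-like synthetic fixture with planted truth
#'
#' Builds an activity table (plus target mapping and PDB ligand tables)
#' around planted analog series: each series takes one scaffold family and
#' one substituent, yielding compounds related by known single-atom
#' replacements and walks, with potencies planted so that a configurable
#' fraction of series form activity cliffs. Potency replicates carry
#' Gaussian noise on the log scale (sd `noise_sd`, centred so the
#' replicate mean equals the planted value and spans stay below the
#' aggregation filter); planted pair potency differences are kept at
#' >= 2.6 or <= 1.4 log units, clear of the 2.0 cliff boundary. Decoy
#' compounds from unrelated scaffolds pair with nothing, and a handful of
#' records violating each curation criterion exercise the exclusion
#' tally. The planted pair set is certified at generation time by
#' [oracle_pairs()]; generation fails if any unplanned pair exists.
#'
#' All randomness derives from `seed`; the caller's RNG state is restored
#' on exit, and a fixed seed reproduces the output byte for byte.
#'
#' @param n_series number of analog series (max 56).
#' @param seed integer random seed.
#' @param fraction_cliffs fraction of series planted as cliff series
#'   (default 0.5).
#' @param fraction_xray fraction of planted cliffs given a matching X-ray
#'   ligand entry, co-crystallizing the higher-potency analog
#'   (default 0.5); a small fraction of those also get a second entry
#'   with the lower-potency analog.
#' @param noise_sd per-record log-unit noise sd (default 0.2).
#' @param max_replicates records per compound are drawn from
#'   1..max_replicates (default 3).
#' @param out_dir optional directory; when given, `activities.csv`,
#'   `mappings.csv` and `ligands.csv` are written there.
#' @return list with `activities`, `mappings`, `ligands` (data.tables),
#'   `truth` (planted truth: `pairs`, `cliffs`, `decoys`, `potencies`),
#'   and `paths` (when `out_dir` was given).
#' @export
generate_fixture <- function(n_series, seed, fraction_cliffs = 0.5,
                             fraction_xray = 0.5, noise_sd = 0.2,
                             max_replicates = 3L, out_dir = NULL) {
  stopifnot(n_series >= 1L)
  combos <- expand.grid(family = names(.FIXTURE_FAMILIES), r = .FIXTURE_RS,
                        stringsAsFactors = FALSE)
  if (n_series > nrow(combos)) {
    stop(sprintf("n_series must be <= %d (distinct scaffold/substituent combinations)",
                 nrow(combos)))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  picks <- combos[sample.int(nrow(combos), n_series), , drop = FALSE]

  # --- compounds -------------------------------------------------------
  comp <- list(); cpd_n <- 0L
  series_meta <- list()
  for (s in seq_len(n_series)) {
    smi <- .FIXTURE_FAMILIES[[picks$family[s]]](picks$r[s])
    ids <- sprintf("CPD%05d", cpd_n + seq_along(smi))
    cpd_n <- cpd_n + length(smi)
    cg <- .FIXTURE_CLASSES[[sample.int(length(.FIXTURE_CLASSES), 1L)]]
    series_meta[[s]] <- list(
      ids = ids, smiles = smi,
      target_id = sprintf("CHEMBL_T%03d", s),
      target_name = sprintf("Synthetic target %03d", s),
      uniprot = sprintf("P%05d", 10000L + s),
      target_class = cg[1L], target_group = cg[2L],
      measurement = sample(c("Ki", "IC50"), 1L),
      is_cliff = stats::runif(1L) < fraction_cliffs
    )
    comp[[s]] <- data.table::data.table(compound_id = ids, smiles = smi,
                                        series = s)
  }
  decoy_ids <- sprintf("DEC%03d", seq_along(.FIXTURE_DECOYS))
  comp <- data.table::rbindlist(c(comp, list(
    data.table::data.table(compound_id = decoy_ids, smiles = .FIXTURE_DECOYS,
                           series = 0L))))

  std <- standardize_compounds(comp$smiles, ids = comp$compound_id)
  if (nrow(std$failures)) {
    stop("internal: fixture scaffold failed standardization: ",
         paste(std$failures$id, collapse = ", "))
  }

  # --- certify planted pairs with the oracle ---------------------------
  orc <- oracle_pairs(std$molecules)
  series_of <- stats::setNames(comp$series, comp$compound_id)
  if (nrow(orc)) {
    cross <- orc[series_of[compound_a] != series_of[compound_b] |
                 series_of[compound_a] == 0L]
    if (nrow(cross)) {
      stop("internal: fixture scaffolds produce cross-series or decoy pairs")
    }
  }

  # --- plant potencies -------------------------------------------------
  pot <- list()
  truth_pairs <- list()
  for (s in seq_len(n_series)) {
    sm <- series_meta[[s]]
    edges <- orc[compound_a %in% sm$ids & compound_b %in% sm$ids]
    cols <- .greedy_colors(sm$ids, unique(edges[, .(compound_a, compound_b)]))
    base <- stats::runif(1L, 4.5, 6.5)
    jit <- stats::runif(length(sm$ids), -0.1, 0.1)
    ppot <- if (sm$is_cliff) base + 2.8 * cols + jit else base + jit
    names(ppot) <- sm$ids
    pot[[s]] <- data.table::data.table(
      compound_id = sm$ids, target_id = sm$target_id,
      measurement = sm$measurement, ppot_true = unname(ppot))
    if (nrow(edges)) {
      e <- data.table::copy(edges)
      e[, `:=`(target_id = sm$target_id, measurement = sm$measurement,
               ppot_a = ppot[compound_a], ppot_b = ppot[compound_b])]
      truth_pairs[[length(truth_pairs) + 1L]] <- e
    }
  }
  pot[[length(pot) + 1L]] <- data.table::data.table(
    compound_id = decoy_ids, target_id = "CHEMBL_T999", measurement = "Ki",
    ppot_true = stats::runif(length(decoy_ids), 5, 7))
  potencies <- data.table::rbindlist(pot)
  truth_pairs <- data.table::rbindlist(truth_pairs)
  truth_pairs[, delta_ppot := abs(ppot_a - ppot_b)]
  truth_cliffs <- truth_pairs[delta_ppot >= 2]
  truth_cliffs <- truth_cliffs[, .(
    cpd_id_1 = ifelse(ppot_a <= ppot_b, compound_a, compound_b),
    cpd_id_2 = ifelse(ppot_a <= ppot_b, compound_b, compound_a),
    kind, swap, target_id, measurement, delta_ppot)]

  # --- activity records ------------------------------------------------
  smiles_of <- stats::setNames(comp$smiles, comp$compound_id)
  tmeta <- data.table::rbindlist(lapply(series_meta, function(sm)
    data.table::data.table(target_id = sm$target_id, target_name = sm$target_name,
                           target_class = sm$target_class,
                           target_group = sm$target_group)))
  tmeta <- rbind(tmeta, data.table::data.table(
    target_id = "CHEMBL_T999", target_name = "Decoy target",
    target_class = "Enzyme", target_group = "Unclassified"))
  recs <- list()
  for (r in seq_len(nrow(potencies))) {
    k <- sample.int(max_replicates, 1L)
    eps <- pmax(pmin(stats::rnorm(k, 0, noise_sd), 0.45), -0.45)
    eps <- eps - mean(eps)
    ti <- tmeta[target_id == potencies$target_id[r]]
    recs[[r]] <- data.table::data.table(
      compound_id = potencies$compound_id[r],
      smiles = smiles_of[[potencies$compound_id[r]]],
      target_id = potencies$target_id[r],
      target_name = ti$target_name, target_class = ti$target_class,
      target_group = ti$target_group,
      organism = "Homo sapiens", assay_relationship = "D",
      assay_confidence = 9L, assay_target_type = "SINGLE PROTEIN",
      measurement = potencies$measurement[r], relation = "=",
      value = 10^(9 - (potencies$ppot_true[r] + eps)), units = "nM")
  }
  activities <- data.table::rbindlist(recs)

  # records violating one curation criterion each (planted exclusions)
  junk_base <- activities[1L]
  junk <- data.table::rbindlist(lapply(seq_len(7L), function(i) data.table::copy(junk_base)))
  junk[, compound_id := sprintf("JUNK%02d", seq_len(.N))]
  junk[1L, organism := "Mus musculus"]
  junk[2L, assay_target_type := "PROTEIN COMPLEX"]
  junk[3L, assay_relationship := "H"]
  junk[4L, assay_confidence := 8L]
  junk[5L, measurement := "EC50"]
  junk[6L, relation := ">"]
  junk[7L, smiles := "C1CC"]
  activities <- rbind(activities, junk)
  activities <- activities[sample.int(nrow(activities))]

  # --- X-ray mapping and ligand tables ---------------------------------
  uniprot_of <- stats::setNames(
    vapply(series_meta, function(sm) sm$uniprot, ""),
    vapply(series_meta, function(sm) sm$target_id, ""))
  maps <- list(); ligs <- list()
  xray <- rep(FALSE, nrow(truth_cliffs))
  xray_both <- rep(FALSE, nrow(truth_cliffs))
  used_pdb <- character(0)
  rand_pdb <- function() {
    repeat {
      id <- paste0(sample(1:9, 1L),
                   paste(sample(c(LETTERS, 0:9), 3L, replace = TRUE), collapse = ""))
      if (!(id %in% used_pdb)) { used_pdb <<- c(used_pdb, id); return(id) }
    }
  }
  if (nrow(truth_cliffs)) {
    for (r in seq_len(nrow(truth_cliffs))) {
      if (stats::runif(1L) >= fraction_xray) next
      xray[r] <- TRUE
      tid <- truth_cliffs$target_id[r]
      p1 <- rand_pdb()
      maps[[length(maps) + 1L]] <- data.table::data.table(
        target_chembl_id = tid, uniprot = uniprot_of[[tid]], pdb_id = p1)
      ligs[[length(ligs) + 1L]] <- data.table::data.table(
        pdb_id = p1, ligand_code = "LG1",
        smiles = smiles_of[[truth_cliffs$cpd_id_2[r]]])
      if (stats::runif(1L) < 0.15) {
        xray_both[r] <- TRUE
        p2 <- rand_pdb()
        maps[[length(maps) + 1L]] <- data.table::data.table(
          target_chembl_id = tid, uniprot = uniprot_of[[tid]], pdb_id = p2)
        ligs[[length(ligs) + 1L]] <- data.table::data.table(
          pdb_id = p2, ligand_code = "LG2",
          smiles = smiles_of[[truth_cliffs$cpd_id_1[r]]])
      }
    }
  }
  # one unrelated entry: mapped structure whose ligand is no analog
  if (n_series >= 1L) {
    p0 <- rand_pdb()
    maps[[length(maps) + 1L]] <- data.table::data.table(
      target_chembl_id = series_meta[[1L]]$target_id,
      uniprot = series_meta[[1L]]$uniprot, pdb_id = p0)
    ligs[[length(ligs) + 1L]] <- data.table::data.table(
      pdb_id = p0, ligand_code = "EOH", smiles = "OCC")
  }
  mappings <- if (length(maps)) data.table::rbindlist(maps) else
    data.table::data.table(target_chembl_id = character(0),
                           uniprot = character(0), pdb_id = character(0))
  ligands <- if (length(ligs)) data.table::rbindlist(ligs) else
    data.table::data.table(pdb_id = character(0), ligand_code = character(0),
                           smiles = character(0))
  truth_cliffs[, `:=`(has_xray = xray, xray_both = xray_both)]

  out <- list(
    activities = activities, mappings = mappings, ligands = ligands,
    truth = list(pairs = truth_pairs[, .(compound_a, compound_b, kind, swap,
                                         target_id, measurement, delta_ppot)],
                 cliffs = truth_cliffs, decoys = decoy_ids,
                 potencies = potencies)
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- file.path(out_dir, c("activities.csv", "mappings.csv", "ligands.csv"))
    data.table::fwrite(activities, paths[1L])
    data.table::fwrite(mappings, paths[2L])
    data.table::fwrite(ligands, paths[3L])
    out$paths <- stats::setNames(paths, c("activities", "mappings", "ligands"))
  }
  out
}

#' Generate random small organic molecules
#'
#' Draws random connected molecular graphs (random trees over C/N/O/S
#' with occasional ring closures and double bonds, valence-respecting),
#' canonicalizes them, and optionally adds, for a fraction of the
#' molecules, a single-atom variant (random admissible substitution or
#' positional exchange) so that batches are rich in true analog pairs.
#' Intended for property-based testing of the pair enumeration against
#' the oracle; randomness comes from the caller's RNG state.
#'
#' @param n number of base molecules.
#' @param min_heavy,max_heavy heavy-atom count range (default 5..10).
#' @param p_variant probability of adding a perturbed sibling per base
#'   molecule (default 0.5).
#' @return named list of `sam_molecule` with pairwise distinct canonical
#'   keys.
#' @export
random_molecules <- function(n, min_heavy = 5L, max_heavy = 10L,
                             p_variant = 0.5) {
  elems <- c("C", "N", "O", "S")
  capacity <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  graphs <- list()
  for (b in seq_len(n)) {
    na <- sample(min_heavy:max_heavy, 1L)
    el <- sample(elems, na, replace = TRUE, prob = c(0.6, 0.16, 0.16, 0.08))
    bsum <- integer(na)
    bonds <- list()
    for (i in seq_len(na)[-1L]) {
      open <- which(bsum[seq_len(i - 1L)] < capacity[el[seq_len(i - 1L)]])
      j <- if (length(open) == 1L) open else sample(open, 1L)
      bonds[[length(bonds) + 1L]] <- c(j, i, 1L)
      bsum[i] <- bsum[i] + 1L
      bsum[j] <- bsum[j] + 1L
    }
    bmat <- do.call(rbind, bonds)
    # occasional ring closure between non-adjacent open atoms
    if (stats::runif(1L) < 0.4) {
      open <- which(bsum < capacity[el])
      if (length(open) >= 2L) {
        cand <- utils::combn(open, 2L)
        adj <- paste(bmat[, 1L], bmat[, 2L])
        ok <- !(paste(cand[1L, ], cand[2L, ]) %in% adj)
        if (any(ok)) {
          pick <- cand[, which(ok)[sample.int(sum(ok), 1L)]]
          bmat <- rbind(bmat, c(pick[1L], pick[2L], 1L))
          bsum[pick] <- bsum[pick] + 1L
        }
      }
    }
    # occasional double bond where both ends have spare valence
    if (stats::runif(1L) < 0.35) {
      ok <- bsum[bmat[, 1L]] < capacity[el[bmat[, 1L]]] &
            bsum[bmat[, 2L]] < capacity[el[bmat[, 2L]]]
      if (any(ok)) {
        k <- which(ok)[sample.int(sum(ok), 1L)]
        bmat[k, 3L] <- 2L
      }
    }
    g <- list(atoms = data.frame(elem = el, charge = 0L, parity = 0L,
                                 stringsAsFactors = FALSE),
              bonds = data.frame(a1 = bmat[, 1L], a2 = bmat[, 2L],
                                 order = bmat[, 3L], stereo = 0L))
    graphs[[length(graphs) + 1L]] <- g
    if (stats::runif(1L) < p_variant) {
      g2 <- .perturb_graph(g)
      if (!is.null(g2)) graphs[[length(graphs) + 1L]] <- g2
    }
  }
  sdf <- unlist(lapply(seq_along(graphs), function(i)
    write_molblock(graphs[[i]], title = as.character(i))))
  keys <- ob_can_from_sdf(sdf, length(graphs))
  keys <- unique(keys[!is.na(keys)])
  if (!length(keys)) return(list())
  molecules_from_keys(keys, ids = sprintf("R%03d", seq_along(keys)))
}

# One random admissible single-atom perturbation (substitution or
# positional exchange); NULL when no site qualifies.
.perturb_graph <- function(g) {
  sums <- bond_order_sums(g)
  n <- nrow(g$atoms)
  moves <- list()
  ds <- directed_swaps(SAM_SWAPS)
  for (i in seq_len(n)) {
    for (h in which(ds$from == g$atoms$elem[i])) {
      if (site_accepts(g, i, ds$to[h], sums)) {
        moves[[length(moves) + 1L]] <- c("sub", i, ds$to[h])
      }
    }
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      x <- g$atoms$elem[i]; y <- g$atoms$elem[j]
      if (x == y || is.na(swap_label(x, y))) next
      if (site_accepts(g, i, y, sums) && site_accepts(g, j, x, sums)) {
        moves[[length(moves) + 1L]] <- c("exch", i, j)
      }
    }
  }
  if (!length(moves)) return(NULL)
  mv <- moves[[sample.int(length(moves), 1L)]]
  if (mv[[1L]] == "sub") {
    g$atoms$elem[as.integer(mv[[2L]])] <- mv[[3L]]
  } else {
    i <- as.integer(mv[[2L]]); j <- as.integer(mv[[3L]])
    tmp <- g$atoms$elem[i]
    g$atoms$elem[i] <- g$atoms$elem[j]
    g$atoms$elem[j] <- tmp
  }
  g
}
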