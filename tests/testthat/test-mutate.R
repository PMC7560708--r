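test_that("single-atom mutation matches textbook transformations", {
  mols <- std_set(AZOLES)
  pyr <- mols$pyridine
  n_pos <- which(pyr$graph$atoms$elem == "N")
  expect_equal(mutate_atom(pyr, n_pos, "C")$canonical_key,
               mols$benzene$canonical_key)
  fur <- mols$furan
  o_pos <- which(fur$graph$atoms$elem == "O")
  expect_equal(mutate_atom(fur, o_pos, "S")$canonical_key,
               mols$thiophene$canonical_key)
})

test_that("valence-violating mutants do not exist", {
  quat <- standardize("CC[N+](C)(C)C", "quat")
  np <- which(quat$graph$atoms$elem == "N")
  # charged site: never mutated
  expect_null(mutate_atom(quat, np, "O"))
  # neutral carbon with four bonds cannot become oxygen
  neo <- standardize("CC(C)(C)C", "neopentane")
  cq <- which(vapply(seq_len(neo$n_heavy), function(i)
    sum(neo$graph$bonds$order[neo$graph$bonds$a1 == i | neo$graph$bonds$a2 == i]),
    0L) == 4L)
  expect_null(mutate_atom(neo, cq[1], "O"))
  expect_null(mutate_atom(neo, cq[1], "N"))
})

test_that("inadmissible swaps are a caller error, not a silent no-op", {
  ben <- standardize("c1ccccc1", "benzene")
  expect_error(mutate_atom(ben, 1L, "S"))   # S-C is not admissible
  expect_error(mutate_atom(ben, 1L, "C"))   # no-op "swap"
  expect_error(mutate_atom(ben, 99L, "N"))
})

test_that("mutant enumeration deduplicates symmetry-equivalent sites", {
  mols <- std_set(AZOLES)
  mk_benzene <- enumerate_mutant_keys(mols$benzene, "N-C")
  expect_equal(nrow(mk_benzene), 1L)          # all six carbons equivalent
  expect_equal(mk_benzene$key, mols$pyridine$canonical_key)

  mk_pyr <- enumerate_mutant_keys(mols$pyridine, "N-C")
  expect_equal(nrow(mk_pyr), 4L)              # benzene + three diazines
  expect_true(mols$benzene$canonical_key %in% mk_pyr$key)
  diazines <- vapply(mols[c("pyridazine", "pyrimidine", "pyrazine")],
                     function(m) m$canonical_key, "")
  expect_setequal(setdiff(mk_pyr$key, mols$benzene$canonical_key),
                  unname(diazines))
})

test_that("a single-atom molecule has a single mutant", {
  m <- standardize("C", "methane")
  mk <- enumerate_mutant_keys(m, "O-C")
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$key, "O")
})

test_that("dedup count equals brute force over all atoms", {
  mols <- std_set(c(AZOLES, anisole = "COc1ccccc1", lutidine = "Cc1cccnc1C"))
  for (m in mols) {
    mk <- enumerate_mutant_keys(m, SAM_SWAPS)
    # brute force: every atom, every admissible directed swap, one at a time
    seen <- character(0)
    for (i in seq_len(m$n_heavy)) {
      from <- m$graph$atoms$elem[i]
      for (lb in SAM_SWAPS) {
        pair <- strsplit(lb, "-", fixed = TRUE)[[1]]
        if (!(from %in% pair)) next
        to <- setdiff(pair, from)
        mut <- tryCatch(mutate_atom(m, i, to), error = function(e) NULL)
        if (!is.null(mut)) seen <- c(seen, paste(from, to, mut$canonical_key))
      }
    }
    expect_equal(nrow(mk), length(unique(seen)), label = m$id)
  }
})

test_that("mutation is reversible through the inverse directed swap", {
  mols <- std_set(AZOLES)
  set.seed(7)
  for (m in mols) {
    mk <- enumerate_mutant_keys(m, SAM_SWAPS)
    for (r in seq_len(nrow(mk))) {
      mut <- standardize(mk$key[r], "mut")
      back <- enumerate_mutant_keys(mut, mk$label[r])
      expect_true(m$canonical_key %in%
                    back$key[back$from == mk$to[r] & back$to == mk$from[r]],
                  label = sprintf("%s -> %s", m$id, mk$key[r]))
    }
  }
})

test_that("mutant keys are invariant to parent atom ordering", {
  mols <- std_set(c(pyridine = "c1ccncc1", cresol = "Cc1ccc(O)cc1"))
  set.seed(13)
  for (m in mols) {
    base <- sort(paste(enumerate_mutant_keys(m, SAM_SWAPS)$label,
                       enumerate_mutant_keys(m, SAM_SWAPS)$key))
    for (rep in 1:3) {
      remol <- standardize(shuffle_smiles(m), m$id)
      mk <- enumerate_mutant_keys(remol, SAM_SWAPS)
      expect_equal(sort(paste(mk$label, mk$key)), base)
    }
  }
})

test_that("positional exchange produces the expected isomer", {
  pyridazine <- standardize("c1ccnnc1", "pyridazine")
  others <- std_set(c(pyrimidine = "c1cncnc1", pyrazine = "c1cnccn1"))
  ex <- exchange_key_table(list(pyridazine))
  expect_true(others$pyrimidine$canonical_key %in% ex$key)
  expect_true(others$pyrazine$canonical_key %in% ex$key)
  # direct call form
  g <- pyridazine$graph
  npos <- which(g$atoms$elem == "N")[1]
  cpos <- which(g$atoms$elem == "C")[1]
  k <- exchange_atoms(pyridazine, npos, cpos)
  expect_false(is.na(k))
})
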