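test_that("records failing one criterion are tallied under it", {
  recs <- rbind(
    make_record("K1"),                                        # kept
    make_record("X1", organism = "Mus musculus"),
    make_record("X2", assay_target_type = "PROTEIN COMPLEX"),
    make_record("X3", assay_relationship = "H"),
    make_record("X4", assay_confidence = 8L),
    make_record("X5", measurement = "EC50"),
    make_record("X6", relation = ">"),
    make_record("X7", units = "ug.mL-1"),
    make_record("X8", value = -5),
    make_record("X9", smiles = "C1CC")
  )
  res <- filter_records(recs)
  expect_equal(res$kept$compound_id, "K1")
  expect_equal(unname(res$tally[c("organism", "target_type", "relationship",
                                  "confidence", "measurement", "relation",
                                  "units", "value", "structure")]),
               rep(1L, 9L))
  # partition property
  expect_equal(nrow(res$kept) + sum(res$tally), nrow(recs))
  expect_equal(nrow(res$kept) + nrow(res$exclusions), nrow(recs))
})

test_that("a record failing several criteria lands on the first", {
  rec <- make_record("X", organism = "Mus musculus", relation = ">")
  res <- filter_records(rec)
  expect_equal(res$exclusions$reason, "organism")
})

test_that("kept records carry canonical structures and molecules", {
  recs <- rbind(make_record("A", smiles = "c1ccncc1"),
                make_record("B", smiles = "n1ccccc1", compound_id = "B"))
  res <- filter_records(recs)
  expect_equal(res$kept$canonical_smiles[1], res$kept$canonical_smiles[2])
  expect_setequal(names(res$molecules), c("A", "B"))
  # an id with two conflicting structures is excluded
  recs2 <- rbind(make_record("A", smiles = "c1ccncc1"),
                 make_record("A", smiles = "c1ccccc1"))
  res2 <- filter_records(recs2)
  expect_equal(nrow(res2$kept), 0L)
  expect_equal(unname(res2$tally["structure"]), 2L)
})

test_that("small fragments are excluded at the curation floor", {
  res <- filter_records(make_record("T", smiles = "CCO"))
  expect_equal(res$exclusions$reason, "structure")
  res2 <- filter_records(make_record("T", smiles = "CCO"), min_heavy_atoms = 1L)
  expect_equal(nrow(res2$kept), 1L)
})

test_that("potency conversion follows the molar log scale", {
  expect_equal(to_ppot(10, "nM"), 8.0)
  expect_equal(to_ppot(1, "uM"), 6.0)
  expect_equal(to_ppot(1, "µM"), 6.0)
  expect_equal(to_ppot(1, "M"), 0.0)
  expect_equal(to_ppot(c(100, 1), c("nM", "uM")), c(7, 6))
  expect_error(to_ppot(10, "mg/mL"), class = "UnknownUnits")
  expect_error(to_ppot(-1, "nM"))
})

test_that("replicates aggregate by arithmetic mean of log potencies", {
  recs <- rbind(make_record("A", value = 10), make_record("A", value = 100))
  agg <- aggregate_potencies(filter_records(recs)$kept)
  expect_equal(agg$potencies$ppot, 7.5)       # span exactly 1.0: kept
  expect_equal(agg$potencies$n_records, 2L)

  wide <- rbind(make_record("A", value = 10), make_record("A", value = 10000))
  agg2 <- aggregate_potencies(filter_records(wide)$kept)
  expect_equal(nrow(agg2$potencies), 0L)       # span 3.0: discarded
  expect_equal(nrow(agg2$discarded), 1L)
})

test_that("Ki and IC50 are never mixed", {
  recs <- rbind(make_record("A", measurement = "Ki", value = 10),
                make_record("A", measurement = "IC50", value = 1000))
  agg <- aggregate_potencies(filter_records(recs)$kept)
  expect_equal(nrow(agg$potencies), 2L)
  expect_setequal(agg$potencies$measurement, c("Ki", "IC50"))
  expect_setequal(agg$potencies$ppot, c(8, 6))
})

test_that("lowering a molar value never decreases the group potency", {
  set.seed(31)
  for (rep in 1:10) {
    vals <- 10^stats::runif(3, 0, 3)
    recs <- do.call(rbind, lapply(vals, function(v) make_record("A", value = v)))
    base <- aggregate_potencies(filter_records(recs)$kept, max_span = Inf)
    k <- sample.int(3, 1)
    vals2 <- vals; vals2[k] <- vals2[k] / (1 + stats::runif(1, 0, 9))
    recs2 <- do.call(rbind, lapply(vals2, function(v) make_record("A", value = v)))
    mod <- aggregate_potencies(filter_records(recs2)$kept, max_span = Inf)
    expect_gte(mod$potencies$ppot, base$potencies$ppot)
  }
})

test_that("the activity reader auto-detects delimiters and extra columns", {
  rec <- make_record("A1")
  rec$extra <- "x"
  csv <- tempfile(fileext = ".csv"); tsv <- tempfile(fileext = ".tsv")
  utils::write.csv(rec, csv, row.names = FALSE)
  utils::write.table(rec, tsv, sep = "\t", row.names = FALSE)
  expect_equal(read_activity_table(csv)$compound_id, "A1")
  expect_equal(read_activity_table(tsv)$compound_id, "A1")
  expect_true("extra" %in% names(read_activity_table(csv)))
  unlink(c(csv, tsv))
  expect_error(read_activity_table(rec[, -2]), "smiles")
})
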