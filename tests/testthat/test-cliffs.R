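make_target_pairs <- function(ppot_a, ppot_b, measurement = "Ki") {
  mols <- std_set(AZOLES[c("benzene", "pyridine")])
  pairs <- find_replacement_pairs(mols)
  pot <- data.frame(compound_id = c("benzene", "pyridine"), target_id = "T1",
                    measurement = measurement, ppot = c(ppot_a, ppot_b),
                    n_records = 1L)
  list(pairs = restrict_to_shared_activity(pairs, pot), pot = pot)
}

test_that("the 100-fold boundary is inclusive", {
  at <- make_target_pairs(5.0, 7.0)       # exactly 100-fold
  cl <- call_cliffs(at$pairs, at$pot)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$delta_ppot, 2.0)
  below <- make_target_pairs(5.0, 6.9)    # ~79-fold
  expect_equal(nrow(call_cliffs(below$pairs, below$pot)), 0L)
  big <- make_target_pairs(4.0, 8.5)
  expect_equal(call_cliffs(big$pairs, big$pot)$delta_ppot, 4.5)
})

test_that("the less potent analog is listed first", {
  at <- make_target_pairs(8.1, 5.0)
  cl <- call_cliffs(at$pairs, at$pot)
  expect_equal(cl$cpd_id_1, "pyridine")
  expect_equal(cl$cpd_id_2, "benzene")
  expect_lt(cl$ppot_1, cl$ppot_2)
  expect_equal(cl$ac_type, "ar_AC")
  expect_equal(cl$mod_type, "N-C")
})

test_that("raising the threshold never adds cliffs; threshold 1 returns all", {
  at <- make_target_pairs(5.0, 7.5)
  ns <- vapply(c(1, 10, 100, 10^2.5, 1000, 1e4), function(f)
    nrow(call_cliffs(at$pairs, at$pot, fold_threshold = f)), 0L)
  expect_true(all(diff(ns) <= 0))
  expect_equal(ns[1], nrow(at$pairs))
  expect_equal(ns[4], 1L)   # inclusive at the exact ratio
  expect_equal(ns[5], 0L)
})

test_that("a pair member without a potency raises MissingPotency", {
  at <- make_target_pairs(5.0, 7.5)
  expect_error(call_cliffs(at$pairs, at$pot[1, ]), class = "MissingPotency")
})

test_that("summaries count by target group and modification type", {
  cl <- data.table::data.table(
    cpd_id_1 = c("a", "c", "e"), cpd_id_2 = c("b", "d", "f"),
    smiles_1 = "C", smiles_2 = "C",
    measurement = c("Ki", "Ki", "IC50"),
    ppot_1 = 5, ppot_2 = 7.5,
    target_name = "T", target_uniprot = "",
    target_chembl_id = c("T1", "T1", "T2"),
    target_class = "Enzyme", target_group = c("Protease", "Protease", "Kinase"),
    ac_type = c("ar_AC", "aw_AC", "ar_AC"),
    mod_type = "N-C", pdb_ids = c("1ABC", "", ""),
    delta_ppot = 2.5, xray_analog = "")
  s <- summarize_cliffs(cl)
  expect_equal(s$targets[measurement == "Ki"]$n, 2L)
  expect_equal(s$types_wide$Ki_ar_AC, c(1L, 0L, 0L, 0L))
  expect_equal(s$types_wide$Ki_aw_AC, c(1L, 0L, 0L, 0L))
  expect_equal(s$types_wide$IC50_ar_AC, c(1L, 0L, 0L, 0L))
  sx <- summarize_cliffs(cl, xray_only = TRUE)
  expect_equal(sum(sx$targets$n), 1L)
  expect_equal(sx$targets$target_group, "Protease")
  # degenerate input
  s0 <- summarize_cliffs(cl[0])
  expect_equal(nrow(s0$targets), 0L)
  expect_equal(sum(s0$types_wide$Ki_ar_AC), 0L)
})

test_that("the dataset round-trips through the published schema", {
  at <- make_target_pairs(5.0, 7.5)
  cl <- call_cliffs(at$pairs, at$pot,
                    target_info = data.frame(target_id = "T1",
                                             target_name = "Thrombin",
                                             target_class = "Enzyme",
                                             target_group = "Protease"))
  cl$pdb_ids[1] <- "1ABC;2DEF"
  path <- tempfile(fileext = ".csv")
  write_cliff_dataset(cl, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(header, samcliff:::CLIFF_COLUMNS)
  back <- read_cliff_dataset(path)
  expect_equal(as.data.frame(back[, samcliff:::CLIFF_COLUMNS, with = FALSE]),
               as.data.frame(cl[, samcliff:::CLIFF_COLUMNS, with = FALSE]))
  expect_equal(back$delta_ppot, cl$delta_ppot)
  unlink(path)
})

test_that("writing to an unwritable path raises WriteFailure", {
  at <- make_target_pairs(5.0, 7.5)
  cl <- call_cliffs(at$pairs, at$pot)
  expect_error(write_cliff_dataset(cl, "/nonexistent-dir/x/y.csv"),
               class = "WriteFailure")
})
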