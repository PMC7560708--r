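test_that("ligand matching compares canonical keys under the stereo mode", {
  cpd <- standardize("C[C@H](N)C(=O)O", "l_ala")
  same <- standardize("C[C@H](N)C(=O)O", "lig")
  partner <- standardize("C[C@H](O)C(=O)O", "lig2")   # N -> O analog
  ent <- standardize("C[C@@H](N)C(=O)O", "lig3")      # enantiomer
  expect_true(ligand_matches(same, cpd))
  expect_false(ligand_matches(partner, cpd))
  expect_true(ligand_matches(ent, cpd))                       # default: ignore
  expect_false(ligand_matches(ent, cpd, stereo_mode = "strict"))
  expect_true(ligand_matches(same, cpd, stereo_mode = "strict"))
})

make_cliff_row <- function(target = "T1", s1 = "Oc1ccccc1", s2 = "Nc1ccccc1") {
  k1 <- standardize(s1, "a")$canonical_key
  k2 <- standardize(s2, "b")$canonical_key
  data.table::data.table(
    cpd_id_1 = "a", cpd_id_2 = "b", smiles_1 = k1, smiles_2 = k2,
    measurement = "Ki", ppot_1 = 5, ppot_2 = 7.5,
    target_name = "T", target_uniprot = "", target_chembl_id = target,
    target_class = "Enzyme", target_group = "Protease",
    ac_type = "ar_AC", mod_type = "N-O", pdb_ids = "",
    delta_ppot = 2.5, xray_analog = "")
}

test_that("cliffs are annotated with matching structures of their target", {
  cl <- make_cliff_row()
  maps <- data.frame(target_chembl_id = c("T1", "T1", "T2"),
                     uniprot = c("P11111", "P11111", "P22222"),
                     pdb_id = c("1AAA", "2BBB", "3CCC"))
  ligs <- data.frame(pdb_id = c("1AAA", "2BBB", "3CCC"),
                     ligand_code = c("LG1", "LG2", "LG3"),
                     smiles = c("Nc1ccccc1",    # higher-potency analog
                                "CCCCO",        # unrelated
                                "Oc1ccccc1"))   # the analog, but on T2
  ann <- annotate_cliffs(cl, read_target_mappings(maps), read_pdb_ligands(ligs))
  expect_equal(ann$pdb_ids, "1AAA")       # no cross-target leakage from 3CCC
  expect_equal(ann$xray_analog, "higher")
  expect_equal(ann$target_uniprot, "P11111")
  expect_false(ann$xray_stereo_relaxed)
})

test_that("both analogs co-crystallized sets the both flag and sorts ids", {
  cl <- make_cliff_row()
  maps <- data.frame(target_chembl_id = "T1", uniprot = "P11111",
                     pdb_id = c("9ZZZ", "1AAA"))
  ligs <- data.frame(pdb_id = c("9ZZZ", "1AAA"), ligand_code = "LG",
                     smiles = c("Oc1ccccc1", "Nc1ccccc1"))
  ann <- annotate_cliffs(cl, read_target_mappings(maps), read_pdb_ligands(ligs))
  expect_equal(ann$pdb_ids, "1AAA;9ZZZ")
  expect_equal(ann$xray_analog, "both")
})

test_that("a target with no mapping keeps an empty PDB field", {
  cl <- make_cliff_row(target = "T9")
  maps <- data.frame(target_chembl_id = "T1", uniprot = "P1",
                     pdb_id = "1AAA")
  ligs <- data.frame(pdb_id = "1AAA", ligand_code = "LG", smiles = "CCCCN")
  ann <- annotate_cliffs(cl, read_target_mappings(maps), read_pdb_ligands(ligs))
  expect_equal(ann$pdb_ids, "")
  expect_equal(ann$xray_analog, "")
})

test_that("stereo-relaxed matches are flagged", {
  cl <- make_cliff_row(s1 = "C[C@H](N)C(=O)O", s2 = "C[C@H](O)C(=O)O")
  maps <- data.frame(target_chembl_id = "T1", uniprot = "P1", pdb_id = "1AAA")
  ligs <- data.frame(pdb_id = "1AAA", ligand_code = "LG",
                     smiles = "C[C@@H](O)C(=O)O")   # enantiomer of analog 2
  ann <- annotate_cliffs(cl, read_target_mappings(maps), read_pdb_ligands(ligs))
  expect_equal(ann$pdb_ids, "1AAA")
  expect_true(ann$xray_stereo_relaxed)
  strict <- annotate_cliffs(cl, read_target_mappings(maps),
                            read_pdb_ligands(ligs), stereo_mode = "strict")
  expect_equal(strict$pdb_ids, "")
})

test_that("invalid PDB ids are dropped by the mapping reader", {
  maps <- data.frame(target_chembl_id = "T1", uniprot = "P1",
                     pdb_id = c("1abc", "TOOLONG", "1A-B"))
  expect_warning(m <- read_target_mappings(maps), "invalid")
  expect_equal(m$pdb_id, "1ABC")   # lower case accepted, stored upper
})

test_that("X-ray counting agrees between annotation and summary", {
  cl <- rbind(make_cliff_row(), make_cliff_row(target = "T9"))
  maps <- data.frame(target_chembl_id = "T1", uniprot = "P1", pdb_id = "1AAA")
  ligs <- data.frame(pdb_id = "1AAA", ligand_code = "LG", smiles = "Nc1ccccc1")
  ann <- annotate_cliffs(cl, read_target_mappings(maps), read_pdb_ligands(ligs))
  sx <- summarize_cliffs(ann, xray_only = TRUE)
  expect_equal(sum(sx$targets$n), sum(nzchar(ann$pdb_ids)))
})
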