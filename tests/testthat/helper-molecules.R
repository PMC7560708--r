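# Shared fixtures: small named molecule sets built in code.

AZOLES <- c(
  benzene = "c1ccccc1", pyridine = "c1ccncc1", phenol = "Oc1ccccc1",
  aniline = "Nc1ccccc1", furan = "c1ccoc1", thiophene = "c1ccsc1",
  pyridazine = "c1ccnnc1", pyrimidine = "c1cncnc1", pyrazine = "c1cnccn1"
)

std_set <- function(smiles) {
  res <- standardize_compounds(smiles)
  expect_equal(nrow(res$failures), 0L)
  res$molecules
}

# a small activity table builder (all curation criteria satisfied unless
# overridden)
make_record <- function(compound_id = "C1", smiles = "c1ccncc1",
                        target_id = "T1", target_name = "Target one",
                        target_class = "Enzyme", target_group = "Kinase",
                        organism = "Homo sapiens", assay_relationship = "D",
                        assay_confidence = 9L,
                        assay_target_type = "SINGLE PROTEIN",
                        measurement = "Ki", relation = "=", value = 10,
                        units = "nM") {
  data.frame(compound_id = compound_id, smiles = smiles, target_id = target_id,
             target_name = target_name, target_class = target_class,
             target_group = target_group, organism = organism,
             assay_relationship = assay_relationship,
             assay_confidence = assay_confidence,
             assay_target_type = assay_target_type, measurement = measurement,
             relation = relation, value = value, units = units,
             stringsAsFactors = FALSE)
}

# unordered (a, b, kind, swap) view of a pair table, for set comparison
pair_set <- function(pairs) {
  df <- as.data.frame(pairs)[, c("compound_a", "compound_b", "kind", "swap")]
  df <- df[order(df$compound_a, df$compound_b, df$kind, df$swap), ]
  rownames(df) <- NULL
  df
}
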