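# samcliff

Systematic identification of **activity cliffs formed by single-atom
modifications** (sam_ACs) in compound-activity data, with association of
cliffs to X-ray complex structures.

An activity cliff is a pair of structurally analogous active compounds
with a large potency difference. The extreme case handled here: the two
analogs differ by exactly one heavy atom, either

* an **atom replacement** (`ar_AC`) — one position changes element, with
  the admissible replacements N-C, O-C, N-O and S-O — or
* an **atom walk** (`aw_AC`) — identical molecular formulas, one
  heteroatom relocated (an admissible element pair exchanging
  positions).

A pair qualifies as a sam_AC when both analogs have curated potency
(pKi or pIC50, never mixed) for the same target and

```
delta_pPot = |pPot_A - pPot_B| >= log10(fold) = 2.0   (fold = 100, inclusive)
```

The package curates ChEMBL-style activity tables to high-confidence
records (human, single protein, direct assay relationship "D",
confidence 9, Ki/IC50 with "=" relation, valid structures), aggregates
replicates on the log scale, enumerates analog pairs with an indexed
canonical-key join over single-atom mutants (no all-pairs graph
comparison), calls cliffs, and matches co-crystallized ligands from
local PDB mapping tables by canonical-SMILES identity. A synthetic
benchmark generator with oracle-certified planted truth makes the whole
pipeline testable offline. Intended users: medicinal/computational
chemists mining SAR data for critical atom positions, and method
developers needing reproducible sam_AC datasets.

Structure standardization and canonical SMILES come from OpenBabel
(`obabel` must be on the PATH); everything else is R (data.table).

## Worked example

```r
library(samcliff)

## a single molecule and its single-atom mutants
m <- standardize("c1ccncc1", "pyridine")
m
#> <sam_molecule> pyridine
#>   key: c1cccnc1
#>   formula: C5N (6 heavy atoms)
enumerate_mutant_keys(m, "N-C")
#>   parent_id site from to label      key
#> 1  pyridine    1    C  N   N-C c1ccncn1
#> 2  pyridine    4    C  N   N-C c1ccnnc1
#> 3  pyridine    2    C  N   N-C n1ccncc1
#> 4  pyridine    5    N  C   N-C c1ccccc1
```

Pyridine has four distinct single-atom analogs under N-C: the three
diazines (C→N at the three symmetry-distinct carbons) and benzene
(N→C). Any compound set containing one of those keys forms an `ar`
pair with pyridine; two compounds sharing a mutant key under the same
directed swap form an `aw` pair (e.g. the three diazines pair with each
other: one ring nitrogen walks).

```r
## end-to-end on a synthetic fixture with planted truth
fx  <- generate_fixture(n_series = 6, seed = 9)
res <- run_sam_pipeline(fx$activities, fx$mappings, fx$ligands)
nrow(res$potencies); nrow(res$pairs); nrow(res$cliffs)
#> [1] 25
#> [1] 17
#> [1] 8

res$cliffs[1:2, c("cpd_id_1", "cpd_id_2", "smiles_1", "smiles_2",
                  "measurement", "ppot_1", "ppot_2", "mod_type", "pdb_ids")]
#>    cpd_id_1 cpd_id_2     smiles_1     smiles_2 measurement   ppot_1    ppot_2 mod_type   pdb_ids
#> 1: CPD00001 CPD00002 ClCCc1ccccc1 ClCCc1ccccn1        IC50 5.518401  8.139152      N-C      2L37
#> 2: CPD00001 CPD00003 ClCCc1ccccc1 ClCCc1cccnc1        IC50 5.518401 11.113917      N-C      19OU
```

Each row is one sam_AC: the two analogs (less potent first), their
canonical SMILES, log-unit potencies, the modification type, and the
PDB entries whose co-crystallized ligand is one of the analogs. The
summary views count cliffs by target group and by kind/modification
type:

```r
cat(paste(samcliff:::format_summary(res$summary), collapse = "\n"))
#> Cliffs by measurement / target class / target group:
#>  measurement         target_class   target_group n
#>         IC50               Enzyme Oxidoreductase 6
#>         IC50 Epigenetic regulator         Eraser 2
#>
#> Cliffs by measurement / kind / modification type:
#>  mod_type IC50_ar_AC IC50_aw_AC Ki_ar_AC Ki_aw_AC
#>       N-C          3          3        0        0
#>       O-C          0          1        0        0
#>       N-O          1          0        0        0
#>       S-O          0          0        0        0
```

Real data enters through the same interfaces: an activity CSV/TSV
(columns `compound_id, smiles, target_id, target_name, target_class,
target_group, organism, assay_relationship, assay_confidence,
assay_target_type, measurement, relation, value, units`), and optional
`mappings.csv` (`target_chembl_id, uniprot, pdb_id`) and `ligands.csv`
(`pdb_id, ligand_code, smiles`) tables. `write_cliff_dataset()` emits
the dataset schema; `read_cliff_dataset()` is its inverse.

A command-line wrapper lives at `inst/scripts/samcliff.R`:

```sh
Rscript inst/scripts/samcliff.R simulate --series 6 --seed 9 --out fx
Rscript inst/scripts/samcliff.R run --activities fx/activities.csv \
    --mappings fx/mappings.csv --ligands fx/ligands.csv --fold 100 --out out
```

See the methods vignette (`vignettes/sam-activity-cliffs.Rmd`) for the
standardization rules, the mutant-key join and its equivalence to the
definitional pair test, and the benchmark design.

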