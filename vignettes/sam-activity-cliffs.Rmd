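---
title: "Identifying activity cliffs formed by single-atom modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying activity cliffs formed by single-atom modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An *activity cliff* (AC) is a pair of structurally similar active
compounds with a large potency difference against the same target. The
special case this package identifies is the most extreme form of
similarity: the two analogs differ by exactly **one heavy atom**. Two
mechanisms qualify:

* **atom replacement (`ar`)** — at one position, one element is replaced
  by another. Admissible replacements are the four element pairs
  `N-C`, `O-C`, `N-O` and `S-O`.
* **atom walk (`aw`)** — the two analogs share a molecular formula and
  differ only in the *position* of one heteroatom: an atom of element X
  at position *i* and an atom of element Y at position *j* trade places,
  with {X, Y} again one of the four admissible pairs.

A qualifying pair becomes a *single-atom-modification activity cliff*
(sam_AC) when the two analogs differ at least 100-fold in potency (pKi
or pIC50 difference of at least 2.0 log units) against a shared target
under the same measurement type. Because a single atom is the smallest
chemical change one can make, such cliffs isolate the contribution of
one atomic interaction to binding, and cliffs with X-ray structures of
the ligand–target complex are direct test cases for structure-based
rationalization (e.g. free-energy perturbation).

## Pipeline overview

`run_sam_pipeline()` chains five stages, each available separately:

1. **Curation** (`filter_records()`): raw activity records are filtered
   to high-confidence data — human assay organism, single-protein
   target, direct assay relationship ("D"), confidence score 9, Ki or
   IC50 measurement with an exact "=" relation, an accepted
   concentration unit, a positive value, and a structure that
   standardizes. Criteria are tested in that fixed order and each
   removed record is tallied under its *first* failing criterion, so
   exclusion tallies are reproducible. The order follows the data
   selection protocol: assay-level criteria first, then
   measurement-level, then structure.
2. **Aggregation** (`aggregate_potencies()`): one potency per
   (compound, target, measurement type), the arithmetic mean of
   per-record log-unit values (equivalently the geometric mean of the
   molar values). Ki and IC50 are well-defined but not mutually
   comparable measurements, so they are never mixed; a structural pair
   measured under different types is not a pair.
3. **Pair enumeration** (`find_replacement_pairs()`,
   `find_walk_pairs()`).
4. **Cliff calling** (`call_cliffs()`): inclusive threshold,
   `delta_ppot >= log10(fold_threshold)` at full floating-point
   precision.
5. **Structure association** (`annotate_cliffs()`): local mapping tables
   (target → UniProt → PDB ids; PDB id → ligand SMILES) are joined and a
   PDB entry is attached to a cliff when its ligand's canonical key
   equals either analog's key.

## Molecule standardization and canonical keys

All structure identity in the package is canonical-SMILES identity
("canonical key"), computed with OpenBabel. `standardize_compounds()`
applies, in order: parsing; charge neutralization where a chemically
sensible neutral form exists (quaternary ammonium and charge-separated
groups such as nitro keep their charges); isotope-label clearing (the
analysis concerns heavy-atom identity, not isotopic state); largest
organic fragment selection (salt/solvent stripping — the fragment with
the most heavy atoms containing at least one carbon; ties break to more
carbons, then first occurrence); valence sanitization against a
standard element/charge valence table; canonical key computation.
Records failing any step are rejected and counted, never silently kept.

Molecule graphs are stored in canonical-SMILES atom order, so atom
indices in this package *are* canonical atom ranks, and every derived
quantity is invariant to the input rendering of a SMILES string. This
is exercised directly in the test suite: rewriting every input SMILES
under a random atom renumbering and shuffling all input rows changes no
output byte.

Stereochemistry: tetrahedral and double-bond descriptors are retained
in canonical keys, so two compounds that differ in stereochemistry *in
addition to* a single-atom change do not pair — "only distinguished by
one atom" is read strictly. For crystallographic ligand matching the
default comparison is stereo-*insensitive* (chemical-component records
frequently omit or re-derive stereo); strict matching is available via
`stereo_mode = "strict"`, and matches that hold only under relaxation
are flagged `xray_stereo_relaxed`.

## The mutation primitive and the indexed join

A *mutant key* is the canonical key of the structure obtained by
replacing one atom's element (`mutate_atom()`). Mutation operates on
the kekulized graph: the element is substituted, implicit hydrogens are
re-derived from the valence model, and aromaticity is re-perceived on
the result (pyridine → benzene changes aromatic perception and must be
recomputed, not patched). Mutants violating the valence model (e.g.
oxygen at a four-bonded position) do not exist; charged sites are never
mutated, so compounds that remain charged after neutralization pair
only with equal-charge analogs. `enumerate_mutant_keys()` deduplicates
by (canonical key, directed swap), collapsing symmetry-equivalent sites
and annotating the lowest canonical rank.

Pair detection is an indexed join over mutant keys, near-linear in
total atom count, instead of an all-pairs graph comparison:

* **ar**: A and B form a replacement pair iff some mutant key of A
  equals B's own key. The join is symmetric because mutation is
  reversible — if A's site *i* mutates into B then B carries the swapped
  element at a site with the same bond-order sum, so the inverse
  mutation exists and returns A's key.
* **aw**: A and B form a walk pair iff they produce the *same* mutant
  key under the *same* directed swap X→Y at different positions. This
  is equivalent to the positional-exchange definition: if A has X at
  *i* and Y at *j*, mutating *i* gives the structure with Y at both
  positions; B (the exchange of A) reaches the identical structure by
  mutating *j*. Conversely, two parents of one shared mutant differ
  exactly by which of the two sites carries X, which is the exchange.
  A compound never pairs with itself: symmetric walk sites produce the
  same canonical key, and input compounds are required to have unique
  keys (`DuplicateStructure` otherwise; the pipeline pre-deduplicates,
  keeping the lexicographically first id).

The two kinds are disjoint by construction — a replacement shifts the
heavy-atom formula by one element pair, a walk preserves it.

Note on walks: a walk's swap pair is the pair of *exchanged* elements,
so nitrogen walks relative to carbon frameworks are `N-C`, oxygen walks
`O-C`, and an N/O or S/O exchange requires both heteroatoms in one
molecule. A sulfur atom exchanging with carbon (e.g. 2- vs
3-substituted thiophene) is *not* admissible, since S-C is not one of
the four pairs.

Site annotation: the `site` of a mutant (and `site_a`/`site_b` of a
pair) is the canonical atom rank of the modified position in the
*parent* compound. A walk modifies two positions per compound; the
reported rank is the minimum over the modified positions seen across
both detection directions — a deterministic, implementation-defined
annotation that does not participate in pair identity. If two compounds
are related by more than one distinct modification (possible in
symmetric molecules), the pair is reported once per distinct swap type.

## Brute-force oracle

`oracle_pairs()` is the definitional check: for every unordered pair it
tests all single mutations of one member against the other's canonical
key (ar), and all position pairs for an admissible element exchange
(aw). It shares only the canonicalization backend with the indexed
join, not the join or deduplication logic, and is quadratic in the
number of compounds — hence its enforced bound of 14 heavy atoms per
molecule. The acceptance suite compares the indexed join against the
oracle on 200 seeded random batches of valence-correct random molecular
graphs over C/N/O/S (8–12 molecules of 5–9 heavy atoms per batch, with
random single-atom siblings planted to keep batches pair-rich); at
these sizes the full comparison runs in well under five minutes on one
CPU while still exercising thousands of pair decisions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fold_threshold` | 100 | minimum potency ratio; inclusive, compared as `delta_ppot >= log10(fold)` in log units at full precision |
| `swaps` | all four | admissible element pairs, labels `N-C`, `O-C`, `N-O`, `S-O` |
| `max_span` | 1.0 log units | replicate sets spanning more than this are discarded entirely (kept at the boundary) |
| `min_heavy_atoms` | 4 | curation floor on standardized structure size; smaller fragments are degenerate for analog analysis |
| `stereo_mode` | `"ignore"` | ligand-matching stereo comparison; pairing always uses stereo-retaining keys |

The aggregation rule (mean of log values, span filter) is the main
curation choice the underlying data protocol leaves open: averaging all
replicates without a guard would let one discordant measurement
fabricate or destroy cliffs, while the 1.0 log-unit span keeps only
groups whose internal disagreement is below half the cliff criterion.
Both the rule's threshold and the fold threshold are arguments, not
constants.

## The synthetic benchmark

`generate_fixture()` emulates the input data shape end to end: an
activity table with assay metadata, replicate measurements in nM, junk
records violating each curation criterion, plus target→PDB mapping and
PDB→ligand tables. Each series takes one scaffold family (azines,
five-membered O/S heteroaromatics, para-substituted benzenes, acyclic
ether/amine linkers) and one substituent, producing compounds with
known ar and aw relations; unrelated carbon-only decoys are added. The
planted pair set is certified at generation time by the oracle, and
generation *fails* if any unplanned pair exists — decoy and
cross-series collisions cannot slip through silently.

Potencies are planted to make cliff recovery exactly decidable:

* compounds in a series are assigned potency levels by greedy proper
  coloring of the series' pair graph, spaced 2.8 log units in cliff
  series and 0 in non-cliff series, with a per-compound jitter of
  ±0.1 — so every planted pair difference is ≥ 2.6 or ≤ 0.2 log units,
  at least 0.6 away from the 2.0 boundary;
* per-record noise (sd 0.2, clamped at ±0.45) is centred within each
  replicate group, so the aggregated mean equals the planted value
  exactly and the span filter never triggers.

Under these conditions pipeline precision and recall are exactly 1.0
for pairs and cliffs; the acceptance suite verifies this on fixtures of
50 series under three seeds. What passing does *not* show: realistic
potency distributions (fully connected series can receive planted pKi
values beyond the physically plausible range), assay heterogeneity,
chemical diversity beyond what pair detection needs, or the behaviour
of the curation rules on the long tail of real database records.
Fixture X-ray tables co-crystallize the higher-potency analog for a
configurable fraction of planted cliffs (default 0.5, a further 15% of
those also getting the lower-potency analog); a ligand of compound X
legitimately matches *every* cliff of that target involving X, so the
planted table is a lower bound on annotations, and the acceptance
check asserts recovery of every planted entry rather than equality.

## Numerical and degenerate-input choices

* Boundary ties: "at least 100-fold" means a difference of exactly 2.0
  log units *is* a cliff. No floating-point slack is added anywhere;
  potencies are carried at full double precision from `9 - log10(nM)`.
* Output determinism: all outputs are sorted (cliffs by measurement,
  target, compound ids; PDB ids lexicographically within a field);
  the less potent analog is always `cpd_id_1`.
* Empty inputs: empty compound sets, pair lists and cliff lists flow
  through every stage and writer without error.
* Degenerate structures: single-atom molecules are valid at the
  chemistry layer (`standardize()` accepts any size; the curation floor
  is applied only in `filter_records()`).
* Units: only nM, µM/uM and M are converted; anything else is an
  exclusion, never a guess.

## Known limitations

* The chemistry backend is OpenBabel; canonical keys are OpenBabel
  canonical SMILES and are not interchangeable with other toolkits'
  canonical forms (all comparisons are internal, so this only matters
  when joining package output against externally canonicalized data —
  re-standardize first).
* Tautomers are not enumerated; two tautomeric renderings of one
  compound count as different structures. InChI-level identity is out
  of scope.
* Ligand matching operates on chemical-component SMILES, not on
  coordinate files; whether a matched ligand is bound to the mapped
  target chain specifically is the responsibility of the mapping-table
  producer.
* The full-scale study requires a pinned ChEMBL extract and PDB
  mapping tables as local files; this package ships only the
  desk-scale synthetic benchmark and consumes such extracts through
  the same CSV interfaces.
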