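# moonjelly

Morphometric dissimilarity and molecular species diagnosis for the
moon-jellyfish genus *Aurelia*.

Moon jellyfish are a textbook case of cryptic diversity: medusae from
opposite sides of the planet can look more alike than two animals from the
same collection lot, while molecular phylogenies split the genus into
dozens of species-level clades. This package implements, as a tested R
pipeline over synthetic data with known ground truth, the two analyses
that question addresses:

1. **Morphometric arm** — does medusa shape carry geographic signal once
   body size is removed? Traits are size-corrected by Lleonart
   standardization, `Y* = Y_i (f1_m / f1_i)^b`, where `f1` is bell
   diameter, `f1_m` its locality-group mean, and `b` the slope of the
   global log–log regression of the trait on `f1`. Missing measurements
   are estimated by inverting the same relation from the locality group
   (or the geographically closest group). After filtering uninformative
   features and 0–1 scaling, specimens are compared by Gower
   dissimilarity, ordinated by non-metric MDS (Kruskal stress-1) with
   weighted-average feature scores, and tested against geographic distance
   with a Mantel permutation test (9,999 permutations,
   `p = (1 + #{r_perm >= r_obs}) / (B + 1)`).

2. **Molecular arm** — species delimitation and diagnosis on annotated
   phylogenies. Species hypotheses pass screening when monophyletic with
   Goodman-Bremer support >= 2 and bootstrap frequency >= 75 on at least
   one single-marker tree, and are re-evaluated on the concatenated tree.
   Diagnostic characters are alignment columns whose most-parsimonious
   reconstructions place a state transformation on the species clade's
   stem branch; each is categorized as **ambiguous**, or unambiguous and
   **unique/non-unique** (derived state absent/present outside the clade)
   × **non-homoplastic/homoplastic** (single origin and no loss in every
   MPR, or not). Gaps are a fifth character state. Uncorrected p-distances
   are partitioned into intra- vs interspecific sets for barcode-gap
   assessment, and concatenated-matrix sequence sets are scored for
   completeness and chimerism.

The Fitch/Hartigan down-pass, the unit-cost dynamic program with exact MPR
enumeration, and the synapomorphy classifier are implemented here and
verified against exhaustive brute-force oracles; standard steps lean on
`ape`, `vegan` and `geosphere`. Intended users are systematists and
methods developers who want a transparent, fully reproducible version of
this analysis style to run on their own alignments, trees and trait
tables.

## Worked example

The `analysis/` scripts run the whole study on synthetic data. Step 1
simulates 80 medusae (8 localities × 10 specimens, 11 features, 10% MCAR
missingness); step 2 runs both morphometric arms:

```sh
$ Rscript analysis/01_simulate_morphology.R
$ Rscript analysis/02_morphospace.R
arm A (with estimation): 95 cells imputed, stress 0.115
  Mantel: r2 = 0.067, p = 0.0001 (B = 9999, n = 80)
arm B (complete cases, n = 25): stress 0.178
  Mantel: r2 = 0.050, p = 0.0087
features removed: g1, g2, g3
```

Read: the three size-independent noise features (`g1`–`g3`) are dropped by
the slope-significance filter; the planted geographic gradient surfaces as
a weak but significant Mantel correlation (r² ≈ 0.07) in both arms, while
ordination stress around 0.12 says the 2-D morphospace is a fair but far
from perfect summary — specimens from different localities overlap
broadly, exactly the situation in which medusa morphometrics fail to
separate species.

Steps 3–4 do the molecular arm (four markers on a known species tree with
planted diagnostic sites):

```sh
$ Rscript analysis/03_simulate_sequences.R
$ Rscript analysis/04_diagnosis_delimitation.R
...
16S: max intra 0.92%, min inter 3.38%, strict gap: TRUE
...
primary species hypotheses: 8 of 9 species
sequence sets: 30% complete, 49% non-chimeric, mean chimerism 59.8%
```

Every planted site is recovered with its exact category (the per-position
listing is written to `results/diagnosis/diagnostic_characters.tsv` with
0-based positions), all eight ingroup species pass the support screen, and
the sequence-set bookkeeping reproduces the generator's composition.

To run the pipeline on real data, point `read_trait_csv()`,
`read_alignment_fasta()`, `read_annotated_tree()` and `read_species_map()`
at your own files and call `run_morphospace()` / `run_diagnosis()` with a
`run_config()`.

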