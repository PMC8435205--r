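---
title: "Methods: morphometric dissimilarity and molecular species diagnosis in moon jellyfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric dissimilarity and molecular species diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moonjelly)
```

`moonjelly` implements the two analysis arms of an integrative-taxonomy
study of the moon-jellyfish genus *Aurelia*: a morphometric arm asking
whether medusa shape carries geographic signal once body size is removed,
and a molecular arm delimiting and diagnosing species on phylogenies. This
vignette explains the models, the tunable parameters, the synthetic-data
generators that stand in for the study's datasets, and the numerical and
design choices that were genuinely open.

## The morphometric model

Continuous and meristic medusa features vary with bell diameter (`f1`, cm).
Shape comparison therefore starts from a power-law allometry: for a feature
$Y$, $Y = a\,f1^{b}\,e^{\varepsilon}$, so $\log Y$ is linear in $\log f1$
with slope $b$. The slope is fitted by ordinary least squares over the
entire dataset, not per locality, because per-locality samples are too
small to estimate stable slopes. Natural logarithms are used; $b$ is
invariant to that choice, and the intercept is stored on the natural-log
scale.

**Size correction** (Lleonart standardization) rescales every specimen to
its locality group's mean bell diameter:
$$Y^{*} = Y_i \left(\frac{f1_m}{f1_i}\right)^{b},$$
where $f1_m$ is the mean `f1` of the specimen's locality group. After the
transformation the within-group log–log slope of $Y^{*}$ on `f1` is
approximately zero (a property the tests check by refitting).

**Missing-data estimation** inverts the same relation: a missing $Y_i$ is
estimated as $\bar{Y}_{g}\,(f1_i/f1_m)^{b}$, where $\bar{Y}_{g}$ is the raw
mean of the feature among the specimens of the group that measured it and
$f1_m$ the mean bell diameter of those same donors. Two readings of
"group average" are possible here — the raw mean (used) or the mean of
size-corrected values. The raw mean was chosen as the dimensionally direct
reading; its cost is that the estimator is exactly unbiased only when
$b = 1$ or when donors share one bell diameter (the mean of $a\,f1^b$ is
not $a\,\bar{f1}^b$ for curved allometries). At the noise levels and size
spreads simulated here the discrepancy is far below the residual noise,
and the test suite checks both the exact regimes and a 2-sigma recovery
envelope under 20% missingness. When a locality has no donor for a
feature, the geographically closest locality (great-circle distance
between locality centroids) donates instead; groups without coordinates
(aquarium material) must name a manual fallback chain, which is also the
hook for folding in morphological-similarity judgment, something we do not
attempt to automate.

**Feature filtering** removes, in this order: categorical features (too
ambiguous to score reliably); configured exclusions (defaults `f19`,
number of lobes, and `f20`, number of rhopalia, which asymmetric
development can distort); near-invariant features (variance below `1e-12`
— no threshold is canonical, so it is configurable); and features whose
slope p-value is at or above `alpha = 0.05` (no alpha is canonical either;
0.05 is the conventional choice and configurable). Remaining features are
min–max scaled to $[0,1]$.

**Dissimilarity and ordination.** Specimen dissimilarity is the Gower
coefficient: the mean over jointly observed features of
$|x_{if}-x_{jf}|/\mathrm{range}_f$ (ranges are 1 after scaling). Pairwise
deletion over the missingness mask lets the same code serve the
no-imputation arm. Ordination is non-metric MDS minimizing Kruskal
stress-1, run through `vegan`'s `monoMDS`/`metaMDS` with random restarts
plus a classical principal-coordinates start, keeping the best solution;
"MDS" alone under-determines the flavor, and NMDS with weighted-average
variable scores is the ordination tradition this analysis belongs to
(classical PCoA remains available via `stress1()` and `cmdscale` for
comparison). Feature contributions are mapped into the ordination as
weighted averages of specimen scores with the feature's scaled values as
weights — a feature with all-zero weight is flagged undefined rather than
placed.

**Geographic signal.** The Mantel statistic is the Pearson correlation $r$
between the off-diagonal entries of the morphological (Gower) and
geographic distance matrices, with a one-tailed (greater) permutation test:
$p = (1 + \#\{r_{\mathrm{perm}} \ge r_{\mathrm{obs}}\})/(B+1)$ with
$B = 9{,}999$ permutations by default. The $+1$ correction keeps $p$ off
zero. Geographic distance is plain Euclidean distance on raw decimal
degrees — deliberately, for fidelity to the analysis being reproduced,
even though great-circle distance is more natural; a `great_circle` flag
exists but is off by default. Aquarium specimens are excluded from the
Mantel test (they have no meaningful coordinates) but retained in the
ordination. $r^2$ is reported alongside $r$; we read the squared Mantel
correlation as the analysis's $R^2$, the only reading available without a
regression variant being specified. Group comparisons of individual
features use Welch's unequal-variance $t$ with Welch–Satterthwaite degrees
of freedom.

## The molecular model

**States.** Alignment columns live on a five-state alphabet: A, C, G, T
and the gap `-` as a fifth state, because alignable indels in rRNA and
ITS1 fragments are genuinely diagnostic. IUPAC ambiguity codes become
polymorphic subsets; `?` and `N` are full ambiguity. Treating gaps as
missing instead would shrink the diagnostic set; the choice is documented
so results can be compared under either convention.

**Parsimony machinery.** Column optimization is unit-cost (Fitch)
parsimony on the rooted input tree. The down-pass uses Hartigan's
state-frequency rule at multifurcations, which keeps the length exact for
polytomies; an exhaustive-enumeration oracle arbitrates in the tests. Most
parsimonious reconstructions (MPRs) are handled two ways: per-node MPR
state sets from a down/up dynamic program, and exact enumeration of all
MPRs by top-down backtracking over per-node optimal choices (ambiguous
terminals are resolved as part of the reconstruction). Enumeration is
exact and cheap because it only branches where MPRs genuinely differ; a
`max_mprs` cap guards pathological columns.

**Diagnostic characters.** For a species clade, a column is a candidate
diagnostic character when some MPR places a state transformation on the
clade's stem branch ending in the derived state of the clade's crown
optimization. The category scheme follows the four-way synapomorphy
classification used in species-diagnosis work:

* **ambiguous** — the presence of the stem transformation, or the identity
  of the derived state, varies across MPRs;
* otherwise unambiguous, and **unique** when the derived state occurs in
  no terminal outside the clade (else non-unique), crossed with
* **non-homoplastic** when in every MPR the derived state originates on
  exactly one branch and is never lost, else **homoplastic**.

The exact internal rules of the originating diagnosis software are not
published in the analysis being reproduced; our operationalization of
homoplasy — more than one origin in some MPR (the root counting as an
origin when assigned the state) or any loss on any edge — is the reading
that makes the three planted constructions below behave as their names
say. Stem-pair realizability is decided exactly from the dynamic program,
so ambiguity is never guessed from heuristics. A species that is
non-monophyletic on a marker is flagged and reported without characters
(not an error); a species absent from a marker is flagged `marker_absent`.
Single-terminal species are diagnosed against their pendant edge by
default (their stem exists even though a one-leaf clade has no crown
variation); a flag disables this. Positions are reported 0-based.

**Distances.** Uncorrected p-distance is the fraction of mismatched sites,
with two gap policies: pairwise deletion (default; sites with `-`, `?` or
`N` in either sequence are dropped) or gap-as-difference (gaps compared as
a fifth state). The convention of the commercial package used by the
original analysis is not stated, hence both. Distances partition into
intraspecific and interspecific sets; the barcode-gap report compares
max(intra) with min(inter) and reports either the strict gap margin or the
overlap interval. Histograms use 0.5-percentage-point bins by default (the
published histograms' granularity is unstated). No distance threshold is
ever used for delimitation — distances are a identification heuristic
here, not a species criterion.

**Delimitation.** A species hypothesis attains *primary* status when on at
least one single-marker tree its terminals are monophyletic with
Goodman-Bremer support ≥ 2 and bootstrap frequency ≥ 75 at the clade's
node (thresholds configurable; a missing support value fails the threshold
and is logged). Primary hypotheses are re-evaluated on the concatenated
tree: non-monophyly rejects, passing supports corroborate. The stem branch
length is recorded with its rank among the evaluated species rather than
cut at any value — branch-length judgment is ad hoc in the source analysis
and stays human. Species distribution is likewise surfaced as a locality
table, never auto-decided. Screening is monotone in both thresholds
(raising them never adds primary hypotheses), which the tests check.

**Sequence-set bookkeeping.** Concatenated-matrix terminals are scored for
completeness (present markers / total markers) and chimerism (sequences
from a different specimen / present sequences), summarized as the
percentage of complete sets, the percentage of non-chimeric sets, and the
mean chimerism among chimeric sets.

## What the generators emulate — and what they do not

`simulate_traits()` draws bell diameters log-normally per locality, builds
each feature as $a\,f1^{b}e^{\mathrm{geo}+\varepsilon}$, and masks cells
MCAR. Defaults are the study conditions the package is tested under: 8
localities on a latitudinal gradient, 10 specimens each, $\sigma = 0.05$
lognormal noise, a weak geographic gradient (geographic SD ≈ 0.4× noise
SD, chosen so the Mantel signal is weak — $r^2$ well under 0.1 — yet
significant at $B = 9{,}999$, the regime the morphometric arm reports) and
10% missingness, leaving roughly a third of specimens complete so the
no-imputation arm remains viable. The generator does **not** emulate
trait–trait covariance beyond the shared size axis, measurement error
structure, or non-MCAR damage patterns; passing tests therefore show the
pipeline recovers its own generating model, not that real medusae are this
well behaved.

`simulate_alignment()` evolves background sites along a known species tree
under an equal-rates model (each site changes with probability
$1-e^{-\mathrm{rate}\cdot bl}$ per branch, to a uniform other base) and
then **constructs** planted diagnostic sites, overwriting evolved columns,
so category ground truth is guaranteed regardless of the stochastic
background: a unique non-homoplastic site is the derived state on every
focal terminal and the ancestral state elsewhere; a unique homoplastic
site additionally reverts the second-deepest terminal of the focal ladder
(clades of fewer than four terminals make the stem transformation
genuinely ambiguous — verified by enumeration — so such plants are
rejected); a non-unique homoplastic site adds an independent origin on an
outside terminal chosen so that connecting the two occurrences in a single
origin would cost more than two gains (otherwise the reconstruction would
be ambiguous); an ambiguous site puts the derived state on exactly the two
shallowest focal terminals. The default species tree has eight ingroup
species of four terminals each plus an outgroup, with one sister pair
whose tip-to-tip path is ≈ 0.02 substitutions/site, emulating the ~2%
COI divergence between recently separated congeners; within-species
branches are 0.001. Simulated node supports (GB 10, bootstrap 100) make
every species screenable. GTR realism, rate heterogeneity across sites and
alignment error are deliberately out of scope.

`simulate_sequence_sets()` constructs (rather than samples) a terminal
composition: by default 100 terminals over 28 species and 4 markers with
exactly 30% complete sets, exactly 49% non-chimeric sets, and mean
chimerism among chimeric sets of 30.5/51 ≈ 59.8% — the closest composition
to 60% achievable with per-set ratios of denominator ≤ 4, a small
arithmetic fact worth recording.

## Numerical choices and degenerate inputs

* NMDS is deterministic given `seed`; 1- and 2-point inputs return stress
  0 directly; the returned stress never exceeds the PCoA start's stress.
* The permutation p-value is bounded below by $1/(B+1)$ and the Mantel
  test refuses $n < 4$.
* A specimen pair sharing no observed feature is an error (no silent NA).
* Constant features must be filtered before scaling; scaling guarantees 0
  and 1 are attained.
* All-gap sequence pairs have no comparable sites and error under pairwise
  deletion.
* Parsimony costs use an additive big-M for impossible leaf states; ties
  in MPR enumeration are resolved exhaustively, never arbitrarily.
* Every stochastic step flows through an explicit seed; reruns are
  byte-identical, which the pipeline tests assert via file checksums.

## Problem sizes

The test suite exercises: oracle agreement on 100+ random instances per
primitive (trees of 5–8 tips for exhaustive parsimony enumeration, up to
16 for monophyly); Mantel null calibration over 200 seeds at $B = 199$,
$n = 30$; trait recovery at $n = 100$ specimens; and full-pipeline runs at
80 specimens × 11 features and 33 terminals × 600 sites. The acceptance
script re-runs both arms at those same sizes with $B = 9{,}999$ for the
headline Mantel values. These sizes were chosen to mirror the scale of the
emulated study (about 150 measured medusae; 650-bp markers; 28 species)
while keeping exhaustive oracles exact.

## Known limitations

* The raw-group-mean imputation reading (above) is first-order, not exact,
  for curved allometries with heterogeneous donor sizes.
* Homoplasy categorization reflects this package's stated rule; other
  software may count reversals inside versus outside the focal clade
  differently, so cross-tool comparisons should re-derive categories from
  the listed positions, which are fully reproducible from (tree,
  alignment, clade).
* Morphological-similarity-guided imputation fallbacks are manual by
  design; the package will not guess them.
* The Mantel test inherits the usual caveats of distance-matrix
  correlation (non-independence of pairs); it is reported exactly as the
  emulated analysis used it, not endorsed as the best spatial statistic.
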