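---
title: "Methods: the tryptophan census, membrane-depth profiling, and conservation ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tryptophan census, membrane-depth profiling, and conservation ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpcensus)
```

# What the package computes

Tryptophan is one of the rarest amino acids, yet it is enriched in
membrane proteins, where its interfacial preference helps anchor
transmembrane (TM) segments in the bilayer. The ceramide synthases
(CerS) — ER-resident enzymes with seven TM domains (TMDs), a lumenal
N-terminus and a cytosolic C-terminus — carry an unusually high Trp
content, distributed asymmetrically toward the ER-lumenal side in the
family members that contain a Hox-like domain. `trpcensus` implements
the quantitative backbone of that kind of analysis as a tested,
download-free pipeline:

1. a **composition census** of protein sequence sets stratified by
   TMD count and family membership, after redundancy filtering;
2. **membrane-depth profiling** of helical structure models: place a
   planar membrane slab, fix its sign convention, and measure signed
   Calpha depths relative to the bilayer center;
3. **conservation ranking** of multiple-sequence-alignment columns by
   information content (IC), with sequence-logo letter heights;
4. the **group statistics** used to compare these quantities
   (Mann-Whitney U, one-way ANOVA, Tukey HSD), implemented from
   formulas with exact small-sample paths;
5. **seeded generators** that produce every input class with ground
   truth attached, so each stage is testable at desk scale.

# Sequence catalog and census

A `protein_record` holds a sequence, its TRANSMEM segments (1-based
inclusive coordinates, the UniProt feature convention) and free-text
subcellular locations. Records come from a UniProt-style flat file (of
which only the ID/AC/FT TRANSMEM/CC SUBCELLULAR LOCATION/SQ line types
are read) or from FASTA plus a tab-separated annotation table; both
dialects round-trip through `write_catalog()`.

Categories: every record is `ALL`; records without TM segments are
`SOLUBLE`; the rest are `TM_ANY` plus exactly one TMD-count bin (1,
2–5, 6–10, ≥11 — the 6–10 bin is the natural comparison group for a
7-TMD family). `ER` membership uses case-insensitive substring matching
of a configurable term list (default `"endoplasmic reticulum"`), a
deliberately permissive rule because location annotation is free text
and frequently ambiguous. Family labels (`CERS`, `TLC_OTHER`) come from
accession lists, with `CERS` taking precedence.

Composition (`composition_of`) counts the 20 standard letters only;
ambiguity letters (X, B, Z, U, O) are excluded from numerator *and*
denominator, so percentages always sum to 100 and rare ambiguity codes
cannot dilute the 20-letter profile. Category summaries are
**unweighted per-protein** means with sample (n−1) SDs — a short
protein counts as much as a long one, matching the per-protein
procedure behind "percent ± SD" census tables. `pooled_composition()`
provides the length-weighted whole-dataset alternative (the view a
tool like Pepstats reports); both are available because published
census tables do not always state which convention a cell uses.

## Redundancy filtering

`cluster_at_threshold()` reproduces the *role* of CD-HIT at `c = 0.7`:
greedy incremental clustering after sorting by length (ties broken by
accession, so output is byte-stable). Identity is defined
reproducibly in-package: identical columns of one optimal global
alignment divided by the shorter sequence length (CD-HIT's default
global-identity convention). The alignment scoring is fixed and
declared — match +1, mismatch −1, affine gaps with −2 for the first gap
residue and −1 for each further one — and the implementation's
traceback tie rule is deterministic; `pairwise_identity()` additionally
canonicalizes argument order so the value is exactly symmetric.
CD-HIT's short-word prefilter and banded alignment are intentionally
**not** reproduced: clustering is used only to deduplicate, and a
declared, reproducible identity is worth more here than bit-level
CD-HIT equivalence (full-scale cluster counts may therefore deviate
slightly). The greedy scheme guarantees that every representative has
identity < `c` to all representatives founded before it; the tests
assert this property on random inputs and check equivalence against a
brute-force oracle with an independently coded aligner.

In the census pipeline each category is filtered **separately** (the
published totals imply per-subgroup filtering: the category counts do
not add up to a single shared pool), with pairwise identities memoized
across categories of the same catalog.

## Group comparison in the census

`run_census()` compares Trp percent across {6–10 TMD, CerS, TLC-other}
with one-way ANOVA plus Tukey HSD. One subtlety: family members *also*
fall into a TMD bin, and overlapping groups are invalid for ANOVA, so
the comparison groups are made disjoint — family members are excluded
from the non-family group. The census *table*, in contrast, keeps the
overlapping memberships, mirroring the published table layout in which
family columns coexist with TMD-bin columns. At full Swiss-Prot scale
the distinction is negligible (a few hundred family sequences among
thousands); at synthetic scale it is decisive.

# Membrane placement and depth profiling

`parse_structure()` extracts one Calpha per residue from PDB ATOM
records (alternate locations resolved by first occurrence,
non-standard residues skipped with a warning).

`place_membrane()` is a deliberate, documented surrogate for a
transfer-energy-based orientation calculation (the full physics of
such tools is out of scope). It maximizes the summed per-residue
hydrophobicity inside a slab,

$$S(\mathbf{n}, d_0) = \sum_i h_i \, \mathbf{1}\!\left[\,|z_i - d_0| \le w\,\right],
\qquad z_i = \mathbf{x}_i \cdot \mathbf{n},$$

with core half-width $w = 15$ Å and $h$ the mean-centered
Kyte–Doolittle scale. Numerical choices, each forced by a property the
tests enforce:

* **Directions** come from a deterministic Fibonacci spiral covering of
  the hemisphere (default 500 points; antipodal directions are
  score-equivalent).
* **Offsets are optimized exactly**: for a fixed normal, $S$ is
  piecewise constant in $d_0$ with breakpoints where a residue enters
  or leaves the core, so the optimum over offsets is found by
  enumerating breakpoint-interval midpoints. This also makes the
  chosen normal exactly invariant under rigid translations of the
  model (an offset *grid* anchored to coordinates is not).
* **Refinement** is multi-start: the ten best grid directions are each
  hill-climbed in 1° steps (offset re-optimized exactly at every
  step), guarding against stalls on the rugged score surface.
* **Degeneracy**: the hard-window score is *exactly flat* over several
  degrees of normal — the same optimal residue set is realized by many
  nearby frames — so "the" maximizer is under-determined. The reported
  frame is the **max-margin** one: among frames achieving the optimal
  score, the frame that fits the included residues with the largest
  minimal slack to the window edges (the Chebyshev center of the
  co-optimal region). For a symmetric hydrophobic belt this is its
  symmetry axis. Smooth-kernel tie-breaks were evaluated and rejected:
  any soft window rewards tilting the normal to compress the
  projection, which biases the recovered normal by far more than the
  plateau itself.

`orient_frame()` fixes the sign so that a known-cytoplasmic reference
set (default: the last 10 modeled residues, because the CerS C-terminus
is cytosolic) has positive mean depth. `residue_depths()` reports
signed depths relative to the bilayer center (0 Å), masks residues
beyond a 40 Å window, and `classify_region()` splits depths at the
±18 Å mean bilayer boundary; $z = 0$ is assigned to the cytoplasmic
half by a declared `>=` tie rule. The 40 Å window is measured from the
bilayer **center**, matching the plotted depth axis of the figure this
computation feeds, although "within 40 Å of the bilayer boundaries"
could also be read as $|z| \le 58$; the center reading is the
implemented one.

`hox_orientation_filter()` rejects models whose N-terminal segment
lies on the same membrane side as the Hox-like domain — a placement
incompatible with the known topology and therefore a sign of a
mis-modeled fold. The per-model Hox/N-terminal residue ranges are
supplied through the cohort table, since they are family- and
model-specific. `compare_trp_depths()` pools included Trp depths per
cohort and applies the two-sided Mann-Whitney U test.

# Conservation

Alignment columns occupied by fewer than 10 sequences are masked
before analysis. Column information content is
$IC = \log_2 20 - H$ bits over the observed non-gap frequencies; gaps
carry no probability mass, and no small-sample correction is applied
by default. This is an observed-frequency IC, not the HMM-weighted
posterior IC of logo web services; rankings of strongly conserved
columns are insensitive to the difference, and bit-for-bit equality
with any particular server is not promised. `rank_positions()` orders
kept columns by IC (ties broken by ascending column index for
byte-stable output) and maps each to the ungapped residue number of a
chosen reference sequence; `logo_heights()` splits each column's IC
across letters by frequency, so heights sum to the column IC.

# Inference statistics

All three tests are implemented from formulas, with base R's
distribution functions and test wrappers reserved for *independent
cross-checks* in the test suite:

* **Mann-Whitney U**: U from midranks; exact enumeration of all
  $\binom{n_1+n_2}{n_1}$ assignments (conditional on observed ties)
  when $n_1 + n_2 \le 12$, otherwise the normal approximation with
  tie-corrected variance and a 0.5 continuity correction. Two-sided
  alternatives are the default throughout, since the source analyses
  name only the test.
* **One-way ANOVA**: $F = \mathrm{MSB}/\mathrm{MSW}$ on $(k-1, N-k)$
  degrees of freedom. $\mathrm{MSW} = 0$ is an error unless the means
  are also equal (every observation identical), which returns
  $F = 0,\ p = 1$.
* **Tukey HSD**: Tukey–Kramer $q$ with the harmonic-mean sample size
  for unequal $n$; the studentized-range CDF is evaluated by the
  package's own two-level numerical quadrature
  (`studentized_range_cdf()`, accurate to about $10^{-6}$), so the
  p-value does not depend on any single library's implementation —
  base R's `ptukey` serves as the oracle in tests.

# Synthetic data: what it emulates, and what it does not

All generators are seeded and byte-deterministic, and each emits a
machine-readable truth object.

* `gen_proteome()` draws sequences i.i.d. per position from
  per-category target frequencies — by default the bundled
  `swissprot_reference_pct` columns (nonredundant Swiss-Prot category
  means), so the default three-category census (CerS-like, 6–10-TMD-
  like, TLC-like; 150 proteins of length 300 each) plants Trp means of
  3.35%, 1.89% and 2.61%. TRANSMEM segments (21 residues) are placed
  non-overlapping at random. *Not emulated*: positional composition
  structure (real TMDs are hydrophobic; here annotation and
  composition are independent), length–composition correlations, and
  phylogenetic relatedness.
* `gen_redundant_copies()` mutates by substitutions only, at distinct
  positions, so the identity of each copy to the seed is exact by
  construction and clustering tests do not depend on the aligner.
  Copies are named so the seed sorts first under the clustering tie
  rule.
* `gen_helical_bundle()` builds ideal-geometry helices (rise 1.5
  Å/residue, 100°/residue, radius 2.3 Å) in an antiparallel bundle,
  assigns hydrophobic types inside the ±15 Å core and polar types
  outside, plants Trp at requested true depths, and can add terminal
  tails, a compact extramembrane "Hox-like" blob on either side, and
  an arbitrary rigid motion. The default is the CerS-like 7-helix
  bundle; with an odd helix count the chain runs from the lumenal side
  to a cytoplasmic C-terminus. *Not emulated*: loops, kinks, irregular
  secondary structure, side chains. Note an intrinsic identifiability
  limit of any slab-fitting method on such fixtures: the belt boundary
  is sampled at roughly one residue per helix per side with ~0.75 Å
  gaps, so small bundles (5 helices, ~17 Å extent) carry ~5° of
  irreducible normal uncertainty; the 7-helix default supports the 5°
  recovery the tests demand.
* `gen_msa()` plants conserved columns (fixed letter with a chosen
  conservation level) among uniform columns, with per-column gap
  rates. *Not emulated*: phylogenetic covariance between rows.
* `gen_depth_cohort()` draws Trp depths from a symmetric baseline
  (interface bands at ±17 Å plus a broad central component) and, in
  the Hox-like cohort, mixes in an asymmetric component with
  probability `bias`: the cytoplasmic-leaflet band (+5 to +10 Å, 1/3
  weight) and the lumenal interface (−20 Å, 2/3 weight). The lumenal
  component dominates because the lumenal-side enrichment is the
  distinguishing feature of the pattern being emulated — with equal
  weights the two bands shift ranks in opposite directions and nearly
  cancel under the Mann-Whitney test, misrepresenting the biology.
  The default `bias = 0.5` reflects that roughly half of the Hox-CerS
  tryptophans belong to the enriched regions, and it is the level at
  which cohorts of 500 Trp per side separate at $p < 0.001$ across the
  seed distribution, as the generator's calibration contract demands;
  `bias = 0` makes the cohorts exchangeable (the null calibration).

Because the generators are idealizations, green tests demonstrate that
the *computations* are correct and calibrated — not that real
structure models are accurate, that real annotation is complete, or
that observed-frequency IC equals HMM-posterior IC on sparse
alignments.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic
data at the scales the generators define as their defaults: 450
proteins of length 300 for the census (per-category redundancy
filtering included), 50 bundles of ~290 residues for membrane
recovery, 500 Trp depths per cohort (100 replicates for the null
level, 2,000 for the rank-test level), and a 209-row alignment for the
conservation ranking. Full-scale inputs (a complete Swiss-Prot
release, structure-database models, a curated family alignment) are
external downloads and out of scope for the automated checks; the same
functions apply unchanged, though the naive all-pairs clustering path
is not intended for half a million sequences.

# Known limitations

* The slab surrogate ignores transfer-energy physics, curvature, and
  lipid-specific interactions; it is validated by parameter recovery
  on synthetic bundles, not against an orientation database.
* Alignment-based identity differs from CD-HIT's word-filtered banded
  identity; nonredundant set sizes can differ slightly at scale.
* The flat-file parser reads only the line types the census needs;
  isoforms, evidence codes and non-TRANSMEM features are out of scope.
* Observed-frequency IC has no small-sample correction by default;
  columns with few residues overstate conservation relative to
  corrected estimators (the occupancy filter bounds, but does not
  remove, this effect).
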