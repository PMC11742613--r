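# trpcensus

Tryptophan is among the rarest amino acids, yet membrane proteins are
enriched in it, and the ceramide synthases (CerS) — ER-resident enzymes
with seven transmembrane domains (TMDs) — carry an unusually high Trp
content that is asymmetrically distributed toward the ER-lumenal side
of the membrane in the Hox-domain-containing family members.
`trpcensus` implements the quantitative machinery behind that kind of
study as a tested R package for structural bioinformaticians and
membrane-protein biochemists:

* **Composition census** — parse Swiss-Prot-style records (UniProt
  flat file, or FASTA + annotation table with a `Transmembrane`
  column), count TMDs, assign category bins (soluble; 1, 2–5, 6–10,
  ≥11 TMDs; ER; family lists), redundancy-filter each category by
  greedy clustering at 70% identity, and report per-protein percent
  composition as mean ± SD per category.
* **Membrane-depth profiling** — place a planar membrane slab on a
  Cα structure model by maximizing windowed hydropathy
  `S(n, d0) = Σ h_i · 1[|x_i·n − d0| ≤ 15 Å]` (max-margin tie-break),
  orient it so the cytoplasmic side is positive, and measure signed
  Cα depths `z` relative to the bilayer center (boundaries at ±18 Å,
  analysis window |z| ≤ 40 Å), with a topology filter that rejects
  models whose N-terminus sits on the same side as the Hox-like
  domain.
* **Conservation ranking** — alignment-column information content
  `IC = log2(20) − H` in bits, sequence-logo letter heights, and a
  top-k ranking mapped to reference-sequence numbering.
* **Group statistics** — Mann-Whitney U (exact enumeration for small
  samples, tie- and continuity-corrected normal approximation
  otherwise), one-way ANOVA, and Tukey HSD with the package's own
  studentized-range quadrature.
* **Seeded generators** for every input class — annotated synthetic
  proteomes with planted per-category composition, ideal helical
  bundles with a known membrane frame and planted Trp depths, MSAs
  with planted conserved columns, and depth cohorts with a controlled
  lumenal-enrichment bias — each with machine-readable ground truth.

## Worked example

Simulate a three-category proteome (CerS-like, 6–10-TMD-like,
TLC-like; Trp targets 3.35%, 1.89%, 2.61%) and run the census
pipeline:

```r
library(trpcensus)

sim <- gen_proteome(list(
  category_spec("cers", 40, c(300, 300), tmd_counts = 7L,
                location = "Endoplasmic reticulum membrane"),
  category_spec("tm_6_10", 40, c(300, 300), tmd_counts = 6:10),
  category_spec("tlc_other", 40, c(300, 300), tmd_counts = 6:10,
                location = "Endoplasmic reticulum membrane")), seed = 42)

cfg <- pipeline_config(out_dir = "census_demo", seed = 42,
  records = sim$records,
  cers_accessions = sim$truth$accession[sim$truth$label == "cers"],
  tlc_accessions  = sim$truth$accession[sim$truth$label == "tlc_other"])
res <- run_census(cfg)
#> census: 120 records in
#> census: TM_6_10 - 120 records, 120 nonredundant
#> census: CERS - 40 records, 40 nonredundant
#> census: Trp comparison across TM_6_10, CERS, TLC_OTHER: F = 19.12, p = 6.54e-08

res$summaries$CERS
#> <category_summary> CERS - 40 protein(s)
#>   Trp 3.38 +/- 1.04%
```

The CerS-like category recovers its planted 3.35% Trp mean, and the
ANOVA flags the between-category differences (at this small demo size
the CerS-vs-TLC Tukey pair is not yet individually significant; the
full study condition of 150 proteins per category, used by the tests
and the acceptance script, separates all three pairs).

Membrane-depth profiling of a synthetic 7-helix bundle tilted 12°:

```r
b <- gen_helical_bundle(tilt_deg = 12, seed = 7)
f <- orient_frame(place_membrane(b$model), b$model)
f
#> <membrane_frame> normal (-0.041, -0.059, 0.997), d0 0.01 A, half-thickness 18.0 A, oriented

head(subset(residue_depths(b$model, f), restype == "W"))
#>     resno restype          z                     region included
#> 38     38       W  16.274332 cytoplasmic_interface_core     TRUE
#> 237   237       W -15.209568     lumenal_interface_core     TRUE
#> 240   240       W -19.157049              lumenal_space     TRUE
```

The planted Trp depths (−20, −16, +8, +17 Å) are recovered to within
the Cα spacing. Conservation ranking on a 209-sequence synthetic
alignment with ten strongly conserved columns, five of them Trp:

```r
simm <- gen_msa(n_rows = 209, n_cols = 64, conserved_cols = seq(6, 60, 6),
                conserved_letters = c("W","H","W","F","W","Y","W","H","W","G"),
                conservation = 0.97, gap_rate = 0.05, seed = 5)
rank_positions(simm$aln, "seq001", k = 10)
#>    rank column ref_position consensus       ic
#> 1     1     30           29         W 4.148324
#> 2     2     60           59         G 4.148324
#> 3     3      6            5         W 4.141997
#> ...
sum(rank_positions(simm$aln, "seq001", k = 10)$consensus == "W")
#> [1] 5
```

## Design notes

The scientific conventions (identity denominator, ambiguity-letter
handling, sign and tie rules for depths, IC definition, test choices)
and the numerical design of the membrane-placement surrogate are
documented in the methods vignette,
`vignettes/trp-census-methods.Rmd`.
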