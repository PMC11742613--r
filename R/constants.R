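#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in alphabetical order.
#' Ambiguity / non-standard letters handled by the parsers are listed in
#' [AA_AMBIGUOUS]; they are retained in sequences but excluded from
#' composition counting.
#'
#' @format Character vectors of length 20 and 5.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_STANDARD
#' @export
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices (Kyte & Doolittle 1982). Used, after
#' mean-centering across the 20 letters, as the default per-residue weight
#' in the membrane-slab placement objective of [place_membrane()].
#'
#' @format Named numeric vector over the 20 standard letters.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Reference amino-acid composition of Swiss-Prot protein categories
#'
#' Mean percent composition (per protein, unweighted) of each of the 20
#' standard amino acids in nonredundant Swiss-Prot (Release 2021_03,
#' identity-filtered at 70%) protein categories: all proteins, all
#' transmembrane (TM) proteins, TM proteins binned by transmembrane-domain
#' count (1, 2-5, 6-10, >=11), the ceramide synthase (CerS) clade, other
#' TLC-domain proteins, and soluble proteins. These values serve as the
#' default per-category target frequencies of the synthetic proteome
#' generator [gen_proteome()], so synthetic censuses are directly
#' comparable with the published full-scale ones. The number of sequences
#' behind each column is stored in `attr(, "n_sequences")`.
#'
#' @format A 20 x 9 numeric matrix; rows are amino acids, columns are
#'   categories (`all`, `tm_any`, `tm_1`, `tm_2_5`, `tm_6_10`, `tm_ge11`,
#'   `cers`, `tlc_other`, `soluble`), cells are mean percent.
#' @export
swissprot_reference_pct <- local({
  m <- matrix(c(
    # all   tm_any  tm_1   tm_2_5 tm_6_10 tm_ge11 cers   tlc    soluble
    8.04,   8.09,   7.37,  8.36,  8.36,   9.16,   6.11,  7.40,  8.03,  # A
    1.57,   1.51,   1.68,  1.41,  1.48,   1.27,   1.68,  1.98,  1.59,  # C
    5.29,   3.83,   4.78,  3.54,  3.12,   3.09,   4.51,  3.06,  5.55,  # D
    6.61,   4.64,   6.01,  4.30,  3.53,   3.54,   4.31,  3.11,  6.97,  # E
    3.96,   5.55,   4.33,  6.01,  6.43,   6.35,   7.45,  7.05,  3.67,  # F
    6.84,   6.85,   6.25,  7.01,  7.08,   7.93,   4.57,  5.55,  6.84,  # G
    2.22,   1.92,   2.08,  1.83,  1.92,   1.63,   2.71,  2.88,  2.28,  # H
    6.06,   7.09,   5.96,  7.59,  7.87,   7.72,   6.98,  6.69,  5.87,  # I
    6.17,   4.73,   5.73,  4.56,  3.95,   3.59,   5.22,  4.24,  6.44,  # K
    9.67,  11.70,  10.20, 12.20, 12.90,  12.70,  11.50, 12.60,  9.29,  # L
    2.43,   2.77,   2.41,  2.92,  2.96,   3.12,   2.73,  3.12,  2.37,  # M
    4.16,   3.86,   4.39,  3.73,  3.47,   3.34,   3.15,  3.41,  4.22,  # N
    4.65,   4.52,   5.14,  4.16,  4.20,   4.18,   3.92,  3.80,  4.68,  # P
    3.79,   3.30,   3.96,  3.06,  2.86,   2.74,   2.76,  2.61,  3.88,  # Q
    5.55,   4.52,   5.14,  4.41,  4.10,   3.66,   5.07,  4.46,  5.74,  # R
    6.82,   7.36,   7.68,  7.11,  7.16,   7.42,   6.75,  7.34,  6.72,  # S
    5.26,   5.48,   5.61,  5.26,  5.50,   5.57,   5.01,  5.26,  5.22,  # T
    6.80,   7.28,   6.74,  7.44,  7.67,   7.78,   6.75,  8.14,  6.71,  # V
    1.10,   1.67,   1.43,  1.73,  1.89,   1.83,   3.35,  2.61,  1.00,  # W
    2.98,   3.30,   3.07,  3.33,  3.54,   3.38,   5.51,  4.74,  2.92   # Y
  ), nrow = 20, byrow = TRUE)
  rownames(m) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  colnames(m) <- c("all", "tm_any", "tm_1", "tm_2_5", "tm_6_10",
                   "tm_ge11", "cers", "tlc_other", "soluble")
  attr(m, "n_sequences") <- c(
    all = 216303L, tm_any = 33668L, tm_1 = 12097L, tm_2_5 = 9767L,
    tm_6_10 = 8613L, tm_ge11 = 3698L, cers = 161L, tlc_other = 308L,
    soluble = 183018L)
  m
})

# Category labels used throughout the catalog / census modules.
CATEGORY_LABELS <- c("ALL", "SOLUBLE", "TM_ANY", "TM_1", "TM_2_5",
                     "TM_6_10", "TM_GE11", "ER", "CERS", "TLC_OTHER")
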