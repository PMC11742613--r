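#' Read and occupancy-filter a multiple sequence alignment
#'
#' Reads an aligned FASTA file (rows of equal length over the 20 standard
#' letters plus `-`; `.` is also accepted as a gap) and masks out columns
#' occupied by fewer than `min_seqs` non-gap residues, so sparsely
#' populated columns do not enter the conservation analysis.
#'
#' @param path Aligned FASTA file.
#' @param min_seqs Minimum non-gap residues for a column to be kept.
#' @return Object of class `msa_alignment`: list with `ids`, `matrix`
#'   (rows x aligned columns, characters) and logical `mask`
#'   (TRUE = kept).
#' @export
read_and_filter_msa <- function(path, min_seqs = 10) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty alignment")
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L)
    stop("unequal row lengths: not an alignment")
  ids <- sub("\\s.*$", "", names(seqs))
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  m[m == "."] <- "-"
  rownames(m) <- ids
  filter_msa(m, min_seqs)
}

#' @rdname read_and_filter_msa
#' @param m Character matrix of aligned residues (rows named by id).
#' @export
filter_msa <- function(m, min_seqs = 10) {
  stopifnot(is.matrix(m), is.character(m))
  mask <- colSums(m != "-") >= min_seqs
  structure(list(ids = rownames(m), matrix = m, mask = mask),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("<msa_alignment>", nrow(x$matrix), "sequences x", ncol(x$matrix),
      "columns,", sum(x$mask), "kept\n")
  invisible(x)
}

#' Information content of an alignment column
#'
#' `IC = log2(20) - H` bits, where `H` is the Shannon entropy of the
#' observed non-gap residue frequencies of the column. Gaps carry no
#' probability mass, and no small-sample correction is applied, so a
#' fully conserved column scores `log2(20) = 4.3219` bits and a uniform
#' column 0 bits.
#'
#' @param column Character vector of residues (may include `-`).
#' @return Information content in bits, in `[0, log2(20)]`.
#' @export
column_ic <- function(column) {
  res <- column[column != "-"]
  if (length(res) == 0L) stop("empty column (all gaps)")
  p <- table(res) / length(res)
  h <- -sum(p * log2(p))
  max(0, log2(20) - h)
}

#' Per-column information content of an alignment
#'
#' @param aln An `msa_alignment` from [read_and_filter_msa()].
#' @return Numeric vector over aligned columns; masked columns are `NA`.
#' @export
alignment_ic <- function(aln) {
  stopifnot(inherits(aln, "msa_alignment"))
  ic <- rep(NA_real_, ncol(aln$matrix))
  for (j in which(aln$mask)) ic[j] <- column_ic(aln$matrix[, j])
  ic
}

#' Rank conserved alignment positions
#'
#' Orders the kept columns by decreasing information content (ties broken
#' by ascending column index, so output is byte-stable) and reports the
#' top `k` with their residue number in a chosen reference sequence
#' (ungapped numbering; `NA` where the reference has a gap) and the
#' column's consensus residue.
#'
#' @param aln An `msa_alignment`.
#' @param reference_id Row id whose ungapped numbering labels the
#'   positions.
#' @param k Number of top positions to report; values beyond the number
#'   of kept columns return all kept columns.
#' @return Data frame with columns `rank`, `column`, `ref_position`,
#'   `consensus`, `ic`, sorted by `ic` descending.
#' @export
rank_positions <- function(aln, reference_id, k = 10) {
  stopifnot(inherits(aln, "msa_alignment"), k >= 0)
  ref_row <- match(reference_id, aln$ids)
  if (is.na(ref_row)) stop("unknown reference id: ", reference_id)
  ic <- alignment_ic(aln)
  kept <- which(aln$mask)
  ord <- kept[order(-ic[kept], kept)]
  top <- utils::head(ord, k)
  ref_chars <- aln$matrix[ref_row, ]
  ref_num <- cumsum(ref_chars != "-")
  out <- data.frame(
    rank = seq_along(top),
    column = top,
    ref_position = ifelse(ref_chars[top] == "-", NA_integer_,
                          ref_num[top]),
    consensus = vapply(top, function(j) {
      col <- aln$matrix[, j]
      col <- col[col != "-"]
      tab <- sort(table(col), decreasing = TRUE)
      names(tab)[1L]              # ties: alphabetically first (table order)
    }, character(1)),
    ic = ic[top],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sequence-logo letter heights
#'
#' For each kept column, the stack height of letter `a` is
#' `IC(col) * p_a(col)` over the non-gap frequencies, so the heights of a
#' column sum to its information content.
#'
#' @param aln An `msa_alignment`.
#' @return Data frame with columns `column`, `letter`, `height`,
#'   restricted to letters observed in each kept column.
#' @export
logo_heights <- function(aln) {
  stopifnot(inherits(aln, "msa_alignment"))
  rows <- list()
  for (j in which(aln$mask)) {
    col <- aln$matrix[, j]
    col <- col[col != "-"]
    p <- table(col) / length(col)
    ic <- column_ic(aln$matrix[, j])
    rows[[length(rows) + 1L]] <- data.frame(
      column = j, letter = names(p), height = as.numeric(ic * p),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(column = integer(), letter = character(),
                      height = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `msa_alignment` (the full matrix is written; the mask is
#'   an analysis-time attribute, not a file feature).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "msa_alignment"))
  seqs <- Biostrings::AAStringSet(apply(aln$matrix, 1L, paste,
                                        collapse = ""))
  names(seqs) <- aln$ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
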