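#' Per-protein amino-acid composition
#'
#' Percent of each of the 20 standard amino acids among the counted
#' residues of one sequence. Ambiguity letters (X, B, Z, U, O) are
#' excluded symmetrically from numerator and denominator, so the 20
#' percentages always sum to 100.
#'
#' @param sequence Nonempty residue string.
#' @return Object of class `composition_vector`: list with `percent`
#'   (named numeric over the 20 standard letters) and `counted_length`.
#' @export
composition_of <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  counts <- tabulate(factor(chars, levels = AA_STANDARD),
                     nbins = length(AA_STANDARD))
  names(counts) <- AA_STANDARD
  counted <- sum(counts)
  if (counted == 0L) stop("no countable residues")
  structure(list(percent = 100 * counts / counted,
                 counted_length = counted),
            class = "composition_vector")
}

#' @export
print.composition_vector <- function(x, ...) {
  cat("<composition_vector>", x$counted_length, "counted residues; Trp",
      sprintf("%.2f%%", x$percent[["W"]]), "\n")
  invisible(x)
}

#' Per-category composition summary
#'
#' Unweighted mean and sample standard deviation (n - 1 denominator) of
#' per-protein composition percentages, per amino acid: the "mean +/- SD"
#' cells of a census table. Short and long proteins count equally; see
#' [pooled_composition()] for the length-weighted alternative.
#'
#' @param vectors Nonempty list of [composition_of()] results.
#' @param label Category label for the summary.
#' @return Object of class `category_summary`: list with `label`,
#'   `n_proteins`, and `stats` (data frame `aa`, `mean`, `sd`). SD is
#'   reported as 0 when `n_proteins` is 1.
#' @export
summarize_category <- function(vectors, label = NA_character_) {
  if (length(vectors) == 0L) stop("empty vector list")
  pct <- t(vapply(vectors, function(v) v$percent,
                  numeric(length(AA_STANDARD))))
  colnames(pct) <- AA_STANDARD
  mu <- colMeans(pct)
  sdev <- if (nrow(pct) == 1L) rep(0, ncol(pct)) else apply(pct, 2L, stats::sd)
  structure(list(label = label, n_proteins = nrow(pct),
                 stats = data.frame(aa = AA_STANDARD, mean = unname(mu),
                                    sd = unname(sdev),
                                    stringsAsFactors = FALSE)),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("<category_summary>", x$label, "-", x$n_proteins, "protein(s)\n")
  w <- x$stats[x$stats$aa == "W", ]
  cat(sprintf("  Trp %.2f +/- %.2f%%\n", w$mean, w$sd))
  invisible(x)
}

#' Pooled (length-weighted) dataset composition
#'
#' Composition of the concatenation of all counted residues in a record
#' set — the whole-dataset view a tool like Pepstats reports, as opposed
#' to the per-protein means of [summarize_category()].
#'
#' @param records Nonempty list of [protein_record()]s.
#' @return A `composition_vector` over the pooled residues.
#' @export
pooled_composition <- function(records) {
  if (length(records) == 0L) stop("empty record list")
  composition_of(paste(vapply(records, function(r) r$sequence, character(1)),
                       collapse = ""))
}

#' Census table over categories
#'
#' Builds the census-table layout: rows are amino acids, columns are
#' categories, each cell "mean +/- SD" of the per-protein percentages,
#' with a final row of category sizes.
#'
#' @param summaries List of [summarize_category()] results.
#' @return Character data frame ready for `write.table`.
#' @export
census_table <- function(summaries) {
  stopifnot(length(summaries) > 0L)
  cols <- lapply(summaries, function(s)
    sprintf("%.2f ± %.2f", s$stats$mean, s$stats$sd))
  out <- data.frame(amino_acid = AA_STANDARD, stringsAsFactors = FALSE)
  for (i in seq_along(summaries)) out[[summaries[[i]]$label]] <- cols[[i]]
  n_row <- c("n_proteins",
             vapply(summaries, function(s) as.character(s$n_proteins),
                    character(1)))
  out <- rbind(out, stats::setNames(as.list(n_row), names(out)))
  out
}
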