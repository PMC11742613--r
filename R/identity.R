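#' Pairwise sequence identity
#'
#' Fraction of identical aligned columns in one optimal global alignment,
#' divided by the length of the shorter sequence (the global-identity
#' convention CD-HIT uses by default). The alignment uses a fixed declared
#' scoring: match +1, mismatch -1, and affine gaps where the first residue
#' of a gap scores -2 and each further residue -1. Traceback ties are
#' resolved deterministically (diagonal, then gap-in-second, then
#' gap-in-first), so the value is reproducible.
#'
#' @param a,b Nonempty residue strings.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  # canonical argument order (shorter, then lexicographic) so the
  # traceback tie rule cannot make the value asymmetric
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  res <- align_global_affine(a, b)
  res$matches / min(nchar(a), nchar(b))
}

#' Greedy identity clustering at a threshold
#'
#' Deduplicates a sequence set the way CD-HIT's greedy incremental scheme
#' does: sequences are sorted by decreasing length (ties broken by
#' ascending accession), each sequence joins the first existing cluster
#' whose representative it matches at identity >= `c`, and otherwise
#' founds a new cluster. Because of the sort order, every representative
#' is the longest member of its cluster (ties lexicographically
#' smallest), and every representative has identity < `c` to all
#' representatives founded before it. Identity is [pairwise_identity()];
#' CD-HIT's short-word prefilter and banded alignment are deliberately not
#' reproduced, so full-scale cluster counts may deviate slightly from
#' CD-HIT's.
#'
#' @param records List of [protein_record()]s, or a named character vector
#'   of sequences (names = accessions).
#' @param c Identity threshold in `(0, 1]`; sequences at or above it merge.
#' @param cache Optional environment memoizing pairwise identities by
#'   accession pair; pass the same environment across calls (e.g. when
#'   clustering overlapping categories of one catalog) to avoid
#'   realigning the same pairs.
#' @return List of clusters, each a list with elements `representative`,
#'   `members` (accessions, representative first), `identities` (of each
#'   member to the representative) and `threshold`; class
#'   `identity_clusters`.
#' @export
cluster_at_threshold <- function(records, c = 0.7, cache = NULL) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0, c <= 1)
  if (is.character(records)) {
    if (is.null(names(records)) || any(!nzchar(names(records))))
      stop("sequence vector must be named by accession")
    acc <- names(records)
    seqs <- unname(records)
  } else {
    acc <- vapply(records, function(r) r$accession, character(1))
    seqs <- vapply(records, function(r) r$sequence, character(1))
  }
  if (length(acc) == 0L) stop("records must be nonempty")
  if (anyDuplicated(acc)) stop("duplicate accessions")
  ord <- order(-nchar(seqs), acc)
  acc <- acc[ord]
  seqs <- seqs[ord]

  pid_of <- function(i, k) {
    if (is.null(cache)) return(pairwise_identity(seqs[i], seqs[k]))
    key <- paste(sort(c(acc[i], acc[k])), collapse = "\r")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- pairwise_identity(seqs[i], seqs[k])
      cache[[key]] <- val
    }
    val
  }

  reps <- integer(0)              # indices into acc/seqs
  members <- list()
  idents <- list()
  for (i in seq_along(acc)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      pid <- pid_of(i, reps[k])
      if (pid >= c) {
        members[[k]] <- c(members[[k]], acc[i])
        idents[[k]] <- c(idents[[k]], pid)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- acc[i]
      idents[[length(reps)]] <- 1.0
    }
  }
  clusters <- lapply(seq_along(reps), function(k) {
    list(representative = acc[reps[k]], members = members[[k]],
         identities = idents[[k]], threshold = c)
  })
  class(clusters) <- "identity_clusters"
  clusters
}

#' @export
print.identity_clusters <- function(x, ...) {
  cat("<identity_clusters>", length(x), "cluster(s),",
      sum(lengths(lapply(x, `[[`, "members"))), "sequence(s), threshold",
      x[[1L]]$threshold, "\n")
  invisible(x)
}

#' Representatives of a clustering
#'
#' @param clusters Result of [cluster_at_threshold()].
#' @return Character vector of representative accessions (the
#'   nonredundant set), in founding order.
#' @export
cluster_representatives <- function(clusters) {
  vapply(clusters, function(cl) cl$representative, character(1))
}

#' Cluster table
#'
#' @param clusters Result of [cluster_at_threshold()].
#' @return Data frame with columns `representative`, `member`, `identity`.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(representative = cl$representative, member = cl$members,
               identity = cl$identities, stringsAsFactors = FALSE)
  }))
}

#' Redundancy-filter a set of records
#'
#' Convenience wrapper: clusters at `c` and returns the representative
#' records only.
#'
#' @inheritParams cluster_at_threshold
#' @return List of [protein_record()]s (the representatives).
#' @export
nonredundant <- function(records, c = 0.7, cache = NULL) {
  cl <- cluster_at_threshold(records, c, cache)
  keep <- cluster_representatives(cl)
  acc <- vapply(records, function(r) r$accession, character(1))
  records[match(keep, acc)]
}
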