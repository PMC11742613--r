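#' Construct a protein record
#'
#' The unit of the census: one protein sequence with its transmembrane
#' (TRANSMEM) segment annotation and subcellular-location strings.
#' Coordinates are 1-based and inclusive, following the UniProt feature
#' convention.
#'
#' @param accession Character scalar, unique identifier within a catalog.
#' @param sequence Residue string over the 20 standard letters plus the
#'   ambiguity letters X, B, Z, U, O (case-insensitive; stored uppercase).
#' @param tm_segments Two-column matrix (or data.frame, or NULL) of
#'   `(start, end)` pairs, 1-based inclusive. Segments are sorted by start
#'   and must be non-overlapping and within the sequence.
#' @param subcellular_locations Character vector of free-text location
#'   strings.
#' @param source_dataset Optional tag for the dataset of origin.
#'
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(accession, sequence, tm_segments = NULL,
                           subcellular_locations = character(),
                           source_dataset = NA_character_) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  sequence <- toupper(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a nonempty string")
  letters_seen <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(letters_seen, c(AA_STANDARD, AA_AMBIGUOUS))
  if (length(bad) > 0L)
    stop("sequence of ", accession, " contains invalid letters: ",
         paste(bad, collapse = ", "))
  if (is.null(tm_segments) || NROW(tm_segments) == 0L) {
    tm_segments <- matrix(integer(0), ncol = 2L,
                          dimnames = list(NULL, c("start", "end")))
  } else {
    tm_segments <- as.matrix(tm_segments)
    storage.mode(tm_segments) <- "integer"
    if (ncol(tm_segments) != 2L)
      stop("tm_segments must have two columns (start, end)")
    colnames(tm_segments) <- c("start", "end")
    tm_segments <- tm_segments[order(tm_segments[, 1L]), , drop = FALSE]
    n <- nchar(sequence)
    if (any(tm_segments[, 1L] < 1L) || any(tm_segments[, 2L] > n) ||
        any(tm_segments[, 1L] > tm_segments[, 2L]))
      stop("tm_segments of ", accession,
           " violate 1 <= start <= end <= sequence length")
    if (nrow(tm_segments) > 1L &&
        any(tm_segments[-1L, 1L] <= tm_segments[-nrow(tm_segments), 2L]))
      stop("tm_segments of ", accession, " overlap")
  }
  structure(list(accession = accession,
                 sequence = sequence,
                 tm_segments = tm_segments,
                 subcellular_locations = as.character(subcellular_locations),
                 source_dataset = source_dataset),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$accession, "-", nchar(x$sequence), "aa,",
      nrow(x$tm_segments), "TMD(s)\n")
  invisible(x)
}

#' Count transmembrane domains of a record
#'
#' The TMD count is the number of annotated TRANSMEM segments; it drives
#' the census category bins.
#'
#' @param record A [protein_record()].
#' @return Non-negative integer.
#' @export
count_tmds <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  nrow(record$tm_segments)
}

#' Assign census categories to a record
#'
#' Every record belongs to `ALL`. Records with no TRANSMEM segment are
#' `SOLUBLE`; the rest are `TM_ANY` plus exactly one TMD-count bin:
#' `TM_1` (1), `TM_2_5` (2-5), `TM_6_10` (6-10) or `TM_GE11` (>= 11).
#' `ER` is added when any subcellular-location string contains (case-
#' insensitively) one of `er_location_terms`. Family labels `CERS` /
#' `TLC_OTHER` come from accession membership lists, with `CERS` taking
#' precedence when an accession appears in both.
#'
#' @param record A [protein_record()].
#' @param cers_accessions,tlc_accessions Character vectors (may be empty)
#'   of family member accessions.
#' @param er_location_terms Character vector of substrings identifying
#'   endoplasmic-reticulum locations. Matching is deliberately permissive
#'   (case-insensitive substring) because location annotation is free text
#'   and often ambiguous.
#' @return Character vector of category labels.
#' @export
assign_categories <- function(record,
                              cers_accessions = character(),
                              tlc_accessions = character(),
                              er_location_terms = "endoplasmic reticulum") {
  stopifnot(inherits(record, "protein_record"))
  labels <- "ALL"
  k <- count_tmds(record)
  if (k == 0L) {
    labels <- c(labels, "SOLUBLE")
  } else {
    bin <- if (k == 1L) "TM_1" else if (k <= 5L) "TM_2_5"
           else if (k <= 10L) "TM_6_10" else "TM_GE11"
    labels <- c(labels, "TM_ANY", bin)
  }
  if (length(er_location_terms) > 0L &&
      length(record$subcellular_locations) > 0L) {
    locs <- tolower(record$subcellular_locations)
    hit <- any(vapply(tolower(er_location_terms),
                      function(term) any(grepl(term, locs, fixed = TRUE)),
                      logical(1)))
    if (hit) labels <- c(labels, "ER")
  }
  if (record$accession %in% cers_accessions) {
    labels <- c(labels, "CERS")
  } else if (record$accession %in% tlc_accessions) {
    labels <- c(labels, "TLC_OTHER")
  }
  labels
}

#' Categorize a whole catalog
#'
#' @param records List of [protein_record()]s.
#' @inheritParams assign_categories
#' @return A logical membership matrix (records x category labels) with
#'   accessions as row names.
#' @export
categorize_catalog <- function(records,
                               cers_accessions = character(),
                               tlc_accessions = character(),
                               er_location_terms = "endoplasmic reticulum") {
  acc <- vapply(records, function(r) r$accession, character(1))
  if (anyDuplicated(acc))
    stop("duplicate accessions in catalog: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  m <- matrix(FALSE, nrow = length(records), ncol = length(CATEGORY_LABELS),
              dimnames = list(acc, CATEGORY_LABELS))
  for (i in seq_along(records)) {
    m[i, assign_categories(records[[i]], cers_accessions, tlc_accessions,
                           er_location_terms)] <- TRUE
  }
  m
}

# ---- parsing -------------------------------------------------------------

parse_tm_cell <- function(cell) {
  # "TRANSMEM 11..31; /note=...; TRANSMEM 45..65" -> matrix of (start, end)
  if (is.na(cell) || !nzchar(trimws(cell))) {
    return(matrix(integer(0), ncol = 2L))
  }
  hits <- regmatches(cell, gregexpr("TRANSMEM\\s+(\\d+)\\.\\.(\\d+)", cell))[[1]]
  if (length(hits) == 0L) return(matrix(integer(0), ncol = 2L))
  starts <- as.integer(sub("TRANSMEM\\s+(\\d+)\\.\\.(\\d+)", "\\1", hits))
  ends <- as.integer(sub("TRANSMEM\\s+(\\d+)\\.\\.(\\d+)", "\\2", hits))
  cbind(starts, ends)
}

#' Parse protein records from a file
#'
#' Two dialects are supported: `"flatfile"`, a UniProt-style text flat
#' file of which only the ID, AC, FT TRANSMEM, CC SUBCELLULAR LOCATION and
#' SQ line types are read (all other line types are ignored), and
#' `"fasta_plus_table"`, a FASTA file accompanied by a tab-separated
#' annotation table with columns `accession`, `Transmembrane` and
#' `Subcellular_location`, where the `Transmembrane` cell holds zero or
#' more `TRANSMEM start..end` features.
#'
#' Malformed entries (for example a TRANSMEM end beyond the sequence
#' length) are reported with their line number and skipped; with
#' `strict = TRUE` they raise an error instead.
#'
#' @param path Path to the flat file or the FASTA file.
#' @param dialect `"flatfile"` or `"fasta_plus_table"`.
#' @param table Path to the annotation table (required for the
#'   `fasta_plus_table` dialect; entries absent from the table get empty
#'   annotation).
#' @param strict Raise on malformed entries instead of skipping them.
#' @return List of [protein_record()]s (possibly empty).
#' @export
parse_records <- function(path, dialect = c("flatfile", "fasta_plus_table"),
                          table = NULL, strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (dialect == "flatfile") {
    parse_flatfile(path, strict = strict)
  } else {
    parse_fasta_plus_table(path, table, strict = strict)
  }
}

parse_flatfile <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  records <- list()
  ends <- which(lines == "//")
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) {
    if (any(nzchar(trimws(lines)))) {
      msg <- "flat file has content but no entry terminator '//'"
      if (strict) stop(msg) else warning(msg)
    }
    return(list())
  }
  for (e in seq_along(ends)) {
    block <- lines[starts[e]:ends[e]]
    offset <- starts[e] - 1L
    rec <- tryCatch(parse_flatfile_entry(block),
                    error = function(err) err)
    if (inherits(rec, "error")) {
      msg <- sprintf("skipping malformed entry at lines %d-%d: %s",
                     starts[e], ends[e], conditionMessage(rec))
      if (strict) stop(msg) else {
        warning(msg, call. = FALSE)
        next
      }
    }
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records
}

parse_flatfile_entry <- function(block) {
  if (!any(nzchar(trimws(block)))) return(NULL)
  ac_lines <- grep("^AC   ", block, value = TRUE)
  if (length(ac_lines) == 0L) stop("no AC line")
  accession <- sub(";.*$", "", sub("^AC   ", "", ac_lines[1L]))
  accession <- trimws(accession)
  sq <- grep("^SQ   ", block)
  if (length(sq) == 0L) stop("no SQ line")
  seq_lines <- block[(sq[1L] + 1L):(length(block) - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence")
  ft <- grep("^FT   TRANSMEM", block, value = TRUE)
  segs <- matrix(integer(0), ncol = 2L)
  if (length(ft) > 0L) {
    # modern "11..31" spans; legacy two-column "11     31" also accepted
    span <- regmatches(ft, regexpr("(\\d+)\\.\\.(\\d+)", ft))
    if (length(span) == length(ft) && all(nzchar(span))) {
      segs <- cbind(as.integer(sub("\\.\\..*$", "", span)),
                    as.integer(sub("^.*\\.\\.", "", span)))
    } else {
      nums <- lapply(ft, function(l)
        as.integer(regmatches(l, gregexpr("\\d+", l))[[1]][1:2]))
      segs <- do.call(rbind, nums)
    }
  }
  cc <- grep("^CC   .*SUBCELLULAR LOCATION:", block, value = TRUE)
  locs <- character()
  if (length(cc) > 0L) {
    txt <- sub("^.*SUBCELLULAR LOCATION:\\s*", "", cc[1L])
    locs <- trimws(strsplit(txt, "[;.]")[[1]])
    locs <- locs[nzchar(locs) & !grepl("^\\{", locs)]
  }
  protein_record(accession, sequence, segs, locs, source_dataset = "flatfile")
}

parse_fasta_plus_table <- function(fasta_path, table_path = NULL,
                                   strict = FALSE) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) return(list())
  acc <- sub("\\s.*$", "", names(seqs))
  ann <- NULL
  if (!is.null(table_path)) {
    if (!file.exists(table_path)) stop("unreadable table: ", table_path)
    ann <- utils::read.delim(table_path, stringsAsFactors = FALSE,
                             check.names = FALSE, colClasses = "character")
    needed <- c("accession", "Transmembrane", "Subcellular_location")
    missing_cols <- setdiff(needed, names(ann))
    if (length(missing_cols) > 0L)
      stop("annotation table lacks column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  records <- list()
  for (i in seq_along(seqs)) {
    segs <- matrix(integer(0), ncol = 2L)
    locs <- character()
    if (!is.null(ann)) {
      row <- match(acc[i], ann$accession)
      if (!is.na(row)) {
        segs <- parse_tm_cell(ann$Transmembrane[row])
        loc_cell <- ann$Subcellular_location[row]
        if (!is.na(loc_cell) && nzchar(trimws(loc_cell)))
          locs <- trimws(strsplit(loc_cell, ";")[[1]])
      }
    }
    rec <- tryCatch(
      protein_record(acc[i], as.character(seqs[[i]]), segs, locs,
                     source_dataset = "fasta_plus_table"),
      error = function(err) err)
    if (inherits(rec, "error")) {
      msg <- sprintf("skipping malformed entry %d (%s): %s", i, acc[i],
                     conditionMessage(rec))
      if (strict) stop(msg) else {
        warning(msg, call. = FALSE)
        next
      }
    }
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Write a catalog in the FASTA + annotation-table dialect
#'
#' The written pair round-trips through
#' `parse_records(dialect = "fasta_plus_table")` field-by-field (except
#' `source_dataset`, which records provenance).
#'
#' @param records List of [protein_record()]s.
#' @param fasta_path,table_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_catalog <- function(records, fasta_path, table_path) {
  acc <- vapply(records, function(r) r$accession, character(1))
  seqs <- Biostrings::AAStringSet(
    vapply(records, function(r) r$sequence, character(1)))
  names(seqs) <- acc
  Biostrings::writeXStringSet(seqs, fasta_path)
  tm_cell <- vapply(records, function(r) {
    if (nrow(r$tm_segments) == 0L) return("")
    paste(sprintf("TRANSMEM %d..%d", r$tm_segments[, 1L],
                  r$tm_segments[, 2L]), collapse = "; ")
  }, character(1))
  loc_cell <- vapply(records, function(r)
    paste(r$subcellular_locations, collapse = "; "), character(1))
  tab <- data.frame(accession = acc, Transmembrane = tm_cell,
                    Subcellular_location = loc_cell,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, table = table_path))
}
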