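flatfile_entry <- function(acc, seq, tm = NULL, loc = NULL) {
  lines <- c(sprintf("ID   %s_TEST            Reviewed;        %d AA.",
                     acc, nchar(seq)),
             sprintf("AC   %s; X99999;", acc))
  if (!is.null(loc))
    lines <- c(lines, sprintf("CC   -!- SUBCELLULAR LOCATION: %s.", loc))
  if (!is.null(tm)) {
    for (i in seq_len(nrow(tm))) {
      lines <- c(lines,
                 sprintf("FT   TRANSMEM        %d..%d", tm[i, 1], tm[i, 2]),
                 "FT                   /note=\"Helical\"")
    }
  }
  chunks <- substring(seq, seq(1, nchar(seq), 60), pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
  c(lines,
    sprintf("SQ   SEQUENCE   %d AA;  0 MW;  0000000000000000 CRC64;",
            nchar(seq)),
    paste0("     ", chunks),
    "//")
}

test_that("flat-file parsing extracts sequence, TRANSMEM segments and locations", {
  set.seed(11)
  seq80 <- random_sequence(80)
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    flatfile_entry("P00001", seq80, tm = rbind(c(11L, 31L), c(45L, 65L))),
    flatfile_entry("P00002", random_sequence(50),
                   loc = "Endoplasmic reticulum membrane; Multi-pass membrane protein")
  ), path)
  recs <- parse_records(path, "flatfile")
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$accession, "P00001")
  expect_equal(recs[[1]]$sequence, seq80)
  expect_equal(nrow(recs[[1]]$tm_segments), 2L)
  expect_equal(unname(recs[[1]]$tm_segments[, "start"]), c(11L, 45L))
  expect_equal(unname(recs[[1]]$tm_segments[, "end"]), c(31L, 65L))
  expect_equal(count_tmds(recs[[2]]), 0L)
  expect_true(any(grepl("Endoplasmic reticulum",
                        recs[[2]]$subcellular_locations)))
})

test_that("empty input yields an empty catalog and malformed entries are skipped or raised", {
  empty <- withr::local_tempfile(fileext = ".dat")
  writeLines(character(), empty)
  expect_length(parse_records(empty, "flatfile"), 0L)

  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    flatfile_entry("P00010", random_sequence(30),
                   tm = rbind(c(5L, 60L))),        # end beyond length
    flatfile_entry("P00011", random_sequence(40))
  ), bad)
  expect_warning(recs <- parse_records(bad, "flatfile"), "malformed")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$accession, "P00011")
  expect_error(parse_records(bad, "flatfile", strict = TRUE), "malformed")
  expect_error(parse_records(file.path(tempdir(), "nope.dat"), "flatfile"),
               "unreadable")
})

test_that("FASTA+table dialect parses, tolerates empty annotation, and round-trips", {
  set.seed(12)
  recs <- list(
    protein_record("A0001", random_sequence(90),
                   rbind(c(10L, 30L), c(50L, 70L)),
                   c("Endoplasmic reticulum membrane", "Cytoplasm")),
    protein_record("A0002", random_sequence(40)),
    protein_record("A0003", random_sequence(120), rbind(c(3L, 23L))))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(recs, fa, tsv)
  back <- parse_records(fa, "fasta_plus_table", table = tsv)
  expect_length(back, 3L)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$accession, recs[[i]]$accession)
    expect_equal(back[[i]]$sequence, recs[[i]]$sequence)
    expect_equal(back[[i]]$tm_segments, recs[[i]]$tm_segments)
    expect_equal(back[[i]]$subcellular_locations,
                 recs[[i]]$subcellular_locations)
  }
  # record with an empty Transmembrane cell has no segments
  expect_equal(nrow(back[[2]]$tm_segments), 0L)
})

test_that("record invariants are enforced and segment order is normalized", {
  expect_error(protein_record("X", ""), "nonempty")
  expect_error(protein_record("X", "ACDJ"), "invalid letters")
  expect_error(protein_record("X", "ACDEFG", rbind(c(2L, 9L))),
               "violate")
  expect_error(protein_record("X", paste(rep("A", 50), collapse = ""),
                              rbind(c(1L, 20L), c(15L, 40L))), "overlap")
  # segments given out of order are sorted: TMD count unchanged
  r1 <- protein_record("X", random_sequence(100),
                       rbind(c(60L, 80L), c(10L, 30L)))
  expect_equal(unname(r1$tm_segments[, "start"]), c(10L, 60L))
  expect_equal(count_tmds(r1), 2L)
})

test_that("category assignment follows the TMD bins, ER terms and family precedence", {
  rec7 <- protein_record("C1", random_sequence(300),
                         cbind(seq(1, 281, 40), seq(21, 301, 40))[1:7, ])
  expect_equal(count_tmds(rec7), 7L)
  lab <- assign_categories(rec7)
  expect_true(all(c("ALL", "TM_ANY", "TM_6_10") %in% lab))

  sol <- protein_record("S1", random_sequence(100))
  lab <- assign_categories(sol)
  expect_true("SOLUBLE" %in% lab)
  expect_false(any(c("TM_ANY", "TM_1", "TM_2_5", "TM_6_10", "TM_GE11")
                   %in% lab))

  # accession in both membership sets: CERS wins
  lab <- assign_categories(sol, cers_accessions = "S1",
                           tlc_accessions = "S1")
  expect_true("CERS" %in% lab)
  expect_false("TLC_OTHER" %in% lab)

  # ER matching is case-insensitive substring
  er <- protein_record("E1", random_sequence(100),
                       subcellular_locations = "ENDOPLASMIC RETICULUM lumen")
  expect_true("ER" %in% assign_categories(er))

  # bin boundaries
  mk <- function(k) protein_record("B", random_sequence(25 * k + 30),
                                   cbind(seq(1, by = 25, length.out = k),
                                         seq(21, by = 25, length.out = k)))
  expect_true("TM_1" %in% assign_categories(mk(1)))
  expect_true("TM_2_5" %in% assign_categories(mk(5)))
  expect_true("TM_6_10" %in% assign_categories(mk(6)))
  expect_true("TM_GE11" %in% assign_categories(mk(11)))
})

test_that("categories partition the catalog: SOLUBLE + TM_ANY = ALL, bins partition TM_ANY", {
  set.seed(13)
  recs <- lapply(1:40, function(i) {
    k <- sample(0:12, 1)
    len <- 30 + 25 * k + sample(0:50, 1)
    segs <- if (k > 0) cbind(seq(1, by = 25, length.out = k),
                             seq(21, by = 25, length.out = k)) else NULL
    protein_record(sprintf("R%03d", i), random_sequence(len), segs)
  })
  m <- categorize_catalog(recs)
  expect_equal(sum(m[, "SOLUBLE"]) + sum(m[, "TM_ANY"]), sum(m[, "ALL"]))
  bins <- m[, c("TM_1", "TM_2_5", "TM_6_10", "TM_GE11"), drop = FALSE]
  expect_equal(unname(rowSums(bins)), as.numeric(m[, "TM_ANY"]))
  expect_false(any(m[, "SOLUBLE"] & m[, "TM_ANY"]))
})
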