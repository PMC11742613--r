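small_census_sim <- function(seed = 91, n = 20, len = 180) {
  gen_proteome(list(
    category_spec("cers", n, c(len, len), tmd_counts = 7L,
                  location = "Endoplasmic reticulum membrane"),
    category_spec("tm_6_10", n, c(len, len), tmd_counts = 4L),
    category_spec("tlc_other", n, c(len, len), tmd_counts = 4L)),
    seed = seed)
}

test_that("census pipeline summarizes categories, tests Trp, and reruns byte-identically", {
  sim <- small_census_sim()
  out1 <- withr::local_tempdir()
  cfg <- pipeline_config(
    out_dir = out1, seed = 91, records = sim$records,
    cers_accessions = sim$truth$accession[sim$truth$label == "cers"],
    tlc_accessions = sim$truth$accession[sim$truth$label == "tlc_other"],
    compare_labels = c("TM_2_5", "CERS", "TLC_OTHER"))
  msgs <- capture_messages(res <- run_census(cfg))
  expect_true(any(grepl("60 records in", msgs)))
  expect_true(all(c("census_table.tsv", "category_summaries.json",
                    "group_tests.json", "manifest.json")
                  %in% list.files(out1)))
  expect_true(all(c("ALL", "CERS", "TLC_OTHER", "ER") %in%
                    names(res$summaries)))
  expect_s3_class(res$anova, "trp_test")
  expect_length(res$tukey, 3L)
  # conservation of inputs: categorized + rejected = in
  expect_equal(res$counts$records_in, 60L)
  expect_equal(res$counts$n_ALL, 60L)

  out2 <- withr::local_tempdir()
  cfg2 <- cfg
  cfg2$out_dir <- out2
  suppressMessages(run_census(cfg2))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("census with a single comparison category skips group tests with a logged reason", {
  sim <- gen_proteome(list(category_spec("cers", 8, c(160, 160),
                                         tmd_counts = 7L)), seed = 92)
  out <- withr::local_tempdir()
  cfg <- pipeline_config(
    out_dir = out, seed = 92, records = sim$records,
    cers_accessions = sim$truth$accession)
  msgs <- capture_messages(res <- run_census(cfg))
  expect_true(any(grepl("group tests skipped", msgs)))
  expect_null(res$anova)
  tests <- jsonlite::fromJSON(file.path(out, "group_tests.json"))
  expect_match(tests$skipped, "fewer than two")
})

test_that("depth pipeline rejects exactly the mis-oriented structures and compares cohorts", {
  dir <- withr::local_tempdir()
  n_hox <- 6
  n_bad <- 2
  n_non <- 4
  rows <- list()
  draw <- gen_depth_cohort(n_a = 200, n_b = 200, seed = 93)
  withr::local_seed(93)
  for (i in seq_len(n_hox + n_non)) {
    is_hox <- i <= n_hox
    is_bad <- i <= n_bad          # first two hox bundles mis-oriented
    depth_pool <- if (is_hox) draw$hox else draw$nonhox
    b <- gen_helical_bundle(
      trp_depths = sample(depth_pool, 6),
      hox_side = if (is_bad) "lumenal" else "cytoplasmic",
      seed = 930 + i,
      accession = sprintf("%s%02d", if (is_hox) "HOX" else "NON", i))
    write_structure(b$model, file.path(dir, paste0(b$model$accession,
                                                   ".pdb")))
    rows[[i]] <- data.frame(
      accession = b$model$accession,
      cohort = if (is_hox) "hox" else "nonhox",
      hox_start = b$ranges$hox[1], hox_end = b$ranges$hox[2],
      nterm_start = b$ranges$nterm[1], nterm_end = b$ranges$nterm[2],
      cyt_start = b$ranges$cterm[1], cyt_end = b$ranges$cterm[2])
  }
  out <- withr::local_tempdir()
  cfg <- pipeline_config(out_dir = out, seed = 93, models_dir = dir,
                         cohorts = do.call(rbind, rows))
  msgs <- capture_messages(res <- run_depth(cfg))
  expect_setequal(res$rejected, c("HOX01", "HOX02"))
  expect_length(res$profiles, n_hox + n_non - n_bad)
  expect_s3_class(res$comparison, "trp_test")
  expect_true(all(c("depths.tsv", "trp_depths.tsv",
                    "cohort_comparison.json", "manifest.json")
                  %in% list.files(out)))
  trp <- read.delim(file.path(out, "trp_depths.tsv"))
  expect_setequal(unique(trp$cohort), c("hox", "nonhox"))
  expect_true(all(abs(trp$z) <= 40))
  # conservation of inputs across the filter
  expect_equal(res$counts$profiled + res$counts$rejected,
               res$counts$models_in)
})

test_that("depth pipeline fails cleanly on an empty model directory", {
  empty <- withr::local_tempdir()
  out <- withr::local_tempdir()
  cfg <- pipeline_config(out_dir = out, seed = 1, models_dir = empty,
                         cohorts = data.frame(accession = "X",
                                              cohort = "hox"))
  expect_error(run_depth(cfg), "no coordinate files")
})

test_that("conservation pipeline ranks planted columns, handles k = 0, reruns identically", {
  sim <- gen_msa(n_rows = 40, n_cols = 30, conserved_cols = c(6, 21),
                 seed = 94)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_msa(sim$aln, fa)
  out1 <- withr::local_tempdir()
  cfg <- pipeline_config(out_dir = out1, seed = 94, msa = fa,
                         reference_id = "seq001", k = 5)
  res <- suppressMessages(run_conserve(cfg))
  expect_setequal(res$ranking$column[1:2], c(6, 21))
  expect_true(all(c("ic_table.tsv", "top_positions.tsv",
                    "logo_heights.tsv", "manifest.json")
                  %in% list.files(out1)))

  cfg0 <- cfg
  cfg0$k <- 0
  cfg0$out_dir <- withr::local_tempdir()
  res0 <- suppressMessages(run_conserve(cfg0))
  expect_equal(nrow(res0$ranking), 0L)

  out2 <- withr::local_tempdir()
  cfg2 <- cfg
  cfg2$out_dir <- out2
  suppressMessages(run_conserve(cfg2))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }

  cfg_bad <- cfg
  cfg_bad$reference_id <- "missing"
  expect_error(suppressMessages(run_conserve(cfg_bad)), "unknown reference")
})
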