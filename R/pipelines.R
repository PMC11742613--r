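#' Pipeline configuration
#'
#' One place for the fixed analysis thresholds (units are spelled out in
#' the names to avoid silent unit errors) plus the input paths and seed a
#' pipeline run needs. Unknown fields are carried through untouched, so
#' each pipeline documents the fields it reads.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and used for any
#'   randomness.
#' @param identity_threshold Redundancy-filter threshold (0.7).
#' @param min_seqs_per_column Alignment column-occupancy threshold (10).
#' @param half_thickness_angstrom Membrane slab half-thickness (18).
#' @param depth_window_angstrom Depth analysis window (40).
#' @param ... Further pipeline-specific fields (see [run_census()],
#'   [run_depth()], [run_conserve()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            identity_threshold = 0.7,
                            min_seqs_per_column = 10,
                            half_thickness_angstrom = 18,
                            depth_window_angstrom = 40, ...) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            min_seqs_per_column >= 1, half_thickness_angstrom > 0,
            depth_window_angstrom > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 identity_threshold = identity_threshold,
                 min_seqs_per_column = min_seqs_per_column,
                 half_thickness_angstrom = half_thickness_angstrom,
                 depth_window_angstrom = depth_window_angstrom, ...),
            class = "pipeline_config")
}

write_manifest <- function(config, pipeline, counts = list()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    pipeline = pipeline,
    package = "trpcensus",
    version = as.character(utils::packageVersion("trpcensus")),
    seed = config$seed,
    thresholds = list(
      identity_threshold = config$identity_threshold,
      min_seqs_per_column = config$min_seqs_per_column,
      half_thickness_angstrom = config$half_thickness_angstrom,
      depth_window_angstrom = config$depth_window_angstrom),
    inputs = config[setdiff(names(config),
                            c("out_dir", "seed", "identity_threshold",
                              "min_seqs_per_column",
                              "half_thickness_angstrom",
                              "depth_window_angstrom"))],
    counts = counts)
  manifest$inputs <- manifest$inputs[
    vapply(manifest$inputs, function(x)
      is.character(x) || is.numeric(x) || is.logical(x), logical(1))]
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the composition census pipeline
#'
#' Stages: parse (or take) the catalog, assign categories,
#' redundancy-filter each category separately at the identity threshold,
#' compute per-protein compositions of the representatives, summarize
#' each category, and compare tryptophan percent across the configured
#' comparison groups with one-way ANOVA plus Tukey HSD. Every stage logs
#' its counts; categories left empty after filtering are reported and
#' omitted, and the group comparison is skipped (with a logged reason)
#' when fewer than two comparison groups survive.
#'
#' Config fields read: `records` (list of [protein_record()]s) or
#' `fasta` + `table` paths, `cers_accessions`, `tlc_accessions`,
#' `er_location_terms` (default "endoplasmic reticulum"),
#' `compare_labels` (default `TM_6_10`, `CERS`, `TLC_OTHER`).
#'
#' Writes `census_table.tsv`, `category_summaries.json`,
#' `group_tests.json` and `manifest.json` under `out_dir`; reruns with
#' the same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summaries`, `anova`, `tukey`,
#'   `counts`.
#' @export
run_census <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- config[["records"]]
  if (is.null(records)) {
    if (is.null(config[["fasta"]])) stop("config needs 'records' or 'fasta'")
    records <- parse_records(config[["fasta"]], "fasta_plus_table",
                             table = config[["table"]])
  }
  if (length(records) == 0L) stop("empty catalog")
  message("census: ", length(records), " records in")
  er_terms <- config[["er_location_terms"]]
  if (is.null(er_terms)) er_terms <- "endoplasmic reticulum"
  membership <- categorize_catalog(
    records,
    cers_accessions = config[["cers_accessions"]] %||% character(),
    tlc_accessions = config[["tlc_accessions"]] %||% character(),
    er_location_terms = er_terms)
  message("census: ", nrow(membership), " records categorized, 0 rejected")
  acc <- rownames(membership)
  cache <- new.env(parent = emptyenv())
  summaries <- list()
  counts <- list(records_in = length(records))
  comp_by_cat <- list()
  for (lab in CATEGORY_LABELS) {
    sel <- which(membership[, lab])
    if (length(sel) == 0L) next
    reps <- nonredundant(records[sel], c = config$identity_threshold,
                         cache = cache)
    if (length(reps) == 0L) {
      message("census: category ", lab, " empty after filtering; omitted")
      next
    }
    vecs <- lapply(reps, function(r) composition_of(r$sequence))
    names(vecs) <- vapply(reps, function(r) r$accession, character(1))
    comp_by_cat[[lab]] <- vecs
    summaries[[lab]] <- summarize_category(vecs, lab)
    counts[[paste0("n_", lab)]] <- length(reps)
    message("census: ", lab, " - ", length(sel), " records, ",
            length(reps), " nonredundant")
  }
  if (length(summaries) == 0L) stop("no category survived filtering")

  compare_labels <- config[["compare_labels"]] %||%
    c("TM_6_10", "CERS", "TLC_OTHER")
  have <- intersect(compare_labels, names(comp_by_cat))
  anova_res <- NULL
  tukey_res <- NULL
  if (length(have) >= 2L) {
    # ANOVA needs disjoint groups: family members (which also sit in a TMD
    # bin) stay out of the non-family comparison groups.
    family <- acc[membership[, "CERS"] | membership[, "TLC_OTHER"]]
    trp_groups <- lapply(have, function(lab) {
      vecs <- comp_by_cat[[lab]]
      keep <- if (lab %in% c("CERS", "TLC_OTHER")) rep(TRUE, length(vecs))
              else !(names(vecs) %in% family)
      vapply(vecs[keep], function(v) v$percent[["W"]], numeric(1))
    })
    names(trp_groups) <- have
    trp_groups <- trp_groups[lengths(trp_groups) >= 2L]
    have <- names(trp_groups)
  }
  if (length(have) >= 2L) {
    anova_res <- anova_oneway(trp_groups)
    tukey_res <- tukey_hsd(trp_groups, labels = have)
    message("census: Trp comparison across ",
            paste(have, collapse = ", "), ": F = ",
            format(anova_res$statistic, digits = 4), ", p = ",
            format(anova_res$p_value, digits = 3))
  } else {
    message("census: group tests skipped - fewer than two of the ",
            "comparison categories (", paste(compare_labels, collapse = ", "),
            ") are present")
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(census_table(summaries),
            file.path(config$out_dir, "census_table.tsv"))
  jsonlite::write_json(
    lapply(summaries, function(s)
      list(label = s$label, n_proteins = s$n_proteins, stats = s$stats)),
    file.path(config$out_dir, "category_summaries.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tests <- list()
  if (!is.null(anova_res)) {
    tests$anova <- unclass(anova_res)
    tests$tukey <- lapply(tukey_res, unclass)
  } else {
    tests$skipped <- "fewer than two comparison groups"
  }
  jsonlite::write_json(tests, file.path(config$out_dir, "group_tests.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(config, "census", counts)
  invisible(list(summaries = summaries, anova = anova_res,
                 tukey = tukey_res, counts = counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the membrane-depth pipeline
#'
#' Stages: parse every coordinate file, place and orient the membrane
#' slab, apply the Hox/N-terminus orientation filter (rejects logged),
#' compute depths within the analysis window, pool tryptophan depths per
#' cohort and compare the two cohorts with the two-sided Mann-Whitney U
#' test.
#'
#' Config fields read: `models_dir` (directory of `.pdb` files) or
#' `models` (list of [structure_model()]s), and `cohorts` — a data frame
#' or TSV path with columns `accession`, `cohort`, and optional
#' `hox_start`, `hox_end`, `nterm_start`, `nterm_end` (enable the
#' orientation filter) and `cyt_start`, `cyt_end` (cytoplasmic reference
#' segment; default last 10 modeled residues). `n_directions` (default
#' 500) sizes the placement grid.
#'
#' Writes `depths.tsv` (per-residue), `trp_depths.tsv` (violin-ready
#' two-cohort layout), `cohort_comparison.json` and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `profiles`, `comparison`, `rejected`,
#'   `counts`.
#' @export
run_depth <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  models <- config[["models"]]
  if (is.null(models)) {
    if (is.null(config[["models_dir"]])) stop("config needs 'models' or 'models_dir'")
    paths <- sort(list.files(config[["models_dir"]], pattern = "\\.pdb$",
                             full.names = TRUE))
    if (length(paths) == 0L)
      stop("no coordinate files in ", config[["models_dir"]])
    models <- lapply(paths, parse_structure)
  }
  cohorts <- config[["cohorts"]]
  if (is.character(cohorts))
    cohorts <- utils::read.delim(cohorts, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(cohorts),
            all(c("accession", "cohort") %in% names(cohorts)))
  message("depth: ", length(models), " models in")

  profiles <- list()
  rejected <- character()
  cohort_of <- character()
  for (model in models) {
    row <- match(model$accession, cohorts$accession)
    if (is.na(row)) {
      message("depth: ", model$accession, " not in cohort table; skipped")
      next
    }
    frame <- place_membrane(model, n_directions = config[["n_directions"]] %||% 500,
                            half_thickness = config$half_thickness_angstrom)
    cyt <- NULL
    if (!is.null(cohorts$cyt_start) && !is.na(cohorts$cyt_start[row]))
      cyt <- seq(cohorts$cyt_start[row], cohorts$cyt_end[row])
    frame <- orient_frame(frame, model, cytoplasmic_residues = cyt)
    has_hox <- !is.null(cohorts$hox_start) && !is.na(cohorts$hox_start[row])
    if (has_hox) {
      verdict <- hox_orientation_filter(
        model, frame,
        hox_range = c(cohorts$hox_start[row], cohorts$hox_end[row]),
        nterm_range = c(cohorts$nterm_start[row], cohorts$nterm_end[row]))
      if (verdict == "reject") {
        message("depth: ", model$accession,
                " rejected (N-terminus on the Hox-domain side)")
        rejected <- c(rejected, model$accession)
        next
      }
    }
    profiles[[model$accession]] <-
      residue_depths(model, frame, window = config$depth_window_angstrom)
    cohort_of[model$accession] <- cohorts$cohort[row]
  }
  message("depth: ", length(profiles), " models profiled, ",
          length(rejected), " rejected")
  levels <- unique(cohorts$cohort)
  if (length(levels) != 2L)
    stop("cohort table must define exactly two cohorts, got: ",
         paste(levels, collapse = ", "))
  by_cohort <- split(profiles, factor(cohort_of[names(profiles)],
                                      levels = levels))
  if (any(lengths(by_cohort) == 0L))
    stop("cohort with zero surviving structures: ",
         paste(levels[lengths(by_cohort) == 0L], collapse = ", "))
  comparison <- compare_trp_depths(by_cohort[[1L]], by_cohort[[2L]])
  message("depth: Mann-Whitney U = ", format(comparison$statistic),
          ", p = ", format(comparison$p_value, digits = 3))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  all_depths <- do.call(rbind, lapply(names(profiles), function(a) {
    p <- profiles[[a]]
    data.frame(accession = a, cohort = unname(cohort_of[a]), p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  write_tsv(all_depths, file.path(config$out_dir, "depths.tsv"))
  trp <- all_depths[all_depths$restype == "W" & all_depths$included, ]
  write_tsv(trp[, c("cohort", "accession", "resno", "z", "region")],
            file.path(config$out_dir, "trp_depths.tsv"))
  jsonlite::write_json(
    list(comparison = unclass(comparison), cohorts = as.list(levels),
         rejected = rejected),
    file.path(config$out_dir, "cohort_comparison.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  counts <- list(models_in = length(models),
                 profiled = length(profiles), rejected = length(rejected))
  write_manifest(config, "depth", counts)
  invisible(list(profiles = profiles, comparison = comparison,
                 rejected = rejected, counts = counts))
}

#' Run the conservation pipeline
#'
#' Stages: read and occupancy-filter the alignment, compute per-column
#' information content, rank the top-k conserved positions with
#' reference-sequence numbering, and compute sequence-logo letter
#' heights.
#'
#' Config fields read: `msa` (aligned FASTA path or `msa_alignment`),
#' `reference_id`, `k` (default 10).
#'
#' Writes `ic_table.tsv`, `top_positions.tsv`, `logo_heights.tsv` and
#' `manifest.json`; reruns are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `ranking`, `ic`, `heights`.
#' @export
run_conserve <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  aln <- config[["msa"]]
  if (is.character(aln))
    aln <- read_and_filter_msa(aln, min_seqs = config$min_seqs_per_column)
  stopifnot(inherits(aln, "msa_alignment"))
  if (is.null(config[["reference_id"]])) stop("config needs 'reference_id'")
  message("conserve: ", nrow(aln$matrix), " sequences x ",
          ncol(aln$matrix), " columns, ", sum(aln$mask), " kept")
  ic <- alignment_ic(aln)
  ranking <- rank_positions(aln, config[["reference_id"]],
                            k = config[["k"]] %||% 10)
  heights <- logo_heights(aln)
  message("conserve: top position column ",
          if (nrow(ranking) > 0) ranking$column[1] else NA,
          " with IC ",
          if (nrow(ranking) > 0) format(ranking$ic[1], digits = 4) else NA)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(column = seq_along(ic), kept = aln$mask, ic = ic),
            file.path(config$out_dir, "ic_table.tsv"))
  write_tsv(ranking, file.path(config$out_dir, "top_positions.tsv"))
  write_tsv(heights, file.path(config$out_dir, "logo_heights.tsv"))
  write_manifest(config, "conserve",
                 list(n_sequences = nrow(aln$matrix),
                      n_columns = ncol(aln$matrix),
                      n_kept = sum(aln$mask)))
  invisible(list(ranking = ranking, ic = ic, heights = heights))
}
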