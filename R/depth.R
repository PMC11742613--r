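#' Construct a structure model
#'
#' An ordered Calpha trace: one residue number, one-letter type and one
#' Calpha coordinate per residue.
#'
#' @param accession Identifier tag.
#' @param resno Strictly increasing integer residue numbers.
#' @param restype One-letter residue types.
#' @param xyz Numeric matrix (n x 3) of Calpha coordinates in Angstrom.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(accession, resno, restype, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(resno),
            length(restype) == length(resno))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  resno <- as.integer(resno)
  if (length(resno) == 0L) stop("empty model")
  if (any(diff(resno) <= 0L)) stop("residue numbers not strictly increasing")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(accession = accession, resno = resno,
                 restype = as.character(restype), xyz = xyz),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$accession, "-", length(x$resno), "residues,",
      sum(x$restype == "W"), "Trp\n")
  invisible(x)
}

#' Parse a Calpha model from a PDB coordinate file
#'
#' Reads ATOM records, keeps one Calpha per residue (alternate locations
#' resolved by first occurrence) and skips non-standard residues with a
#' warning.
#'
#' @param path PDB-format coordinate file.
#' @param accession Tag for the model; defaults to the file name.
#' @return A [structure_model()].
#' @export
parse_structure <- function(path, accession = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (is.null(accession))
    accession <- sub("\\.[^.]*$", "", basename(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha atoms in ", path)
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  ca <- ca[!duplicated(key), , drop = FALSE]    # altloc: first occurrence
  one <- suppressWarnings(bio3d::aa321(ca$resid))
  std <- one %in% AA_STANDARD
  if (any(!std)) {
    warning("skipping ", sum(!std), " non-standard residue(s): ",
            paste(unique(ca$resid[!std]), collapse = ", "), call. = FALSE)
    ca <- ca[std, , drop = FALSE]
    one <- one[std]
  }
  if (nrow(ca) == 0L) stop("no standard-residue Calpha atoms in ", path)
  structure_model(accession, ca$resno, one,
                  cbind(ca$x, ca$y, ca$z))
}

#' Construct a membrane frame
#'
#' A planar membrane slab: unit normal, center offset `d0` along the
#' normal, and half-thickness (default 18 Angstrom, the mean predicted
#' bilayer boundary). The signed depth of a point `p` is
#' `dot(p, normal) - d0`; after [orient_frame()] the positive side is
#' cytoplasmic.
#'
#' @param normal Length-3 vector; normalized internally.
#' @param d0 Center offset along the normal (Angstrom).
#' @param half_thickness Half-thickness in Angstrom (> 0).
#' @param oriented Whether the sign convention has been fixed.
#' @return Object of class `membrane_frame`.
#' @export
membrane_frame <- function(normal, d0 = 0, half_thickness = 18,
                           oriented = FALSE) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3L, all(is.finite(normal)),
            half_thickness > 0)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("zero normal vector")
  structure(list(normal = normal / nn, d0 = as.numeric(d0),
                 half_thickness = half_thickness, oriented = oriented),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> normal (%.3f, %.3f, %.3f), d0 %.2f A, half-thickness %.1f A%s\n",
              x$normal[1], x$normal[2], x$normal[3], x$d0,
              x$half_thickness, if (x$oriented) ", oriented" else ""))
  invisible(x)
}

# Deterministic spiral covering of the upper hemisphere (Fibonacci
# lattice); antipodal directions are score-equivalent so one hemisphere
# suffices.
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + crossprod_3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place a membrane slab on a structure model
#'
#' Surrogate for an orientations-of-proteins-in-membranes style
#' calculation: finds the slab that maximizes the summed per-residue
#' hydrophobicity inside a core window,
#' `S(normal, d0) = sum_i h(res_i) * 1[|z_i - d0| <= core_half_width]`,
#' by a deterministic grid search over `n_directions` spiral-distributed
#' unit normals, followed by local hill-climbing refinement of the
#' normal in 1-degree steps until no move improves the score. For each
#' candidate normal the score is piecewise constant in the offset `d0`,
#' so the optimum over offsets is computed exactly by enumerating the
#' residue entry/exit breakpoints (no offset grid), and the reported
#' `d0` is the midpoint of the optimal plateau — which makes the result
#' exactly invariant under translations of the model. The default
#' per-residue weight is the mean-centered Kyte-Doolittle scale. The
#' returned frame is unoriented; fix the sign with [orient_frame()].
#'
#' @param model A [structure_model()] with >= 20 residues.
#' @param scale Named hydrophobicity scale over the 20 letters; mean-
#'   centered internally. Default [kyte_doolittle].
#' @param core_half_width Core half-width of the scoring window
#'   (Angstrom).
#' @param n_directions Number of grid directions on the hemisphere.
#' @param half_thickness Half-thickness recorded in the returned frame
#'   (reporting convention; does not enter the objective).
#' @return An unoriented [membrane_frame()] with the achieved score in
#'   `attr(, "score")`.
#' @export
place_membrane <- function(model, scale = kyte_doolittle,
                           core_half_width = 15, n_directions = 500,
                           half_thickness = 18) {
  stopifnot(inherits(model, "structure_model"))
  n <- length(model$resno)
  if (n < 20L) stop("model must have >= 20 residues")
  scale <- scale - mean(scale)
  h <- unname(scale[model$restype])
  h[is.na(h)] <- 0
  coords <- model$xyz
  sv <- svd(sweep(coords, 2L, colMeans(coords)))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("degenerate model: Calpha trace is collinear")

  w <- core_half_width
  # exact optimum over the offset for a fixed normal: the windowed score
  # is piecewise constant in d0 with breakpoints where a residue enters
  # or leaves the core, so evaluating the breakpoint-interval midpoints
  # covers every attainable residue set
  best_offset <- function(z) {
    o <- order(z)
    zs <- z[o]
    cs0 <- c(0, cumsum(h[o]))
    n <- length(zs)
    bp <- sort(c(zs - w, zs + w))
    cand <- (bp[-1] + bp[-length(bp)]) / 2
    lo <- findInterval(cand - w - 1e-9, zs)
    hi <- findInterval(cand + w + 1e-9, zs)
    keep <- hi > lo                     # windows containing >= 1 residue
    cand <- cand[keep]; lo <- lo[keep]; hi <- hi[keep]
    s <- cs0[hi + 1L] - cs0[lo + 1L]
    m <- which.max(s)
    # midpoint of the d0 plateau realizing this residue set
    low_b <- max(zs[hi[m]] - w,
                 if (lo[m] >= 1L) zs[lo[m]] + w else -Inf,
                 bp[1])
    high_b <- min(zs[lo[m] + 1L] + w,
                  if (hi[m] < n) zs[hi[m] + 1L] - w else Inf,
                  bp[length(bp)])
    list(score = s[m], d0 = (low_b + high_b) / 2)
  }

  eval_dir <- function(dir) {
    r <- best_offset(as.numeric(coords %*% dir))
    list(score = r$score, dir = dir, d0 = r$d0)
  }
  ortho_axes <- function(dir) {
    ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    ax1 <- crossprod_3(dir, ref)
    ax1 <- ax1 / sqrt(sum(ax1^2))
    list(ax1, crossprod_3(dir, ax1))
  }
  ang <- pi / 180
  hill_climb <- function(best) {
    it <- 0L
    repeat {
      improved <- FALSE
      axes <- ortho_axes(best$dir)
      for (ax in axes) for (s in c(ang, -ang)) {
        cand <- eval_dir(rotate_about(best$dir, ax, s))
        if (cand$score > best$score + 1e-9) {
          best <- cand
          improved <- TRUE
        }
      }
      it <- it + 1L
      if (!improved || it > 720L) break
    }
    best
  }
  # The hard-window score is exactly flat over several degrees of normal
  # (the same optimal residue set is realized by many nearby frames),
  # which leaves the frame under-determined. Ties are broken by the
  # max-margin rule: among frames achieving the optimal score, report
  # the one that fits the included residues in the window with the
  # largest minimal slack to the window edges (the Chebyshev center of
  # the co-optimal region) — for a symmetric hydrophobic belt this is
  # its symmetry axis.
  margin_eval <- function(dir, target_score) {
    z <- as.numeric(coords %*% dir)
    r <- best_offset(z)
    if (r$score < target_score - 1e-9) return(NULL)   # off the plateau
    o <- order(z)
    zs <- z[o]
    n <- length(zs)
    # recover the included index range at the reported optimum
    lo <- findInterval(r$d0 - w - 1e-9, zs)
    hi <- findInterval(r$d0 + w + 1e-9, zs)
    z_in_lo <- zs[lo + 1L]
    z_in_hi <- zs[hi]
    z_out_lo <- if (lo >= 1L) zs[lo] else -Inf
    z_out_hi <- if (hi < n) zs[hi + 1L] else Inf
    margin_at <- function(d) {
      min(w - max(z_in_hi - d, d - z_in_lo),
          z_out_hi - d - w, d - z_out_lo - w)
    }
    grid <- seq(z_in_hi - w, z_in_lo + w, by = 0.02)
    if (length(grid) == 0L) grid <- (z_in_hi + z_in_lo) / 2
    vals <- vapply(grid, margin_at, numeric(1))
    m <- which.max(vals)
    list(dir = dir, d0 = grid[m], score = r$score, margin = vals[m])
  }
  margin_refine <- function(best) {
    cur <- margin_eval(best$dir, best$score)
    for (step in c(1, 0.5, 0.25, 0.1)) {
      it <- 0L
      repeat {
        improved <- FALSE
        for (ax in ortho_axes(cur$dir)) for (sgn in c(1, -1)) {
          cand <- margin_eval(rotate_about(cur$dir, ax, sgn * step * ang),
                              best$score)
          if (!is.null(cand) && cand$margin > cur$margin + 1e-9) {
            cur <- cand
            improved <- TRUE
          }
        }
        it <- it + 1L
        if (!improved || it > 180L) break
      }
    }
    cur
  }

  dirs <- fibonacci_hemisphere(n_directions)
  Z <- coords %*% t(dirs)
  grid <- lapply(seq_len(n_directions), function(d) {
    r <- best_offset(Z[, d])
    list(score = r$score, dir = dirs[d, ], d0 = r$d0)
  })
  scores <- vapply(grid, `[[`, numeric(1), "score")
  # multi-start refinement from the best-scoring grid directions guards
  # against hill-climb stalls on rugged parts of the score surface
  starts <- order(scores, decreasing = TRUE)[seq_len(min(10L, n_directions))]
  best <- list(score = -Inf)
  for (s in starts) {
    cand <- hill_climb(grid[[s]])
    if (cand$score > best$score) best <- cand
  }
  final <- margin_refine(best)
  out <- membrane_frame(final$dir, final$d0, half_thickness,
                        oriented = FALSE)
  attr(out, "score") <- final$score
  out
}

#' Fix the sign convention of a membrane frame
#'
#' Flips the normal (and center offset) if needed so that the mean depth
#' of a known-cytoplasmic residue set is positive. For ceramide-synthase-
#' like topology (cytosolic C-terminus) the default reference set is the
#' last 10 modeled residues.
#'
#' @param frame A [membrane_frame()].
#' @param model The [structure_model()] the frame was placed on.
#' @param cytoplasmic_residues Residue numbers of the cytoplasmic
#'   reference set; `NULL` uses the last 10 modeled residues.
#' @return The oriented [membrane_frame()].
#' @export
orient_frame <- function(frame, model, cytoplasmic_residues = NULL) {
  stopifnot(inherits(frame, "membrane_frame"),
            inherits(model, "structure_model"))
  if (is.null(cytoplasmic_residues))
    cytoplasmic_residues <- utils::tail(model$resno, 10L)
  sel <- model$resno %in% cytoplasmic_residues
  if (!any(sel)) stop("cytoplasmic reference set not present in model")
  z <- coords_depth(model, frame)[sel]
  m <- mean(z)
  if (m == 0) stop("ambiguous orientation: reference set mean depth is 0")
  if (m < 0) {
    frame$normal <- -frame$normal
    frame$d0 <- -frame$d0
  }
  frame$oriented <- TRUE
  frame
}

coords_depth <- function(model, frame) {
  as.numeric(model$xyz %*% frame$normal) - frame$d0
}

#' Signed per-residue Calpha depths
#'
#' Depth of each Calpha along the membrane normal, relative to the
#' bilayer center (0 Angstrom), cytoplasmic side positive once the frame
#' is oriented. Residues beyond the analysis window (default 40 Angstrom
#' from the center) are masked out: they stay in the table with
#' `included = FALSE` and carry no depth or region.
#'
#' @param model A [structure_model()].
#' @param frame An oriented [membrane_frame()].
#' @param window Analysis window half-width in Angstrom.
#' @return Object of class `depth_profile`: data frame with columns
#'   `resno`, `restype`, `z`, `region`, `included`, plus an `accession`
#'   attribute.
#' @export
residue_depths <- function(model, frame, window = 40) {
  stopifnot(inherits(model, "structure_model"),
            inherits(frame, "membrane_frame"))
  z <- coords_depth(model, frame)
  included <- abs(z) <= window
  out <- data.frame(resno = model$resno, restype = model$restype,
                    z = ifelse(included, z, NA_real_),
                    region = ifelse(included,
                                    classify_region(z, frame$half_thickness),
                                    NA_character_),
                    included = included, stringsAsFactors = FALSE)
  attr(out, "accession") <- model$accession
  class(out) <- c("depth_profile", class(out))
  out
}

#' Classify a depth into membrane regions
#'
#' With the cytoplasmic-positive convention: depths beyond
#' `+half_thickness` are cytoplasmic space, depths beyond
#' `-half_thickness` are lumenal space, and depths inside the slab fall
#' in the cytoplasmic (`z >= 0`; the bilayer center itself is assigned to
#' the cytoplasmic half by this declared tie rule) or lumenal half.
#'
#' @param z Numeric vector of signed depths (Angstrom).
#' @param half_thickness Slab half-thickness (Angstrom).
#' @return Character vector over `cytoplasmic_space`,
#'   `cytoplasmic_interface_core`, `lumenal_interface_core`,
#'   `lumenal_space`.
#' @export
classify_region <- function(z, half_thickness = 18) {
  stopifnot(all(is.finite(z)))
  ifelse(z > half_thickness, "cytoplasmic_space",
         ifelse(z >= 0, "cytoplasmic_interface_core",
                ifelse(z >= -half_thickness, "lumenal_interface_core",
                       "lumenal_space")))
}

#' Topology filter on Hox-domain vs N-terminus placement
#'
#' Rejects structure models whose N-terminal segment sits on the same
#' side of the transmembrane bundle as the Hox-like domain — a placement
#' incompatible with the known topology (lumenal N-terminus, cytosolic
#' Hox-like domain), indicating a mis-modeled fold.
#'
#' @param model A [structure_model()].
#' @param frame A [membrane_frame()] for the model.
#' @param hox_range,nterm_range Length-2 `(start, end)` residue-number
#'   ranges of the Hox-like domain and the N-terminal segment; both must
#'   select at least one modeled residue.
#' @return `"pass"` or `"reject"`.
#' @export
hox_orientation_filter <- function(model, frame, hox_range, nterm_range) {
  stopifnot(inherits(model, "structure_model"),
            inherits(frame, "membrane_frame"),
            length(hox_range) == 2L, length(nterm_range) == 2L)
  z <- coords_depth(model, frame)
  sel_h <- model$resno >= hox_range[1] & model$resno <= hox_range[2]
  sel_n <- model$resno >= nterm_range[1] & model$resno <= nterm_range[2]
  if (!any(sel_h)) stop("Hox range selects no modeled residues")
  if (!any(sel_n)) stop("N-terminal range selects no modeled residues")
  mh <- mean(z[sel_h])
  mn <- mean(z[sel_n])
  if (mh == 0 || mn == 0)
    stop("ambiguous placement: a reference segment has mean depth 0")
  if (sign(mh) == sign(mn)) "reject" else "pass"
}

#' Compare pooled Trp depths between two cohorts
#'
#' Pools the included tryptophan Calpha depths of each cohort and
#' compares the two pooled samples with the two-sided Mann-Whitney U rank
#' test.
#'
#' @param cohort_a,cohort_b Lists of [residue_depths()] profiles; each
#'   cohort must contribute at least one included Trp depth.
#' @return A [test_result()] with extra fields `n_trp`, `medians`.
#' @export
compare_trp_depths <- function(cohort_a, cohort_b) {
  pool <- function(profiles) {
    z <- unlist(lapply(profiles, function(p)
      p$z[p$restype == "W" & p$included]))
    z[!is.na(z)]
  }
  za <- pool(cohort_a)
  zb <- pool(cohort_b)
  if (length(za) == 0L || length(zb) == 0L)
    stop("a cohort contributes no Trp depths")
  res <- mann_whitney_u(za, zb, alternative = "two.sided")
  res$n_trp <- c(length(za), length(zb))
  res$medians <- c(stats::median(za), stats::median(zb))
  res
}

#' Write a Calpha model as a PDB coordinate file
#'
#' Minimal single-chain ATOM-record writer (coordinates at the format's
#' 0.001-Angstrom precision); round-trips through [parse_structure()].
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  res3 <- bio3d::aa123(model$restype)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(model$resno), res3, model$resno,
    model$xyz[, 1], model$xyz[, 2], model$xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
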