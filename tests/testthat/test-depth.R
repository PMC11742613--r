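pdb_line <- function(serial, name, res3, resno, x, y, z, alt = " ") {
  sprintf("ATOM  %5d %4s%s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, sprintf(" %-3s", name), alt, res3, resno, x, y, z)
}

coords_depth_for_test <- function(model, frame)
  as.numeric(model$xyz %*% frame$normal) - frame$d0

test_that("structure parsing keeps one Calpha per residue and skips non-standard residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- character()
  s <- 0L
  for (i in 1:10) {
    s <- s + 1L
    lines <- c(lines, pdb_line(s, "N", "ALA", i, i, 0, 0))   # non-CA ignored
    s <- s + 1L
    lines <- c(lines, pdb_line(s, "CA", "ALA", i, i, 0, i * 1.5))
  }
  s <- s + 1L
  lines <- c(lines, pdb_line(s, "CA", "UNK", 11, 0, 0, 99))  # non-standard
  writeLines(c(lines, "END"), path)
  expect_warning(model <- parse_structure(path), "non-standard")
  expect_length(model$resno, 10L)
  expect_true(all(model$restype == "A"))
  expect_equal(model$xyz[, "z"], (1:10) * 1.5)

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "N", "ALA", 1, 0, 0, 0), "END"), empty)
  expect_error(parse_structure(empty), "no Calpha")
})

test_that("the bundle writer round-trips through the parser at format precision", {
  b <- gen_helical_bundle(n_helices = 4, res_per_helix = 20, seed = 51,
                          n_tail_n = 0, n_tail_c = 0)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b$model, path)
  back <- parse_structure(path)
  expect_equal(back$resno, b$model$resno)
  expect_equal(back$restype, b$model$restype)
  expect_lt(max(abs(back$xyz - b$model$xyz)), 1e-3 + 1e-9)
})

test_that("depths are signed projections with the 40 A window and region tie rules", {
  model <- structure_model("T", 1:3, c("W", "A", "W"),
                           rbind(c(3, -7, 10), c(0, 0, 45), c(1, 1, -20)))
  frame <- membrane_frame(c(0, 0, 1), 0, oriented = TRUE)
  dp <- residue_depths(model, frame)
  expect_equal(dp$z[1], 10)
  expect_false(dp$included[2])        # z = 45 masked out
  expect_true(is.na(dp$z[2]))
  expect_equal(dp$region[3], "lumenal_space")
  expect_equal(sum(dp$included) + sum(!dp$included), 3L)

  expect_equal(classify_region(20), "cytoplasmic_space")
  expect_equal(classify_region(-20), "lumenal_space")
  expect_equal(classify_region(0), "cytoplasmic_interface_core")
  expect_equal(classify_region(c(5, -5, 18, -18)),
               c("cytoplasmic_interface_core", "lumenal_interface_core",
                 "cytoplasmic_interface_core", "lumenal_interface_core"))
})

test_that("orient_frame flips the normal so the cytoplasmic reference has positive mean depth", {
  z <- seq(-30, 30, length.out = 40)
  model <- structure_model("T", 1:40, rep("A", 40),
                           cbind(rnorm(40), rnorm(40), z))
  # raw frame pointing the wrong way: reference (last 10, z near +30) maps negative
  frame <- membrane_frame(c(0, 0, -1), 0)
  zref <- mean((model$xyz %*% c(0, 0, -1))[31:40])
  expect_lt(zref, 0)
  oriented <- orient_frame(frame, model)
  expect_equal(oriented$normal, c(0, 0, 1))
  expect_gt(mean(coords_depth_for_test(model, oriented)[31:40]), 0)
  expect_true(oriented$oriented)

  # already-correct frame is unchanged
  ok <- orient_frame(membrane_frame(c(0, 0, 1), 0), model)
  expect_equal(ok$normal, c(0, 0, 1))

  # ambiguous reference: mean depth exactly zero
  sym <- structure_model("S", 1:20, rep("A", 20),
                         cbind(0, 0, rep(c(-1, 1), 10)))
  expect_error(orient_frame(membrane_frame(c(0, 0, 1), 0), sym,
                            cytoplasmic_residues = 1:20), "ambiguous")
})

test_that("the Hox/N-terminus orientation filter rejects same-side placements", {
  # 30 membrane residues plus two extramembrane segments
  z <- c(seq(25, 21, length.out = 5),        # residues 1-5: N-term, +side
         seq(-15, 15, length.out = 30),      # membrane span
         seq(21, 25, length.out = 5))        # residues 36-40: blob, +side
  model <- structure_model("T", 1:40, rep("A", 40),
                           cbind(seq_len(40) * 0.1, 0, z))
  frame <- membrane_frame(c(0, 0, 1), 0, oriented = TRUE)
  expect_equal(hox_orientation_filter(model, frame, c(36, 40), c(1, 5)),
               "reject")
  # flip the N-terminal segment to the other side: correct topology
  z2 <- z
  z2[1:5] <- -z[1:5]
  model2 <- structure_model("T2", 1:40, rep("A", 40),
                            cbind(seq_len(40) * 0.1, 0, z2))
  expect_equal(hox_orientation_filter(model2, frame, c(36, 40), c(1, 5)),
               "pass")
  expect_error(hox_orientation_filter(model, frame, c(100, 110), c(1, 5)),
               "no modeled residues")
})

test_that("membrane placement recovers planted frames and depths on tilted bundles", {
  set.seed(52)
  for (i in 1:4) {
    tilt <- c(0, 10, 20, 30)[i]
    b <- gen_helical_bundle(tilt_deg = tilt, d0 = sample(-3:3, 1), seed = 60 + i)
    frame <- place_membrane(b$model)
    frame <- orient_frame(frame, b$model,
                          cytoplasmic_residues =
                            seq(b$ranges$cterm[1], b$ranges$cterm[2]))
    expect_lt(angle_deg(frame$normal, b$frame$normal), 5)
    expect_lt(abs(frame$d0 - b$frame$d0), 2)
    dp <- residue_depths(b$model, frame)
    err <- abs(dp$z - b$truth$z_true)
    expect_gte(mean(err[dp$included] <= 2, na.rm = TRUE), 0.95)
  }
})

test_that("placement is equivariant under rotation and invariant under translation", {
  R <- local({ set.seed(53); random_rotation() })
  b0 <- gen_helical_bundle(tilt_deg = 15, seed = 54)
  b1 <- gen_helical_bundle(tilt_deg = 15, seed = 54, rotation = R)
  f0 <- place_membrane(b0$model)
  f1 <- place_membrane(b1$model)
  # recovered normal tracks the rotated truth
  expect_lt(angle_deg(f1$normal, as.numeric(R %*% c(0, 0, 1))), 5)

  t <- c(100, 100, 100)
  b2 <- gen_helical_bundle(tilt_deg = 15, seed = 54, translation = t)
  f2 <- place_membrane(b2$model)
  expect_lt(angle_deg(f2$normal, f0$normal), 1e-6)
  shift <- sum(t * f2$normal) * sign(sum(f2$normal * f0$normal))
  expect_lt(abs(f2$d0 - (f0$d0 + shift)), 0.5)

  # depths are rigid-motion invariant given the transformed truth frame
  dp0 <- residue_depths(b0$model, b0$frame)
  dp1 <- residue_depths(b1$model, b1$frame)
  expect_equal(dp1$z, dp0$z, tolerance = 1e-9)
  expect_equal(dp0$z[dp0$included], b0$truth$z_true[dp0$included],
               tolerance = 1e-9)
})

test_that("pooled Trp depth comparison handles identity and planted asymmetry", {
  # cohort compared with itself: U = n^2/2, p = 1 on the exact path
  prof <- as_trp_profile(c(-20.5, 3.2, 17.8))
  res <- compare_trp_depths(list(prof), list(prof))
  expect_equal(res$U, 4.5)
  expect_equal(res$p_value, 1)

  sim <- gen_depth_cohort(n_a = 500, n_b = 500, bias = 0.35, seed = 55)
  res2 <- compare_trp_depths(list(as_trp_profile(sim$hox)),
                             list(as_trp_profile(sim$nonhox)))
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$n_trp, c(500L, 500L))

  expect_error(compare_trp_depths(list(), list(prof)), "no Trp depths")
})
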