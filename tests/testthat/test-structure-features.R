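test_that("PDB round trip and NMR first-model rule", {
  dir <- tempfile("pdb")
  dir.create(dir)
  s <- quick_structure(60, seed = 31)
  path <- file.path(dir, "one.pdb")
  write_pdb(s, path)
  p1 <- parse_structure(path)
  p2 <- parse_structure(path)
  expect_identical(p1$aa, s$aa)
  expect_equal(p1$ca, s$ca, tolerance = 1e-3)
  expect_identical(p1$experiment, "xray")
  expect_identical(p1, p2)

  # multi-model file: coordinates must equal model 1's
  m1 <- s
  m2 <- s; m2$ca <- s$ca + 2; m2$backbone <- lapply(s$backbone, function(m) m + 2)
  m3 <- s; m3$ca <- s$ca - 2; m3$backbone <- lapply(s$backbone, function(m) m - 2)
  nmr_path <- file.path(dir, "nmr.pdb")
  write_pdb(m1, nmr_path, models = list(m1, m2, m3))
  pn <- parse_structure(nmr_path)
  expect_identical(pn$experiment, "nmr")
  expect_identical(pn$model_index, 1L)
  expect_equal(pn$ca, m1$ca, tolerance = 1e-3)
})

test_that("files without standard ATOM records are rejected", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1      10.000  10.000  10.000  1.00  0.00           O",
    "END"), f)
  expect_error(parse_structure(f), "ATOM")

  # unknown residue code: skipped with a warning
  s <- quick_structure(55, seed = 33)
  path <- tempfile(fileext = ".pdb")
  write_pdb(s, path)
  lines <- readLines(path)
  atom <- grep("^ATOM", lines)
  resno <- as.integer(substr(lines[atom], 23, 26))
  lines[atom[resno == 5]] <- sub(substr(lines[atom[resno == 5]][1], 18, 20),
                                 "XXX", lines[atom[resno == 5]])
  writeLines(lines, path)
  expect_warning(p <- parse_structure(path), "unknown")
  expect_identical(length(p$aa), 54L)
})

test_that("structure quality filters fire in the documented order", {
  ok <- quick_structure(60, seed = 41)
  expect_true(validate_structure(ok)$accept)

  short <- quick_structure(49, seed = 42)
  v <- validate_structure(short)
  expect_false(v$accept)
  expect_identical(v$reason, "length")

  gapped <- ok
  keep <- setdiff(seq_along(ok$aa), 30)
  gapped$resno <- gapped$resno[keep]; gapped$aa <- gapped$aa[keep]
  gapped$ca <- gapped$ca[keep, ]
  gapped$backbone <- lapply(gapped$backbone, function(m) m[keep, ])
  v <- validate_structure(gapped)
  expect_false(v$accept)
  expect_identical(v$reason, "gapped chain")

  nobb <- ok
  nobb$backbone$O[10, ] <- NA_real_
  v <- validate_structure(nobb)
  expect_false(v$accept)
  expect_identical(v$reason, "incomplete backbone")
})

test_that("RSA normalization clamps and validates", {
  ref <- c(A = 113, G = 85, W = 259)
  expect_equal(compute_rsa("A", 113), 1.0)
  expect_equal(compute_rsa("A", 1.3 * 113), 1.0)
  expect_equal(compute_rsa("G", 0), 0.0)
  expect_equal(compute_rsa("W", 259 / 2), 0.5)
  expect_error(compute_rsa("X", 10), "nonstandard")
  expect_error(compute_rsa("A", -1), "nonnegative")
})

test_that("residue classification follows the 25% rule and 20-bin scheme", {
  c1 <- classify_residue(0.10, "H")
  expect_identical(c1$exposure, "buried")
  expect_identical(c1$rsa_bin, 3L)
  expect_identical(c1$ss_category, "helix")

  c2 <- classify_residue(0.60, "S")
  expect_identical(c2$exposure, "exposed")
  expect_identical(c2$rsa_bin, 13L)
  expect_identical(c2$ss_category, "turn")

  expect_identical(classify_residue(1.0, "E")$rsa_bin, 20L)
  expect_identical(classify_residue(0.25, ".")$exposure, "exposed")
  expect_identical(classify_residue(0.15, "B")$rsa_bin, 4L)
  expect_identical(classify_residue(0.9999, "G")$rsa_bin, 20L)
  expect_error(classify_residue(0.5, "Q"), "DSSP")
  expect_error(classify_residue(1.2, "H"), "rsa")

  # the bins partition [0,1]: every value lands in exactly one bin and the
  # bin's nominal interval contains it
  set.seed(1)
  rsa <- c(runif(200), seq(0, 1, by = 0.05))
  bins <- classify_residue(rsa, rep("H", length(rsa)))$rsa_bin
  expect_true(all(bins >= 1L & bins <= 20L))
  lo <- (bins - 1) * 0.05
  hi <- ifelse(bins == 20L, 1 + 1e-12, bins * 0.05)
  expect_true(all(rsa >= lo - 1e-9 & rsa < hi + 1e-9))
  expect_true(all(classify_residue(rsa, rep("H", length(rsa)))$exposure ==
                    ifelse(rsa < 0.25, "buried", "exposed")))
})

test_that("feature tables join structure and DSSP records and drop mismatches", {
  s <- quick_structure(80, seed = 51)
  dir <- tempfile(); dir.create(dir)
  dssp_path <- file.path(dir, "s.dssp")
  write_dssp_table(s, dssp_path)
  dssp <- read_dssp_table(dssp_path)
  f <- residue_features(s, dssp)
  expect_identical(nrow(f), 80L)
  expect_true(all(f$rsa >= 0 & f$rsa <= 1))
  expect_true(all((f$exposure == "buried") == (f$rsa < 0.25)))

  # a residue whose identity disagrees between records is dropped
  dssp$aa[10] <- setdiff(c("A", "G"), dssp$aa[10])[1]
  f2 <- residue_features(s, dssp)
  expect_identical(nrow(f2), 79L)
  expect_false(10L %in% f2$position)
})

test_that("fraction exposed is the exposed percentage", {
  feats <- data.frame(exposure = c(rep("exposed", 30), rep("buried", 70)))
  expect_equal(fraction_exposed(feats), 30)
  expect_equal(fraction_exposed(data.frame(exposure = rep("exposed", 5))), 100)
  expect_equal(fraction_exposed(data.frame(exposure = rep("buried", 5))), 0)
  expect_error(fraction_exposed(data.frame(exposure = character(0))), "empty")
})
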