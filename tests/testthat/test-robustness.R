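test_that("mutation counts follow the per-length rate with a floor of one", {
  s150 <- paste(rep("A", 150), collapse = "")
  m50 <- mutate_sequence(s150, denominator = 50, seed = 1)
  expect_identical(sum(m50 != "A"), 3L)
  m10 <- mutate_sequence(s150, denominator = 10, seed = 1)
  expect_identical(sum(m10 != "A"), 15L)
  m_short <- mutate_sequence(strrep("A", 30), denominator = 50, seed = 1)
  expect_identical(sum(m_short != "A"), 1L)

  # every mutated position holds a different amino acid, deterministically
  s <- quick_structure(100, seed = 77)
  m1 <- mutate_sequence(s$aa, denominator = 10, seed = 9)
  m2 <- mutate_sequence(s$aa, denominator = 10, seed = 9)
  expect_identical(m1, m2)
  changed <- which(m1 != s$aa)
  expect_identical(length(changed), 10L)
  expect_true(all(m1[changed] != s$aa[changed]))
  expect_error(mutate_sequence(character(0)), "empty")
})

test_that("per-site scans record absolute stability perturbations", {
  model <- fixture_model()
  s <- quick_structure(60, seed = 78)
  scan <- scan_point_mutations(s, model, seed = 5)
  expect_identical(nrow(scan), 60L)
  expect_true(all(scan$ddg_abs >= 0))
  expect_true(all(scan$mutant_aa != scan$native_aa))
  # forcing the identity mutation gives |ddG| = 0
  native_dg <- attr(scan, "native_dg")
  expect_equal(score_structure(s, model, sequence = s$aa), native_dg)

  # buried residues are hit harder than exposed ones
  f <- residue_features(s)
  rsa <- f$rsa[match(scan$position, f$position)]
  expect_gt(mean(scan$ddg_abs[rsa < 0.25]), mean(scan$ddg_abs[rsa > 0.25]))
})

test_that("mutant populations yield the documented Z and rank statistics", {
  model <- fixture_model()
  s <- quick_structure(80, seed = 79)
  pop <- build_mutant_population(s, model, denominator = 50,
                                 n_replicates = 120, seed = 3)
  # closed-form identities on the population itself
  expect_equal(pop$z_score,
               (pop$native_dg - mean(pop$mutant_dgs)) / sd(pop$mutant_dgs))
  expect_identical(pop$rank, 1L + sum(pop$mutant_dgs < pop$native_dg))
  expect_true(pop$rank >= 1L && pop$rank <= 121L)

  pop2 <- build_mutant_population(s, model, denominator = 50,
                                  n_replicates = 120, seed = 3)
  expect_identical(pop$mutant_dgs, pop2$mutant_dgs)
  expect_error(build_mutant_population(s, model, n_replicates = 1), ">= 2")
})

test_that("rank extremes and the degenerate-sd signal behave as designed", {
  model <- fixture_model()
  s <- quick_structure(70, seed = 80)
  tess <- tessellate(s, cutoff = model$cutoff)
  aa_order <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  aa_idx <- match(s$aa, aa_order)
  quad <- matrix(aa_idx[tess$simplices], ncol = 4)
  quad <- t(apply(quad, 1, sort))
  native_keys <- unique((quad[, 1] - 1) * 8000 + (quad[, 2] - 1) * 400 +
                          (quad[, 3] - 1) * 20 + quad[, 4])

  # rewarding exactly the native compositions makes the native minimal
  low <- model; low$lookup[] <- 0; low$lookup[native_keys] <- 10
  pop_low <- build_mutant_population(s, low, n_replicates = 100, seed = 4)
  expect_identical(pop_low$rank, 1L)
  expect_lt(pop_low$z_score, 0)

  # penalizing them makes the native maximal
  high <- model; high$lookup[] <- 0; high$lookup[native_keys] <- -10
  pop_high <- build_mutant_population(s, high, n_replicates = 100, seed = 4)
  expect_identical(pop_high$rank, 101L)
  expect_gt(pop_high$z_score, 0)

  # a flat score table collapses the population: sd = 0, Z undefined
  flat <- model; flat$lookup[] <- 0
  pop_flat <- build_mutant_population(s, flat, n_replicates = 50, seed = 4)
  expect_identical(pop_flat$z_status, "sd_zero")
  expect_true(is.na(pop_flat$z_score))
  expect_identical(pop_flat$rank, 1L)
})

test_that("Z-score and rank are concordant across structures", {
  model <- fixture_model()
  stats <- t(vapply(1:12, function(k) {
    s <- quick_structure(60 + 6 * k, age = "vertebrata", seed = 81000 + k)
    pop <- build_mutant_population(s, model, n_replicates = 80, seed = k)
    c(z = pop$z_score, rank = pop$rank)
  }, numeric(2)))
  expect_gt(cor(stats[, "z"], stats[, "rank"], method = "spearman"), 0)
})
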