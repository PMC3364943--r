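test_that("generator is deterministic and respects chain geometry", {
  cfg <- sim_config(chain_length = 100, seed = 7)
  s1 <- generate_toy_structure(cfg)
  s2 <- generate_toy_structure(cfg)
  expect_identical(s1$ca, s2$ca)
  expect_identical(s1$aa, s2$aa)
  expect_identical(s1$annotation, s2$annotation)

  d <- sqrt(rowSums(diff(s1$ca)^2))
  expect_true(all(d >= 3.6 & d <= 4.0))
  expect_true(all(diff(s1$resno) == 1L))
  expect_false(anyNA(s1$backbone$N) || anyNA(s1$backbone$C) || anyNA(s1$backbone$O))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(chain_length = 9), "chain_length")
  expect_error(sim_config(core_fraction = 1.2), "core_fraction")
  expect_error(sim_config(base_rate = -0.1), "base_rate")
  expect_error(sim_config(rsa_slope = -1), "rsa_slope")
  expect_error(sim_config(age_class = "archaea"))
})

test_that("chains are compact: radius of gyration grows sublinearly", {
  rg <- vapply(c(75L, 300L), function(L) {
    s <- generate_toy_structure(sim_config(chain_length = L, seed = 21))
    cen <- colMeans(s$ca)
    sqrt(mean(rowSums((s$ca - matrix(cen, L, 3, byrow = TRUE))^2)))
  }, numeric(1))
  # a 4x longer chain must not be anywhere near 4x larger (globular scaling)
  expect_lt(rg[2] / rg[1], 2)
})

test_that("planted core fraction is recovered through the feature pipeline", {
  fr <- vapply(1:12, function(i) {
    s <- generate_toy_structure(sim_config(chain_length = 200,
                                           core_fraction = 0.4,
                                           seed = 500 + i))
    mean(residue_features(s)$rsa < 0.25)
  }, numeric(1))
  expect_gt(mean(fr), 0.3)
  expect_lt(mean(fr), 0.5)
  # core-designated residues are the buried ones
  s <- generate_toy_structure(sim_config(chain_length = 150, seed = 3))
  f <- residue_features(s)
  expect_lt(mean(f$rsa[s$annotation$core]), mean(f$rsa[!s$annotation$core]))
})

test_that("ortholog pairs back-translate to the structure sequence", {
  for (seed in c(11, 12)) {
    cfg <- sim_config(chain_length = 80, age_class = "metazoa", seed = seed)
    s <- generate_toy_structure(cfg)
    f <- residue_features(s)
    p <- generate_ortholog_pair(s, f, cfg)
    expect_identical(translate_cds(p$cds_a), paste(s$aa, collapse = ""))
    expect_identical(nchar(p$cds_a), 3L * cfg$chain_length)
    expect_identical(nchar(p$cds_b), 3L * cfg$chain_length)
  }
})

test_that("zero-rate configuration yields identical sequences", {
  cfg <- sim_config(chain_length = 60, base_rate = 0, rsa_slope = 0, seed = 5)
  s <- generate_toy_structure(cfg)
  p <- generate_ortholog_pair(s, residue_features(s), cfg)
  expect_identical(p$cds_a, p$cds_b)
})

test_that("pair generation validates the feature table and batches replicates", {
  cfg <- sim_config(chain_length = 60, seed = 5)
  s <- generate_toy_structure(cfg)
  f <- residue_features(s)
  expect_error(generate_ortholog_pair(s, f[1:10, ], cfg), "residues")
  prs <- generate_ortholog_pairs(s, f, cfg, n_pairs = 3)
  expect_length(prs, 3)
  for (p in prs)
    expect_identical(translate_cds(p$cds_a), paste(s$aa, collapse = ""))
  # replicates are not copies of one another
  expect_false(identical(prs[[1]]$cds_a, prs[[2]]$cds_a))
})

test_that("homolog profiles span exactly the planted phylogenetic width", {
  groups <- species_groups_default()
  for (age in c("mammalia", "vertebrata", "metazoa", "eukarya")) {
    for (seed in 1:5) {
      hits <- generate_homolog_profile(age, seed = seed)
      expect_true(all(hits$e_value <= 1e-4))
      asg <- assign_age(hits)
      expect_identical(asg$age_class, age)
    }
  }
  euk <- generate_homolog_profile("eukarya", seed = 2)
  expect_true(any(euk$subject_species %in% groups$eukarya))
  mam <- generate_homolog_profile("mammalia", seed = 2)
  expect_true(all(mam$subject_species %in% groups$mammalia))
  expect_error(generate_homolog_profile("bacteria"), "age_class")
})

test_that("decoy sets preserve what they must preserve", {
  s <- quick_structure(70, seed = 9)
  expect_error(generate_decoy_set(s, 0, "shuffle_sequence"), "positive")

  sh <- generate_decoy_set(s, 5, "shuffle_sequence", seed = 4)
  for (d in sh) {
    expect_identical(sort(d$aa), sort(s$aa))
    expect_identical(d$ca, s$ca)
  }
  sh2 <- generate_decoy_set(s, 5, "shuffle_sequence", seed = 4)
  expect_identical(lapply(sh, `[[`, "aa"), lapply(sh2, `[[`, "aa"))

  pz <- generate_decoy_set(s, 3, "perturb_coordinates", seed = 4,
                           max_displacement = 0)
  for (d in pz) expect_equal(d$ca, s$ca)
  pb <- generate_decoy_set(s, 3, "perturb_coordinates", seed = 4,
                           max_displacement = 0.5)
  for (d in pb) {
    expect_identical(d$aa, s$aa)
    expect_true(all(sqrt(rowSums((d$ca - s$ca)^2)) <= 0.5 + 1e-12))
  }
})
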