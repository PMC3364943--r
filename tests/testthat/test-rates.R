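test_that("back-translation expands residues to codons and gaps to codon gaps", {
  aln <- backtranslate_alignment(c("MA", "MA"), "ATGGCT", "ATGGCA")
  expect_identical(aln$codons_a, c("ATG", "GCT"))
  expect_identical(aln$codons_b, c("ATG", "GCA"))

  gap <- backtranslate_alignment(c("M-A", "MKA"), "ATGGCT", "ATGAAAGCA")
  expect_identical(gap$codons_a, c("ATG", "---", "GCT"))
  expect_identical(gap$codons_b, c("ATG", "AAA", "GCA"))

  expect_error(backtranslate_alignment(c("MA", "MA"), "ATGGGT", "ATGGCA"),
               "position 2")
})

test_that("NG86 counting matches the frozen hand-derived examples", {
  a <- rep("GCT", 11)
  ident <- estimate_dn_ds(codon_alignment(a, a))
  expect_equal(ident$dn, 0)
  expect_equal(ident$ds, 0)

  b <- a; b[1] <- "GCC"  # one synonymous change among 11 alanine codons
  syn <- estimate_dn_ds(codon_alignment(a, b))
  expect_equal(syn$dn, 0)
  expect_equal(syn$ds, 0.0969088, tolerance = 1e-6)
  expect_equal(syn$s_sites, 11)
  expect_equal(syn$n_sites, 22)

  b2 <- a; b2[1] <- "GTT"  # one nonsynonymous change
  nsy <- estimate_dn_ds(codon_alignment(a, b2))
  expect_equal(nsy$ds, 0)
  expect_equal(nsy$dn, 0.0468903, tolerance = 1e-6)
  expect_identical(nsy$omega_status, "undefined")
})

test_that("NG86 is symmetric, additive in sites, and matches the oracle", {
  set.seed(71)
  for (i in 1:50) {
    al <- random_alignment(30, p_change = runif(1, 0.05, 0.3))
    est <- estimate_dn_ds(codon_alignment(al$a, al$b))
    rev <- estimate_dn_ds(codon_alignment(al$b, al$a))
    expect_equal(est$dn, rev$dn)
    expect_equal(est$ds, rev$ds)
    expect_equal(est$n_sites + est$s_sites, 3 * 30, tolerance = 1e-9)

    orc <- oracle_ng86(al$a, al$b)
    expect_equal(est$n_sites, orc$n_sites, tolerance = 1e-12)
    expect_equal(est$s_sites, orc$s_sites, tolerance = 1e-12)
    expect_equal(est$n_diffs, orc$n_diffs, tolerance = 1e-12)
    expect_equal(est$s_diffs, orc$s_diffs, tolerance = 1e-12)
    if (!orc$dn_saturated) expect_equal(est$dn, orc$dn, tolerance = 1e-12)
    if (!orc$ds_saturated) expect_equal(est$ds, orc$ds, tolerance = 1e-12)
  }
})

test_that("saturation and degenerate inputs raise the documented signals", {
  a <- rep("GCT", 100)
  b <- a; b[1:76] <- "GCC"  # pS = 0.76 >= 3/4
  est <- estimate_dn_ds(codon_alignment(a, b))
  expect_identical(est$ds_status, "saturated")
  expect_true(is.na(est$ds))

  expect_error(estimate_dn_ds(codon_alignment(c("ATG", "TAA"), c("ATG", "TAA"))),
               "stop codon")
  expect_error(estimate_dn_ds(codon_alignment("AT?", "ATG")), "invalid codon")
})

test_that("a purely synonymous planted process yields dN = 0", {
  for (seed in c(3, 4)) {
    cfg <- sim_config(chain_length = 120, base_rate = 0.3, rsa_slope = 0.2,
                      ns_fraction = 0, seed = seed)
    s <- generate_toy_structure(cfg)
    p <- generate_ortholog_pair(s, residue_features(s), cfg)
    est <- estimate_dn_ds(codon_alignment(p$codons_a, p$codons_b))
    expect_equal(est$dn, 0)
    expect_gt(est$ds, 0)
  }
})

test_that("concatenation groups columns by category and filters identities", {
  mk_entry <- function(n_helix, seed) {
    cfg <- sim_config(chain_length = 60, seed = seed)
    s <- generate_toy_structure(cfg)
    f <- residue_features(s)
    f$ss_category <- c(rep("helix", n_helix),
                       rep("coil", 60 - n_helix))
    list(pair = generate_ortholog_pair(s, f, cfg), features = f,
         age_class = "eukarya")
  }
  e1 <- mk_entry(10, 81)
  e2 <- mk_entry(15, 82)
  groups <- concatenate_by_category(list(e1, e2), "ss_category")
  expect_identical(length(groups$helix$codons_a), 25L)
  expect_identical(length(groups$coil$codons_a), 95L)

  # a low-identity pair contributes nothing
  lo <- e1
  lo$pair$codons_b[1:40] <- ifelse(substr(lo$pair$codons_a[1:40], 1, 1) == "C",
                                   "AAA", "CCC")
  groups2 <- concatenate_by_category(list(lo, e2), "ss_category")
  expect_identical(length(groups2$helix$codons_a), 15L)

  # RSA-bin grouping yields at most 20 groups (60 when crossed with 3 ages)
  entries <- list(e1, e2)
  gb <- concatenate_by_category(entries, "rsa_bin")
  expect_lte(length(gb), 20L)
  gba <- concatenate_by_category(entries, "rsa_bin", by_age = TRUE)
  expect_lte(length(gba), 60L)
})

test_that("rate filters discard short, fast and saturated estimates", {
  a <- rep(c("GCT", "AAA"), 50)
  est <- estimate_dn_ds(codon_alignment(a, a))
  expect_false(apply_rate_filters(est, aa_length = 59)$retained)
  expect_identical(apply_rate_filters(est, aa_length = 59)$reason,
                   "shorter than 60 aa")
  expect_true(apply_rate_filters(est, aa_length = 100)$retained)

  fast <- list(dn = 0.6, ds = 0.2, dn_status = "ok", ds_status = "ok",
               n_codons = 100)
  expect_identical(apply_rate_filters(structure(fast, class = "rate_estimate"))$reason,
                   "dN > 0.5")
  sat <- list(dn = 0.1, ds = 2.5, dn_status = "ok", ds_status = "ok",
              n_codons = 100)
  expect_identical(apply_rate_filters(structure(sat, class = "rate_estimate"))$reason,
                   "dS > 2")
})
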