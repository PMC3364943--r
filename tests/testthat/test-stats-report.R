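mk_series <- function(slope, intercept = 0.003, noise = 0, bins = 1:20,
                      age = NA_character_) {
  mid <- (bins - 0.5) / 20
  data.frame(rsa_bin = bins, midpoint = mid, age_class = age,
             dn = intercept + slope * mid + rnorm(length(bins), 0, noise),
             dn_se = NA_real_, n_codons = 1000L, stringsAsFactors = FALSE)
}

test_that("binned Pearson correlation handles perfect, constant and short series", {
  exact <- mk_series(0.005)
  pc <- pearson_binned_correlation(exact)
  expect_equal(pc$r, 1)
  expect_lt(pc$p_value, 1e-10)

  flat <- mk_series(0)
  expect_identical(pearson_binned_correlation(flat)$status, "undefined")
  expect_error(pearson_binned_correlation(mk_series(0.005, bins = 1:2)),
               "3 bins")
})

test_that("per-age fits recover planted slopes and interactions", {
  set.seed(5)
  series <- list(eukarya = mk_series(0.0025, noise = 5e-5),
                 vertebrata = mk_series(0.006, noise = 5e-5))
  fit <- fit_rsa_age_model(series, "dN~RSA+RSA*age+age")
  sl <- setNames(fit$per_age$slope, fit$per_age$age_class)
  expect_lt(abs(sl["eukarya"] - 0.0025) / 0.0025, 0.2)
  expect_lt(abs(sl["vertebrata"] - 0.006) / 0.006, 0.2)
  expect_lt(fit$pairwise$interaction_p, 0.01)

  # equal slopes, negligible noise: interaction indistinguishable from zero
  same <- list(a = mk_series(0.003, noise = 1e-4),
               b = mk_series(0.003, noise = 1e-4))
  fit0 <- fit_rsa_age_model(same, "dN~RSA+RSA*age+age")
  expect_gt(fit0$pairwise$interaction_p, 0.05)
  expect_lt(abs(fit0$pairwise$interaction), 5e-4)

  # two points: exact interpolation
  two <- list(a = mk_series(0.004, bins = c(5L, 15L)))
  fit2 <- fit_rsa_age_model(two, "dN~RSA")
  expect_equal(fit2$per_age$slope, 0.004, tolerance = 1e-12)
})

test_that("wilcoxon wrapper matches exhaustive enumeration for small samples", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    a <- round(rnorm(n), 6); b <- round(rnorm(m) + 0.5, 6)
    got <- wilcoxon_test(a, b)
    expect_equal(got$p_value, oracle_ranksum_p(a, b), tolerance = 1e-12,
                 info = sprintf("rank-sum case %d", i))
  }
  for (i in 1:10) {
    n <- sample(4:8, 1)
    a <- round(rnorm(n), 6); b <- round(rnorm(n) + 0.3, 6)
    got <- wilcoxon_test(a, b, paired = TRUE)
    expect_equal(got$p_value, oracle_signedrank_p(a, b), tolerance = 1e-12,
                 info = sprintf("signed-rank case %d", i))
  }
})

test_that("wilcoxon wrapper flags degenerate input and detects real shifts", {
  x <- c(1, 2, 3)
  expect_identical(wilcoxon_test(x, x, paired = TRUE)$status, "degenerate")
  expect_error(wilcoxon_test(1:3, 1:4, paired = TRUE), "equal length")

  set.seed(41)
  a <- rnorm(200); b <- rnorm(200) + 1
  expect_lt(wilcoxon_test(a, b)$p_value, 0.01)
  ident <- rnorm(50)
  expect_gt(wilcoxon_test(ident, ident)$p_value, 0.9)
})

test_that("length-binned pairing equalizes group length distributions", {
  set.seed(51)
  lengths <- sample(seq(60, 300), 120, replace = TRUE)
  g1 <- data.frame(length = lengths, dg = rnorm(120, -50, 5))
  g2 <- data.frame(length = lengths, dg = rnorm(120, -50, 5))
  pr <- length_bin_pairing(list(a = g1, b = g2), bin_width = 25, seed = 1)
  expect_false(pr$empty)
  expect_identical(nrow(pr$records), 240L)
  counts <- table(pr$records$bin, pr$records$group)
  expect_true(all(counts[, 1] == counts[, 2]))

  # disjoint length ranges: empty result, flagged, exclusion reported
  g3 <- data.frame(length = sample(1000:1200, 40, TRUE), dg = rnorm(40))
  pr2 <- length_bin_pairing(list(a = g1, b = g2, c = g3), bin_width = 25, seed = 1)
  expect_true(pr2$empty)
  expect_true("c" %in% pr2$rescuable_without)

  # deterministic down-sampling
  g4 <- data.frame(length = sample(60:300, 200, TRUE), dg = rnorm(200))
  p1 <- length_bin_pairing(list(a = g1, b = g4), seed = 7)
  p2 <- length_bin_pairing(list(a = g1, b = g4), seed = 7)
  expect_identical(p1$records, p2$records)
})

test_that("a planted stability offset is detected after length pairing", {
  set.seed(61)
  n <- 150
  lens <- sample(seq(75, 250), n, replace = TRUE)
  old <- data.frame(length = lens, dg = -60 - 0.2 * lens + rnorm(n, 0, 1))
  young <- data.frame(length = sample(seq(75, 250), n, TRUE), dg = NA)
  young$dg <- -60 - 0.2 * young$length + 1.5 + rnorm(n, 0, 1)
  pr <- length_bin_pairing(list(old = old, young = young), bin_width = 25, seed = 2)
  a <- pr$records[pr$records$group == "old", ]
  b <- pr$records[pr$records$group == "young", ]
  w <- wilcoxon_test(a$dg, b$dg, paired = TRUE)
  expect_lt(w$p_value, 0.01)
})

test_that("binned series carry bootstrap errors and bin midpoints", {
  cfg <- sim_config(chain_length = 150, age_class = "vertebrata", seed = 91)
  s <- generate_toy_structure(cfg)
  f <- residue_features(s)
  entries <- lapply(generate_ortholog_pairs(s, f, cfg, n_pairs = 6),
                    function(p) list(pair = p, features = f, age_class = "vertebrata"))
  groups <- concatenate_by_category(entries, "rsa_bin")
  ser <- binned_rate_series(groups, n_boot = 50, seed = 2)
  expect_true(all(ser$midpoint == (ser$rsa_bin - 0.5) / 20))
  expect_true(all(ser$n_codons > 0))
  expect_true(any(is.finite(ser$dn_se)))
})
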