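# Statistical layer: binned RSA-rate correlation, per-age linear fits with
# RSA x age interaction, Wilcoxon suites, and length-binned pairing for
# stability comparisons.

#' Binned dN series over RSA bins
#'
#' Estimates dN for each RSA-bin concatenation and attaches the bin
#' midpoint and a codon-bootstrap standard error (the error estimator for
#' the binned points; 200 resamples by default).
#'
#' @param groups Named list of `codon_alignment` objects keyed by RSA bin
#'   (`"1"`..`"20"`, or `"bin.age"` when crossed with age).
#' @param n_boot Bootstrap resamples for the dN standard error (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return Data frame of class `bin_series`: `rsa_bin`, `midpoint`,
#'   `age_class` (`NA` if not crossed), `dn`, `dn_se`, `n_codons`.
#' @export
binned_rate_series <- function(groups, n_boot = 200L, seed = 1L) {
  ct <- codon_data()
  rows <- lapply(names(groups), function(g) {
    aln <- drop_gap_columns(groups[[g]])
    est <- estimate_dn_ds(aln)
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    bin <- as.integer(parts[1])
    age <- if (length(parts) > 1L) parts[2] else NA_character_
    se <- NA_real_
    if (n_boot > 0L && est$dn_status == "ok") {
      idx <- cbind(match(aln$codons_a, ct$codons), match(aln$codons_b, ct$codons))
      nd <- ct$nd[idx]
      nsites <- (ct$nonsyn_sites[aln$codons_a] + ct$nonsyn_sites[aln$codons_b]) / 2
      m <- length(nd)
      boot <- with_seed(seed + bin, vapply(seq_len(n_boot), function(b) {
        take <- sample.int(m, m, replace = TRUE)
        p <- sum(nd[take]) / sum(nsites[take])
        if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
      }, numeric(1)))
      se <- sd(boot, na.rm = TRUE)
    }
    data.frame(rsa_bin = bin, midpoint = (bin - 0.5) / 20,
               age_class = age, dn = est$dn, dn_se = se,
               n_codons = est$n_codons, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age_class, out$rsa_bin), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bin_series", class(out))
  out
}

#' Pearson correlation over a binned series
#'
#' Correlates dN with the RSA-bin midpoint across bins; two-sided p-value
#' from the t transform.
#'
#' @param series A `bin_series` (or data frame with `midpoint` and `dn`).
#' @return List with `r`, `p_value`, `n_bins`, `status` (`"ok"` or
#'   `"undefined"` for a constant series).
#' @export
pearson_binned_correlation <- function(series) {
  series <- series[!is.na(series$dn), , drop = FALSE]
  if (nrow(series) < 3L) stopf("need at least 3 bins with defined dN")
  if (sd(series$dn) == 0 || sd(series$midpoint) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_bins = nrow(series),
                status = "undefined"))
  ct <- cor.test(series$midpoint, series$dn, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_bins = nrow(series),
       status = "ok")
}

#' Linear and interaction models of dN on RSA and age
#'
#' Ordinary least squares on the binned points. `dN ~ RSA` is fit within
#' each age class; the interaction model `dN ~ RSA + RSA*age + age` is fit
#' for every pairwise combination of age classes with age as a two-level
#' factor, and the interaction coefficient tests whether the RSA slope
#' differs between the two ages.
#'
#' @param series_by_age Named list (age class -> `bin_series`), each with
#'   at least 3 bins.
#' @param formula `"dN~RSA"` or `"dN~RSA+RSA*age+age"`.
#' @return Object of class `rsa_age_fit`: `per_age` data frame (slope,
#'   intercept, p-values) and, for the interaction formula, `pairwise` data
#'   frame (ages, interaction coefficient, p-value).
#' @export
fit_rsa_age_model <- function(series_by_age,
                              formula = c("dN~RSA", "dN~RSA+RSA*age+age")) {
  formula <- match.arg(formula)
  per_age <- do.call(rbind, lapply(names(series_by_age), function(age) {
    s <- series_by_age[[age]]
    s <- s[!is.na(s$dn), , drop = FALSE]
    if (nrow(s) < 2L) stopf("age class %s has fewer than 2 usable bins", age)
    fit <- lm(dn ~ midpoint, data = s)
    cf <- summary(fit)$coefficients
    data.frame(age_class = age, intercept = cf[1, 1], slope = cf[2, 1],
               slope_se = cf[2, 2],
               slope_p = if (nrow(s) > 2L) cf[2, 4] else NA_real_,
               n_bins = nrow(s), stringsAsFactors = FALSE)
  }))
  pairwise <- NULL
  if (formula == "dN~RSA+RSA*age+age") {
    ages <- names(series_by_age)
    combs <- combn(ages, 2L)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      a1 <- combs[1, k]; a2 <- combs[2, k]
      d <- rbind(cbind(series_by_age[[a1]], age = a1),
                 cbind(series_by_age[[a2]], age = a2))
      d <- d[!is.na(d$dn), , drop = FALSE]
      d$age <- factor(d$age, levels = c(a1, a2))
      fit <- lm(dn ~ midpoint * age, data = d)
      cf <- summary(fit)$coefficients
      irow <- grep(":", rownames(cf))
      data.frame(age_a = a1, age_b = a2,
                 interaction = cf[irow, 1], interaction_se = cf[irow, 2],
                 interaction_p = cf[irow, 4], stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_age = per_age, pairwise = pairwise, formula = formula),
            class = "rsa_age_fit")
}

#' @export
print.rsa_age_fit <- function(x, ...) {
  cat(sprintf("<rsa_age_fit> %s\n", x$formula))
  print(x$per_age, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise RSA x age interactions:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Wilcoxon test wrapper
#'
#' Rank-sum (unpaired) or signed-rank (paired) test. Exact enumeration is
#' used for small untied samples (min sample size <= 25), the tie-corrected
#' normal approximation with continuity correction otherwise. All-zero
#' paired differences yield a degenerate signal rather than an error.
#'
#' @param a,b Numeric samples (equal length when paired).
#' @param paired Paired test flag.
#' @return List with `statistic`, `p_value`, `status`.
#' @export
wilcoxon_test <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stopf("paired samples must have equal length")
  if (paired && all(a - b == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, status = "degenerate"))
  has_ties <- if (paired) anyDuplicated(abs(a - b)[a - b != 0]) > 0 else
    anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 25 && !has_ties
  wt <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, status = "ok")
}

#' Length-binned pairing of stability scores across age classes
#'
#' Bins structures by length (default bin width 25 residues) and, within
#' each bin present in all groups, retains an equal count per group by
#' seeded down-sampling, so the compared groups share the same length
#' distribution at bin resolution. Bins lacking any group are dropped. When
#' no bin contains all groups the result is empty and flagged; the
#' `rescuable_without` field lists groups whose exclusion would make the
#' pairing non-empty (the situation in which one age class must be dropped
#' from the stability comparison).
#'
#' @param groups Named list (age class -> data frame with `length` and
#'   `dg`).
#' @param bin_width Length bin width in residues (default 25).
#' @param seed Seed for the down-sampling.
#' @return Object of class `length_pairing`: `records` data frame
#'   (`bin`, `group`, `length`, `dg`), `empty` flag, `rescuable_without`.
#' @export
length_bin_pairing <- function(groups, bin_width = 25L, seed = 1L) {
  stopifnot(length(groups) >= 2L)
  binned <- lapply(groups, function(g) {
    g$bin <- as.integer(floor(g$length / bin_width))
    g
  })
  common_bins <- Reduce(intersect, lapply(binned, function(g) unique(g$bin)))
  records <- NULL
  if (length(common_bins) > 0L) {
    records <- with_seed(seed, do.call(rbind, lapply(sort(common_bins), function(b) {
      per_group <- lapply(binned, function(g) g[g$bin == b, , drop = FALSE])
      m <- min(vapply(per_group, nrow, integer(1)))
      do.call(rbind, lapply(names(per_group), function(gn) {
        g <- per_group[[gn]]
        take <- if (nrow(g) > m) sample.int(nrow(g), m) else seq_len(nrow(g))
        data.frame(bin = b, group = gn, length = g$length[take],
                   dg = g$dg[take], stringsAsFactors = FALSE)
      }))
    })))
  }
  empty <- is.null(records) || nrow(records) == 0L
  rescuable <- character(0)
  if (empty && length(groups) > 2L) {
    for (drop_g in names(groups)) {
      rest <- binned[setdiff(names(binned), drop_g)]
      if (length(Reduce(intersect, lapply(rest, function(g) unique(g$bin)))) > 0L)
        rescuable <- c(rescuable, drop_g)
    }
  }
  structure(list(records = records, empty = empty,
                 rescuable_without = rescuable, bin_width = bin_width),
            class = "length_pairing")
}

#' @export
print.length_pairing <- function(x, ...) {
  if (x$empty) {
    cat("<length_pairing> empty: no length bin contains every group\n")
    if (length(x$rescuable_without) > 0L)
      cat(sprintf("  pairing possible after excluding: %s\n",
                  paste(x$rescuable_without, collapse = ", ")))
  } else {
    cat(sprintf("<length_pairing> %d records in %d bins x %d groups (width %d)\n",
                nrow(x$records), length(unique(x$records$bin)),
                length(unique(x$records$group)), x$bin_width))
  }
  invisible(x)
}
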