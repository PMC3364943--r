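# End-to-end orchestration: synthetic cohort generation, feature
# extraction, age assignment, rate estimation, stability and robustness,
# and the statistical report.

#' Pipeline configuration
#'
#' Defaults define the synthetic study conditions at desk scale: three
#' analysed age classes with age-dependent core fraction, overall rate and
#' accessibility slope (see [sim_config()]), a disjoint training corpus for
#' the potential, the 1-per-50-residue mutation rate with 1000 replicates,
#' and 200 bootstrap resamples for binned-dN standard errors.
#'
#' @param seed Master seed; every downstream seed derives from it.
#' @param ages Age classes to simulate (mammalia is excluded from analysis
#'   by design, mirroring its scarcity).
#' @param n_structures Structures per age class.
#' @param chain_length Min/max residue count per structure.
#' @param n_train,train_length Training-corpus size and length range for
#'   the potential.
#' @param cutoff,pseudocount Potential parameters.
#' @param denominator,n_replicates Robustness parameters.
#' @param n_boot Bootstrap resamples for binned standard errors.
#' @param length_bin_width Length bin width for the stability comparison.
#' @param stages Pipeline stages to run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            ages = c("eukarya", "metazoa", "vertebrata"),
                            n_structures = 24L,
                            chain_length = c(120L, 260L),
                            n_train = 50L, train_length = c(80L, 160L),
                            cutoff = 8.5, pseudocount = 1,
                            denominator = 50L, n_replicates = 1000L,
                            n_boot = 200L, length_bin_width = 25L,
                            stages = c("features", "rates", "stability",
                                       "robustness", "stats")) {
  cfg <- list(seed = as.integer(seed), ages = ages,
              n_structures = as.integer(n_structures),
              chain_length = as.integer(chain_length),
              n_train = as.integer(n_train),
              train_length = as.integer(train_length),
              cutoff = cutoff, pseudocount = pseudocount,
              denominator = as.integer(denominator),
              n_replicates = as.integer(n_replicates),
              n_boot = as.integer(n_boot),
              length_bin_width = as.integer(length_bin_width),
              stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf)
  unname(tools::md5sum(tf))
}

# generate the analysis cohort: structures + features + ortholog pairs +
# age assignments, one list entry per structure
generate_cohort <- function(config) {
  entries <- list()
  i <- 0L
  for (age in config$ages) {
    for (k in seq_len(config$n_structures)) {
      i <- i + 1L
      sseed <- (config$seed * 10007L + i * 131L) %% 2000000000L
      len <- with_seed(sseed,
                       sample(config$chain_length[1]:config$chain_length[2], 1L))
      sc <- sim_config(chain_length = len, age_class = age, seed = sseed)
      struct <- generate_toy_structure(sc, id = sprintf("SYN_%s_%03d", age, k))
      feats <- residue_features(struct)
      pair <- generate_ortholog_pair(struct, feats, sc)
      hits <- generate_homolog_profile(age, seed = sseed + 7L,
                                       query_id = struct$id)
      assigned <- assign_age(hits)
      entries[[struct$id]] <- list(structure = struct, features = feats,
                                   pair = pair, config = sc,
                                   age_class = assigned$age_class,
                                   age_status = assigned$status)
    }
  }
  entries
}

pipeline_rates <- function(cohort, config) {
  # per-structure whole-chain estimates with robustness filters
  per_structure <- do.call(rbind, lapply(cohort, function(e) {
    est <- estimate_dn_ds(codon_alignment(e$pair$codons_a, e$pair$codons_b))
    filt <- apply_rate_filters(est, aa_length = est$n_codons)
    data.frame(structure_id = e$structure$id, age_class = e$age_class,
               n_codons = est$n_codons, dn = est$dn, ds = est$ds,
               omega = est$omega, retained = filt$retained,
               filter_reason = filt$reason, stringsAsFactors = FALSE)
  }))
  rownames(per_structure) <- NULL

  pair_entries <- unname(lapply(cohort, function(e)
    list(pair = e$pair, features = e$features, age_class = e$age_class)))
  groups_bin <- concatenate_by_category(pair_entries, "rsa_bin")
  groups_bin_age <- concatenate_by_category(pair_entries, "rsa_bin", by_age = TRUE)
  series_all <- binned_rate_series(groups_bin, n_boot = config$n_boot,
                                   seed = config$seed)
  series_age <- binned_rate_series(groups_bin_age, n_boot = 0L)
  series_by_age <- split(series_age, series_age$age_class)

  # per-structure per-category estimates for the category/age comparisons
  cat_rows <- list()
  for (e in cohort) {
    feats <- e$features
    for (grouping in c("ss_category", "exposure")) {
      for (g in unique(feats[[grouping]])) {
        sel <- feats$position[feats[[grouping]] == g]
        est <- estimate_dn_ds(codon_alignment(e$pair$codons_a[sel],
                                              e$pair$codons_b[sel]))
        filt <- apply_rate_filters(est, aa_length = length(sel))
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          structure_id = e$structure$id, age_class = e$age_class,
          category = g, n_codons = length(sel), dn = est$dn, ds = est$ds,
          omega = est$omega, retained = filt$retained,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_category <- do.call(rbind, cat_rows)
  rownames(per_category) <- NULL
  list(per_structure = per_structure, per_category = per_category,
       series_all = series_all, series_by_age = series_by_age)
}

CATEGORY_SET <- c("helix", "sheet", "turn", "coil", "exposed", "buried")

pipeline_stats <- function(rates, cohort, config) {
  ages <- config$ages
  overall_cor <- pearson_binned_correlation(rates$series_all)
  per_age_cor <- lapply(rates$series_by_age, pearson_binned_correlation)
  fits <- fit_rsa_age_model(rates$series_by_age, "dN~RSA+RSA*age+age")

  # fraction-exposed and whole-chain rate comparisons across age classes
  fe <- do.call(rbind, lapply(cohort, function(e) data.frame(
    structure_id = e$structure$id, age_class = e$age_class,
    fraction_exposed = fraction_exposed(e$features),
    stringsAsFactors = FALSE)))
  rownames(fe) <- NULL
  pairs <- combn(ages, 2L)
  age_tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a1 <- pairs[1, k]; a2 <- pairs[2, k]
    ps <- rates$per_structure[rates$per_structure$retained, ]
    w_fe <- wilcoxon_test(fe$fraction_exposed[fe$age_class == a1],
                          fe$fraction_exposed[fe$age_class == a2])
    w_dn <- wilcoxon_test(ps$dn[ps$age_class == a1], ps$dn[ps$age_class == a2])
    ok <- !is.na(ps$omega)
    w_om <- wilcoxon_test(ps$omega[ok & ps$age_class == a1],
                          ps$omega[ok & ps$age_class == a2])
    data.frame(age_a = a1, age_b = a2,
               p_fraction_exposed = w_fe$p_value,
               p_dn = w_dn$p_value, p_omega = w_om$p_value,
               median_dn_a = median(ps$dn[ps$age_class == a1], na.rm = TRUE),
               median_dn_b = median(ps$dn[ps$age_class == a2], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  # category-by-age matrix (6 categories x 3 age pairs x {dN/dS, dN})
  pc <- rates$per_category[rates$per_category$retained, ]
  cat_rows <- list()
  for (cat in CATEGORY_SET) {
    for (k in seq_len(ncol(pairs))) {
      a1 <- pairs[1, k]; a2 <- pairs[2, k]
      xa <- pc[pc$category == cat & pc$age_class == a1, ]
      xb <- pc[pc$category == cat & pc$age_class == a2, ]
      p_dn <- p_om <- NA_real_
      if (nrow(xa) >= 2L && nrow(xb) >= 2L) {
        p_dn <- wilcoxon_test(xa$dn, xb$dn)$p_value
        oa <- xa$omega[!is.na(xa$omega)]; ob <- xb$omega[!is.na(xb$omega)]
        if (length(oa) >= 2L && length(ob) >= 2L)
          p_om <- wilcoxon_test(oa, ob)$p_value
      }
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        category = cat, age_a = a1, age_b = a2,
        p_omega = p_om, p_dn = p_dn, stringsAsFactors = FALSE)
    }
  }
  category_age_matrix <- do.call(rbind, cat_rows)

  list(overall_cor = overall_cor, per_age_cor = per_age_cor, fits = fits,
       fraction_exposed = fe, age_tests = age_tests,
       category_age_matrix = category_age_matrix)
}

pipeline_stability <- function(cohort, config) {
  train <- lapply(seq_len(config$n_train), function(k) {
    sseed <- (config$seed * 20011L + k * 197L) %% 2000000000L
    len <- with_seed(sseed,
                     sample(config$train_length[1]:config$train_length[2], 1L))
    age <- config$ages[1L + (k %% length(config$ages))]
    generate_toy_structure(sim_config(chain_length = len, age_class = age,
                                      seed = sseed),
                           id = sprintf("TRAIN_%03d", k))
  })
  model <- train_potential(train, cutoff = config$cutoff,
                           pseudocount = config$pseudocount)
  dg <- do.call(rbind, lapply(cohort, function(e) data.frame(
    structure_id = e$structure$id, age_class = e$age_class,
    length = length(e$structure$aa),
    dg = score_structure(e$structure, model), stringsAsFactors = FALSE)))
  rownames(dg) <- NULL
  groups <- lapply(split(dg, dg$age_class), function(d)
    data.frame(length = d$length, dg = d$dg))
  pairing <- length_bin_pairing(groups, bin_width = config$length_bin_width,
                                seed = config$seed)
  paired_tests <- NULL
  if (!pairing$empty) {
    grs <- unique(pairing$records$group)
    cmb <- combn(grs, 2L)
    paired_tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      a <- pairing$records[pairing$records$group == cmb[1, k], ]
      b <- pairing$records[pairing$records$group == cmb[2, k], ]
      w <- wilcoxon_test(a$dg, b$dg, paired = TRUE)
      data.frame(group_a = cmb[1, k], group_b = cmb[2, k],
                 median_a = median(a$dg), median_b = median(b$dg),
                 p_value = w$p_value, n = nrow(a), stringsAsFactors = FALSE)
    }))
  }
  list(model = model, dg_table = dg, pairing = pairing,
       paired_tests = paired_tests)
}

pipeline_robustness <- function(cohort, model, config) {
  tab <- do.call(rbind, lapply(cohort, function(e) {
    pop <- build_mutant_population(
      e$structure, model, denominator = config$denominator,
      n_replicates = config$n_replicates,
      seed = (string_seed(e$structure$id) + config$seed) %% 2000000000L)
    data.frame(structure_id = e$structure$id, age_class = e$age_class,
               native_dg = pop$native_dg,
               mutant_mean = mean(pop$mutant_dgs),
               mutant_sd = sd(pop$mutant_dgs),
               z_score = pop$z_score, rank = pop$rank,
               denominator = pop$mutation_rate_denominator,
               n_replicates = pop$n_replicates, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  pairs <- combn(config$ages, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a1 <- pairs[1, k]; a2 <- pairs[2, k]
    data.frame(age_a = a1, age_b = a2,
               p_z = wilcoxon_test(tab$z_score[tab$age_class == a1],
                                   tab$z_score[tab$age_class == a2])$p_value,
               p_rank = wilcoxon_test(tab$rank[tab$age_class == a1],
                                      tab$rank[tab$age_class == a2])$p_value,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, tests = tests)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates cohort generation, feature extraction, age assignment, rate
#' estimation, potential training and stability scoring, mutational
#' robustness, and the statistical comparisons. Stage failures are logged
#' and dependent downstream products carry an explicit `"skipped"` status.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, intermediate tables are
#'   written as TSV and the run manifest as JSON.
#' @return Object of class `evostruct_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  status <- list()
  run_stage <- function(name, expr) {
    if (!name %in% c("features", config$stages)) {
      status[[name]] <<- "disabled"
      return(NULL)
    }
    tryCatch({
      out <- force(expr)
      status[[name]] <<- "ok"
      out
    }, error = function(e) {
      status[[name]] <<- paste("failed:", conditionMessage(e))
      NULL
    })
  }

  cohort <- generate_cohort(config)
  features <- do.call(rbind, unname(lapply(cohort, function(e) e$features)))
  rates <- run_stage("rates", pipeline_rates(cohort, config))
  stats <- if (!is.null(rates)) run_stage("stats", pipeline_stats(rates, cohort, config))
  else { status$stats <- "skipped (rates unavailable)"; NULL }
  stability <- run_stage("stability", pipeline_stability(cohort, config))
  robustness <- if (!is.null(stability))
    run_stage("robustness", pipeline_robustness(cohort, stability$model, config))
  else { status$robustness <- "skipped (stability unavailable)"; NULL }

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("evostruct")),
                   n_structures = length(cohort),
                   stages = status)
  report <- structure(list(config = config, features = features,
                           rates = rates, stats = stats,
                           stability = stability, robustness = robustness,
                           manifest = manifest), class = "evostruct_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    path <- file.path(outdir, name)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# evostruct %s seed=%d hash=%s",
                       name, report$config$seed, report$manifest$config_hash), con)
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$features, "residue_features.tsv")
  if (!is.null(report$rates)) {
    wt(report$rates$per_structure, "rates_per_structure.tsv")
    wt(report$rates$per_category, "rates_per_category.tsv")
    wt(report$rates$series_all, "rates_rsa_bins.tsv")
    wt(do.call(rbind, report$rates$series_by_age), "rates_rsa_bins_by_age.tsv")
  }
  if (!is.null(report$stats)) {
    wt(report$stats$age_tests, "age_comparisons.tsv")
    wt(report$stats$category_age_matrix, "category_age_matrix.tsv")
    wt(report$stats$fraction_exposed, "fraction_exposed.tsv")
    wt(report$stats$fits$per_age, "rsa_fits_per_age.tsv")
    wt(report$stats$fits$pairwise, "rsa_age_interactions.tsv")
  }
  if (!is.null(report$stability)) {
    wt(report$stability$dg_table, "stability_scores.tsv")
    wt(report$stability$paired_tests, "stability_paired_tests.tsv")
  }
  if (!is.null(report$robustness)) {
    wt(report$robustness$table, "robustness.tsv")
    wt(report$robustness$tests, "robustness_tests.tsv")
  }
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.evostruct_report <- function(x, ...) {
  cat("<evostruct_report>\n")
  cat(sprintf("  cohort: %d structures, %d residues\n",
              x$manifest$n_structures, nrow(x$features)))
  for (s in names(x$manifest$stages))
    cat(sprintf("  stage %-10s %s\n", s, x$manifest$stages[[s]]))
  if (!is.null(x$stats)) {
    cat(sprintf("  binned RSA-dN Pearson r = %.3f (p = %.3g)\n",
                x$stats$overall_cor$r, x$stats$overall_cor$p_value))
    sl <- x$stats$fits$per_age
    cat(sprintf("  dN~RSA slopes: %s\n",
                paste(sprintf("%s %.4f", sl$age_class, sl$slope), collapse = ", ")))
  }
  invisible(x)
}

#' Figure-analogue plot of the binned RSA-dN relationship
#'
#' Plots dN against RSA-bin midpoint per age class with least-squares
#' lines, the analogue of the binned accessibility-rate figure.
#'
#' @param x An `evostruct_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.evostruct_report <- function(x, ...) {
  if (is.null(x$rates)) stopf("report has no rates stage")
  sba <- x$rates$series_by_age
  cols <- setNames(seq_along(sba) + 1L, names(sba))
  all_pts <- do.call(rbind, sba)
  graphics::plot(all_pts$midpoint, all_pts$dn, type = "n",
                 xlab = "RSA bin midpoint", ylab = "dN", ...)
  for (age in names(sba)) {
    s <- sba[[age]]
    graphics::points(s$midpoint, s$dn, col = cols[age], pch = 19)
    graphics::abline(lm(dn ~ midpoint, data = s), col = cols[age])
  }
  graphics::legend("topleft", legend = names(sba), col = cols, pch = 19, bty = "n")
  invisible(x)
}
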