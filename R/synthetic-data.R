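# Synthetic-data generators: compact toy structures with a planted
# hydrophobic core, orthologous codon pairs whose per-residue substitution
# probability is linear in relative solvent accessibility, homolog
# presence/absence hit tables, and decoy sets for potential validation.

# the four age classes, youngest to oldest
AGE_ORDER <- c("mammalia", "vertebrata", "metazoa", "eukarya")

#' Species groups used for phylostratigraphic age assignment
#'
#' Named list mapping each age class to its diagnostic species: mammals
#' (*Mus musculus*, *Rattus norvegicus*), non-mammalian vertebrates
#' (*Gallus gallus*, *Xenopus tropicalis*, *Danio rerio*,
#' *Takifugu rubripes*), other metazoans (*Ciona intestinalis*,
#' *Drosophila melanogaster*, *Anopheles gambiae*,
#' *Caenorhabditis elegans*) and other eukaryotes
#' (*Schizosaccharomyces pombe*, *Saccharomyces cerevisiae*,
#' *Oryza sativa*, *Arabidopsis thaliana*). Alternative clade schemes can be
#' passed to [assign_age()].
#'
#' @export
species_groups_default <- function() {
  list(
    mammalia   = c("Mus musculus", "Rattus norvegicus"),
    vertebrata = c("Gallus gallus", "Xenopus tropicalis", "Danio rerio",
                   "Takifugu rubripes"),
    metazoa    = c("Ciona intestinalis", "Drosophila melanogaster",
                   "Anopheles gambiae", "Caenorhabditis elegans"),
    eukarya    = c("Schizosaccharomyces pombe", "Saccharomyces cerevisiae",
                   "Oryza sativa", "Arabidopsis thaliana"))
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic small integer derived from a string (used for jitter seeds)
string_seed <- function(x) {
  sum(utf8ToInt(x) * seq_len(nchar(x))) %% 2147483647L
}

#' Simulation configuration
#'
#' Bundles the parameters of one synthetic protein: chain length, target
#' buried-core fraction, age class, and the two parameters of the planted
#' substitution process (per-codon substitution probability
#' `min(1, base_rate + rsa_slope * RSA)`).
#'
#' Per-age defaults encode the study conditions the generators emulate:
#' older proteins have a larger buried core (`core_fraction` 0.45 / 0.40 /
#' 0.35 for eukarya / metazoa / vertebrata), younger proteins evolve faster
#' overall (`base_rate` 0.01 / 0.02 / 0.04) and show a steeper accessibility
#' dependence (`rsa_slope` 0.0075 / 0.009 / 0.018, a 2.4-fold
#' eukarya-to-vertebrata ratio on the substitution-probability scale).
#'
#' @param chain_length Number of residues (>= 10).
#' @param age_class One of `"eukarya"`, `"metazoa"`, `"vertebrata"`,
#'   `"mammalia"`.
#' @param core_fraction Target fraction of buried residues in `[0, 1]`;
#'   default depends on `age_class`.
#' @param base_rate Expected substitutions per codon for fully buried
#'   residues (RSA = 0); default depends on `age_class`.
#' @param rsa_slope Increment of per-codon substitution probability per unit
#'   RSA; default depends on `age_class`.
#' @param ns_fraction Probability that a planted substitution is
#'   nonsynonymous (default 0.75, the approximate random expectation).
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chain_length = 150L, age_class = "eukarya",
                       core_fraction = NULL, base_rate = NULL,
                       rsa_slope = NULL, ns_fraction = 0.75, seed = 1L) {
  age_class <- match.arg(age_class, AGE_ORDER)
  defaults <- list(
    eukarya    = list(core_fraction = 0.45, base_rate = 0.01, rsa_slope = 0.0075),
    metazoa    = list(core_fraction = 0.40, base_rate = 0.02, rsa_slope = 0.009),
    vertebrata = list(core_fraction = 0.35, base_rate = 0.04, rsa_slope = 0.018),
    mammalia   = list(core_fraction = 0.33, base_rate = 0.05, rsa_slope = 0.020))
  d <- defaults[[age_class]]
  cfg <- list(chain_length = as.integer(chain_length),
              age_class = age_class,
              core_fraction = core_fraction %||% d$core_fraction,
              base_rate = base_rate %||% d$base_rate,
              rsa_slope = rsa_slope %||% d$rsa_slope,
              ns_fraction = ns_fraction,
              seed = as.integer(seed))
  if (cfg$chain_length < 10L) stopf("chain_length must be >= 10 (got %d)", cfg$chain_length)
  if (cfg$core_fraction < 0 || cfg$core_fraction > 1)
    stopf("core_fraction must lie in [0, 1]")
  if (cfg$base_rate < 0) stopf("base_rate must be >= 0")
  if (cfg$rsa_slope < 0) stopf("rsa_slope must be >= 0")
  if (cfg$ns_fraction < 0 || cfg$ns_fraction > 1)
    stopf("ns_fraction must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(1, 0, 0) else v / nv
}

# Collapsed self-avoiding walk: consecutive alpha carbons 3.7-3.9 Angstroms
# apart, each step biased toward the running centroid so the chain forms a
# compact globule; candidate steps closer than ~3.8 A to any earlier residue
# are rejected (best candidate kept if all trials fail, so the walk always
# terminates).
gen_ca_trace <- function(n) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    prev <- xyz[i - 1L, ]
    cen <- if (i > 2L) colMeans(xyz[seq_len(i - 1L), , drop = FALSE]) else prev
    best <- NULL
    best_min <- -Inf
    for (trial in 1:40) {
      d <- unit(rnorm(3))
      if (i > 4L) d <- unit(d + 0.9 * unit(cen - prev))
      cand <- prev + runif(1, 3.7, 3.9) * d
      if (i > 2L) {
        others <- xyz[seq_len(i - 2L), , drop = FALSE]
        dmin <- min((others[, 1] - cand[1])^2 + (others[, 2] - cand[2])^2 +
                      (others[, 3] - cand[3])^2)
      } else dmin <- Inf
      if (dmin > 14.44) { # 3.8^2
        best <- cand
        break
      }
      if (dmin > best_min) {
        best_min <- dmin
        best <- cand
      }
    }
    xyz[i, ] <- best
  }
  xyz
}

# idealized backbone placement: N toward the previous alpha carbon, C toward
# the next, carbonyl O off the local chain plane
place_backbone <- function(ca) {
  n <- nrow(ca)
  Nm <- Cm <- Om <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    to_prev <- if (i > 1L) unit(ca[i - 1L, ] - ca[i, ]) else unit(ca[i, ] - ca[i + 1L, ])
    to_next <- if (i < n) unit(ca[i + 1L, ] - ca[i, ]) else unit(ca[i, ] - ca[i - 1L, ])
    perp <- unit(pracma_cross(to_prev, to_next))
    Nm[i, ] <- ca[i, ] + 1.46 * to_prev
    Cm[i, ] <- ca[i, ] + 1.52 * to_next
    Om[i, ] <- Cm[i, ] + 1.23 * perp
  }
  list(N = Nm, C = Cm, O = Om)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# piecewise-linear map of burial-rank quantile -> target RSA, calibrated so
# that the expected fraction of residues below RSA 0.25 equals core_fraction
rsa_from_rank <- function(q, core_fraction) {
  ifelse(q < core_fraction,
         0.25 * q / max(core_fraction, 1e-9),
         0.25 + 0.75 * (q - core_fraction) / max(1 - core_fraction, 1e-9))
}

# secondary-structure letters emitted in runs, with realistic class weights
gen_ss_letters <- function(n) {
  out <- character(0)
  classes <- c("H", "E", "T", "C")
  while (length(out) < n) {
    len <- sample(3:12, 1L)
    cls <- sample(classes, 1L, prob = c(0.35, 0.22, 0.23, 0.20))
    letter <- switch(cls,
                     H = "H", E = "E",
                     T = sample(c("S", "T"), 1L),
                     C = sample(c("B", "G", "I", "."), 1L))
    out <- c(out, rep(letter, len))
  }
  out[seq_len(n)]
}

#' Generate a compact toy protein structure with a planted hydrophobic core
#'
#' Builds a single contiguous chain by a collapsed self-avoiding walk
#' (consecutive alpha-carbon distance 3.8 +/- 0.1 Angstroms), assigns
#' hydrophobic amino acids preferentially to the residues nearest the
#' centroid so that approximately `core_fraction * chain_length` residues
#' are buried, places idealized backbone atoms, and plants per-residue
#' accessibility (RSA, emitted as DSSP-style integer ACC values) and
#' secondary-structure letters.
#'
#' @param config A [sim_config()].
#' @param id Structure identifier.
#' @return An object of class `protein_structure` with components `id`,
#'   `resno`, `aa`, `ca` (n x 3 matrix), `backbone` (list of N/C/O
#'   matrices), `experiment`, `model_index` and `annotation` (data frame
#'   with planted `rsa`, `acc`, `ss` per residue).
#' @export
generate_toy_structure <- function(config, id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$chain_length
  id <- id %||% sprintf("SYN%04d", config$seed %% 10000L)
  with_seed(config$seed, {
    ca <- gen_ca_trace(n)
    cen <- colMeans(ca)
    burial <- sqrt(rowSums((ca - matrix(cen, n, 3, byrow = TRUE))^2))
    brank <- rank(burial, ties.method = "first")
    n_core <- round(config$core_fraction * n)
    core <- brank <= n_core
    aa <- character(n)
    aa[core] <- sample(HYDROPHOBIC, sum(core), replace = TRUE)
    aa[!core] <- sample(POLAR, sum(!core), replace = TRUE)
    q <- (brank - 0.5) / n
    rsa <- pmin(1, pmax(0, rsa_from_rank(q, config$core_fraction) + rnorm(n, 0, 0.05)))
    ref <- miller_asa_table()
    acc <- as.integer(round(rsa * ref[aa]))
    ss <- gen_ss_letters(n)
    bb <- place_backbone(ca)
    structure(list(
      id = id, resno = seq_len(n), aa = aa, ca = ca, backbone = bb,
      experiment = "xray", model_index = 1L,
      annotation = data.frame(resno = seq_len(n), aa = aa, ss = ss,
                              acc = acc, rsa = rsa, core = core,
                              stringsAsFactors = FALSE),
      config = config), class = "protein_structure")
  })
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues (%s, model %d)\n",
              x$id, length(x$aa), x$experiment, x$model_index))
  invisible(x)
}

#' Generate an aligned orthologous codon-sequence pair
#'
#' Back-translates the structure's amino-acid sequence into a coding
#' sequence (uniform synonymous codon choice), then derives the second
#' sequence by substituting codon `i` with probability
#' `min(1, base_rate + rsa_slope * RSA_i)`. A substitution is nonsynonymous
#' with probability `ns_fraction` (single-nucleotide neighbor, never a stop
#' codon) and synonymous otherwise; a synonymous draw at a codon with no
#' synonymous single-nucleotide neighbor (Met, Trp) leaves the codon
#' unchanged, so the nonsynonymous process is exactly
#' `ns_fraction * p` at every position.
#'
#' @param struct A `protein_structure`.
#' @param features Per-residue feature table covering every residue (needs
#'   columns `position` and `rsa`), as returned by [residue_features()].
#' @param config A [sim_config()]; the RNG is seeded from `config$seed + 1`.
#' @return Object of class `ortholog_pair`: gap-free aligned CDS pair
#'   (`cds_a`, `cds_b`), codon vectors, and the per-codon RSA used.
#' @export
generate_ortholog_pair <- function(struct, features, config) {
  stopifnot(inherits(struct, "protein_structure"))
  n <- length(struct$aa)
  if (nrow(features) != n)
    stopf("feature table has %d rows but structure has %d residues",
          nrow(features), n)
  with_seed(config$seed + 1L, {
    sim <- sim_codon_pair(struct$aa, features$rsa, config)
    structure(list(
      structure_id = struct$id,
      cds_a = paste(sim$a, collapse = ""),
      cds_b = paste(sim$b, collapse = ""),
      codons_a = sim$a, codons_b = sim$b,
      rsa = features$rsa, age_class = config$age_class), class = "ortholog_pair")
  })
}

# vectorized core of the pair generator; consumes the current RNG stream
sim_codon_pair <- function(aa, rsa, config) {
  ct <- codon_data()
  n <- length(aa)
  # uniform synonymous codon per residue, drawn grouped by amino acid
  codons_a <- character(n)
  for (a in unique(aa)) {
    pool <- ct$syn_codons_by_aa[[a]]
    sel <- aa == a
    codons_a[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }
  p_sub <- pmin(1, config$base_rate + config$rsa_slope * rsa)
  hit <- runif(n) < p_sub
  codons_b <- codons_a
  if (any(hit)) {
    nonsyn <- runif(n) < config$ns_fraction
    idx <- which(hit)
    # neighbor choice grouped by (source codon, substitution type)
    key <- paste0(codons_a[idx], ifelse(nonsyn[idx], "N", "S"))
    for (kk in unique(key)) {
      sel <- idx[key == kk]
      src <- substr(kk, 1, 3)
      pool <- if (substr(kk, 4, 4) == "N") ct$nonsyn_neighbors[[src]] else
        ct$syn_neighbors[[src]]
      # a synonymous draw at a codon with no synonymous single-nt neighbor
      # (Met, Trp) is dropped rather than diverted: diverting it would make
      # the realized nonsynonymous rate depend on local amino-acid
      # composition and distort the planted linear RSA relation
      if (length(pool) == 0L) next
      codons_b[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
    }
  }
  list(a = codons_a, b = codons_b)
}

#' Generate several independent ortholog pairs for one structure
#'
#' Replicate pairs share the structure (hence the RSA profile) but draw
#' independent codon choices and substitution events; replicates are
#' simulated in one vectorized pass, which matters for the large
#' parameter-recovery experiments.
#'
#' @inheritParams generate_ortholog_pair
#' @param n_pairs Number of independent pairs.
#' @return List of `ortholog_pair` objects.
#' @export
generate_ortholog_pairs <- function(struct, features, config, n_pairs = 1L) {
  stopifnot(inherits(struct, "protein_structure"))
  n <- length(struct$aa)
  if (nrow(features) != n)
    stopf("feature table has %d rows but structure has %d residues",
          nrow(features), n)
  with_seed(config$seed + 1L, {
    sim <- sim_codon_pair(rep(struct$aa, n_pairs), rep(features$rsa, n_pairs),
                          config)
    lapply(seq_len(n_pairs), function(k) {
      take <- seq.int((k - 1L) * n + 1L, k * n)
      structure(list(
        structure_id = struct$id,
        cds_a = paste(sim$a[take], collapse = ""),
        cds_b = paste(sim$b[take], collapse = ""),
        codons_a = sim$a[take], codons_b = sim$b[take],
        rsa = features$rsa, age_class = config$age_class),
        class = "ortholog_pair")
    })
  })
}

#' Generate a homolog presence/absence hit table for a chosen age class
#'
#' Emits BLAST-tabular-style hit records whose subject species span exactly
#' the phylogenetic width implied by `age_class`: at least one hit in the
#' age-defining group, optional hits in every younger group, none in older
#' groups. All e-values are at or below the 1e-4 detection cutoff.
#'
#' @param age_class One of the four age classes.
#' @param seed Integer seed.
#' @param query_id Query identifier for the hit records.
#' @return Data frame of class `homolog_hits` in outfmt-6 column order plus
#'   a `subject_species` column.
#' @export
generate_homolog_profile <- function(age_class, seed = 1L, query_id = "query1") {
  if (!age_class %in% AGE_ORDER) stopf("unknown age_class '%s'", age_class)
  groups <- species_groups_default()
  idx <- match(age_class, AGE_ORDER)
  with_seed(seed, {
    rows <- list()
    for (g in seq_len(idx)) {
      gname <- AGE_ORDER[g]
      species <- groups[[gname]]
      present <- runif(length(species)) < 0.7
      if (g == idx && !any(present)) present[sample.int(length(species), 1L)] <- TRUE
      for (sp in species[present]) {
        qlen <- sample(80:400, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query_id,
          subject_id = sprintf("%s_%03d", toupper(substr(gsub(" ", "", sp), 1, 5)),
                               sample.int(999L, 1L)),
          subject_species = sp,
          percent_identity = round(runif(1, 30, 95), 1),
          alignment_length = qlen,
          mismatches = sample.int(50L, 1L),
          gap_openings = sample.int(5L, 1L),
          query_start = 1L, query_end = qlen,
          subject_start = 1L, subject_end = qlen,
          e_value = 10^runif(1, -180, -4),
          bit_score = round(runif(1, 60, 900), 1),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("homolog_hits", class(out))
    out
  })
}

#' Generate decoys from a native structure
#'
#' `shuffle_sequence` decoys permute the amino-acid sequence (exact
#' composition preserved) on the fixed native coordinates;
#' `perturb_coordinates` decoys keep the sequence and displace every alpha
#' carbon by a random vector of norm at most `max_displacement`, preserving
#' chain connectivity.
#'
#' @param struct Native `protein_structure`.
#' @param n Number of decoys (> 0).
#' @param mode `"shuffle_sequence"` or `"perturb_coordinates"`.
#' @param seed Integer seed.
#' @param max_displacement Displacement bound in Angstroms for coordinate
#'   perturbation (default 1).
#' @return List of `n` `protein_structure` decoys.
#' @export
generate_decoy_set <- function(struct, n, mode = c("shuffle_sequence", "perturb_coordinates"),
                               seed = 1L, max_displacement = 1.0) {
  mode <- match.arg(mode)
  if (n <= 0) stopf("n must be positive")
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      d <- struct
      d$id <- sprintf("%s_decoy%03d", struct$id, k)
      if (mode == "shuffle_sequence") {
        perm <- sample.int(length(struct$aa))
        d$aa <- struct$aa[perm]
      } else {
        m <- length(struct$aa)
        dir <- matrix(rnorm(3 * m), m, 3)
        dir <- dir / sqrt(rowSums(dir^2))
        r <- max_displacement * runif(m)^(1 / 3)
        d$ca <- struct$ca + dir * r
      }
      d
    })
  })
}
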