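# Mutational robustness: random mutagenesis at one mutation per 50 (or 10)
# residues, per-site mutation scans, and the Z-score / rank statistics of
# the native sequence within its mutant population.

#' Randomly mutate a sequence at a fixed per-length rate
#'
#' Introduces `k = max(1, floor(length / denominator))` mutations at
#' distinct uniformly chosen positions; each mutated position receives a
#' uniformly chosen amino acid different from the native one.
#'
#' @param sequence Amino-acid sequence (character vector or string).
#' @param denominator Residues per mutation: 50 (2% of residues) or 10
#'   (10%).
#' @param seed Optional integer seed for reproducibility.
#' @return Mutated sequence as a character vector.
#' @export
mutate_sequence <- function(sequence, denominator = 50L, seed = NULL) {
  seq_vec <- if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    strsplit(sequence, "")[[1]] else sequence
  n <- length(seq_vec)
  if (n < 1L) stopf("empty sequence")
  do_mutate <- function() {
    k <- max(1L, n %/% as.integer(denominator))
    pos <- sample.int(n, k)
    for (p in pos) {
      alt <- setdiff(AA20, seq_vec[p])
      seq_vec[p] <- alt[sample.int(length(alt), 1L)]
    }
    seq_vec
  }
  if (is.null(seed)) do_mutate() else with_seed(seed, do_mutate())
}

#' Per-site random mutation scan
#'
#' Mutates each residue, one at a time, to a randomly selected different
#' amino acid, scores the mutant on the fixed native conformation, and
#' records the absolute stability perturbation
#' `|DeltaDeltaG| = |DeltaG(native) - DeltaG(mutant)|`.
#'
#' @param struct A `protein_structure`.
#' @param model A `four_body_potential`.
#' @param seed Integer seed.
#' @return Object of class `mutation_scan`: data frame with `position`,
#'   `native_aa`, `mutant_aa`, `ddg_abs`; native score in attribute
#'   `native_dg`.
#' @export
scan_point_mutations <- function(struct, model, seed = 1L) {
  ctx <- make_score_context(struct, model)
  aa_idx <- match(struct$aa, AA20)
  native_dg <- context_score(ctx, aa_idx)
  n <- length(aa_idx)
  with_seed(seed, {
    mut_idx <- vapply(aa_idx, function(a) {
      alt <- setdiff(seq_len(20L), a)
      alt[sample.int(19L, 1L)]
    }, integer(1))
    ddg <- numeric(n)
    work <- aa_idx
    for (p in seq_len(n)) {
      work[p] <- mut_idx[p]
      ddg[p] <- abs(native_dg - context_score(ctx, work))
      work[p] <- aa_idx[p]
    }
    out <- data.frame(position = seq_len(n), native_aa = struct$aa,
                      mutant_aa = AA20[mut_idx], ddg_abs = ddg,
                      stringsAsFactors = FALSE)
    attr(out, "native_dg") <- native_dg
    class(out) <- c("mutation_scan", class(out))
    out
  })
}

#' Mutant population and robustness statistics
#'
#' Generates `n_replicates` mutants of the native sequence via
#' [mutate_sequence()], scores each on the fixed native conformation, and
#' derives the robustness statistics: `Z = (DeltaG - <DeltaG>) / sigma`
#' (mean and standard deviation over the mutant population, n-1
#' denominator) and the rank of the native score in the sorted mutant list,
#' from lowest (most stable) to highest. Mutants scoring exactly the native
#' value count as above it, so `rank = 1 + #(mutants strictly below
#' native)`.
#'
#' @param struct A `protein_structure`.
#' @param model A `four_body_potential`.
#' @param denominator Residues per mutation (50 or 10).
#' @param n_replicates Population size (default 1000, >= 2).
#' @param seed Integer seed.
#' @return Object of class `mutant_population`.
#' @export
build_mutant_population <- function(struct, model, denominator = 50L,
                                    n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 2L) stopf("n_replicates must be >= 2")
  ctx <- make_score_context(struct, model)
  aa_idx <- match(struct$aa, AA20)
  native_dg <- context_score(ctx, aa_idx)
  n <- length(aa_idx)
  k <- max(1L, n %/% as.integer(denominator))
  mutant_dgs <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      work <- aa_idx
      pos <- sample.int(n, k)
      for (p in pos) {
        alt <- setdiff(seq_len(20L), work[p])
        work[p] <- alt[sample.int(19L, 1L)]
      }
      context_score(ctx, work)
    }, numeric(1))
  })
  sigma <- sd(mutant_dgs)
  z <- if (sigma > 0) (native_dg - mean(mutant_dgs)) / sigma else NA_real_
  structure(list(
    structure_id = struct$id, native_dg = native_dg,
    mutant_dgs = mutant_dgs,
    z_score = z,
    z_status = if (sigma > 0) "ok" else "sd_zero",
    rank = 1L + sum(mutant_dgs < native_dg),
    mutation_rate_denominator = as.integer(denominator),
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "mutant_population")
}

#' @export
print.mutant_population <- function(x, ...) {
  cat(sprintf(paste0("<mutant_population> %s: native DeltaG %.2f, %d mutants ",
                     "(1/%d rate): Z = %s, rank = %d/%d\n"),
              x$structure_id, x$native_dg, x$n_replicates,
              x$mutation_rate_denominator,
              if (x$z_status == "ok") sprintf("%.3f", x$z_score) else "undefined",
              x$rank, x$n_replicates + 1L))
  invisible(x)
}

#' @export
summary.mutant_population <- function(object, ...) {
  c(native_dg = object$native_dg, mutant_mean = mean(object$mutant_dgs),
    mutant_sd = sd(object$mutant_dgs), z_score = object$z_score,
    rank = object$rank)
}
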