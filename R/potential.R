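# Coarse-grained four-body knowledge-based potential.
#
# Residues are represented by their alpha carbons; the Delaunay
# tetrahedralization of those points defines quadruplets of spatially
# neighboring residues.  Simplices with any edge longer than the cutoff
# (default 8.5 Angstroms) are discarded to suppress artifactual
# surface-spanning tetrahedra.  The score of an unordered amino-acid
# quadruplet composition q is the log-odds ln(f_q / p_q) of its observed
# frequency among all retained simplices of a training corpus against the
# multinomial expectation from corpus amino-acid frequencies (with the
# multiset multiplicity factor).  The stability score of a (conformation,
# sequence) pair is DeltaG = -sum of simplex scores, so lower DeltaG means
# greater stability.

#' Delaunay tessellation of alpha-carbon positions
#'
#' Computes the 3D Delaunay tetrahedralization of the chain's alpha carbons
#' and discards simplices with any edge longer than `cutoff`. Degenerate
#' point configurations are retried once after a deterministic jitter of
#' 1e-6 Angstroms seeded from the structure id.
#'
#' @param x A `protein_structure` or an n x 3 coordinate matrix (n >= 4).
#' @param cutoff Maximum retained edge length in Angstroms (default 8.5).
#' @return Object of class `tessellation`: `simplices` (k x 4 matrix of
#'   1-based residue indices, rows sorted), `max_edge` (per simplex),
#'   `cutoff`, `n_points`.
#' @export
tessellate <- function(x, cutoff = 8.5) {
  coords <- if (inherits(x, "protein_structure")) x$ca else as.matrix(x)
  id <- if (inherits(x, "protein_structure")) x$id else "points"
  if (nrow(coords) < 4L) stopf("tessellation needs at least 4 points")
  simp <- .delaunay3d_cpp(coords)
  if (nrow(simp) == 0L) {
    jit <- with_seed(string_seed(id),
                     matrix(rnorm(length(coords), 0, 1e-6), nrow(coords), 3))
    simp <- .delaunay3d_cpp(coords + jit)
    if (nrow(simp) == 0L) stopf("degenerate point configuration (coplanar input)")
  }
  max_edge <- simplex_max_edge(coords, simp)
  keep <- max_edge <= cutoff
  structure(list(simplices = simp[keep, , drop = FALSE],
                 max_edge = max_edge[keep], cutoff = cutoff,
                 n_points = nrow(coords)), class = "tessellation")
}

simplex_max_edge <- function(coords, simp) {
  if (nrow(simp) == 0L) return(numeric(0))
  pairs <- combn(4L, 2L)
  m <- matrix(0, nrow(simp), ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- coords[simp[, pairs[1, k]], , drop = FALSE]
    b <- coords[simp[, pairs[2, k]], , drop = FALSE]
    m[, k] <- sqrt(rowSums((a - b)^2))
  }
  apply(m, 1, max)
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d simplices over %d points (edge cutoff %.1f A)\n",
              nrow(x$simplices), x$n_points, x$cutoff))
  invisible(x)
}

# row-sort a k x 4 integer matrix with a 5-comparator sorting network
sort4_rows <- function(m) {
  a <- m[, 1]; b <- m[, 2]; c <- m[, 3]; d <- m[, 4]
  t1 <- pmin(a, b); b <- pmax(a, b); a <- t1
  t1 <- pmin(c, d); d <- pmax(c, d); c <- t1
  t1 <- pmin(a, c); c <- pmax(a, c); a <- t1
  t1 <- pmin(b, d); d <- pmax(b, d); b <- t1
  t1 <- pmin(b, c); c <- pmax(b, c); b <- t1
  cbind(a, b, c, d, deparse.level = 0)
}

# integer key of a row-sorted quadruplet of amino-acid indices (1..20)
comp_key <- function(sorted) {
  (sorted[, 1] - 1L) * 8000L + (sorted[, 2] - 1L) * 400L +
    (sorted[, 3] - 1L) * 20L + sorted[, 4]
}

# all C(20+4-1, 4) = 8855 unordered quadruplet compositions
all_compositions <- function() {
  cmb <- combn(23L, 4L)  # strictly increasing 4-subsets of 1..23
  comps <- cmb - 0:3     # -> nondecreasing quadruplets over 1..20
  t(comps)
}

composition_label <- function(comp_rows) {
  apply(comp_rows, 1, function(r) paste(AA20[r], collapse = ""))
}

simplex_keys <- function(tess, aa_idx) {
  quad <- matrix(aa_idx[tess$simplices], ncol = 4)
  comp_key(sort4_rows(quad))
}

#' Train the four-body potential
#'
#' Counts quadruplet compositions over the retained Delaunay simplices of a
#' training corpus and scores each of the 8,855 compositions as
#' `ln(f_q / p_q)`, where `f_q` is the pseudocount-adjusted observed
#' frequency and `p_q` the multinomial expectation
#' `(4! / prod(m_a!)) * prod(freq_a ^ m_a)` from the corpus amino-acid
#' frequencies (`m_a` = multiplicity of amino acid `a` in the quadruplet).
#' Add-one pseudocounts keep every score finite, including for compositions
#' never observed.
#'
#' @param structures List of `protein_structure` objects (non-empty).
#' @param cutoff Edge-length cutoff in Angstroms (default 8.5).
#' @param pseudocount Added to every composition count before frequency
#'   normalization (default 1).
#' @return Object of class `four_body_potential`.
#' @export
train_potential <- function(structures, cutoff = 8.5, pseudocount = 1) {
  if (length(structures) == 0L) stopf("empty training corpus")
  comps <- all_compositions()
  keys <- comp_key(comps)
  key_index <- integer(160000L)
  key_index[keys] <- seq_len(nrow(comps))

  counts <- numeric(nrow(comps))
  aa_counts <- setNames(numeric(20), AA20)
  n_simplices <- 0L
  for (s in structures) {
    aa_idx <- match(s$aa, AA20)
    if (anyNA(aa_idx)) stopf("structure %s has nonstandard residues", s$id)
    tess <- tessellate(s, cutoff = cutoff)
    if (nrow(tess$simplices) == 0L) next
    k <- simplex_keys(tess, aa_idx)
    tab <- tabulate(key_index[k], nbins = nrow(comps))
    counts <- counts + tab
    n_simplices <- n_simplices + length(k)
    aa_counts <- aa_counts + tabulate(aa_idx, nbins = 20L)
  }
  if (n_simplices == 0L) stopf("training corpus produced no simplices")

  freq <- (aa_counts + 1) / (sum(aa_counts) + 20)
  mult_factor <- apply(comps, 1, function(r) {
    m <- table(r)
    factorial(4) / prod(factorial(m))
  })
  p_q <- mult_factor * exp(rowSums(matrix(log(freq[comps]), ncol = 4)))
  f_q <- (counts + pseudocount) / (n_simplices + pseudocount * nrow(comps))
  scores <- log(f_q / p_q)

  lookup <- numeric(160000L)
  lookup[keys] <- scores
  structure(list(
    scores = setNames(scores, composition_label(comps)),
    counts = setNames(counts, composition_label(comps)),
    lookup = lookup, aa_freq = freq,
    cutoff = cutoff, pseudocount = pseudocount,
    n_structures = length(structures), n_simplices = n_simplices),
    class = "four_body_potential")
}

#' @export
print.four_body_potential <- function(x, ...) {
  cat(sprintf(paste0("<four_body_potential> %d compositions trained on %d ",
                     "structures (%d simplices, cutoff %.1f A, pseudocount %g)\n"),
              length(x$scores), x$n_structures, x$n_simplices,
              x$cutoff, x$pseudocount))
  invisible(x)
}

#' @export
summary.four_body_potential <- function(object, ...) {
  s <- object$scores
  out <- list(n_structures = object$n_structures,
              n_simplices = object$n_simplices,
              n_observed = sum(object$counts > 0),
              score_range = range(s),
              top = head(sort(s, decreasing = TRUE), 5),
              bottom = head(sort(s), 5))
  class(out) <- "summary.four_body_potential"
  out
}

#' @export
print.summary.four_body_potential <- function(x, ...) {
  cat(sprintf("Four-body potential: %d simplices from %d structures\n",
              x$n_simplices, x$n_structures))
  cat(sprintf("Compositions observed: %d of 8855; score range [%.3f, %.3f]\n",
              x$n_observed, x$score_range[1], x$score_range[2]))
  cat("Most favored quadruplets:\n")
  print(round(x$top, 3))
  cat("Least favored quadruplets:\n")
  print(round(x$bottom, 3))
  invisible(x)
}

#' Stability score of a (conformation, sequence) pair
#'
#' `DeltaG = -sum` over retained simplices of the composition score under
#' the supplied sequence, on the fixed conformation. Lower values imply
#' greater stability. The sequence may differ from the native one (mutant
#' scoring on the native conformation).
#'
#' @param struct A `protein_structure` (the conformation).
#' @param model A `four_body_potential`.
#' @param sequence Amino-acid sequence (character vector or string);
#'   defaults to the structure's native sequence. Must match the structure
#'   length.
#' @param tess Optional precomputed [tessellate()] result for `struct` at
#'   the model's cutoff.
#' @return The scalar stability score.
#' @export
score_structure <- function(struct, model, sequence = NULL, tess = NULL) {
  stopifnot(inherits(model, "four_body_potential"))
  seq_vec <- sequence %||% struct$aa
  if (is.character(seq_vec) && length(seq_vec) == 1L && nchar(seq_vec) > 1L)
    seq_vec <- strsplit(seq_vec, "")[[1]]
  if (length(seq_vec) != length(struct$aa))
    stopf("sequence length %d does not match structure length %d",
          length(seq_vec), length(struct$aa))
  aa_idx <- match(seq_vec, AA20)
  if (anyNA(aa_idx)) stopf("nonstandard residue in sequence")
  tess <- tess %||% tessellate(struct, cutoff = model$cutoff)
  if (nrow(tess$simplices) == 0L) return(0)
  -sum(model$lookup[simplex_keys(tess, aa_idx)])
}

#' @export
predict.four_body_potential <- function(object, struct, sequence = NULL, ...) {
  score_structure(struct, object, sequence = sequence)
}

# Precomputed scoring context: tessellation done once, mutants scored by
# swapping sequence indices only.
make_score_context <- function(struct, model) {
  tess <- tessellate(struct, cutoff = model$cutoff)
  list(struct = struct, model = model, tess = tess,
       simplices = tess$simplices)
}

context_score <- function(ctx, aa_idx) {
  if (nrow(ctx$simplices) == 0L) return(0)
  quad <- matrix(aa_idx[ctx$simplices], ncol = 4)
  -sum(ctx$model$lookup[comp_key(sort4_rows(quad))])
}
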