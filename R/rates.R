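# Concatenated codon alignments and dN/dS estimation.
#
# Rates are estimated with the Nei-Gojobori (1986) counting method:
# per-codon synonymous/nonsynonymous site fractions averaged over the two
# sequences, pathway-averaged difference counts for multi-nucleotide codon
# differences, and the Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p)
# applied to the proportions pN and pS.  This deterministic counting
# estimator stands in for maximum-likelihood codon models; for the closely
# related pairs analysed here (dS <= 2) the two agree well in ordering,
# though absolute values can differ.

#' Construct a codon alignment
#'
#' @param codons_a,codons_b Equal-length character vectors of codons
#'   (`"---"` for a gap column).
#' @param meta Optional per-column provenance data frame.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons_a, codons_b, meta = NULL) {
  if (length(codons_a) != length(codons_b))
    stopf("codon rows differ in length (%d vs %d)", length(codons_a), length(codons_b))
  structure(list(codons_a = codons_a, codons_b = codons_b, meta = meta),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d codon columns (%d gap)\n",
              length(x$codons_a),
              sum(x$codons_a == "---" | x$codons_b == "---")))
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue column becomes its source codon triplet; protein
#' gaps become `---` codon gaps. The ungapped protein rows must translate
#' exactly from the supplied coding sequences.
#'
#' @param protein_alignment Character vector of two aligned protein rows
#'   (equal length, `-` for gaps).
#' @param cds_a,cds_b In-frame coding sequences of the two ungapped rows.
#' @return A `codon_alignment`.
#' @export
backtranslate_alignment <- function(protein_alignment, cds_a, cds_b) {
  stopifnot(length(protein_alignment) == 2L)
  rows <- strsplit(protein_alignment, "")
  if (length(rows[[1]]) != length(rows[[2]]))
    stopf("aligned protein rows differ in length")
  expand_row <- function(row, cds, label) {
    ungapped <- row[row != "-"]
    trans <- strsplit(translate_cds(cds), "")[[1]]
    if (length(trans) != length(ungapped))
      stopf("%s: CDS translates to %d residues but protein row has %d",
            label, length(trans), length(ungapped))
    mism <- which(trans != ungapped)
    if (length(mism) > 0L)
      stopf("%s: translation mismatch at protein position %d ('%s' vs '%s')",
            label, mism[1], trans[mism[1]], ungapped[mism[1]])
    codons <- split_codons(cds)
    out <- rep("---", length(row))
    out[row != "-"] <- codons
    out
  }
  codon_alignment(expand_row(rows[[1]], cds_a, "sequence A"),
                  expand_row(rows[[2]], cds_b, "sequence B"))
}

drop_gap_columns <- function(aln) {
  keep <- aln$codons_a != "---" & aln$codons_b != "---"
  codon_alignment(aln$codons_a[keep], aln$codons_b[keep],
                  if (!is.null(aln$meta)) aln$meta[keep, , drop = FALSE])
}

#' Estimate dN, dS and dN/dS by Nei-Gojobori counting
#'
#' Gap columns are removed first. Internal stop codons are an error. When a
#' proportion of differences reaches 3/4 the Jukes-Cantor correction is
#' undefined and the corresponding rate is flagged `"saturated"`; when there
#' are no synonymous sites or dS is zero, omega is flagged undefined.
#'
#' @param aln A `codon_alignment`.
#' @return Object of class `rate_estimate` with `dn`, `ds`, `omega`, the
#'   underlying real-valued site and difference counts, codon count and
#'   per-quantity status flags.
#' @export
estimate_dn_ds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  aln <- drop_gap_columns(aln)
  n_codons <- length(aln$codons_a)
  if (n_codons < 1L) stopf("alignment has no ungapped codon columns")
  ct <- codon_data()
  bad <- !(aln$codons_a %in% ct$codons) | !(aln$codons_b %in% ct$codons)
  if (any(bad)) stopf("invalid codon at column %d", which(bad)[1])
  stopped <- ct$aa[aln$codons_a] == "*" | ct$aa[aln$codons_b] == "*"
  if (any(stopped)) stopf("internal stop codon at column %d", which(stopped)[1])

  s_sites <- (sum(ct$syn_sites[aln$codons_a]) + sum(ct$syn_sites[aln$codons_b])) / 2
  n_sites <- (sum(ct$nonsyn_sites[aln$codons_a]) + sum(ct$nonsyn_sites[aln$codons_b])) / 2
  idx <- cbind(match(aln$codons_a, ct$codons), match(aln$codons_b, ct$codons))
  n_diffs <- sum(ct$nd[idx])
  s_diffs <- sum(ct$sd[idx])

  jc <- function(p) {
    if (p >= 0.75) return(list(d = NA_real_, status = "saturated"))
    list(d = -0.75 * log(1 - 4 * p / 3), status = "ok")
  }
  p_n <- if (n_sites > 0) n_diffs / n_sites else 0
  p_s <- if (s_sites > 0) s_diffs / s_sites else 0
  dn <- jc(p_n)
  ds <- jc(p_s)
  omega <- NA_real_
  omega_status <- "undefined"
  if (dn$status == "ok" && ds$status == "ok" && s_sites > 0 && ds$d > 0) {
    omega <- dn$d / ds$d
    omega_status <- "ok"
  }
  structure(list(dn = dn$d, ds = ds$d, omega = omega,
                 n_sites = n_sites, s_sites = s_sites,
                 n_diffs = n_diffs, s_diffs = s_diffs,
                 n_codons = n_codons,
                 dn_status = dn$status, ds_status = ds$status,
                 omega_status = omega_status),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<rate_estimate> %d codons: dN = %s, dS = %s, dN/dS = %s\n",
              x$n_codons,
              if (x$dn_status == "ok") format(x$dn, digits = digits) else x$dn_status,
              if (x$ds_status == "ok") format(x$ds, digits = digits) else x$ds_status,
              if (x$omega_status == "ok") format(x$omega, digits = digits) else x$omega_status))
  invisible(x)
}

# fraction of identical residues over aligned non-gap codon columns
pair_identity <- function(pair) {
  ct <- codon_data()
  keep <- pair$codons_a != "---" & pair$codons_b != "---"
  if (!any(keep)) return(0)
  mean(ct$aa[pair$codons_a[keep]] == ct$aa[pair$codons_b[keep]])
}

#' Concatenate codon columns by structural category
#'
#' Builds one concatenated codon alignment per group (secondary-structure
#' category, exposure class, or RSA bin, optionally crossed with age
#' class). Columns are taken only where the structure's residue and the
#' protein residue agree (enforced upstream by [residue_features()]); source
#' pairs whose aligned protein identity is below 50% contribute nothing.
#'
#' @param pairs List of entries, each a list with elements `pair` (an
#'   `ortholog_pair` or gap-free `codon_alignment`), `features` (the
#'   matching feature table; `position` indexes codon columns) and
#'   optionally `age_class`.
#' @param grouping One of `"ss_category"`, `"exposure"`, `"rsa_bin"`.
#' @param by_age Cross the grouping with the age class of each pair.
#' @param min_identity Identity filter on the source pair (default 0.5).
#' @return Named list of `codon_alignment` objects; groups with zero
#'   columns are omitted with a warning.
#' @export
concatenate_by_category <- function(pairs, grouping = c("ss_category", "exposure", "rsa_bin"),
                                    by_age = FALSE, min_identity = 0.5) {
  grouping <- match.arg(grouping)
  acc <- list()
  for (entry in pairs) {
    p <- entry$pair
    codons_a <- if (inherits(p, "ortholog_pair")) p$codons_a else p$codons_a
    codons_b <- if (inherits(p, "ortholog_pair")) p$codons_b else p$codons_b
    if (pair_identity(list(codons_a = codons_a, codons_b = codons_b)) < min_identity)
      next
    feats <- entry$features
    pos <- feats$position
    groups <- as.character(feats[[grouping]])
    if (by_age) {
      age <- entry$age_class %||% "unknown"
      groups <- paste(groups, age, sep = ".")
    }
    for (g in unique(groups)) {
      sel <- pos[groups == g]
      if (is.null(acc[[g]])) acc[[g]] <- list(a = list(), b = list())
      acc[[g]]$a[[length(acc[[g]]$a) + 1L]] <- codons_a[sel]
      acc[[g]]$b[[length(acc[[g]]$b) + 1L]] <- codons_b[sel]
    }
  }
  acc <- lapply(acc, function(x) list(a = unlist(x$a), b = unlist(x$b)))
  empty <- vapply(acc, function(x) length(x$a) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("omitting empty group(s): %s",
                    paste(names(acc)[empty], collapse = ", ")), call. = FALSE)
    acc <- acc[!empty]
  }
  lapply(acc, function(x) codon_alignment(x$a, x$b))
}

#' Robustness filters on a rate estimate
#'
#' Discards estimates from concatenations shorter than 60 amino acids, or
#' with dN above 0.5 (suggesting non-homology) or dS above 2 (saturation).
#'
#' @param estimate A `rate_estimate`.
#' @param aa_length Number of amino acids (codon columns) behind the
#'   estimate; defaults to the estimate's codon count.
#' @return List with `retained` (logical) and `reason`.
#' @export
apply_rate_filters <- function(estimate, aa_length = estimate$n_codons) {
  if (aa_length < 60)
    return(list(retained = FALSE, reason = "shorter than 60 aa"))
  if (!is.na(estimate$dn) && estimate$dn > 0.5)
    return(list(retained = FALSE, reason = "dN > 0.5"))
  if (!is.na(estimate$ds) && estimate$ds > 2)
    return(list(retained = FALSE, reason = "dS > 2"))
  if (estimate$dn_status == "saturated" || estimate$ds_status == "saturated")
    return(list(retained = FALSE, reason = "saturated"))
  list(retained = TRUE, reason = NA_character_)
}
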