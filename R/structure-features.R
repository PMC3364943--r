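# Structure parsing, quality filters, relative solvent accessibility and
# residue classification.
#
# Filters mirror the study design: chains shorter than 50 residues,
# discontinuous (gapped) chains and chains with an incomplete backbone are
# rejected before any downstream analysis.  RSA is the DSSP accessibility
# normalized by the residue's reference Gly-X-Gly area and clamped to 1;
# residues are buried below 25% accessibility, exposed otherwise, and
# apportioned into 20 equal-width RSA bins.

#' Parse a protein chain from a PDB-format file
#'
#' Multi-model (NMR) files yield the first structural model only. Residues
#' with nonstandard residue codes are skipped with a warning.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default: first chain in the file.
#' @param id Structure id; default: file base name.
#' @return A `protein_structure`.
#' @export
parse_structure <- function(path, chain = NULL, id = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stopf("cannot parse PDB file %s: %s", path, conditionMessage(e)))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stopf("no ATOM records in %s", path)
  chain <- chain %||% atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stopf("no ATOM records for chain %s in %s", chain, path)
  n_models <- if (!is.null(pdb$xyz) && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  # bio3d's atom table carries the first model's coordinates

  resnos <- sort(unique(atoms$resno))
  keep_aa <- character(0)
  keep_resno <- integer(0)
  ca <- nmat <- cmat <- omat <- NULL
  rows_ca <- rows_n <- rows_c <- rows_o <- list()
  for (r in resnos) {
    sub <- atoms[atoms$resno == r, , drop = FALSE]
    res3 <- sub$resid[1]
    if (!res3 %in% names(AA1)) {
      warning(sprintf("skipping residue %d with unknown code '%s'", r, res3),
              call. = FALSE)
      next
    }
    get_atom <- function(name) {
      i <- which(sub$elety == name)[1]
      if (is.na(i)) c(NA_real_, NA_real_, NA_real_) else
        c(sub$x[i], sub$y[i], sub$z[i])
    }
    keep_resno <- c(keep_resno, r)
    keep_aa <- c(keep_aa, AA1[[res3]])
    rows_ca[[length(rows_ca) + 1L]] <- get_atom("CA")
    rows_n[[length(rows_n) + 1L]] <- get_atom("N")
    rows_c[[length(rows_c) + 1L]] <- get_atom("C")
    rows_o[[length(rows_o) + 1L]] <- get_atom("O")
  }
  if (length(keep_resno) == 0L) stopf("no standard residues in %s", path)
  structure(list(
    id = id %||% sub("\\.pdb$", "", basename(path)),
    resno = keep_resno, aa = keep_aa,
    ca = do.call(rbind, rows_ca),
    backbone = list(N = do.call(rbind, rows_n), C = do.call(rbind, rows_c),
                    O = do.call(rbind, rows_o)),
    experiment = if (n_models > 1L) "nmr" else "xray",
    model_index = 1L), class = "protein_structure")
}

#' Structure-level quality filter
#'
#' Rejects a chain if it is shorter than 50 residues, if its residue
#' numbering is discontinuous (gapped chain), or if any residue lacks a
#' backbone atom (N, CA, C or O). The reason names the first failed rule.
#'
#' @param struct A `protein_structure`.
#' @return List with `accept` (logical) and `reason` (`NA` when accepted).
#' @export
validate_structure <- function(struct) {
  n <- length(struct$aa)
  if (n < 50L)
    return(list(accept = FALSE, reason = "length"))
  if (n > 1L && any(diff(struct$resno) != 1L))
    return(list(accept = FALSE, reason = "gapped chain"))
  bb <- cbind(struct$ca, struct$backbone$N, struct$backbone$C, struct$backbone$O)
  if (anyNA(bb))
    return(list(accept = FALSE, reason = "incomplete backbone"))
  list(accept = TRUE, reason = NA_character_)
}

#' Relative solvent accessibility
#'
#' `rsa = asa / reference_asa(amino_acid)`, clamped to 1 where the DSSP
#' accessibility exceeds the Gly-X-Gly reference area.
#'
#' @param amino_acid One-letter code(s).
#' @param asa Absolute accessibility in square Angstroms (>= 0).
#' @return RSA fraction(s) in `[0, 1]`.
#' @export
compute_rsa <- function(amino_acid, asa) {
  ref <- miller_asa_table()
  bad <- !amino_acid %in% names(ref)
  if (any(bad))
    stopf("nonstandard amino acid(s): %s", paste(unique(amino_acid[bad]), collapse = ", "))
  if (any(asa < 0)) stopf("asa must be nonnegative")
  pmin(1, asa / unname(ref[amino_acid]))
}

SS_MAP <- c(H = "helix", E = "sheet", S = "turn", T = "turn",
            B = "coil", G = "coil", I = "coil", "." = "coil")

#' Classify a residue by accessibility and secondary structure
#'
#' Exposure follows the 25% rule (buried strictly below 0.25; exactly 0.25
#' is exposed). The RSA bin is the index of the 20 equal-width bins on
#' `[0, 1]` (`[lo, hi)`, bin 20 closed at 1). DSSP letters map to helix (H),
#' sheet (E), turn (S, T) and coil (B, G, I, `.`).
#'
#' @param rsa RSA fraction(s) in `[0, 1]`.
#' @param dssp_class DSSP class letter(s).
#' @return Data frame with `exposure`, `rsa_bin`, `ss_category`.
#' @export
classify_residue <- function(rsa, dssp_class) {
  if (any(rsa < 0 | rsa > 1)) stopf("rsa must lie in [0, 1]")
  bad <- !dssp_class %in% names(SS_MAP)
  if (any(bad))
    stopf("unknown DSSP class letter(s): %s", paste(unique(dssp_class[bad]), collapse = ", "))
  data.frame(
    exposure = ifelse(rsa < 0.25, "buried", "exposed"),
    # small tolerance keeps exact bin boundaries in the upper bin despite
    # binary floating point (e.g. 0.15 / 0.05 = 2.9999...)
    rsa_bin = pmin(20L, as.integer(floor(rsa / 0.05 + 1e-9)) + 1L),
    ss_category = unname(SS_MAP[dssp_class]),
    stringsAsFactors = FALSE)
}

#' Per-residue feature table for one structure
#'
#' Joins the coordinate chain with its DSSP-style record by residue number,
#' drops positions where the two disagree on the amino acid, and computes
#' ASA/RSA/exposure/bin/secondary-structure features.
#'
#' @param struct A `protein_structure`.
#' @param dssp DSSP-style table (from [read_dssp_table()] or the
#'   structure's planted annotation).
#' @return Feature data frame: `structure_id`, `position` (1-based index in
#'   the chain), `amino_acid`, `asa`, `rsa`, `exposure`, `rsa_bin`,
#'   `ss_category`.
#' @export
residue_features <- function(struct, dssp = NULL) {
  dssp <- dssp %||% struct$annotation
  m <- match(struct$resno, dssp$resno)
  keep <- which(!is.na(m) & struct$aa == dssp$aa[m])
  if (length(keep) == 0L) stopf("no residues shared between structure and DSSP record")
  aa <- struct$aa[keep]
  asa <- dssp$acc[m[keep]]
  rsa <- compute_rsa(aa, asa)
  cls <- classify_residue(rsa, dssp$ss[m[keep]])
  data.frame(structure_id = struct$id, position = keep, amino_acid = aa,
             asa = asa, rsa = rsa, cls, stringsAsFactors = FALSE)
}

#' Percentage of exposed residues
#'
#' `100 * exposed / (exposed + buried)`.
#'
#' @param features Feature table with an `exposure` column.
#' @return Percentage in `[0, 100]`.
#' @export
fraction_exposed <- function(features) {
  if (NROW(features) == 0L) stopf("empty feature table")
  100 * mean(features$exposure == "exposed")
}
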