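# File emission and ingestion for the standard formats the pipeline touches.
# PDB parsing goes through bio3d; FASTA through Biostrings.  The DSSP-style
# per-residue table is a documented tab-separated dialect (resno, chain, aa,
# ss, acc) carrying exactly the fields the feature extractor consumes.

#' Write a structure (or NMR model series) as a PDB-format file
#'
#' Emits standard fixed-width ATOM records for the backbone atoms
#' (N, CA, C, O) of a single chain. When `models` is a list of structures
#' the file is written as a multi-model (NMR-style) entry with
#' MODEL/ENDMDL records.
#'
#' @param struct A `protein_structure`, or the first model when `models`
#'   is given.
#' @param path Output file path.
#' @param models Optional list of `protein_structure` objects to emit as
#'   successive MODEL records (overrides `struct`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path, models = NULL) {
  models <- models %||% list(struct)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    s <- models[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    lines <- character(0)
    for (i in seq_along(s$aa)) {
      res3 <- AA3[[s$aa[i]]]
      atoms <- list(N = s$backbone$N[i, ], CA = s$ca[i, ],
                    C = s$backbone$C[i, ], O = s$backbone$O[i, ])
      for (an in names(atoms)) {
        serial <- serial + 1L
        xyz <- atoms[[an]]
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, an, res3, "A", s$resno[i], xyz[1], xyz[2], xyz[3],
          1.0, 0.0, substr(an, 1, 1)))
      }
    }
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read a DSSP-style per-residue table
#'
#' Tab-separated columns: `resno`, `chain`, `aa` (one-letter), `ss` (DSSP
#' class letter, `.` for unassigned), `acc` (absolute accessibility in
#' square Angstroms). Comment lines start with `#`.
#'
#' @param struct A `protein_structure` carrying a planted `annotation`
#'   table, or a data frame with columns `resno`, `aa`, `ss`, `acc`.
#' @param path File path.
#' @return `path` invisibly for the writer; the table for the reader.
#' @export
write_dssp_table <- function(struct, path) {
  tab <- if (inherits(struct, "protein_structure")) struct$annotation else struct
  out <- data.frame(resno = tab$resno, chain = "A", aa = tab$aa,
                    ss = tab$ss, acc = tab$acc, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# DSSP-style residue table: resno chain aa ss acc", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dssp_table
#' @export
read_dssp_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(ss = "character", aa = "character"))
  if (!all(c("resno", "aa", "ss", "acc") %in% names(tab)))
    stopf("not a DSSP-style residue table: %s", path)
  tab
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_openings",
                 "query_start", "query_end", "subject_start", "subject_end",
                 "e_value", "bit_score")

#' Write / read BLAST tabular (outfmt-6 style) hit files
#'
#' The twelve standard columns, tab-separated, no header. Subject species
#' are not part of the format; `read_blast_tab` re-attaches them from a
#' `subject_id -> species` map (configuration in real use, emitted by
#' [generate_homolog_profile()] for synthetic data).
#'
#' @param hits Hit data frame (extra columns are dropped on write).
#' @param path File path.
#' @param species_map Named character vector, `subject_id -> species`.
#' @return `path` invisibly for the writer; a hit data frame for the reader.
#' @export
write_blast_tab <- function(hits, path) {
  write.table(hits[, BLAST6_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_blast_tab
#' @export
read_blast_tab <- function(path, species_map = NULL) {
  hits <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != length(BLAST6_COLS))
    stopf("expected %d outfmt-6 columns, found %d", length(BLAST6_COLS), ncol(hits))
  names(hits) <- BLAST6_COLS
  if (!is.null(species_map))
    hits$subject_species <- unname(species_map[hits$subject_id])
  hits
}

#' Write a per-residue feature table as TSV
#'
#' @param features Feature table from [residue_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-residue features: structure_id position aa asa rsa exposure rsa_bin ss_category", con)
  write.table(features, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
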