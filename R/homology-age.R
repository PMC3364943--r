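# Structure-mapping hit filter and phylostratigraphic age assignment.

#' Filter structure-mapping hits
#'
#' Keeps hits with at least 99% identity; among mutually overlapping
#' retained hits (sharing at least one query position, 1-based inclusive)
#' exactly one is kept: highest percent identity, ties broken by longer
#' alignment, then lower e-value. The output is pairwise non-overlapping on
#' the query.
#'
#' @param hits Hit data frame with `percent_identity`, `query_start`,
#'   `query_end`, `alignment_length`, `e_value`.
#' @return The retained hits (possibly empty).
#' @export
filter_structure_hits <- function(hits) {
  hits <- hits[hits$percent_identity >= 99, , drop = FALSE]
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$percent_identity,
               -(hits$query_end - hits$query_start + 1L),
               hits$e_value)
  hits <- hits[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    overlaps <- any(hits$query_start[i] <= hits$query_end[kept] &
                      hits$query_end[i] >= hits$query_start[kept])
    if (!overlaps) kept <- c(kept, i)
  }
  hits[kept, , drop = FALSE]
}

#' Assign an evolutionary age class by phylogenetic width
#'
#' Hits with e-value above 1e-4 are ignored; the age is the oldest species
#' group containing at least one surviving hit
#' (mammalia < vertebrata < metazoa < eukarya, youngest to oldest).
#' Mammalia assignments are flagged as excluded from downstream analysis
#' (too few structures fall in that class to analyse).
#'
#' @param hits Hit data frame with `subject_species` and `e_value` columns.
#' @param species_groups Mapping age class -> species vector; defaults to
#'   [species_groups_default()]. Must cover every subject species present.
#' @param evalue_cutoff Detection cutoff (default 1e-4).
#' @return Object of class `age_assignment`: list with `age_class` (`NA`
#'   when unassignable), `status` (`"ok"`, `"excluded_from_analysis"` or
#'   `"unassignable"`) and `n_hits` per group.
#' @export
assign_age <- function(hits, species_groups = species_groups_default(),
                       evalue_cutoff = 1e-4) {
  stopifnot(all(AGE_ORDER %in% names(species_groups)))
  surviving <- hits[hits$e_value <= evalue_cutoff, , drop = FALSE]
  unknown <- setdiff(surviving$subject_species, unlist(species_groups))
  if (length(unknown) > 0L)
    stopf("species not covered by species_groups: %s", paste(unknown, collapse = ", "))
  n_hits <- vapply(AGE_ORDER, function(g)
    sum(surviving$subject_species %in% species_groups[[g]]), integer(1))
  present <- which(n_hits > 0L)
  if (length(present) == 0L)
    return(structure(list(age_class = NA_character_, status = "unassignable",
                          n_hits = n_hits), class = "age_assignment"))
  age <- AGE_ORDER[max(present)]
  status <- if (age == "mammalia") "excluded_from_analysis" else "ok"
  structure(list(age_class = age, status = status, n_hits = n_hits),
            class = "age_assignment")
}

#' @export
print.age_assignment <- function(x, ...) {
  cat(sprintf("<age_assignment> %s (%s); hits per group: %s\n",
              x$age_class %||% "NA", x$status,
              paste(sprintf("%s=%d", names(x$n_hits), x$n_hits), collapse = " ")))
  invisible(x)
}
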