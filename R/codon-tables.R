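# Genetic-code lookup tables used by the ortholog-pair generator and the
# Nei-Gojobori counting estimator.  Built once per session from the standard
# code shipped with Biostrings and cached.
#
# Conventions (documented in the methods vignette):
#  * Synonymous site fraction of a codon = (# synonymous single-nucleotide
#    changes)/3; changes producing a stop codon count as nonsynonymous, so
#    nonsyn + syn sites = 3 for every sense codon.
#  * For codons differing at k positions, the syn/nonsyn difference counts
#    are averaged over the k! orderings of the changes, excluding orderings
#    that pass through a stop codon; if every ordering is blocked the
#    average falls back to all orderings (steps into/out of a stop count as
#    nonsynonymous).

codon_env <- new.env(parent = emptyenv())

codon_data <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  n <- length(codons)
  nts <- c("A", "C", "G", "T")
  codon_chars <- do.call(rbind, strsplit(codons, ""))

  syn_sites <- rep(NA_real_, n)
  syn_nbr <- vector("list", n)
  nonsyn_nbr <- vector("list", n)
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    n_syn <- 0L
    sn <- character(0)
    nn <- character(0)
    for (pos in 1:3) {
      for (nt in setdiff(nts, codon_chars[i, pos])) {
        ch <- codon_chars[i, ]
        ch[pos] <- nt
        c2 <- paste(ch, collapse = "")
        aa2 <- unname(gc_map[c2])
        if (aa2 == aa[i]) {
          n_syn <- n_syn + 1L
          sn <- c(sn, c2)
        } else if (aa2 != "*") {
          nn <- c(nn, c2)
        }
        # stop-producing change: counts toward nonsynonymous sites but is
        # never offered as a mutation target
      }
    }
    syn_sites[i] <- n_syn / 3
    syn_nbr[[i]] <- sn
    nonsyn_nbr[[i]] <- nn
  }

  # pathway-averaged difference counts for every ordered codon pair
  nd_tab <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  sd_tab <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  perms3 <- list(1L, list(1:2, 2:1),
                 list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    for (j in seq_len(n)) {
      if (aa[j] == "*") next
      diffs <- which(codon_chars[i, ] != codon_chars[j, ])
      k <- length(diffs)
      if (k == 0L) {
        nd_tab[i, j] <- 0
        sd_tab[i, j] <- 0
        next
      }
      orderings <- if (k == 1L) list(diffs) else
        lapply(if (k == 2L) perms3[[2]] else perms3[[3]], function(p) diffs[p])
      path_nd <- numeric(0)
      path_sd <- numeric(0)
      blocked_nd <- numeric(0)
      blocked_sd <- numeric(0)
      for (ord in orderings) {
        cur <- codon_chars[i, ]
        cur_aa <- aa[i]
        nd <- 0
        sdc <- 0
        blocked <- FALSE
        for (pos in ord) {
          cur[pos] <- codon_chars[j, pos]
          nxt <- paste(cur, collapse = "")
          nxt_aa <- unname(gc_map[nxt])
          if (nxt_aa == "*") blocked <- TRUE
          if (nxt_aa == cur_aa && nxt_aa != "*" && cur_aa != "*") {
            sdc <- sdc + 1
          } else {
            nd <- nd + 1
          }
          cur_aa <- nxt_aa
        }
        if (blocked) {
          blocked_nd <- c(blocked_nd, nd)
          blocked_sd <- c(blocked_sd, sdc)
        } else {
          path_nd <- c(path_nd, nd)
          path_sd <- c(path_sd, sdc)
        }
      }
      if (length(path_nd) == 0L) {
        path_nd <- blocked_nd
        path_sd <- blocked_sd
      }
      nd_tab[i, j] <- mean(path_nd)
      sd_tab[i, j] <- mean(path_sd)
    }
  }

  syn_codons_by_aa <- split(codons[aa != "*"], aa[aa != "*"])

  codon_env$tab <- list(
    codons = codons, aa = setNames(aa, codons),
    syn_sites = setNames(syn_sites, codons),
    nonsyn_sites = setNames(ifelse(is.na(syn_sites), NA, 3 - syn_sites), codons),
    syn_neighbors = setNames(syn_nbr, codons),
    nonsyn_neighbors = setNames(nonsyn_nbr, codons),
    nd = nd_tab, sd = sd_tab,
    syn_codons_by_aa = syn_codons_by_aa)
  codon_env$tab
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds A nucleotide string whose length is a multiple of 3.
#' @return Single-letter amino-acid string (stops rendered as `*`).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stopf("CDS length %d is not a multiple of 3", nchar(cds))
  ct <- codon_data()
  cod <- split_codons(cds)
  paste(unname(ct$aa[cod]), collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3
  substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
}
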