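# Independent brute-force oracles used to verify the implementation.
# These deliberately share no code with the package internals.

# All 4-point subsets whose circumsphere contains no other point strictly
# inside (the definition of a Delaunay simplex).
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  out <- NULL
  for (s in combn(n, 4, simplify = FALSE)) {
    cs <- oracle_circumsphere(pts[s, , drop = FALSE])
    if (is.null(cs)) next
    d2 <- rowSums((pts - matrix(cs$cc, n, 3, byrow = TRUE))^2)
    if (all(d2[-s] > cs$r2 * (1 - 1e-9))) out <- rbind(out, sort(s))
  }
  out
}

oracle_circumsphere <- function(P) {
  A <- 2 * (P[2:4, ] - matrix(P[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(P[2:4, ]^2) - sum(P[1, ]^2)
  cc <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(cc)) return(NULL)
  list(cc = cc, r2 = sum((cc - P[1, ])^2))
}

# does every simplex of a tessellation have an empty circumsphere?
oracle_empty_circumsphere <- function(pts, simplices) {
  n <- nrow(pts)
  for (row in seq_len(nrow(simplices))) {
    s <- simplices[row, ]
    cs <- oracle_circumsphere(pts[s, , drop = FALSE])
    if (is.null(cs)) return(FALSE)
    d2 <- rowSums((pts - matrix(cs$cc, n, 3, byrow = TRUE))^2)
    if (any(d2[-s] < cs$r2 * (1 - 1e-9))) return(FALSE)
  }
  TRUE
}

# ---- Nei-Gojobori (1986) + Jukes-Cantor, written from the definition ----

oracle_gc <- as.list(Biostrings::GENETIC_CODE)

oracle_codon_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  aa <- oracle_gc[[codon]]
  syn <- 0
  for (pos in 1:3) {
    for (nt in nts[nts != ch[pos]]) {
      ch2 <- ch
      ch2[pos] <- nt
      aa2 <- oracle_gc[[paste(ch2, collapse = "")]]
      if (aa2 == aa) syn <- syn + 1  # stop-producing changes are nonsynonymous
    }
  }
  c(syn = syn / 3, nonsyn = 3 - syn / 3)
}

oracle_pair_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diffs <- which(ch1 != ch2)
  k <- length(diffs)
  if (k == 0) return(c(nd = 0, sd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  ok_nd <- ok_sd <- numeric(0)
  bl_nd <- bl_sd <- numeric(0)
  for (ord in perms(diffs)) {
    cur <- ch1
    cur_aa <- oracle_gc[[c1]]
    nd <- sdd <- 0
    blocked <- FALSE
    for (pos in ord) {
      cur[pos] <- ch2[pos]
      nxt_aa <- oracle_gc[[paste(cur, collapse = "")]]
      if (nxt_aa == "*") blocked <- TRUE
      if (nxt_aa != "*" && cur_aa != "*" && nxt_aa == cur_aa) sdd <- sdd + 1
      else nd <- nd + 1
      cur_aa <- nxt_aa
    }
    if (blocked) { bl_nd <- c(bl_nd, nd); bl_sd <- c(bl_sd, sdd) }
    else { ok_nd <- c(ok_nd, nd); ok_sd <- c(ok_sd, sdd) }
  }
  if (length(ok_nd) == 0) { ok_nd <- bl_nd; ok_sd <- bl_sd }
  c(nd = mean(ok_nd), sd = mean(ok_sd))
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- N <- Nd <- Sd <- 0
  for (i in seq_along(codons_a)) {
    sa <- oracle_codon_sites(codons_a[i])
    sb <- oracle_codon_sites(codons_b[i])
    S <- S + (sa["syn"] + sb["syn"]) / 2
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
    d <- oracle_pair_diffs(codons_a[i], codons_b[i])
    Nd <- Nd + d["nd"]
    Sd <- Sd + d["sd"]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pn <- unname(if (N > 0) Nd / N else 0)
  ps <- unname(if (S > 0) Sd / S else 0)
  list(dn = jc(pn), ds = jc(ps), n_sites = unname(N), s_sites = unname(S),
       n_diffs = unname(Nd), s_diffs = unname(Sd),
       dn_saturated = pn >= 0.75, ds_saturated = ps >= 0.75)
}

# random gap-free sense-codon alignment with controlled divergence
random_alignment <- function(n_codons, p_change = 0.1) {
  ct_codons <- names(oracle_gc)[unlist(oracle_gc) != "*"]
  a <- sample(ct_codons, n_codons, replace = TRUE)
  b <- a
  change <- runif(n_codons) < p_change
  b[change] <- sample(ct_codons, sum(change), replace = TRUE)
  list(a = a, b = b)
}

# ---- exact Wilcoxon by enumeration ----

oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n <- length(a)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  all_w <- apply(combn(length(pooled), n), 2, function(idx)
    sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(all_w <= w_obs)
  p_ge <- mean(all_w >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

oracle_signedrank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  all_v <- as.matrix(signs) %*% r
  p_le <- mean(all_v <= v_obs)
  p_ge <- mean(all_v >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
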