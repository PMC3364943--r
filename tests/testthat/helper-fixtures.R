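# Shared fixtures, built once per test run.

quick_structure <- function(n = 80, age = "eukarya", seed = 1, ...) {
  generate_toy_structure(sim_config(chain_length = n, age_class = age,
                                    seed = seed, ...),
                         id = sprintf("FIX%d_%d", n, seed))
}

# a small trained potential shared across tests (built lazily, cached)
fixture_env <- new.env()

fixture_model <- function() {
  if (is.null(fixture_env$model)) {
    train <- lapply(1:24, function(k) {
      age <- c("eukarya", "metazoa", "vertebrata")[1 + (k %% 3)]
      generate_toy_structure(sim_config(chain_length = 60 + 4 * k,
                                        age_class = age, seed = 90000 + k),
                             id = paste0("TR", k))
    })
    fixture_env$model <- train_potential(train)
  }
  fixture_env$model
}

# Twelve-case defect fixture covering the structure- and rate-level filters.
# Each case carries what is being fed in and the designed verdict.
defect_fixture <- function(dir = tempfile("defects")) {
  dir.create(dir, showWarnings = FALSE)
  cases <- list()
  add <- function(name, kind, expected, payload = NULL)
    cases[[name]] <<- list(name = name, kind = kind, expected = expected,
                           payload = payload)

  # 1: 49 residues, complete -> reject (length)
  s1 <- quick_structure(49, seed = 101)
  write_pdb(s1, file.path(dir, "c01.pdb"))
  add("c01", "structure", "reject:length")

  # 2: 50 residues, complete -> accept
  s2 <- quick_structure(50, seed = 102)
  write_pdb(s2, file.path(dir, "c02.pdb"))
  add("c02", "structure", "accept")

  # 3: 60 residues with residue 30 missing -> reject (gapped chain)
  s3 <- quick_structure(61, seed = 103)
  keep <- setdiff(seq_along(s3$aa), 30)
  s3$resno <- s3$resno[keep]; s3$aa <- s3$aa[keep]
  s3$ca <- s3$ca[keep, ]
  s3$backbone <- lapply(s3$backbone, function(m) m[keep, ])
  write_pdb(s3, file.path(dir, "c03.pdb"))
  add("c03", "structure", "reject:gapped chain")

  # 4: 60 residues, O atom of residue 10 missing -> reject (backbone)
  s4 <- quick_structure(60, seed = 104)
  write_pdb(s4, file.path(dir, "c04.pdb"))
  lines <- readLines(file.path(dir, "c04.pdb"))
  drop <- grep("^ATOM", lines)
  resno <- as.integer(substr(lines[drop], 23, 26))
  aty <- trimws(substr(lines[drop], 13, 16))
  lines <- lines[-drop[resno == 10 & aty == "O"][1]]
  writeLines(lines, file.path(dir, "c04.pdb"))
  add("c04", "structure", "reject:incomplete backbone")

  # 5: structure-mapping hit at 98.9% identity -> hit removed
  add("c05", "hits", "removed", data.frame(
    query_id = "q5", subject_id = "s5", percent_identity = 98.9,
    alignment_length = 100, mismatches = 1, gap_openings = 0,
    query_start = 1, query_end = 100, subject_start = 1, subject_end = 100,
    e_value = 1e-50, bit_score = 200))

  # 6: overlapping hits at 99.2% and 100% -> the 100% hit kept
  add("c06", "hits", "keep:100", data.frame(
    query_id = "q6", subject_id = c("lo", "hi"),
    percent_identity = c(99.2, 100),
    alignment_length = c(120, 110), mismatches = 0, gap_openings = 0,
    query_start = c(1, 50), query_end = c(120, 159),
    subject_start = 1, subject_end = c(120, 110),
    e_value = 1e-60, bit_score = 220))

  # 7: 59-codon alignment -> rate estimate discarded (shorter than 60 aa)
  add("c07", "rates", "discard:shorter than 60 aa",
      list(a = rep("GCT", 59), b = rep("GCT", 59)))

  # 8: dN > 0.5 -> discarded (90 of 100 codons carry a nonsynonymous change)
  a8 <- rep("GCT", 100); b8 <- a8; b8[1:90] <- "GTT"
  add("c08", "rates", "discard:dN > 0.5", list(a = a8, b = b8))

  # 9: dS > 2 -> discarded (72 of 100 codons carry a synonymous change)
  a9 <- rep("GCT", 100); b9 <- a9; b9[1:72] <- "GCC"
  add("c09", "rates", "discard:dS > 2", list(a = a9, b = b9))

  # 10: well-behaved alignment -> retained
  a10 <- rep(c("GCT", "AAA", "GAT", "TTG"), 25)
  b10 <- a10; b10[c(1, 10)] <- c("GCC", "AAG"); b10[c(5, 20)] <- c("ACT", "TTC")
  add("c10", "rates", "retain", list(a = a10, b = b10))

  # 11: 3-model NMR file -> model 1 used
  m1 <- quick_structure(55, seed = 111)
  m2 <- m1; m2$ca <- m1$ca + 1.5
  m2$backbone <- lapply(m1$backbone, function(m) m + 1.5)
  m3 <- m1; m3$ca <- m1$ca - 1.5
  m3$backbone <- lapply(m1$backbone, function(m) m - 1.5)
  write_pdb(m1, file.path(dir, "c11.pdb"), models = list(m1, m2, m3))
  add("c11", "nmr", "model1", m1)

  # 12: HETATM-only file -> parse error
  writeLines(c(
    "HETATM    1  O   HOH A   1      10.000  10.000  10.000  1.00  0.00           O",
    "END"), file.path(dir, "c12.pdb"))
  add("c12", "parse", "error")

  list(dir = dir, cases = cases)
}
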