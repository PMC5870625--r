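# Small fixtures built in code.

# A hand-built phosphopeptide table exercising every preprocessing filter:
# canonical mapping, monophosphorylation, replicate/peptide averaging and
# the per-condition coverage cutoff (use min_coverage = 6 with this table:
# c1 has 8 quantified sites, c2 has 6, c3 only 5 and is dropped).
toy_records <- function() {
  rec <- function(protein, positions, residues, condition, replicate, log2fc,
                  canonical = TRUE, peptide = NA_character_) {
    data.frame(protein = protein, positions = positions, residues = residues,
               condition = condition, replicate = replicate, log2fc = log2fc,
               canonical = canonical, peptide = peptide,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # S1 = P1_10_S: peptide pepA in two replicates (1, 3 -> 2),
    # peptide pepD once (4); replicate-first averaging gives (2 + 4) / 2 = 3
    rec("P1", "10", "S", "c1", "r1", 1.0, peptide = "pepA"),
    rec("P1", "10", "S", "c1", "r2", 3.0, peptide = "pepA"),
    rec("P1", "10", "S", "c1", "r1", 4.0, peptide = "pepD"),
    # S2 = P2_20_T: two distinct peptides, one replicate each -> 1.5
    rec("P2", "20", "T", "c1", "r1", 1.0, peptide = "pepB"),
    rec("P2", "20", "T", "c1", "r1", 2.0, peptide = "pepC"),
    # S3 = P3_30_Y: single row
    rec("P3", "30", "Y", "c1", "r1", -1.0),
    # S4 = P4_40_S: non-canonical row must be ignored, canonical kept
    rec("P4", "40", "S", "c1", "r1", 9.0, canonical = FALSE),
    rec("P4", "40", "S", "c1", "r1", 0.5),
    # S5 = P5_50_S: doubly phosphorylated row ignored, mono row kept
    rec("P5", "50;52", "S;T", "c1", "r1", 9.0),
    rec("P5", "50", "S", "c1", "r1", -0.5),
    # S6..S8 single rows
    rec("P6", "60", "T", "c1", "r1", 0.25),
    rec("P7", "70", "S", "c1", "r1", -2.0),
    rec("P8", "80", "S", "c1", "r1", 1.25),
    # S9: only non-canonical -> absent
    rec("P9", "90", "S", "c1", "r1", 5.0, canonical = FALSE),
    # S10: only multiply phosphorylated -> absent
    rec("P10", "100;103", "S;S", "c1", "r1", 5.0),
    # S11: unparseable fold change -> missing -> absent
    rec("P11", "110", "S", "c1", "r1", NA_real_),
    # c2: exactly six sites, retained at min_coverage = 6
    rec("P1", "10", "S", "c2", "r1", 0.1),
    rec("P2", "20", "T", "c2", "r1", 0.2),
    rec("P3", "30", "Y", "c2", "r1", 0.3),
    rec("P4", "40", "S", "c2", "r1", 0.4),
    rec("P5", "50", "S", "c2", "r1", 0.5),
    rec("P6", "60", "T", "c2", "r1", 0.6),
    # c3: five sites only -> condition dropped at min_coverage = 6
    rec("P1", "10", "S", "c3", "r1", 1.0),
    rec("P2", "20", "T", "c3", "r1", 1.0),
    rec("P3", "30", "Y", "c3", "r1", 1.0),
    rec("P4", "40", "S", "c3", "r1", 1.0),
    rec("P5", "50", "S", "c3", "r1", 1.0)
  )
  out <- do.call(rbind, rows)
  out$n_sites <- lengths(strsplit(out$positions, ";", fixed = TRUE))
  out
}

# expected site-level matrix for toy_records() at min_coverage = 6
toy_expected_c1 <- c(
  P1_10_S = 3.0, P2_20_T = 1.5, P3_30_Y = -1.0, P4_40_S = 0.5,
  P5_50_S = -0.5, P6_60_T = 0.25, P7_70_S = -2.0, P8_80_S = 1.25
)

write_records_tsv <- function(records, path = tempfile(fileext = ".tsv")) {
  df <- records
  df$log2fc <- ifelse(is.na(df$log2fc), "NA", as.character(df$log2fc))
  write.table(df[, c("protein", "positions", "residues", "condition",
                     "replicate", "log2fc", "canonical", "peptide")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_network <- function() {
  ks_network(data.frame(
    kinase = c("KA", "KA", "KA", "KB", "KB"),
    protein = c("P1", "P2", "P3", "P5", "P6"),
    position = c(10, 20, 30, 50, 60),
    residue = c("S", "T", "Y", "S", "T"),
    evidence = c("in_vivo", "in_vivo", "in_vitro", "in_vivo", "in_silico"),
    score = c(NA, NA, NA, NA, 0.8),
    stringsAsFactors = FALSE
  ))
}

# named fold-change vector with a known substrate shift
toy_fc <- function(n = 100, n_sub = 10, shift = 2, seed = 42, sd = 1) {
  set.seed(seed)
  fc <- rnorm(n, 0, sd)
  names(fc) <- sprintf("P%03d_1", seq_len(n))
  fc[seq_len(n_sub)] <- fc[seq_len(n_sub)] + shift
  list(fc = fc, substrates = names(fc)[seq_len(n_sub)])
}

random_pwm <- function(n_seq = 20, seed = 1, pseudocount = 0.01) {
  set.seed(seed)
  wins <- vapply(seq_len(n_seq), function(i) {
    paste(sample(c(LETTERS[LETTERS %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]),
                 15, replace = TRUE), collapse = "")
  }, character(1))
  build_pwm(wins, pseudocount = pseudocount, min_sequences = 1)
}

random_window <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, 15, replace = TRUE), collapse = "")
}
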