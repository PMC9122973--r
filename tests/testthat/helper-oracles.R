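# Shared fixtures and independent oracles for the test suite.  Oracles
# are deliberately naive re-implementations (plain dynamic programming,
# explicit rule tables) kept independent of the package code paths they
# check.

# small tandem-array configuration used throughout the unit tests
small_cfg <- function(n_units = 4L, seed = 42L, snv = 5e-4) {
  array_config(vector_len = 2000L, flank_left_len = 1500L,
               flank_right_len = 1500L, unit_len = 3200L,
               n_units = n_units, per_unit_snv_rate = snv, seed = seed)
}

# Gotoh affine-gap Smith-Waterman, returning only the best score.
# Mirrors the scoring used by the block scanner (match 2 / mismatch -3 /
# gap open 5 / extend 2, N scores 0) but shares no code with it.
sw_oracle_score <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                            gap_ext = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == "N" || bv[j - 1] == "N") 0
           else if (av[i - 1] == bv[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext,
                     E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext,
                     F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Independent re-statement of the isoform decision table, driven by the
# *generated* attributes of a toy gene rather than by measuring its
# sequence.
oracle_isoform_class <- function(missing_exon1, frameshift, mature_len,
                                 ala_frac, period_score, has_signal,
                                 has_pro) {
  if (missing_exon1 || frameshift ||
        (mature_len < 37 && period_score < 0.5)) return("pseudogene")
  if (ala_frac < 0.15 && mature_len >= 100 && mature_len <= 200) {
    return("gig2_like")
  }
  if (ala_frac >= 0.40 && period_score >= 0.5) {
    if (has_signal && !has_pro && mature_len >= 120) return("maxi")
    if (has_signal && has_pro && mature_len >= 60 && mature_len < 120) {
      return("midi")
    }
    if (has_signal && has_pro && mature_len < 60) return("liver")
    if (!has_signal && mature_len >= 37 && mature_len <= 60) return("skin")
  }
  "unclassified"
}

# Build a toy single-gene locus realizing the requested peptide traits,
# and report the traits as actually realized (computed naively from the
# residue vector, not via package code) so the rule-table oracle sees
# exactly what the classifier will measure.
make_toy_gene <- function(mature_len, ala_frac, periodic, has_signal,
                          has_pro, frameshift = FALSE,
                          missing_exon1 = FALSE, gene_name = "toy") {
  stopifnot(mature_len >= 5)
  resid <- rep("L", mature_len)
  resid[1] <- "M"
  thr <- if (periodic) seq(2, mature_len - 1, by = 11) else
    unique(pmin(c(3, 5, 9, 20), mature_len - 1))
  if (periodic && length(thr) < 2) thr <- unique(c(2, mature_len - 1))
  resid[thr] <- "T"
  free <- which(resid == "L")
  n_ala <- min(round(ala_frac * mature_len), length(free))
  if (n_ala > 0) resid[free[seq_len(n_ala)]] <- "A"
  mature <- paste(resid, collapse = "")

  # naive trait computation for the oracle
  thr_pos <- which(resid == "T")
  spac <- diff(thr_pos)
  traits <- list(mature_len = mature_len,
                 ala_frac = sum(resid == "A") / mature_len,
                 period_score = if (length(spac) >= 1) mean(spac == 11)
                                else 0,
                 has_signal = has_signal, has_pro = has_pro,
                 frameshift = frameshift, missing_exon1 = missing_exon1)

  sig <- if (has_signal) "MKFLVLLA" else ""
  pro <- if (has_pro) "SPDR" else ""
  protein <- paste0(sig, pro, mature)
  codon <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
             G = "GGT", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
             M = "ATG", N = "AAC", P = "CCA", Q = "CAG", R = "CGT",
             S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")
  cds <- paste0(paste(codon[strsplit(protein, "")[[1]]], collapse = ""),
                "TAA")
  if (frameshift) cds <- paste0(cds, "G")   # length no longer %% 3 == 0

  intron <- strrep("G", 60)
  pad5 <- strrep("A", 20); pad3 <- strrep("A", 20)
  ga <- list(c(gene_name = gene_name))
  if (missing_exon1) {
    seq <- paste0(pad5, cds, pad3)
    e2 <- c(20L, 20L + nchar(cds))
    feats <- rbind_features(
      feature_table("toylocus", e2[1], e2[2], "+", "gene", ga),
      feature_table("toylocus", e2[1], e2[2], "+", "exon", ga),
      feature_table("toylocus", e2[1], e2[2], "+", "CDS", ga))
    cds_segs <- e2
  } else if (has_signal) {
    # exon 1 carries the first 12 CDS bases (signal genes have a coding
    # first exon)
    split_at <- 12L
    seq <- paste0(pad5, substring(cds, 1, split_at), intron,
                  substring(cds, split_at + 1), pad3)
    e1 <- c(20L, 20L + split_at)
    e2 <- c(e1[2] + nchar(intron),
            e1[2] + nchar(intron) + nchar(cds) - split_at)
    feats <- rbind_features(
      feature_table("toylocus", e1[1], e2[2], "+", "gene", ga),
      feature_table("toylocus", e1[1], e1[2], "+", "exon", ga),
      feature_table("toylocus", e2[1], e2[2], "+", "exon", ga),
      feature_table("toylocus", c(e1[1], e2[1]), c(e1[2], e2[2]), "+",
                    "CDS", ga))
    sig_nt <- 3L * nchar(sig)
    feats <- rbind_features(feats, feature_table(
      "toylocus", c(e1[1], e2[1]),
      c(e1[2], e2[1] + sig_nt - split_at), "+", "signal_peptide", ga))
    if (has_pro) {
      feats <- rbind_features(feats, feature_table(
        "toylocus", e2[1] + sig_nt - split_at,
        e2[1] + sig_nt + 3L * nchar(pro) - split_at, "+", "propeptide",
        ga))
    }
  } else {
    exon1 <- strrep("C", 30)
    seq <- paste0(pad5, exon1, intron, cds, pad3)
    e1 <- c(20L, 20L + nchar(exon1))
    e2 <- c(e1[2] + nchar(intron), e1[2] + nchar(intron) + nchar(cds))
    feats <- rbind_features(
      feature_table("toylocus", e1[1], e2[2], "+", "gene", ga),
      feature_table("toylocus", e1[1], e1[2], "+", "exon", ga),
      feature_table("toylocus", e2[1], e2[2], "+", "exon", ga),
      feature_table("toylocus", e2[1], e2[2], "+", "CDS", ga))
  }
  list(locus = annotated_locus(seq_record("toylocus", seq), feats),
       traits = traits)
}
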