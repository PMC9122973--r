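# Mature-peptide derivation and the isoform decision rules.

test_that("thr_period_score arithmetic", {
  p <- rep("A", 37); p[c(2, 13, 24)] <- "T"
  r <- thr_period_score(paste(p, collapse = ""))
  expect_equal(r$period_score, 1.0)
  expect_equal(r$n_repeats, 2L)

  p2 <- rep("A", 37); p2[c(2, 13, 20)] <- "T"
  r2 <- thr_period_score(paste(p2, collapse = ""))
  expect_equal(r2$period_score, 0.5)

  r3 <- thr_period_score("AAAAAAAAAAAAAA")
  expect_equal(r3$period_score, 0)
  expect_true(r3$too_few_thr)
})

test_that("ala_fraction", {
  expect_equal(ala_fraction("AAAA"), 1.0)
  expect_equal(ala_fraction("MDAT"), 0.25)
  expect_error(ala_fraction(""), "empty")
})

test_that("mature_peptide removes annotated regions and the amide Gly", {
  # skin-type: 37-codon CDS returns the unchanged translation
  skin <- make_toy_gene(37, 0.5, periodic = TRUE, has_signal = FALSE,
                        has_pro = FALSE)
  g <- gene_model(skin$locus, "toy")
  m <- mature_peptide(g, skin$locus)
  expect_equal(nchar(m$seq), 37L)
  expect_equal(substring(m$seq, 1, 1), "M")   # Met retained

  # liver-type toy with terminal Gly: signal 8 aa + pro 4 aa + mature + G
  mat <- paste0(paste(rep("A", 37), collapse = ""), "G")
  codon <- c(A = "GCC", G = "GGT", M = "ATG", K = "AAG", F = "TTC",
             L = "CTG", V = "GTG", S = "AGC", P = "CCA", D = "GAC",
             R = "CGT")
  protein <- paste0("MKFLVLLA", "SPDR", mat)
  cds <- paste0(paste(codon[strsplit(protein, "")[[1]]], collapse = ""),
                "TAA")
  split_at <- 12L
  ga <- list(c(gene_name = "lv"))
  seq <- paste0(strrep("T", 10), substring(cds, 1, split_at),
                strrep("G", 50), substring(cds, split_at + 1),
                strrep("T", 10))
  e1 <- c(10L, 10L + split_at)
  e2 <- c(e1[2] + 50L, e1[2] + 50L + nchar(cds) - split_at)
  loc <- annotated_locus(
    seq_record("l", seq),
    rbind_features(
      feature_table("l", e1[1], e2[2], "+", "gene", ga),
      feature_table("l", e1[1], e1[2], "+", "exon", ga),
      feature_table("l", e2[1], e2[2], "+", "exon", ga),
      feature_table("l", c(e1[1], e2[1]), c(e1[2], e2[2]), "+", "CDS", ga),
      feature_table("l", c(e1[1], e2[1]), c(e1[2], e2[1] + 24L - split_at),
                    "+", "signal_peptide", ga),
      feature_table("l", e2[1] + 24L - split_at, e2[1] + 36L - split_at,
                    "+", "propeptide", ga)))
  g2 <- gene_model(loc, "lv")
  m2 <- mature_peptide(g2, loc)
  full_len <- nchar(protein)
  expect_equal(nchar(m2$seq), full_len - 8L - 4L - 1L)
  # length conservation: mature + removed + dropped Gly = full translation
  m2_keep <- mature_peptide(g2, loc, amidation_gly_removal = FALSE)
  expect_equal(nchar(m2_keep$seq), full_len - 8L - 4L)

  # inconsistency: signal annotated but exon 1 non-coding
  bad <- make_toy_gene(40, 0.5, TRUE, has_signal = FALSE, has_pro = FALSE)
  f <- bad$locus$features
  cds_row <- f[f$kind == "CDS", ]
  f2 <- rbind_features(f, feature_table(
    "toylocus", cds_row$start[1], cds_row$start[1] + 24L, "+",
    "signal_peptide", list(c(gene_name = "toy"))))
  bad2 <- annotated_locus(bad$locus$record, f2)
  expect_error(mature_peptide(gene_model(bad2, "toy"), bad2),
               "inconsistency")
})

test_that("classify_isoform walks the documented rules", {
  # 38 aa, no signal, Ala-rich, periodic -> skin
  sk <- make_toy_gene(38, 0.45, TRUE, FALSE, FALSE)
  expect_equal(classify_isoform(gene_model(sk$locus, "toy"),
                                sk$locus)$class, "skin")
  # 195 aa Ala-rich with signal, no propeptide -> maxi
  mx <- make_toy_gene(195, 0.6, TRUE, TRUE, FALSE)
  expect_equal(classify_isoform(gene_model(mx$locus, "toy"),
                                mx$locus)$class, "maxi")
  # 76 aa with signal + propeptide -> midi
  md <- make_toy_gene(76, 0.6, TRUE, TRUE, TRUE)
  expect_equal(classify_isoform(gene_model(md$locus, "toy"),
                                md$locus)$class, "midi")
  # 38 aa with signal + propeptide -> liver
  lv <- make_toy_gene(38, 0.6, TRUE, TRUE, TRUE)
  expect_equal(classify_isoform(gene_model(lv$locus, "toy"),
                                lv$locus)$class, "liver")
  # 147 aa at ~5% Ala -> gig2_like
  gg <- make_toy_gene(147, 0.05, FALSE, FALSE, FALSE)
  expect_equal(classify_isoform(gene_model(gg$locus, "toy"),
                                gg$locus)$class, "gig2_like")
  # missing exon 1 -> pseudogene, whatever else holds
  ps <- make_toy_gene(38, 0.5, TRUE, FALSE, FALSE, missing_exon1 = TRUE)
  call <- classify_isoform(gene_model(ps$locus, "toy"), ps$locus)
  expect_equal(call$class, "pseudogene")
  expect_true(length(call$evidence) > 0L)
  # short remnant without periodicity -> pseudogene
  rem <- make_toy_gene(16, 0.3, FALSE, FALSE, FALSE)
  expect_equal(classify_isoform(gene_model(rem$locus, "toy"),
                                rem$locus)$class, "pseudogene")
})

test_that("classifier agrees with the rule-table oracle on 200 random
           gene models", {
  with_seed(71, {
    for (i in 1:200) {
      len <- sample(c(10:60, 76, 100:200, 210), 1)
      ala <- sample(c(0.05, 0.1, 0.2, 0.42, 0.6, 0.8), 1)
      periodic <- sample(c(TRUE, FALSE), 1)
      has_signal <- sample(c(TRUE, FALSE), 1)
      has_pro <- has_signal && sample(c(TRUE, FALSE), 1)
      fs <- sample(c(TRUE, FALSE), 1, prob = c(0.15, 0.85))
      me1 <- sample(c(TRUE, FALSE), 1, prob = c(0.15, 0.85))
      toy <- make_toy_gene(len, ala, periodic, has_signal, has_pro,
                           frameshift = fs, missing_exon1 = me1)
      got <- classify_isoform(gene_model(toy$locus, "toy"), toy$locus)
      tr <- toy$traits
      want <- oracle_isoform_class(tr$missing_exon1, tr$frameshift,
                                   tr$mature_len, tr$ala_frac,
                                   tr$period_score, tr$has_signal,
                                   tr$has_pro)
      expect_equal(got$class, want,
                   info = sprintf("case %d: len=%d ala=%.2f per=%s sig=%s pro=%s fs=%s me1=%s",
                                  i, len, ala, periodic, has_signal,
                                  has_pro, fs, me1))
    }
  })
})

test_that("census recovers the generator truth and handles empty loci", {
  # snv = 0: point mutations can legitimately demote a cassette (e.g. a
  # Thr hit destroys periodicity), so exact truth recovery is asserted on
  # the mutation-free fixture
  bac <- build_tandem_bac(small_cfg(n_units = 4L, seed = 72, snv = 0))
  cen <- census_locus(bac)
  expect_equal(cen$afp_count, 8L)
  expect_equal(unname(cen$counts["skin"]), 4L)
  expect_equal(unname(cen$counts["liver"]), 4L)
  # truth classes all recovered
  truth_cls <- feat_attr(bac$features[bac$features$kind == "gene", ],
                         "isoform_class")
  expect_equal(sort(c(table(cen$calls$class))), sort(c(table(truth_cls))))

  empty <- annotated_locus(seq_record("e", "ACGT"))
  cen0 <- census_locus(empty)
  expect_equal(cen0$afp_count, 0L)
  expect_equal(sum(cen0$counts), 0L)
})

test_that("classification is order-independent and total", {
  bac <- build_tandem_bac(small_cfg(n_units = 3L, seed = 73))
  cen <- census_locus(bac)
  expect_equal(sum(cen$counts), nrow(cen$calls))   # exactly one class each
  # permuting the feature table does not change any call
  perm <- with_seed(2, sample(nrow(bac$features)))
  bac2 <- annotated_locus(bac$record, bac$features[perm, ])
  cen2 <- census_locus(bac2)
  expect_equal(cen2$calls[order(cen2$calls$gene), ]$class,
               cen$calls[order(cen$calls$gene), ]$class)
})
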