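# The synthetic-locus generator and its attached ground truth.

test_that("build_tandem_bac realizes the configured architecture", {
  one <- build_tandem_bac(small_cfg(n_units = 1L))
  ru <- one$features[one$features$kind == "repeat_unit", ]
  expect_equal(nrow(ru), 1L)
  expect_equal(length(one$record),
               2000L + 1500L + 1500L + 3200L)
  expect_equal(one$record$topology, "circular")

  deflt <- build_tandem_bac(array_config(seed = 3))
  ru <- deflt$features[deflt$features$kind == "repeat_unit", ]
  expect_equal(nrow(ru), 12L)
  expect_equal(sum(ru$end - ru$start), 134400L)
  expect_equal(sort(as.integer(feat_attr(ru, "unit_index"))), 1:12)
})

test_that("zero SNV rate gives byte-identical unit copies", {
  bac <- build_tandem_bac(small_cfg(snv = 0))
  ru <- bac$features[bac$features$kind == "repeat_unit", ]
  seqs <- vapply(seq_len(nrow(ru)), function(i) {
    substring(bac$record$seq, ru$start[i] + 1L, ru$end[i])
  }, character(1))
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(unique(seqs), bac$truth$unit_template)
})

test_that("SNV truth exactly reconciles unit copies with the template", {
  bac <- build_tandem_bac(small_cfg(snv = 2e-3, seed = 9))
  ru <- bac$features[bac$features$kind == "repeat_unit", ]
  tpl <- strsplit(bac$truth$unit_template, "")[[1]]
  expect_gt(nrow(bac$truth$snvs), 0L)
  for (i in seq_len(nrow(ru))) {
    copy <- strsplit(substring(bac$record$seq, ru$start[i] + 1L,
                               ru$end[i]), "")[[1]]
    sn <- bac$truth$snvs[bac$truth$snvs$unit == i, ]
    rebuilt <- tpl
    if (nrow(sn) > 0L) {
      expect_equal(tpl[sn$pos + 1L], sn$ref)
      rebuilt[sn$pos + 1L] <- sn$alt
    }
    expect_identical(copy, rebuilt)
    # diff oracle: the truth lists exactly the differing positions
    expect_equal(which(copy != tpl), sort(sn$pos + 1L))
  }
})

test_that("fixtures are byte-identical under the same seed", {
  a <- build_tandem_bac(small_cfg(seed = 5))
  b <- build_tandem_bac(small_cfg(seed = 5))
  expect_identical(a$record$seq, b$record$seq)
  expect_identical(a$features, b$features)
  ra <- simulate_reads(a, read_sim_config(n_reads = 30, mean_len = 2000,
                                          sd_len = 500, seed = 6))
  rb <- simulate_reads(b, read_sim_config(n_reads = 30, mean_len = 2000,
                                          sd_len = 500, seed = 6))
  expect_identical(vapply(ra$reads, `[[`, "", "seq"),
                   vapply(rb$reads, `[[`, "", "seq"))
  expect_identical(ra$truth, rb$truth)
})

test_that("error-free reads are substrings of the doubled circle and the
           truth intervals tile and reproduce each read", {
  bac <- build_tandem_bac(small_cfg(seed = 2))
  rs <- simulate_reads(bac, read_sim_config(
    n_reads = 25, mean_len = 3000, sd_len = 800, sub_rate = 0,
    ins_rate = 0, del_rate = 0, seed = 3))
  doubled <- paste0(bac$record$seq, bac$record$seq)
  for (i in seq_along(rs$reads)) {
    r <- rs$reads[[i]]
    expect_true(grepl(r$seq, doubled, fixed = TRUE))
    tr <- rs$truth[[r$id]]
    # tiling: segments abut and cover [0, len)
    expect_equal(tr$read_start[1], 0L)
    expect_equal(tr$read_end[nrow(tr)], nchar(r$seq))
    if (nrow(tr) > 1L) {
      expect_equal(tr$read_start[-1], tr$read_end[-nrow(tr)])
    }
    # mapping the source intervals back reproduces the read
    rebuilt <- paste(vapply(seq_len(nrow(tr)), function(j) {
      substring(bac$record$seq, tr$src_start[j] + 1L, tr$src_end[j])
    }, character(1)), collapse = "")
    expect_identical(rebuilt, r$seq)
  }
})

test_that("read starts are uniform on the circle (chi-square GOF)", {
  bac <- build_tandem_bac(small_cfg(seed = 4))
  rs <- simulate_reads(bac, read_sim_config(n_reads = 1000,
                                            mean_len = 2000, sd_len = 500,
                                            seed = 10))
  starts <- vapply(rs$truth, function(tr) tr$src_start[1], numeric(1))
  L <- length(bac$record)
  counts <- table(cut(starts, breaks = seq(0, L, length.out = 21),
                      include.lowest = TRUE))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("simulate_reads validates configuration", {
  bac <- build_tandem_bac(small_cfg())
  expect_error(simulate_reads(bac, read_sim_config(
    n_reads = 5, mean_len = 1e7, sd_len = 10, min_len = 100)),
    "mean_len")
  lin <- annotated_locus(seq_record("x", random_dna(100)))
  expect_error(simulate_reads(lin, read_sim_config(n_reads = 1,
                                                   mean_len = 50,
                                                   sd_len = 5,
                                                   min_len = 10)),
               "circular")
})

test_that("build_allele_pair: deletions, divergence and truth", {
  same <- build_allele_pair(small_cfg(seed = 12), integer(0),
                            divergence = 0)
  expect_identical(same$allele_a$record$seq, same$allele_b$record$seq)

  del <- build_allele_pair(small_cfg(seed = 12), 2:4, divergence = 0)
  ru_b <- del$allele_b$features[del$allele_b$features$kind == "repeat_unit", ]
  expect_equal(nrow(ru_b), 1L)
  expect_equal(length(del$allele_b$record),
               length(del$allele_a$record) - 3L * 3200L)

  expect_error(build_allele_pair(small_cfg(), c(2, 2)), "plan error")
  expect_error(build_allele_pair(small_cfg(), 99L), "plan error")

  # realized substitutions within 3 SD of the binomial expectation
  div <- build_allele_pair(small_cfg(seed = 13), integer(0),
                           divergence = 0.02)
  a <- strsplit(div$allele_a$record$seq, "")[[1]]
  b <- strsplit(div$allele_b$record$seq, "")[[1]]
  n <- length(a)
  observed <- sum(a != b)
  expect_lt(abs(observed - n * 0.02), 3 * sqrt(n * 0.02 * 0.98))
})

test_that("build_provenance_pair constructs the stated homology", {
  pp <- build_provenance_pair(1.0, "replaced", seed = 21)
  for (j in seq_len(nrow(pp$truth))) {
    sa <- substring(pp$locus_a$record$seq, pp$truth$a_start[j] + 1L,
                    pp$truth$a_end[j])
    sb <- substring(pp$locus_b$record$seq, pp$truth$b_start[j] + 1L,
                    pp$truth$b_end[j])
    expect_identical(sa, sb)
  }
  cds_b <- substring(pp$locus_b$record$seq, pp$cds_b[1] + 1L, pp$cds_b[2])
  expect_equal(cds_b, strrep("GCC", 40))
  expect_equal(translate_dna(cds_b)[1], strrep("A", 40),
               ignore_attr = TRUE)
  # Gig2-like side: 147 aa translation with low Ala
  tr_a <- translate_cds(pp$locus_a, "Gig2")
  expect_equal(nchar(tr_a$seq), 147L)
  expect_lt(ala_fraction(tr_a), 0.10)
  expect_error(build_provenance_pair(0.4), "identity")
})

test_that("build_synteny_scenario lays out gene orders", {
  sc <- build_synteny_scenario(list(
    flounder = c("MTX2", "Gig2", "CADH5"),
    halibut = c("HDAC5", "ZG57", "Gig2", "Gig2", "XYLT1"),
    none = c("MTX2", "CADH5")))
  g <- sc$flounder$features
  expect_equal(feat_attr(g[order(g$start), ], "gene_name"),
               c("MTX2", "Gig2", "CADH5"))
  gh <- sc$halibut$features
  expect_equal(sum(feat_attr(gh, "gene_name") == "Gig2"), 2L)
  expect_equal(nrow(sc$none$features), 2L)
  expect_error(build_synteny_scenario(list(x = c("A", "Gig2", "A"))),
               "duplicate")
})
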