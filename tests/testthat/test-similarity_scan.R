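# Identity computation, block scanning, contrast annotation, tandem
# period and exon-window matching.

test_that("global_identity basics and N handling", {
  expect_equal(global_identity("ACGTACGT", "ACGTACGT")$identity, 1.0)
  r <- global_identity("ACGT", "ACGA")
  expect_equal(r$matches, 3L)
  expect_equal(r$columns, 4L)
  expect_equal(r$identity, 0.75)
  # N never counts as a match
  rn <- global_identity("ACGN", "ACGN")
  expect_equal(rn$matches, 3L)
  expect_error(global_identity(seq_record("a", "ACGT"),
                               seq_record("p", "MA", type = "AA")),
               "mismatch")
  # protein path
  rp <- global_identity(seq_record("p1", "MKTAYIA", type = "AA"),
                        seq_record("p2", "MKTAYIA", type = "AA"))
  expect_equal(rp$identity, 1.0)
})

test_that("global_identity is symmetric in its arguments", {
  with_seed(51, {
    for (i in 1:8) {
      a <- random_dna(120)
      b_int <- dna_to_int(a)
      hit <- sample(120, 15)
      b_int[hit] <- (b_int[hit] + sample.int(3, 15, TRUE)) %% 4
      b <- int_to_dna(b_int)
      r1 <- global_identity(a, b)
      r2 <- global_identity(b, a)
      expect_equal(r1$identity, r2$identity)
      expect_equal(r1$score, r2$score)
    }
  })
})

test_that("local_blocks: self-comparison yields the full-length block", {
  loc <- with_seed(52, seq_record("x", random_dna(2500)))
  bl <- local_blocks(loc, loc, min_len = 100)
  expect_gte(nrow(bl), 1L)
  main <- bl[which.max(bl$columns), ]
  expect_equal(main$a_start, 0L)
  expect_equal(main$a_end, 2500L)
  expect_equal(main$identity, 1.0)
})

test_that("every reported block satisfies the scan thresholds", {
  pp <- build_provenance_pair(0.85, "replaced", seed = 53)
  bl <- local_blocks(pp$locus_a, pp$locus_b, min_len = 100,
                     min_identity = 0.70)
  expect_gt(nrow(bl), 0L)
  expect_true(all(bl$identity >= 0.70))
  expect_true(all(bl$columns >= 100))
  expect_true(all(bl$a_start < bl$a_end & bl$b_start < bl$b_end))
  expect_false(is.unsorted(bl$a_start))
})

test_that("provenance-pair blocks respect the generator truth", {
  pp <- build_provenance_pair(0.85, "replaced", seed = 54)
  bl <- local_blocks(pp$locus_a, pp$locus_b, min_len = 100,
                     min_identity = 0.70)
  expect_gt(nrow(bl), 0L)
  # >= 95% of block-covered a-side bases fall in truth-homologous segments
  La <- length(pp$locus_a$record)
  hom <- rep(FALSE, La)
  for (j in seq_len(nrow(pp$truth))) {
    hom[(pp$truth$a_start[j] + 1L):pp$truth$a_end[j]] <- TRUE
  }
  cov <- rep(FALSE, La)
  for (i in seq_len(nrow(bl))) cov[(bl$a_start[i] + 1L):bl$a_end[i]] <- TRUE
  expect_gte(sum(cov & hom) / sum(cov), 0.95)
  # no block covers more than 20% of the replaced CDS
  cds <- pp$cds_a
  cds_cov <- vapply(seq_len(nrow(bl)), function(i) {
    max(0, min(bl$a_end[i], cds[2]) - max(bl$a_start[i], cds[1]))
  }, numeric(1))
  expect_true(all(cds_cov <= 0.2 * (cds[2] - cds[1])))
})

test_that("block scores match an independent Smith-Waterman oracle", {
  with_seed(55, {
    for (i in 1:5) {
      core <- random_dna(80)
      a <- paste0(random_dna(40), core, random_dna(40))
      mut <- dna_to_int(core)
      hit <- sample(80, 6)
      mut[hit] <- (mut[hit] + sample.int(3, 6, TRUE)) %% 4
      b <- paste0(random_dna(30), int_to_dna(mut), random_dna(30))
      bl <- local_blocks(seq_record("a", a), seq_record("b", b),
                         min_len = 40, min_identity = 0.7,
                         both_strands = FALSE)
      expect_gte(nrow(bl), 1L)
      expect_equal(max(bl$score), sw_oracle_score(a, b))
    }
  })
})

test_that("reverse-strand homology is found and mapped to forward coords", {
  with_seed(56, {
    core <- random_dna(300)
    a <- paste0(random_dna(100), core, random_dna(100))
    b <- paste0(random_dna(50), revcomp(core), random_dna(50))
  })
  bl <- local_blocks(seq_record("a", a), seq_record("b", b), min_len = 100)
  expect_gte(nrow(bl), 1L)
  expect_equal(bl$strand[which.max(bl$columns)], "-")
  top <- bl[which.max(bl$columns), ]
  expect_lte(abs(top$b_start - 50), 10)
  expect_lte(abs(top$b_end - 350), 10)
})

test_that("annotate_blocks applies the majority rule and contrast", {
  seq <- with_seed(57, random_dna(1000))
  ga <- list(c(gene_name = "g"))
  loc <- annotated_locus(
    seq_record("s", seq),
    rbind_features(
      feature_table("s", 100L, 400L, "+", "intron", ga),
      feature_table("s", 400L, 700L, "+", "CDS", ga)))
  mk_block <- function(a0, a1) {
    b <- data.frame(a_start = a0, a_end = a1, b_start = a0, b_end = a1,
                    matches = a1 - a0, columns = a1 - a0, identity = 1,
                    score = 2 * (a1 - a0), strand = "+",
                    feature_class = NA_character_)
    class(b) <- c("similarity_blocks", "data.frame")
    b
  }
  # wholly inside the intron
  r1 <- annotate_blocks(mk_block(150L, 350L), loc)
  expect_equal(r1$blocks$feature_class, "intron")
  # 70% intron / 30% CDS -> majority intron
  r2 <- annotate_blocks(mk_block(190L, 490L), loc)
  expect_equal(r2$blocks$feature_class, "intron")
  # 50/50 -> mixed
  r3 <- annotate_blocks(mk_block(300L, 500L), loc)
  expect_equal(r3$blocks$feature_class, "mixed")
  expect_true(all(r1$summary$matched_bases <= r1$summary$total_bases))
})

test_that("provenance fixture: non-coding/coding contrast ratio >= 5", {
  pp <- build_provenance_pair(0.85, "replaced", seed = 58)
  bl <- local_blocks(pp$locus_a, pp$locus_b)
  ann <- annotate_blocks(bl, pp$locus_a)
  expect_gte(ann$noncoding_coding_ratio, 5)
})

test_that("closest_match_identity", {
  set_b <- with_seed(59, lapply(1:4, function(i) {
    seq_record(paste0("b", i), random_dna(60))
  }))
  set_a <- set_b[1:2]
  res <- closest_match_identity(set_a, set_b)
  expect_equal(res$mean_identity, 1.0)
  expect_equal(res$per_query$best_b_id, c("b1", "b2"))

  a1 <- seq_record("q", "ACGTACGTAC")
  b1 <- seq_record("t", "ACGTACGTAA")
  res2 <- closest_match_identity(list(a1), list(b1))
  expect_equal(res2$mean_identity, 0.9)
  expect_error(closest_match_identity(list(a1), list()), "empty")
})

test_that("tandem_period recovers the unit length and rejects noise", {
  bac <- build_tandem_bac(small_cfg(n_units = 6L, seed = 60))
  ru <- bac$features[bac$features$kind == "repeat_unit", ]
  tp <- tandem_period(bac, region = c(min(ru$start), max(ru$end)))
  expect_true(tp$tandem)
  expect_lte(abs(tp$period - 3200), 100)
  expect_gte(tp$n_units_est, 5L)

  noise <- seq_record("r", with_seed(61, random_dna(20000)))
  tpn <- tandem_period(noise)
  expect_false(tpn$tandem)
})

test_that("exon_window_matches counts matches over the exon window", {
  with_seed(62, {
    exon <- random_dna(44)
    a_seq <- paste0(random_dna(200), exon, random_dna(200))
    # inject exactly 5 substitutions into the b-side exon copy
    x <- dna_to_int(exon)
    hit <- sample(44, 5)
    x[hit] <- (x[hit] + sample.int(3, 5, TRUE)) %% 4
    b_seq <- paste0(random_dna(150), int_to_dna(x), random_dna(150))
  })
  ga <- list(c(gene_name = "g"))
  a <- annotated_locus(seq_record("a", a_seq),
                       feature_table("a", 200L, 244L, "+", "exon", ga))
  b <- annotated_locus(seq_record("b", b_seq))
  r <- exon_window_matches(a, a$features[1, ], b)
  expect_equal(r$columns, 44L)
  expect_equal(r$matches, 39L)

  # identical exon -> full-length match
  r2 <- exon_window_matches(a, a$features[1, ], a)
  expect_equal(r2$matches, 44L)
})

test_that("self dot plot is symmetric about the main diagonal", {
  loc <- seq_record("x", with_seed(63, paste0(random_dna(400),
                                              substring(random_dna(400), 1))))
  dp <- dotplot_coords(loc, loc, seed_len = 12)
  key <- paste(dp$a_pos, dp$b_pos)
  mirrored <- paste(dp$b_pos, dp$a_pos)
  expect_setequal(key, mirrored)
})
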