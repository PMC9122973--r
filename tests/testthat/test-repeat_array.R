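# Read classification, copy-number estimation and outer-unit anchoring.

bac_fixture <- build_tandem_bac(small_cfg(seed = 31))
ref_fixture <- component_reference_from_truth(bac_fixture)

test_that("exact component substrings classify cleanly", {
  vec_read <- seq_record("v1", substring(ref_fixture$vector, 101, 1900))
  unit_read <- seq_record("u1", substring(ref_fixture$unit_consensus,
                                          201, 2800))
  cc <- classify_reads(list(vec_read, unit_read), ref_fixture)
  pr <- cc$per_read
  expect_equal(pr$category, c("vector", "repeat"))
  expect_equal(pr$vector[1], nchar(vec_read$seq))
  expect_equal(pr[["repeat"]][2], nchar(unit_read$seq))
})

test_that("junction reads split bases about evenly (base mode)", {
  # 1000 bases of vector then 1000 of flank_left
  jr <- seq_record("j1", paste0(
    substring(ref_fixture$vector, 1001, 2000),
    substring(ref_fixture$flank_left, 1, 1000)))
  # the 50/50 read ties at read level -> ambiguous, and being the only
  # read triggers the degenerate-input warning
  expect_warning(cc <- classify_reads(list(jr), ref_fixture), "ambiguous")
  pr <- cc$per_read
  # within one 500-bp window of the true 50/50 split
  expect_lte(abs(pr$vector[1] - 1000), 500)
  expect_lte(abs(pr$flank[1] - 1000), 500)
  expect_equal(pr$vector[1] + pr$flank[1] + pr$ambiguous[1] +
                 pr[["repeat"]][1], 2000)
})

test_that("classification recovers the truth for >=95% of
           single-component reads at long-read error rates", {
  rs <- simulate_reads(bac_fixture, read_sim_config(
    n_reads = 300, mean_len = 2000, sd_len = 600, seed = 32))
  cc <- classify_reads(rs, ref_fixture)
  to_cat <- function(comp) {
    ifelse(comp == "vector", "vector",
           ifelse(grepl("^flank", comp), "flank", "repeat"))
  }
  truth_cat <- vapply(rs$truth, function(tr) {
    cats <- unique(to_cat(tr$component))
    if (length(cats) == 1L) cats else NA_character_
  }, character(1))
  idx <- !is.na(truth_cat)
  expect_gt(sum(idx), 50)
  agree <- cc$per_read$category[idx] == truth_cat[idx]
  expect_gte(mean(agree), 0.95)
})

test_that("classification is invariant to read order", {
  rs <- simulate_reads(bac_fixture, read_sim_config(
    n_reads = 60, mean_len = 2000, sd_len = 500, seed = 33))
  cc1 <- classify_reads(rs, ref_fixture)
  perm <- with_seed(1, sample(seq_along(rs$reads)))
  cc2 <- classify_reads(rs$reads[perm], ref_fixture)
  expect_equal(cc1$totals, cc2$totals)
  e1 <- estimate_copy_number(cc1, ref_fixture, B = 200, seed = 4)
  e2 <- estimate_copy_number(cc2, ref_fixture, B = 200, seed = 4)
  expect_equal(e1$n_hat, e2$n_hat)
  expect_equal(e1$ci95, e2$ci95)   # bootstrap sorts reads canonically
})

fake_counts <- function(repeat_bases, vector_bases, n_reads = 100L) {
  # a category_counts object with the given totals spread over reads
  pr <- data.frame(
    id = sprintf("r%04d", seq_len(n_reads)),
    vector = rep(vector_bases / n_reads, n_reads),
    flank = 0, `repeat` = rep(repeat_bases / n_reads, n_reads),
    ambiguous = 0,
    category = rep(c("vector", "repeat"),
                   c(n_reads %/% 2, n_reads - n_reads %/% 2)),
    check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(
    totals = data.frame(
      category = c("vector", "flank", "repeat", "ambiguous"),
      read_count = c(n_reads %/% 2, 0L, n_reads - n_reads %/% 2, 0L),
      base_count = c(vector_bases, 0, repeat_bases, 0)),
    per_read = pr, n_reads_total = n_reads, k = 15L, window = 500L,
    degenerate = FALSE), class = "category_counts")
}

test_that("estimator formula identities hold", {
  # C_repeat = C_vector and L_vector = L_unit -> n_hat = 1
  ref_eq <- component_reference(strrep("A", 100), "CC", "GG",
                                strrep("T", 100))
  expect_equal(estimate_copy_number(fake_counts(5e5, 5e5), ref_eq,
                                    B = 0)$n_hat, 1.0)

  # L_vector 7,500 / L_unit 11,200, base ratio 17.92 -> exactly 12
  ref_paper <- component_reference(strrep("A", 7500), "CC", "GG",
                                   strrep("T", 11200))
  est <- estimate_copy_number(fake_counts(17.92e6, 1e6), ref_paper, B = 0)
  expect_equal(est$n_hat, 12.0, tolerance = 1e-12)

  # doubling C_repeat doubles n_hat
  e1 <- estimate_copy_number(fake_counts(4e6, 1e6), ref_paper, B = 0)
  e2 <- estimate_copy_number(fake_counts(8e6, 1e6), ref_paper, B = 0)
  expect_equal(e2$n_hat, 2 * e1$n_hat)

  # no vector support is an error
  expect_error(estimate_copy_number(fake_counts(1e6, 0), ref_paper, B = 0),
               "no vector support")
})

test_that("read mode and base mode agree on the synthetic array", {
  rs <- simulate_reads(bac_fixture, read_sim_config(
    n_reads = 600, mean_len = 1500, sd_len = 300, seed = 35))
  cc <- classify_reads(rs, ref_fixture)
  eb <- estimate_copy_number(cc, ref_fixture, mode = "bases", B = 200,
                             seed = 1)
  er <- estimate_copy_number(cc, ref_fixture, mode = "reads", B = 200,
                             seed = 1)
  expect_equal(eb$mode, "bases")
  expect_equal(er$mode, "reads")
  # both recover the true unit count within their bootstrap CI width
  expect_lt(abs(eb$n_hat - 4), 4 * eb$se + 1e-9)
  expect_lt(abs(er$n_hat - 4), 4 * er$se + 1e-9)
  # invariants of the estimate object
  expect_gte(eb$ci95[2], eb$n_hat)
  expect_lte(eb$ci95[1], eb$n_hat)
  expect_gte(eb$se, 0)
})

test_that("anchor_assemble resolves outer units and calls a planted SNV", {
  cfg <- small_cfg(n_units = 3L, seed = 36, snv = 0)
  bac <- build_tandem_bac(cfg)
  ref <- component_reference_from_truth(bac)
  # plant one diagnostic substitution in unit 1 (consensus position 1501)
  u1 <- bac$features[bac$features$kind == "repeat_unit", ][1, ]
  pos <- u1$start + 1500L
  old <- substring(bac$record$seq, pos + 1L, pos + 1L)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  seq2 <- paste0(substring(bac$record$seq, 1, pos), new,
                 substring(bac$record$seq, pos + 2L))
  bac2 <- bac
  bac2$record$seq <- seq2

  # error-free reads of ~1.5 unit lengths starting in the left flank
  mk_read <- function(i, start) {
    seq_record(sprintf("a%02d", i),
               substring(seq2, start + 1L, start + 4800L))
  }
  reads <- lapply(1:6, function(i) mk_read(i, 2000L + 200L * i))
  res <- anchor_assemble(reads, ref, min_support = 3L)
  expect_gte(res$units_resolved_left, 1.0)
  v <- res$variants
  expect_true(any(v$side == "left" & v$unit == 1L & v$pos == 1501L &
                    v$alt == new))
})

test_that("anchor_assemble degrades gracefully", {
  cfg <- small_cfg(n_units = 2L, seed = 37, snv = 0)
  bac <- build_tandem_bac(cfg)
  ref <- component_reference_from_truth(bac)
  L <- length(bac$record)

  # error-free reads covering the whole molecule resolve all units on
  # both sides
  whole <- lapply(1:3, function(i) {
    seq_record(paste0("w", i), substring(
      paste0(bac$record$seq, bac$record$seq), 1, L))
  })
  res <- anchor_assemble(whole, ref, min_support = 3L)
  expect_gte(res$units_resolved_left, 2.0)
  expect_gte(res$units_resolved_right, 2.0)

  # reads shorter than one unit cannot resolve a full unit
  short <- lapply(1:5, function(i) {
    s <- 2000L + 300L * i
    seq_record(paste0("s", i),
               substring(bac$record$seq, s + 1L, s + 2500L))
  })
  res2 <- anchor_assemble(short, ref, min_support = 3L)
  expect_lt(res2$units_resolved_left, 1.0)
  expect_lt(res2$units_resolved_right, 1.0)

  # no anchored reads at all
  noise <- list(seq_record("n1", with_seed(1, random_dna(800))))
  expect_warning(res3 <- anchor_assemble(noise, ref), "anchor")
  expect_equal(res3$units_resolved_left, 0)
  expect_equal(res3$units_resolved_right, 0)
})
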