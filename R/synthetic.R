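# Synthetic fixtures with attached ground truth: tandem-array BAC molecules,
# error-bearing long reads, deletion-derived allele pairs, provenance pairs
# and microsynteny scenarios.  Every generator is deterministic under its
# seed and never perturbs the caller's RNG stream.

#' Configuration for a synthetic tandem-array BAC
#'
#' Defaults describe a BAC carrying an insert with twelve near-identical
#' 11.2-kb tandem units on a 7.5-kb vector backbone, each unit carrying a
#' skin-type and a liver-type AFP gene cassette.
#'
#' @param vector_len vector backbone length in bp.
#' @param flank_left_len,flank_right_len insert flank lengths in bp.
#' @param unit_len tandem-unit length in bp (>= 3000 so the two gene
#'   cassettes fit).
#' @param n_units number of tandem units (>= 1).
#' @param per_unit_snv_rate substitutions per bp applied independently to
#'   each unit copy.
#' @param seed integer seed.
#' @return a list of class `array_config`.
#' @export
array_config <- function(vector_len = 7500L, flank_left_len = 6000L,
                         flank_right_len = 6000L, unit_len = 11200L,
                         n_units = 12L, per_unit_snv_rate = 5e-4,
                         seed = 1L) {
  cfg <- list(vector_len = as.integer(vector_len),
              flank_left_len = as.integer(flank_left_len),
              flank_right_len = as.integer(flank_right_len),
              unit_len = as.integer(unit_len),
              n_units = as.integer(n_units),
              per_unit_snv_rate = per_unit_snv_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_units >= 1L, cfg$unit_len >= 3000L,
            cfg$vector_len > 0L, cfg$flank_left_len > 0L,
            cfg$flank_right_len > 0L,
              cfg$per_unit_snv_rate >= 0, cfg$per_unit_snv_rate <= 1)
  class(cfg) <- "array_config"
  cfg
}

# random DNA with DraI sites scrubbed (so embedded sites are the only
# deterministic ones in structured regions)
random_dna_scrubbed <- function(n, site = "TTTAAA") {
  s <- random_dna(n)
  while (grepl(site, s, fixed = TRUE)) {
    s <- sub(site, "TTTCAA", s, fixed = TRUE)
  }
  s
}

# crude reverse translation with a fixed codon per amino acid
REV_CODON <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
               G = "GGT", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
               M = "ATG", N = "AAC", P = "CCA", Q = "CAG", R = "CGT",
               S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")

reverse_translate <- function(protein) {
  paste(REV_CODON[strsplit(protein, "")[[1]]], collapse = "")
}

# AFP-like mature peptide: Asp at 2, Arg last, Thr every 11 residues
afp_mature_peptide <- function(len = 38L, first_thr = 13L) {
  p <- rep("A", len)
  p[1] <- "M"; p[2] <- "D"; p[len] <- "R"
  thr <- seq(first_thr, len - 1L, by = 11L)
  p[thr] <- "T"
  paste(p, collapse = "")
}

LIVER_SIGNAL <- "MALSLFTVGQLIFLFWTMRITEA"   # 23 aa, hydrophobic core
LIVER_PRO <- "SPDPAAKAA"                    # 9 aa propeptide

# Build one gene cassette; returns list(seq, features builder given offset).
# Skin: non-coding exon 1; liver: exon 1 carries the first 47 CDS bases
# (phase-2 split codon at the intron).
build_cassette <- function(kind = c("skin", "liver")) {
  kind <- match.arg(kind)
  if (kind == "skin") {
    mat <- substring(afp_mature_peptide(38L), 2L)      # Met + 37 more
    protein <- paste0("M", mat)
    cds <- paste0(reverse_translate(protein), "TAA")
    exon1 <- random_dna_scrubbed(44L)
    intron <- random_dna_scrubbed(400L)
    utr5 <- random_dna_scrubbed(20L)
    utr3 <- random_dna_scrubbed(150L)
    exon2 <- paste0(utr5, cds, utr3)
    seqs <- list(exon1 = exon1, intron = intron, exon2 = exon2)
    layout <- list(kind = kind, protein = protein,
                   cds_in_exon1 = 0L, utr5 = 20L, cds_len = nchar(cds))
  } else {
    mature <- {
      p <- rep("A", 38L); p[1] <- "D"; p[38] <- "R"
      p[seq(12L, 37L, by = 11L)] <- "T"
      paste(p, collapse = "")
    }
    protein <- paste0(LIVER_SIGNAL, LIVER_PRO, mature, "G")
    cds <- paste0(reverse_translate(protein), "TAA")
    exon1_utr <- random_dna_scrubbed(30L)
    cds_in_exon1 <- 47L                                 # phase 2
    intron <- random_dna_scrubbed(500L)
    utr3 <- random_dna_scrubbed(150L)
    exon1 <- paste0(exon1_utr, substring(cds, 1L, cds_in_exon1))
    exon2 <- paste0(substring(cds, cds_in_exon1 + 1L), utr3)
    seqs <- list(exon1 = exon1, intron = intron, exon2 = exon2)
    layout <- list(kind = kind, protein = protein,
                   cds_in_exon1 = cds_in_exon1, utr5 = 30L,
                   cds_len = nchar(cds))
  }
  c(seqs, list(layout = layout))
}

# features for a cassette placed at `offset` (0-based) on `seq_id`
cassette_features <- function(cas, offset, seq_id, gene_name, unit_index = NA) {
  l1 <- nchar(cas$exon1); li <- nchar(cas$intron); l2 <- nchar(cas$exon2)
  lay <- cas$layout
  base_attr <- c(gene_name = gene_name,
                 isoform_class = lay$kind)
  if (!is.na(unit_index)) base_attr["unit_index"] <- as.character(unit_index)
  e1 <- c(offset, offset + l1)
  ir <- c(e1[2], e1[2] + li)
  e2 <- c(ir[2], ir[2] + l2)
  feats <- feature_table(seq_id,
                         start = c(e1[1], e1[1], ir[1], e2[1]),
                         end = c(e2[2], e1[2], ir[2], e2[2]),
                         strand = "+",
                         kind = c("gene", "exon", "intron", "exon"),
                         attributes = list(base_attr))
  if (lay$kind == "skin") {
    cds_start <- e2[1] + lay$utr5
    feats <- rbind_features(feats, feature_table(
      seq_id, cds_start, cds_start + lay$cds_len, "+", "CDS",
      list(base_attr)))
  } else {
    # CDS split across both exons; signal peptide spans the split
    cds1 <- c(e1[1] + lay$utr5, e1[2])
    cds2 <- c(e2[1], e2[1] + (lay$cds_len - lay$cds_in_exon1))
    sig_len_nt <- nchar(LIVER_SIGNAL) * 3L              # 69
    pro_len_nt <- nchar(LIVER_PRO) * 3L                 # 27
    feats <- rbind_features(feats,
      feature_table(seq_id, c(cds1[1], cds2[1]), c(cds1[2], cds2[2]),
                    "+", "CDS", list(base_attr)),
      feature_table(seq_id, c(cds1[1], cds2[1]),
                    c(cds1[2], cds2[1] + (sig_len_nt - lay$cds_in_exon1)),
                    "+", "signal_peptide", list(base_attr)),
      feature_table(seq_id,
                    cds2[1] + (sig_len_nt - lay$cds_in_exon1),
                    cds2[1] + (sig_len_nt + pro_len_nt - lay$cds_in_exon1),
                    "+", "propeptide", list(base_attr)))
  }
  feats
}

# assemble one unit template; the two DraI sites bracket both cassettes so
# that every unit contributes an identical probe-positive fragment
build_unit_template <- function(unit_len, seq_id) {
  skin <- build_cassette("skin")
  liver <- build_cassette("liver")
  len_skin <- nchar(skin$exon1) + nchar(skin$intron) + nchar(skin$exon2)
  len_liver <- nchar(liver$exon1) + nchar(liver$intron) + nchar(liver$exon2)
  site <- "TTTAAA"
  # fixed anchors: site1 early, cassettes mid, site2 at 80% of the unit
  p_site1 <- max(100L, round(0.02 * unit_len))
  p_skin <- p_site1 + 6L + 200L
  p_liver <- p_skin + len_skin + 300L
  p_site2 <- max(p_liver + len_liver + 200L, round(0.80 * unit_len))
  if (p_site2 + 6L >= unit_len) {
    stop("unit_len too small for the embedded gene cassettes")
  }
  seq <- paste0(random_dna_scrubbed(p_site1), site,
                random_dna_scrubbed(p_skin - p_site1 - 6L),
                skin$exon1, skin$intron, skin$exon2,
                random_dna_scrubbed(p_liver - (p_skin + len_skin)),
                liver$exon1, liver$intron, liver$exon2,
                random_dna_scrubbed(p_site2 - (p_liver + len_liver)), site,
                random_dna_scrubbed(unit_len - p_site2 - 6L))
  stopifnot(nchar(seq) == unit_len)
  list(seq = seq, skin = skin, liver = liver,
       p_skin = p_skin, p_liver = p_liver,
       probe_start = p_skin + nchar(skin$exon1) + nchar(skin$intron),
       probe_len = min(214L, nchar(skin$exon2)))
}

apply_snvs <- function(seq, rate) {
  x <- dna_to_int(seq)
  hit <- which(stats::runif(length(x)) < rate & x < 4L)
  if (length(hit) == 0L) {
    return(list(seq = seq, snvs = data.frame(pos = integer(0),
                                             ref = character(0),
                                             alt = character(0))))
  }
  ref <- x[hit]
  alt <- (ref + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  x[hit] <- alt
  list(seq = int_to_dna(x),
       snvs = data.frame(pos = hit - 1L,
                         ref = strsplit(int_to_dna(ref), "")[[1]],
                         alt = strsplit(int_to_dna(alt), "")[[1]]))
}

#' Build a synthetic tandem-array BAC with ground truth
#'
#' The circular molecule is vector + left flank + `n_units` mutated copies
#' of one random unit template + right flank.  Features mark the vector,
#' flanks, each repeat unit (with `unit_index` and its injected SNVs) and
#' the gene cassettes; `$truth` carries the unit template, the SNV table
#' and the component layout.
#'
#' @param cfg an [array_config()].
#' @return an [annotated_locus()] (circular) with an extra `truth` element.
#' @export
build_tandem_bac <- function(cfg = array_config()) {
  stopifnot(inherits(cfg, "array_config"))
  with_seed(cfg$seed, {
    seq_id <- sprintf("synth_bac_n%d", cfg$n_units)
    vec <- random_dna_scrubbed(cfg$vector_len)
    fl <- random_dna_scrubbed(cfg$flank_left_len)
    fr <- random_dna_scrubbed(cfg$flank_right_len)
    tpl <- build_unit_template(cfg$unit_len, seq_id)

    units <- vector("list", cfg$n_units)
    snv_tab <- vector("list", cfg$n_units)
    for (i in seq_len(cfg$n_units)) {
      m <- apply_snvs(tpl$seq, cfg$per_unit_snv_rate)
      units[[i]] <- m$seq
      if (nrow(m$snvs) > 0L) m$snvs$unit <- i
      snv_tab[[i]] <- m$snvs
    }
    snvs <- do.call(rbind, Filter(function(d) nrow(d) > 0L, snv_tab))
    if (is.null(snvs)) {
      snvs <- data.frame(pos = integer(0), ref = character(0),
                         alt = character(0), unit = integer(0))
    }

    seq <- paste0(vec, fl, paste(units, collapse = ""), fr)
    u0 <- cfg$vector_len + cfg$flank_left_len
    comp <- data.frame(
      name = c("vector", "flank_left",
               sprintf("unit_%02d", seq_len(cfg$n_units)), "flank_right"),
      start = c(0L, cfg$vector_len,
                u0 + (seq_len(cfg$n_units) - 1L) * cfg$unit_len,
                u0 + cfg$n_units * cfg$unit_len),
      stringsAsFactors = FALSE)
    comp$end <- c(comp$start[-1], nchar(seq))

    feats <- rbind_features(
      feature_table(seq_id, 0L, cfg$vector_len, "+", "misc",
                    list(c(gene_name = "vector"))),
      feature_table(seq_id, cfg$vector_len, u0, "+", "misc",
                    list(c(gene_name = "flank_left"))),
      feature_table(seq_id, u0 + cfg$n_units * cfg$unit_len, nchar(seq),
                    "+", "misc", list(c(gene_name = "flank_right"))))
    for (i in seq_len(cfg$n_units)) {
      off <- u0 + (i - 1L) * cfg$unit_len
      sn <- snvs[snvs$unit == i, , drop = FALSE]
      snv_str <- if (nrow(sn) > 0L) {
        paste(sprintf("%d:%s-%s", sn$pos, sn$ref, sn$alt), collapse = "|")
      } else ""
      feats <- rbind_features(
        feats,
        feature_table(seq_id, off, off + cfg$unit_len, "+", "repeat_unit",
                      list(c(unit_index = as.character(i), snvs = snv_str))),
        cassette_features(tpl$skin, off + tpl$p_skin, seq_id,
                          sprintf("S%d", i), i),
        cassette_features(tpl$liver, off + tpl$p_liver, seq_id,
                          sprintf("L%d", i), i))
      if (i == 1L) {
        feats <- rbind_features(feats, feature_table(
          seq_id, off + tpl$probe_start, off + tpl$probe_start + tpl$probe_len,
          "+", "probe", list(c(gene_name = "skin_exon2_probe"))))
      }
    }

    locus <- annotated_locus(
      seq_record(seq_id, seq, topology = "circular",
                 description = sprintf("synthetic BAC, %d x %d bp units",
                                       cfg$n_units, cfg$unit_len)),
      feats)
    locus$truth <- list(cfg = cfg, unit_template = tpl$seq,
                        snvs = snvs[, c("unit", "pos", "ref", "alt")],
                        components = comp,
                        vector = vec, flank_left = fl, flank_right = fr)
    locus
  })
}

#' Configuration for long-read simulation
#'
#' Log-normal read lengths truncated to `[min_len, molecule length]`;
#' per-bp substitution / single-base insertion / deletion errors emulating
#' noisy single-molecule long reads.
#'
#' @param n_reads number of reads.
#' @param mean_len,sd_len mean and SD of the read-length distribution (bp).
#' @param sub_rate,ins_rate,del_rate per-bp error rates.
#' @param min_len minimum read length (bp).
#' @param seed integer seed.
#' @return a list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 1000L, mean_len = 8000, sd_len = 4000,
                            sub_rate = 0.08, ins_rate = 0.05,
                            del_rate = 0.02, min_len = 500L, seed = 1L) {
  cfg <- list(n_reads = as.integer(n_reads), mean_len = mean_len,
              sd_len = sd_len, sub_rate = sub_rate, ins_rate = ins_rate,
              del_rate = del_rate, min_len = as.integer(min_len),
              seed = as.integer(seed))
  stopifnot(cfg$n_reads >= 1L, cfg$mean_len > cfg$min_len,
            cfg$sub_rate >= 0, cfg$ins_rate >= 0, cfg$del_rate >= 0)
  class(cfg) <- "read_sim_config"
  cfg
}

mutate_dna_int <- function(x, sub_rate, ins_rate, del_rate) {
  n <- length(x)
  u <- stats::runif(n)
  del <- u < del_rate
  subm <- !del & (u < del_rate + sub_rate)
  if (any(subm)) {
    x[subm] <- (x[subm] + sample.int(3L, sum(subm), replace = TRUE)) %% 4L
  }
  ni <- stats::rbinom(1L, n + 1L, ins_rate)
  keep <- !del
  if (ni > 0L) {
    pos <- sample.int(n + 1L, ni, replace = TRUE) - 1L
    ibase <- sample.int(4L, ni, replace = TRUE) - 1L
    vals <- c(x[keep], ibase)
    # integer keys (2i for originals, 2p+1 for the gap after p): radix sort
    keys <- c(2L * seq_len(n)[keep], 2L * pos + 1L)
    vals[order(keys, method = "radix")]
  } else {
    x[keep]
  }
}

#' Simulate long reads from a circular molecule
#'
#' Start positions are uniform on the circle; lengths are log-normal
#' truncated to `[min_len, molecule length]`.  Truth intervals (component
#' of origin, read-local and source coordinates) are recorded before
#' errors are applied, and tile each error-free read exactly.
#'
#' @param locus a circular [annotated_locus()], typically from
#'   [build_tandem_bac()].
#' @param cfg a [read_sim_config()].
#' @return a list of class `read_set`: `reads` (list of [seq_record()]) and
#'   `truth` (named list of per-read data frames).
#' @export
simulate_reads <- function(locus, cfg = read_sim_config()) {
  stopifnot(inherits(locus, "annotated_locus"),
            inherits(cfg, "read_sim_config"))
  if (locus$record$topology != "circular") {
    stop("simulate_reads requires a circular molecule")
  }
  L <- nchar(locus$record$seq)
  if (cfg$mean_len >= L) stop("config error: mean_len >= molecule length")
  comp <- locus$truth$components
  if (is.null(comp)) {
    comp <- data.frame(name = "molecule", start = 0L, end = L)
  }
  doubled <- paste0(locus$record$seq, locus$record$seq)
  meanlog <- log(cfg$mean_len^2 / sqrt(cfg$mean_len^2 + cfg$sd_len^2))
  sdlog <- sqrt(log(1 + (cfg$sd_len / cfg$mean_len)^2))

  with_seed(cfg$seed, {
    starts <- floor(stats::runif(cfg$n_reads) * L)
    lens <- round(stats::rlnorm(cfg$n_reads, meanlog, sdlog))
    # truncate by redrawing out-of-range lengths
    bad <- which(lens < cfg$min_len | lens > L)
    tries <- 0L
    while (length(bad) > 0L && tries < 100L) {
      lens[bad] <- round(stats::rlnorm(length(bad), meanlog, sdlog))
      bad <- which(lens < cfg$min_len | lens > L)
      tries <- tries + 1L
    }
    if (length(bad) > 0L) lens[bad] <- pmin(pmax(lens[bad], cfg$min_len), L)

    reads <- vector("list", cfg$n_reads)
    truth <- vector("list", cfg$n_reads)
    ids <- sprintf("read_%05d", seq_len(cfg$n_reads))
    for (i in seq_len(cfg$n_reads)) {
      s <- starts[i]; l <- lens[i]
      raw <- substring(doubled, s + 1L, s + l)
      truth[[i]] <- read_truth_intervals(comp, s, l, L)
      x <- dna_to_int(raw)
      mut <- mutate_dna_int(x, cfg$sub_rate, cfg$ins_rate, cfg$del_rate)
      # generator output is already validated uppercase ACGT
      reads[[i]] <- structure(
        list(id = ids[i], seq = int_to_dna(mut), type = "DNA",
             topology = "linear",
             description = sprintf("src=%d len=%d", s, l)),
        class = "seq_record")
    }
    names(truth) <- ids
    structure(list(reads = reads, truth = truth), class = "read_set")
  })
}

# split the circular interval [s, s+l) into per-component truth segments
read_truth_intervals <- function(comp, s, l, L) {
  if (s + l <= L) {
    seg_s <- s; seg_e <- s + l; seg_r <- 0L
  } else {
    seg_s <- c(s, 0L); seg_e <- c(L, s + l - L); seg_r <- c(0L, L - s)
  }
  component <- character(0)
  read_start <- read_end <- src_start <- src_end <- integer(0)
  for (j in seq_along(seg_s)) {
    sel <- comp$end > seg_s[j] & comp$start < seg_e[j]
    if (!any(sel)) next
    st <- pmax(comp$start[sel], seg_s[j])
    en <- pmin(comp$end[sel], seg_e[j])
    component <- c(component, comp$name[sel])
    read_start <- c(read_start, seg_r[j] + (st - seg_s[j]))
    read_end <- c(read_end, seg_r[j] + (en - seg_s[j]))
    src_start <- c(src_start, st)
    src_end <- c(src_end, en)
  }
  o <- order(read_start)
  structure(list(component = component[o], read_start = read_start[o],
                 read_end = read_end[o], src_start = src_start[o],
                 src_end = src_end[o]),
            class = "data.frame", row.names = seq_along(o))
}

#' Derive an allele pair by deleting tandem units and adding divergence
#'
#' Allele A is the linear insert (flanks + units) of a [build_tandem_bac()]
#' molecule.  Allele B is allele A with the units in `deletion_plan`
#' removed and `divergence` substitutions per bp applied outside the
#' deleted spans (emulating allelic flank divergence).  Deletion
#' breakpoints are recorded in `$truth`.
#'
#' @param cfg an [array_config()].
#' @param deletion_plan integer vector of unit indices to delete from
#'   allele B.
#' @param divergence substitutions per bp outside deleted spans
#'   (default 0.02).
#' @return list with `allele_a`, `allele_b` (both [annotated_locus()]) and
#'   `truth` (deletion breakpoints in allele-A coordinates).
#' @export
build_allele_pair <- function(cfg = array_config(), deletion_plan = integer(0),
                              divergence = 0.02) {
  if (anyDuplicated(deletion_plan)) {
    stop("plan error: overlapping (duplicate) deletions")
  }
  if (length(deletion_plan) > 0L &&
      (min(deletion_plan) < 1L || max(deletion_plan) > cfg$n_units)) {
    stop("plan error: unit index out of range")
  }
  bac <- build_tandem_bac(cfg)
  ins_start <- cfg$vector_len
  L <- nchar(bac$record$seq)
  a_seq <- substring(bac$record$seq, ins_start + 1L, L)
  fa <- bac$features
  fa <- fa[!(fa$kind == "misc" & feat_attr(fa, "gene_name") == "vector"), ,
           drop = FALSE]
  fa$start <- fa$start - ins_start
  fa$end <- fa$end - ins_start
  fa$seq_id <- "allele_A"
  allele_a <- annotated_locus(seq_record("allele_A", a_seq), fa)

  # deletion spans in allele-A coordinates (contiguous runs merged)
  u0 <- cfg$flank_left_len
  del <- sort(unique(as.integer(deletion_plan)))
  spans <- NULL
  if (length(del) > 0L) {
    runs <- split(del, cumsum(c(1L, diff(del) != 1L)))
    spans <- do.call(rbind, lapply(runs, function(r) {
      data.frame(start = u0 + (min(r) - 1L) * cfg$unit_len,
                 end = u0 + max(r) * cfg$unit_len)
    }))
  }

  keep_mask <- rep(TRUE, nchar(a_seq))
  if (!is.null(spans)) {
    for (j in seq_len(nrow(spans))) {
      keep_mask[(spans$start[j] + 1L):spans$end[j]] <- FALSE
    }
  }
  with_seed(cfg$seed + 104729L, {
    x <- dna_to_int(a_seq)
    if (divergence > 0) {
      hit <- which(stats::runif(length(x)) < divergence & keep_mask & x < 4L)
      if (length(hit) > 0L) {
        x[hit] <- (x[hit] + sample.int(3L, length(hit), TRUE)) %% 4L
      }
    }
    b_seq <- int_to_dna(x[keep_mask])
  })

  # remap features: drop those touching a deleted span, shift the rest
  shift_of <- cumsum(!keep_mask)
  fb <- allele_a$features
  ok <- rep(TRUE, nrow(fb))
  if (!is.null(spans)) {
    for (j in seq_len(nrow(spans))) {
      ok <- ok & !(fb$start < spans$end[j] & fb$end > spans$start[j])
    }
  }
  fb <- fb[ok, , drop = FALSE]
  fb$start <- fb$start - ifelse(fb$start > 0L, shift_of[fb$start], 0L)
  fb$end <- fb$end - shift_of[fb$end]
  fb$seq_id <- "allele_B"
  allele_b <- annotated_locus(seq_record("allele_B", b_seq), fb)
  list(allele_a = allele_a, allele_b = allele_b,
       truth = list(deleted_units = del, deletion_spans_a = spans,
                    divergence = divergence))
}

#' Build a provenance pair: shared non-coding scaffold, divergent coding
#'
#' Two single-gene loci (a Gig2-like progenitor and an AFP-like gene)
#' share the 5' flank, non-coding exon 1, intron and 3' region at the
#' requested identity, while the coding part of exon 2 is either
#' point-diverged or wholly replaced by a GC-rich `(GCC)n` repeat
#' (the two coding-origin hypotheses).  `$truth` marks which segments are
#' homologous.
#'
#' @param shared_scaffold_identity fraction in (0.5, 1].
#' @param cds_model `"divergent"` or `"replaced"`.
#' @param seed integer seed.
#' @return list with `locus_a` (Gig2-like), `locus_b` (AFP-like) and
#'   `truth` (homologous segment table in both coordinate systems).
#' @export
build_provenance_pair <- function(shared_scaffold_identity = 0.85,
                                  cds_model = c("divergent", "replaced"),
                                  seed = 1L) {
  cds_model <- match.arg(cds_model)
  if (shared_scaffold_identity <= 0.5 || shared_scaffold_identity > 1) {
    stop("shared_scaffold_identity must be in (0.5, 1]")
  }
  with_seed(seed, {
    # Gig2-like protein: 147 aa, ~5% Ala
    aa_pool <- setdiff(names(REV_CODON), "A")
    prot_a <- c(sample(aa_pool, 147L, replace = TRUE))
    prot_a[1] <- "M"
    prot_a[sample(2:147, 7L)] <- "A"
    cds_a <- paste0(reverse_translate(paste(prot_a, collapse = "")), "TAA")

    flank5 <- random_dna_scrubbed(800L)
    exon1 <- random_dna_scrubbed(44L)
    intron <- random_dna_scrubbed(700L)
    utr5 <- random_dna_scrubbed(20L)
    utr3 <- random_dna_scrubbed(200L)
    flank3 <- random_dna_scrubbed(600L)

    seg_names <- c("flank5", "exon1", "intron", "utr5", "cds", "utr3",
                   "flank3")
    segs_a <- list(flank5, exon1, intron, utr5, cds_a, utr3, flank3)

    mut <- function(s, rate) {
      x <- dna_to_int(s)
      hit <- which(stats::runif(length(x)) < rate & x < 4L)
      if (length(hit) > 0L) {
        x[hit] <- (x[hit] + sample.int(3L, length(hit), TRUE)) %% 4L
      }
      int_to_dna(x)
    }
    rate <- 1 - shared_scaffold_identity
    cds_b <- if (cds_model == "replaced") {
      strrep("GCC", 40L)
    } else {
      mut(cds_a, 0.40)
    }
    segs_b <- lapply(seq_along(segs_a), function(i) {
      if (seg_names[i] == "cds") cds_b else mut(segs_a[[i]], rate)
    })

    assemble <- function(segs, id, gene_name) {
      lens <- vapply(segs, nchar, integer(1))
      ends <- cumsum(lens)
      starts <- c(0L, ends[-length(ends)])
      names(starts) <- names(ends) <- seg_names
      seq <- paste(unlist(segs), collapse = "")
      ga <- list(c(gene_name = gene_name))
      feats <- rbind_features(
        feature_table(id, starts["exon1"], ends["utr3"], "+", "gene", ga),
        feature_table(id, starts["exon1"], ends["exon1"], "+", "exon", ga),
        feature_table(id, starts["intron"], ends["intron"], "+", "intron", ga),
        feature_table(id, starts["utr5"], ends["utr3"], "+", "exon", ga),
        feature_table(id, starts["cds"], ends["cds"], "+", "CDS", ga))
      list(locus = annotated_locus(seq_record(id, seq), feats),
           starts = starts, ends = ends)
    }
    a <- assemble(segs_a, "gig2_locus", "Gig2")
    b <- assemble(segs_b, "afp_locus", "S")
    hom <- seg_names[seg_names != "cds"]
    truth <- data.frame(segment = hom,
                        a_start = unname(a$starts[hom]),
                        a_end = unname(a$ends[hom]),
                        b_start = unname(b$starts[hom]),
                        b_end = unname(b$ends[hom]),
                        stringsAsFactors = FALSE)
    list(locus_a = a$locus, locus_b = b$locus, truth = truth,
         cds_a = c(unname(a$starts["cds"]), unname(a$ends["cds"])),
         cds_b = c(unname(b$starts["cds"]), unname(b$ends["cds"])))
  })
}

#' Build toy loci realizing per-species gene orders
#'
#' @param orders named list: species -> character vector of gene names in
#'   chromosomal order (prefix `-` for minus strand).
#' @param focal focal gene family name (duplicates of this name are
#'   allowed within a locus; any other duplicate is an error).
#' @param seed integer seed.
#' @return named list of [annotated_locus()].
#' @export
build_synteny_scenario <- function(orders, focal = "Gig2", seed = 1L) {
  stopifnot(is.list(orders), length(orders) > 0L,
            !is.null(names(orders)))
  with_seed(seed, {
    out <- lapply(names(orders), function(sp) {
      genes <- orders[[sp]]
      if (length(genes) == 0L) stop("empty gene list for ", sp)
      strand <- ifelse(startsWith(genes, "-"), "-", "+")
      names_clean <- sub("^-", "", genes)
      non_focal <- names_clean[tolower(names_clean) != tolower(focal)]
      if (anyDuplicated(non_focal)) {
        stop("spec error: duplicate gene name in ", sp, ": ",
             non_focal[duplicated(non_focal)][1])
      }
      glen <- 300L; gap <- 200L
      n <- length(genes)
      starts <- gap + (seq_len(n) - 1L) * (glen + gap)
      seq <- random_dna(gap + n * (glen + gap))
      feats <- feature_table(sp, starts, starts + glen, strand, "gene",
                             lapply(names_clean,
                                    function(g) c(gene_name = g)))
      annotated_locus(seq_record(sp, seq), feats)
    })
    names(out) <- names(orders)
    out
  })
}
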