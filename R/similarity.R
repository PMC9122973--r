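# Local homology mapping between loci: optimal pairwise identities,
# seed-and-extend block detection, feature-class annotation of blocks
# (the coding vs non-coding contrast), tandem-period estimation and
# exon-window matching.
#
# Identity is always matches / alignment columns, with gap columns in the
# denominator and N never counting as a match.

dna_subst_matrix <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

alignment_identity <- function(al) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  columns <- length(p)
  matches <- sum(p == s & p != "-" & p != "N")
  list(matches = matches, columns = columns,
       identity = if (columns > 0) matches / columns else 0)
}

#' Optimal global alignment identity between two sequences
#'
#' Needleman-Wunsch under declared scoring (DNA defaults +1/-1, gap open 2
#' extend 1; protein BLOSUM62, gap open 10 extend 1).  Identity is
#' matches / alignment columns; gap columns count in the denominator and
#' N bases never count as matches.
#'
#' @param a,b [seq_record()] of the same molecule type (or plain strings,
#'   assumed DNA).
#' @param match,mismatch DNA scores (ignored for protein).
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return list of class `identity_result`: `matches`, `columns`,
#'   `identity`, `score`, `a_span`, `b_span` (0-based half-open).
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1,
                            gap_open = NULL, gap_extend = 1) {
  if (is.character(a)) a <- seq_record("a", a)
  if (is.character(b)) b <- seq_record("b", b)
  if (a$type != b$type) stop("molecule-type mismatch")
  if (!nzchar(a$seq) || !nzchar(b$seq)) stop("empty sequence")
  if (a$type == "DNA") {
    sm <- dna_subst_matrix(match, mismatch)
    go <- gap_open %||% 2
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a$seq), Biostrings::DNAString(b$seq),
      type = "global", substitutionMatrix = sm,
      gapOpening = go, gapExtension = gap_extend)
  } else {
    go <- gap_open %||% 10
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a$seq), Biostrings::AAString(b$seq),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = go, gapExtension = gap_extend)
  }
  idn <- alignment_identity(al)
  structure(c(idn, list(
    score = Biostrings::score(al),
    a_span = c(Biostrings::start(Biostrings::pattern(al)) - 1L,
               Biostrings::end(Biostrings::pattern(al))),
    b_span = c(Biostrings::start(Biostrings::subject(al)) - 1L,
               Biostrings::end(Biostrings::subject(al))))),
    class = "identity_result")
}

# forward (strand-specific) 2-bit rolling hashes; NA where the window
# contains a non-ACGT base
forward_hashes <- function(seq, k) {
  x <- dna_to_int(seq)
  n <- length(x)
  if (n < k) return(numeric(0))
  h <- numeric(n - k + 1L)
  for (j in seq_len(k)) h <- h * 4 + x[j:(n - k + j)]
  bad <- cumsum(x >= 4L)
  nb <- bad[k:n] - c(0, bad[seq_len(n - k)])
  h[nb > 0] <- NA_real_
  h
}

scan_one_strand <- function(a_seq, b_seq, seed_len, min_len, min_identity,
                            max_gap, band) {
  ha <- forward_hashes(a_seq, seed_len)
  hb <- forward_hashes(b_seq, seed_len)
  da <- data.table::data.table(h = ha, apos = seq_along(ha) - 1L)[!is.na(h)]
  db <- data.table::data.table(h = hb, bpos = seq_along(hb) - 1L)[!is.na(h)]
  seeds <- merge(da, db, by = "h", allow.cartesian = TRUE)
  if (nrow(seeds) == 0L) return(NULL)
  seeds[, diag := apos - bpos]
  data.table::setorder(seeds, diag, apos)
  brk <- c(FALSE, diff(seeds$diag) > band | abs(diff(seeds$apos)) > max_gap)
  seeds[, cluster := cumsum(brk)]
  cl <- seeds[, .(a0 = min(apos), a1 = max(apos) + seed_len,
                  b0 = min(bpos), b1 = max(bpos) + seed_len,
                  n = .N), by = cluster]
  cl <- cl[n >= 2L & (a1 - a0) >= min_len / 2]
  if (nrow(cl) == 0L) return(NULL)

  pad <- 100L
  la <- nchar(a_seq); lb <- nchar(b_seq)
  out <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    a0 <- max(0L, cl$a0[i] - pad); a1 <- min(la, cl$a1[i] + pad)
    b0 <- max(0L, cl$b0[i] - pad); b1 <- min(lb, cl$b1[i] + pad)
    sa <- substring(a_seq, a0 + 1L, a1)
    sb <- substring(b_seq, b0 + 1L, b1)
    if (sa == sb) {
      # identical candidate regions need no DP
      out[[i]] <- data.frame(a_start = a0, a_end = a1, b_start = b0,
                             b_end = b1, matches = nchar(sa),
                             columns = nchar(sa), identity = 1,
                             score = 2 * nchar(sa))
      next
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sa), Biostrings::DNAString(sb), type = "local",
      substitutionMatrix = dna_subst_matrix(2, -3),
      gapOpening = 5, gapExtension = 2)
    idn <- alignment_identity(al)
    if (idn$columns == 0L) next
    out[[i]] <- data.frame(
      a_start = a0 + Biostrings::start(Biostrings::pattern(al)) - 1L,
      a_end = a0 + Biostrings::end(Biostrings::pattern(al)),
      b_start = b0 + Biostrings::start(Biostrings::subject(al)) - 1L,
      b_end = b0 + Biostrings::end(Biostrings::subject(al)),
      matches = idn$matches, columns = idn$columns,
      identity = idn$identity, score = Biostrings::score(al))
  }
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Find local similarity blocks between two loci
#'
#' Exact seed matches of length `seed_len` are chained along diagonals,
#' candidate regions are re-scored by optimal local alignment (so reported
#' identities are exact), blocks overlapping >= 50% on both axes collapse
#' to the higher-scoring one, and both strands are scanned.  Coordinates
#' are always reported on the forward strand of each locus.
#'
#' @param a,b [annotated_locus()] or [seq_record()].
#' @param seed_len exact seed length (>= 8, default 12).
#' @param min_len minimum block alignment columns (default 100).
#' @param min_identity minimum block identity (default 0.70).
#' @param max_gap,band seed-chaining parameters in bp.
#' @param both_strands scan the reverse strand of `b` too.
#' @return data.frame of class `similarity_blocks`, sorted by `a_start`.
#' @export
local_blocks <- function(a, b, seed_len = 12L, min_len = 100L,
                         min_identity = 0.70, max_gap = 400L, band = 50L,
                         both_strands = TRUE) {
  if (seed_len < 8L) stop("seed_len must be >= 8")
  a_seq <- if (inherits(a, "annotated_locus")) a$record$seq else a$seq
  b_seq <- if (inherits(b, "annotated_locus")) b$record$seq else b$seq
  fwd <- scan_one_strand(a_seq, b_seq, seed_len, min_len, min_identity,
                         max_gap, band)
  if (!is.null(fwd) && nrow(fwd) > 0L) fwd$strand <- "+"
  rev <- NULL
  if (both_strands) {
    rev <- scan_one_strand(a_seq, revcomp(b_seq), seed_len, min_len,
                           min_identity, max_gap, band)
    if (!is.null(rev) && nrow(rev) > 0L) {
      lb <- nchar(b_seq)
      b0 <- lb - rev$b_end; b1 <- lb - rev$b_start
      rev$b_start <- b0; rev$b_end <- b1
      rev$strand <- "-"
    }
  }
  blocks <- rbind(fwd, rev)
  if (is.null(blocks) || nrow(blocks) == 0L) return(empty_blocks())
  blocks <- blocks[blocks$columns >= min_len &
                     blocks$identity >= min_identity, , drop = FALSE]
  if (nrow(blocks) == 0L) return(empty_blocks())
  blocks <- merge_blocks(blocks)
  blocks <- blocks[order(blocks$a_start, blocks$b_start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks$feature_class <- NA_character_
  class(blocks) <- c("similarity_blocks", "data.frame")
  blocks
}

empty_blocks <- function() {
  b <- data.frame(a_start = integer(0), a_end = integer(0),
                  b_start = integer(0), b_end = integer(0),
                  matches = integer(0), columns = integer(0),
                  identity = numeric(0), score = numeric(0),
                  strand = character(0), feature_class = character(0))
  class(b) <- c("similarity_blocks", "data.frame")
  b
}

# collapse blocks whose projections overlap >= 50% on both axes
merge_blocks <- function(blocks) {
  blocks <- blocks[order(-blocks$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(blocks))
  ov_frac <- function(s1, e1, s2, e2) {
    ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
    ov / pmin(e1 - s1, e2 - s2)
  }
  for (i in seq_len(nrow(blocks))[-1]) {
    if (!keep[i]) next
    prev <- which(keep[seq_len(i - 1L)])
    fa <- ov_frac(blocks$a_start[prev], blocks$a_end[prev],
                  blocks$a_start[i], blocks$a_end[i])
    fb <- ov_frac(blocks$b_start[prev], blocks$b_end[prev],
                  blocks$b_start[i], blocks$b_end[i])
    if (any(fa >= 0.5 & fb >= 0.5 &
              blocks$strand[prev] == blocks$strand[i])) keep[i] <- FALSE
  }
  blocks[keep, , drop = FALSE]
}

# per-base feature class along a locus: coding > intron > UTR/non-coding
# exon > intergenic
base_classes <- function(locus) {
  L <- nchar(locus$record$seq)
  cls <- rep(4L, L)                    # intergenic
  f <- locus$features
  paint <- function(kinds, code) {
    ff <- f[f$kind %in% kinds, , drop = FALSE]
    for (j in seq_len(nrow(ff))) {
      cls[(ff$start[j] + 1L):ff$end[j]] <<- code
    }
  }
  paint(c("exon", "five_prime_UTR", "three_prime_UTR"), 3L)
  paint("intron", 2L)
  paint("CDS", 1L)
  cls
}

CLASS_NAMES <- c("coding", "intron", "UTR/non-coding-exon", "intergenic")

#' Annotate similarity blocks with feature classes and summarize contrast
#'
#' Each block is classified by majority base overlap (>= 60%, else
#' `mixed`) against the a-side annotation.  The summary aggregates
#' block-covered bases by class and reports the non-coding vs coding
#' coverage ratio that quantifies provenance from a non-coding scaffold.
#'
#' @param blocks result of [local_blocks()].
#' @param a the a-side [annotated_locus()] (source of the feature classes).
#' @return list of class `contrast_summary`: `blocks` (with
#'   `feature_class` filled), `summary` (per class: matched_bases,
#'   total_bases, coverage), `noncoding_coding_ratio`.
#' @export
annotate_blocks <- function(blocks, a) {
  stopifnot(inherits(a, "annotated_locus"))
  cls <- base_classes(a)
  L <- length(cls)
  covered <- rep(FALSE, L)
  if (nrow(blocks) > 0L) {
    for (i in seq_len(nrow(blocks))) {
      span <- (blocks$a_start[i] + 1L):min(blocks$a_end[i], L)
      covered[span] <- TRUE
      tab <- tabulate(cls[span], nbins = 4L)
      top <- which.max(tab)
      blocks$feature_class[i] <-
        if (tab[top] / sum(tab) >= 0.60) CLASS_NAMES[top] else "mixed"
    }
  }
  summary <- data.frame(
    feature_class = CLASS_NAMES,
    matched_bases = vapply(1:4, function(cc) sum(covered & cls == cc),
                           integer(1)),
    total_bases = tabulate(cls, nbins = 4L))
  summary$coverage <- ifelse(summary$total_bases > 0,
                             summary$matched_bases / summary$total_bases, NA)
  nc <- summary[summary$feature_class != "coding", ]
  noncoding_cov <- sum(nc$matched_bases) / max(1L, sum(nc$total_bases))
  coding_cov <- summary$coverage[summary$feature_class == "coding"]
  ratio <- if (is.na(coding_cov)) NA_real_
           else if (coding_cov == 0) Inf else noncoding_cov / coding_cov
  structure(list(blocks = blocks, summary = summary,
                 noncoding_coding_ratio = ratio),
            class = "contrast_summary")
}

#' Best-match identity of each query against a reference set
#'
#' For each record in `set_a`, [global_identity()] against every record in
#' `set_b`; reports the argmax and the unweighted mean of the per-query
#' maxima.
#'
#' @param set_a,set_b lists of [seq_record()] of one molecule type.
#' @return list of class `closest_match_result`: `per_query` data frame
#'   and `mean_identity`.
#' @export
closest_match_identity <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) stop("empty input set")
  types <- unique(c(vapply(set_a, `[[`, "", "type"),
                    vapply(set_b, `[[`, "", "type")))
  if (length(types) != 1L) stop("molecule-type mismatch")
  rows <- lapply(set_a, function(qa) {
    idn <- vapply(set_b, function(qb) global_identity(qa, qb)$identity,
                  numeric(1))
    best <- which.max(idn)
    data.frame(a_id = qa$id, best_b_id = set_b[[best]]$id,
               best_identity = idn[best], stringsAsFactors = FALSE)
  })
  per_query <- do.call(rbind, rows)
  structure(list(per_query = per_query,
                 mean_identity = mean(per_query$best_identity)),
            class = "closest_match_result")
}

#' Estimate the tandem period of a repeat region
#'
#' The period is read off the dominant off-diagonal of a seed
#' self-comparison (histogram of spacings between successive occurrences
#' of each k-mer), reported to the nearest 100 bp, and unit boundaries are
#' phased to maximize inter-unit identity.  Absence of a dominant
#' off-diagonal is a `no tandem structure` result, not an error.
#'
#' @param locus an [annotated_locus()] or [seq_record()].
#' @param region optional `c(start, end)` 0-based half-open search region.
#' @param k seed length (default 15).
#' @param bin histogram bin width in bp (default 100).
#' @return list of class `tandem_period`: `tandem` (logical), `period`
#'   (bp, nearest 100), `period_raw`, `boundaries`, `n_units_est`.
#' @export
tandem_period <- function(locus, region = NULL, k = 15L, bin = 100L) {
  seq <- if (inherits(locus, "annotated_locus")) locus$record$seq
         else locus$seq
  if (!is.null(region)) {
    seq <- substring(seq, region[1] + 1L, region[2])
  } else {
    region <- c(0L, nchar(seq))
  }
  h <- forward_hashes(seq, k)
  dt <- data.table::data.table(h = h, pos = seq_along(h) - 1L)[!is.na(h)]
  data.table::setorder(dt, h, pos)
  same <- c(FALSE, diff(dt$h) == 0)
  diffs <- diff(dt$pos)[same[-1]]
  diffs <- diffs[diffs >= k]
  no_structure <- list(tandem = FALSE, period = NA_real_,
                       period_raw = NA_real_, boundaries = NULL,
                       n_units_est = NA_real_)
  class(no_structure) <- "tandem_period"
  if (length(diffs) < 20L) return(no_structure)
  bins <- round(diffs / bin)
  tab <- table(bins)
  top <- which.max(tab)
  if (tab[top] < 20L || tab[top] < 0.2 * length(diffs)) return(no_structure)
  period_raw <- mean(diffs[bins == as.integer(names(tab)[top])])
  period <- round(period_raw / 100) * 100

  # phase boundaries on a coarse grid to maximize adjacent-unit identity
  p <- as.integer(round(period_raw))
  L <- nchar(seq)
  n_units <- floor(L / p)
  if (n_units < 2L) return(no_structure)
  phase_grid <- seq(0L, p - 1L, by = max(1L, p %/% 56L))
  sc <- vapply(phase_grid, function(ph) {
    n_fit <- floor((L - ph) / p)
    if (n_fit < 2L) return(-1)
    tot <- 0; m <- 0
    for (u in seq_len(n_fit - 1L)) {
      s1 <- substring(seq, ph + (u - 1L) * p + 1L, ph + u * p)
      s2 <- substring(seq, ph + u * p + 1L, ph + (u + 1L) * p)
      v1 <- utf8ToInt(s1); v2 <- utf8ToInt(s2)
      m <- m + sum(v1 == v2); tot <- tot + length(v1)
    }
    m / tot
  }, numeric(1))
  best_ph <- phase_grid[which.max(sc)]
  n_fit <- floor((L - best_ph) / p)
  boundaries <- region[1] + best_ph + (0:n_fit) * p
  structure(list(tandem = TRUE, period = period, period_raw = period_raw,
                 boundaries = boundaries, n_units_est = n_fit,
                 phase_identity = max(sc)),
            class = "tandem_period")
}

#' Match an exon against another locus
#'
#' Best local alignment of the exon (plus optional flank) against `b`,
#' on either strand; matches are counted over the exon-only window and
#' the denominator is the exon length.
#'
#' @param a an [annotated_locus()].
#' @param a_exon one exon row of `a$features`.
#' @param b [annotated_locus()] or [seq_record()].
#' @param flank bp of context added to each side of the exon (default 0).
#' @return list: `matches`, `columns` (= exon length), `identity`,
#'   `strand`.
#' @export
exon_window_matches <- function(a, a_exon, b, flank = 0L) {
  stopifnot(nrow(a_exon) == 1L)
  if (a_exon$kind != "exon") stop("a_exon must be an exon feature")
  b_seq <- if (inherits(b, "annotated_locus")) b$record$seq else b$seq
  exon_len <- a_exon$end - a_exon$start
  w0 <- max(0L, a_exon$start - flank)
  w1 <- min(nchar(a$record$seq), a_exon$end + flank)
  pat <- substring(a$record$seq, w0 + 1L, w1)
  ex_lo <- a_exon$start - w0          # exon window within pattern, 0-based
  ex_hi <- ex_lo + exon_len

  best <- NULL
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") b_seq else revcomp(b_seq)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pat), Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = dna_subst_matrix(2, -3),
      gapOpening = 5, gapExtension = 2)
    if (is.null(best) || Biostrings::score(al) > best$score) {
      best <- list(al = al, score = Biostrings::score(al), strand = strand)
    }
  }
  if (best$score <= 0) {
    return(list(matches = 0L, columns = exon_len, identity = 0,
                strand = NA_character_))
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(best$al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(best$al)), "")[[1]]
  ppos <- Biostrings::start(Biostrings::pattern(best$al)) - 1L
  matches <- 0L
  for (i in seq_along(p)) {
    if (p[i] != "-") {
      if (ppos >= ex_lo && ppos < ex_hi &&
            p[i] == s[i] && p[i] != "N") matches <- matches + 1L
      ppos <- ppos + 1L
    }
  }
  list(matches = matches, columns = exon_len,
       identity = matches / exon_len, strand = best$strand)
}

#' Dot-plot coordinates from exact seed matches
#'
#' @param a,b loci or records.
#' @param seed_len exact seed length.
#' @return data.frame with `a_pos`, `b_pos` (0-based seed starts),
#'   forward strand only.
#' @export
dotplot_coords <- function(a, b, seed_len = 12L) {
  a_seq <- if (inherits(a, "annotated_locus")) a$record$seq else a$seq
  b_seq <- if (inherits(b, "annotated_locus")) b$record$seq else b$seq
  ha <- forward_hashes(a_seq, seed_len)
  hb <- forward_hashes(b_seq, seed_len)
  da <- data.table::data.table(h = ha, a_pos = seq_along(ha) - 1L)[!is.na(h)]
  db <- data.table::data.table(h = hb, b_pos = seq_along(hb) - 1L)[!is.na(h)]
  m <- merge(da, db, by = "h", allow.cartesian = TRUE)
  data.table::setorder(m, a_pos, b_pos)
  as.data.frame(m[, .(a_pos, b_pos)])
}
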