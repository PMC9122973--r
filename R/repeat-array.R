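# Tandem-array copy number from long-read category counts, and resolution
# of the outer units by anchoring reads to flank polymorphisms.  Counting
# and anchoring are separate deliverables: interior units of a
# near-identical array are deliberately never assembled.

#' Reference components for read classification
#'
#' @param vector,flank_left,flank_right,unit_consensus DNA sequences
#'   (character or [seq_record()]).
#' @return list of class `component_reference`.
#' @export
component_reference <- function(vector, flank_left, flank_right,
                                unit_consensus) {
  as_chr <- function(x) if (inherits(x, "seq_record")) x$seq else toupper(x)
  ref <- list(vector = as_chr(vector), flank_left = as_chr(flank_left),
              flank_right = as_chr(flank_right),
              unit_consensus = as_chr(unit_consensus))
  stopifnot(all(vapply(ref, nchar, integer(1)) > 0L))
  class(ref) <- "component_reference"
  ref
}

#' Component reference from a synthetic BAC's ground truth
#'
#' @param bac result of [build_tandem_bac()].
#' @return a [component_reference()].
#' @export
component_reference_from_truth <- function(bac) {
  tr <- bac$truth
  if (is.null(tr)) stop("locus carries no generator truth")
  component_reference(tr$vector, tr$flank_left, tr$flank_right,
                      tr$unit_template)
}

#' Classify reads into vector / flank / repeat / ambiguous categories
#'
#' Error-tolerant canonical k-mer voting: each 500-bp read window is
#' assigned to the component sharing the most k-mers with it (ties or no
#' votes give `ambiguous`), and a read's bases are split across categories
#' by window.  In read mode a read goes to its majority-base category.
#' K-mers shared between two reference components are discarded up front.
#'
#' @param reads a `read_set` (or plain list of [seq_record()]).
#' @param ref a [component_reference()].
#' @param k k-mer size (>= 11, <= 26; default 15).
#' @param window window size in bp for proportional base assignment.
#' @return list of class `category_counts`: `totals` (category,
#'   read_count, base_count), `per_read`, `n_reads_total`, and a
#'   `degenerate` flag set when every read is ambiguous.
#' @export
classify_reads <- function(reads, ref, k = 15L, window = 500L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (length(reads) == 0L) stop("no reads supplied")
  if (k < 11L) stop("k must be >= 11")
  stopifnot(inherits(ref, "component_reference"))

  sets <- list(
    vector = c_kmer_set(ref$vector, k),
    flank = sort(unique(c(c_kmer_set(ref$flank_left, k),
                          c_kmer_set(ref$flank_right, k)))),
    repeat_ = c_kmer_set(ref$unit_consensus, k))
  # drop k-mers claimed by more than one component
  shared <- c(intersect(sets$vector, sets$flank),
              intersect(sets$vector, sets$repeat_),
              intersect(sets$flank, sets$repeat_))
  if (length(shared) > 0L) {
    sets <- lapply(sets, function(s) setdiff(s, shared))
  }

  ids <- vapply(reads, function(r) r$id, character(1))
  seqs <- vapply(reads, function(r) r$seq, character(1))
  votes <- c_window_votes(seqs, as.integer(k), as.integer(window), sets)

  cats <- c("vector", "flank", "repeat", "ambiguous")
  per_read <- matrix(0, nrow = length(reads), ncol = 4L,
                     dimnames = list(NULL, cats))
  for (i in seq_along(reads)) {
    v <- votes[[i]]
    len <- nchar(seqs[i])
    nwin <- nrow(v)
    widths <- rep(window, nwin)
    widths[nwin] <- len - (nwin - 1L) * window
    top <- max.col(v, ties.method = "first")
    best <- v[cbind(seq_len(nwin), top)]
    n_best <- rowSums(v == best)
    amb <- best == 0L | n_best > 1L
    wcat <- ifelse(amb, 4L, top)
    for (j in seq_len(nwin)) {
      per_read[i, wcat[j]] <- per_read[i, wcat[j]] + widths[j]
    }
  }
  read_cat <- cats[max.col(per_read, ties.method = "first")]
  ties <- rowSums(per_read == per_read[cbind(seq_len(nrow(per_read)),
                                             max.col(per_read))]) > 1L
  read_cat[ties] <- "ambiguous"

  per_read_df <- data.frame(id = ids, per_read, category = read_cat,
                            stringsAsFactors = FALSE)
  names(per_read_df)[2:5] <- cats
  totals <- data.frame(
    category = cats,
    read_count = vapply(cats, function(cc) sum(read_cat == cc), integer(1)),
    base_count = vapply(cats, function(cc) sum(per_read_df[[cc]]),
                        numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  degenerate <- all(read_cat == "ambiguous")
  if (degenerate) warning("degenerate input: all reads ambiguous")
  structure(list(totals = totals, per_read = per_read_df,
                 n_reads_total = length(reads), k = k, window = window,
                 degenerate = degenerate),
            class = "category_counts")
}

#' Estimate tandem-unit copy number from category counts
#'
#' Point estimate `n_hat = (C_repeat / C_vector) * (L_vector / L_unit)`
#' where C is the base count (default) or read count of each category; the
#' ambiguous category is excluded from both numerator and denominator.
#' Uncertainty is a nonparametric bootstrap over reads (reads are resampled
#' after a canonical sort by id, so the estimate is invariant to input
#' order); an analytic ratio-of-Poissons SE on read counts is also
#' reported for comparison.
#'
#' @param counts a `category_counts` from [classify_reads()].
#' @param ref the [component_reference()] used for classification.
#' @param mode `"bases"` (default) or `"reads"`.
#' @param B bootstrap replicates (default 1000; 0 skips the bootstrap).
#' @param seed bootstrap seed.
#' @return list of class `copy_number_estimate` with `n_hat`, `se`,
#'   `ci95`, `se_poisson`, `mode`, `B`, `n_reads_used`.
#' @export
estimate_copy_number <- function(counts, ref, mode = c("bases", "reads"),
                                 B = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "category_counts"),
            inherits(ref, "component_reference"))
  L_vector <- nchar(ref$vector)
  L_unit <- nchar(ref$unit_consensus)
  scale <- L_vector / L_unit

  pr <- counts$per_read[order(counts$per_read$id), , drop = FALSE]
  stat <- function(rows) {
    d <- pr[rows, , drop = FALSE]
    if (mode == "bases") {
      c(r = sum(d[["repeat"]]), v = sum(d[["vector"]]))
    } else {
      c(r = sum(d$category == "repeat"), v = sum(d$category == "vector"))
    }
  }
  full <- stat(seq_len(nrow(pr)))
  if (full["v"] == 0) stop("estimation error: no vector support")
  n_hat <- unname(full["r"] / full["v"]) * scale

  se <- ci <- NA_real_
  ci95 <- c(NA_real_, NA_real_)
  if (B > 0L) {
    boots <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        rows <- sample.int(nrow(pr), nrow(pr), replace = TRUE)
        s <- stat(rows)
        if (s["v"] == 0) NA_real_ else unname(s["r"] / s["v"]) * scale
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 2L) {
      se <- stats::sd(boots)
      ci95 <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
      # guarantee the invariant ci95 contains n_hat even at small B
      ci95[1] <- min(ci95[1], n_hat)
      ci95[2] <- max(ci95[2], n_hat)
    }
  }
  nr <- sum(pr$category == "repeat")
  nv <- sum(pr$category == "vector")
  se_pois <- if (nr > 0 && nv > 0) n_hat * sqrt(1 / nr + 1 / nv) else NA_real_

  structure(list(n_hat = n_hat, se = se, ci95 = ci95,
                 se_poisson = se_pois, mode = mode, B = as.integer(B),
                 n_reads_used = nrow(pr),
                 degenerate = isTRUE(counts$degenerate),
                 category_table = counts$totals),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("Tandem-unit copy number: %.1f +/- %.1f (95%% CI %.1f-%.1f), %s mode, %d reads\n",
              x$n_hat, x$se, x$ci95[1], x$ci95[2], x$mode, x$n_reads_used))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Outer-unit resolution by flank anchoring

# evenly spaced probes from a flank that occur exactly once across all
# reference components
flank_anchors <- function(flank, ref_all, anchor_len = 31L, n_anchors = 40L) {
  n <- nchar(flank)
  if (n < anchor_len) return(data.frame(kmer = character(0), pos = integer(0)))
  pos <- unique(round(seq(1L, n - anchor_len + 1L,
                          length.out = min(n_anchors, n - anchor_len + 1L))))
  kmer <- substring(flank, pos, pos + anchor_len - 1L)
  keep <- vapply(kmer, function(km) {
    hits <- sum(vapply(ref_all, function(s) {
      length(c_exact_hits(s, km)[[1]]) +
        length(c_exact_hits(s, revcomp(km))[[1]])
    }, numeric(1)))
    hits == 1L
  }, logical(1))
  data.frame(kmer = kmer[keep], pos = pos[keep] - 1L,
             stringsAsFactors = FALSE)
}

# per-consensus-position read base calls from a local alignment
alignment_calls <- function(al) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  cp <- Biostrings::start(Biostrings::pattern(al)) - 1L
  cons_pos <- integer(0); base <- character(0)
  for (i in seq_along(p)) {
    if (p[i] != "-") {
      cp <- cp + 1L
      if (s[i] != "-") {
        cons_pos <- c(cons_pos, cp)
        base <- c(base, s[i])
      }
    }
  }
  data.frame(cons_pos = cons_pos, base = base, stringsAsFactors = FALSE)
}

#' Resolve outer tandem units by anchoring reads to the flanks
#'
#' Reads containing a unique exact anchor k-mer from a flank are oriented
#' and walked unit-by-unit against the unit consensus.  Substitution
#' variants are called per unit when at least `min_support` anchored reads
#' agree (and outvote the consensus base); `units_resolved_left/right` is
#' the number of consecutive units (fractional) over which every consensus
#' position retains `min_support` anchored coverage.
#'
#' @param reads a `read_set` or list of [seq_record()].
#' @param ref a [component_reference()].
#' @param min_support minimum agreeing anchored reads (default 3).
#' @param anchor_len anchor k-mer length (default 31).
#' @param max_units walk depth bound per side (default 20).
#' @return list of class `anchored_resolution`: `units_resolved_left`,
#'   `units_resolved_right`, `variants`, `n_anchored_left/right`.
#' @export
anchor_assemble <- function(reads, ref, min_support = 3L, anchor_len = 31L,
                            max_units = 20L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  stopifnot(inherits(ref, "component_reference"))
  U <- nchar(ref$unit_consensus)
  ref_all <- list(ref$vector, ref$flank_left, ref$flank_right,
                  ref$unit_consensus)
  anch <- list(
    left = flank_anchors(ref$flank_left, ref_all, anchor_len),
    right = flank_anchors(ref$flank_right, ref_all, anchor_len))
  if (nrow(anch$left) == 0L && nrow(anch$right) == 0L) {
    warning("no usable flank anchors")
  }

  cov <- list(left = matrix(0L, nrow = max_units, ncol = U),
              right = matrix(0L, nrow = max_units, ncol = U))
  vote_keys <- list(left = list(), right = list())
  n_anchored <- c(left = 0L, right = 0L)
  cons_chars <- strsplit(ref$unit_consensus, "")[[1]]

  orient_read <- function(sq, a) {
    # returns list(seq, anchor_flank_pos, anchor_read_pos) or NULL
    for (s in c(sq, revcomp(sq))) {
      hits <- c_exact_hits(s, a$kmer)
      nh <- vapply(hits, length, integer(1))
      hit_i <- which(nh > 0L)
      if (length(hit_i) > 0L) {
        # use the median implied offset across anchor hits
        offs <- unlist(lapply(hit_i, function(j) hits[[j]] - a$pos[j]))
        return(list(seq = s, offset = stats::median(offs)))
      }
    }
    NULL
  }

  walk <- function(sq, insert_off, side) {
    # insert_off: read offset (0-based) of unit-1 start for this side
    # (left: first unit after flank_left; right: first unit before
    # flank_right, walking away from it)
    len <- nchar(sq)
    for (u in seq_len(max_units)) {
      if (side == "left") {
        lo <- insert_off + (u - 1L) * U
        hi <- lo + U
      } else {
        hi <- insert_off - (u - 1L) * U
        lo <- hi - U
      }
      pad <- ceiling(0.15 * U)
      s0 <- max(0L, lo - pad); s1 <- min(len, hi + pad)
      if (s1 - s0 < 0.3 * U) break
      seg <- substring(sq, s0 + 1L, s1)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(ref$unit_consensus),
        Biostrings::DNAString(seg),
        type = "local",
        substitutionMatrix = dna_subst_matrix(2, -3),
        gapOpening = 5, gapExtension = 2)
      calls <- alignment_calls(al)
      if (nrow(calls) < 0.2 * U && s1 - s0 >= U) break
      if (nrow(calls) == 0L) break
      cov[[side]][u, calls$cons_pos] <<- cov[[side]][u, calls$cons_pos] + 1L
      mism <- calls[calls$base != cons_chars[calls$cons_pos] &
                      calls$base %in% c("A", "C", "G", "T"), , drop = FALSE]
      if (nrow(mism) > 0L) {
        keys <- sprintf("%d:%d:%s", u, mism$cons_pos, mism$base)
        vk <- vote_keys[[side]]
        for (key in keys) vk[[key]] <- (vk[[key]] %||% 0L) + 1L
        vote_keys[[side]] <<- vk
      }
      if ((side == "left" && hi >= len) || (side == "right" && lo <= 0L)) break
    }
  }

  for (r in reads) {
    done <- FALSE
    if (nrow(anch$left) > 0L) {
      o <- orient_read(r$seq, anch$left)
      if (!is.null(o)) {
        insert_off <- o$offset + nchar(ref$flank_left)
        n_anchored["left"] <- n_anchored["left"] + 1L
        walk(o$seq, insert_off, "left")
        done <- TRUE
      }
    }
    if (nrow(anch$right) > 0L) {
      o <- orient_read(r$seq, anch$right)
      if (!is.null(o)) {
        n_anchored["right"] <- n_anchored["right"] + 1L
        walk(o$seq, o$offset, "right")
      }
    }
  }

  if (sum(n_anchored) == 0L) warning("no anchored reads; resolution 0/0")

  resolved <- function(side) {
    cc <- cov[[side]]
    if (side == "right") cc <- cc[, rev(seq_len(U)), drop = FALSE]
    flat <- as.vector(t(cc))           # unit 1 pos 1..U, unit 2 ...
    ok <- flat >= min_support
    first_bad <- which(!ok)[1]
    n_ok <- if (is.na(first_bad)) length(ok) else first_bad - 1L
    n_ok / U
  }
  var_df <- do.call(rbind, lapply(c("left", "right"), function(side) {
    vk <- vote_keys[[side]]
    if (length(vk) == 0L) return(NULL)
    parts <- strsplit(names(vk), ":")
    d <- data.frame(side = side,
                    unit = as.integer(vapply(parts, `[`, "", 1L)),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    alt = vapply(parts, `[`, "", 3L),
                    support = unlist(vk, use.names = FALSE),
                    stringsAsFactors = FALSE)
    d$ref <- cons_chars[d$pos]
    d$coverage <- cov[[side]][cbind(d$unit, d$pos)]
    d[d$support >= min_support & d$support > (d$coverage - d$support), ,
      drop = FALSE]
  }))
  if (is.null(var_df)) {
    var_df <- data.frame(side = character(0), unit = integer(0),
                         pos = integer(0), alt = character(0),
                         support = integer(0), ref = character(0),
                         coverage = integer(0))
  }
  structure(list(units_resolved_left = resolved("left"),
                 units_resolved_right = resolved("right"),
                 variants = var_df,
                 n_anchored_left = unname(n_anchored["left"]),
                 n_anchored_right = unname(n_anchored["right"])),
            class = "anchored_resolution")
}
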