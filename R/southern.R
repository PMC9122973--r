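# Virtual Southern blotting: restriction digestion, probe hybridization
# as a thresholded local-alignment proxy, gel-resolution band merging and
# scoring of observed band lists against candidate alleles.

#' A restriction enzyme definition
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (ACGT only).
#' @param cut_offset bases from the recognition start to the cut on the
#'   top strand (DraI: TTTAAA, blunt cut at offset 3).
#' @return list of class `enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (grepl("[^ACGT]", recognition)) {
    stop("enzyme definition error: recognition must be ACGT only (no N)")
  }
  stopifnot(cut_offset >= 0L, cut_offset <= nchar(recognition))
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset),
                 palindromic = recognition == revcomp(recognition)),
            class = "enzyme")
}

#' Built-in enzyme registry
#'
#' @param name enzyme name (currently `DraI`, `EcoRI`, `HindIII`).
#' @return an [enzyme()].
#' @export
get_enzyme <- function(name) {
  reg <- list(DraI = enzyme("DraI", "TTTAAA", 3L),
              EcoRI = enzyme("EcoRI", "GAATTC", 1L),
              HindIII = enzyme("HindIII", "AAGCTT", 1L))
  e <- reg[[name]]
  if (is.null(e)) stop("unknown enzyme: ", name)
  e
}

#' Digest a sequence with a restriction enzyme
#'
#' All recognition occurrences on the top strand cut at `cut_offset`;
#' non-palindromic recognitions are scanned on both strands.  A linear
#' molecule with n cuts yields n+1 fragments; a circular one yields n
#' fragments (or one uncut full-length fragment).
#'
#' @param rec a DNA [seq_record()].
#' @param enz an [enzyme()] or registry name.
#' @return list of class `digest_result`: `cuts` (0-based positions
#'   between bases) and `fragments` (start, end, size; end may exceed the
#'   sequence length for the circular wrap-around fragment).
#' @export
digest <- function(rec, enz) {
  if (is.character(enz)) enz <- get_enzyme(enz)
  stopifnot(inherits(rec, "seq_record"), rec$type == "DNA",
            inherits(enz, "enzyme"))
  L <- nchar(rec$seq)
  top <- Biostrings::start(Biostrings::matchPattern(enz$recognition,
                                                    Biostrings::DNAString(rec$seq)))
  cuts <- top - 1L + enz$cut_offset
  if (!enz$palindromic) {
    bot <- Biostrings::start(Biostrings::matchPattern(revcomp(enz$recognition),
                                                      Biostrings::DNAString(rec$seq)))
    cuts <- c(cuts, bot - 1L + (nchar(enz$recognition) - enz$cut_offset))
  }
  if (rec$topology == "circular") {
    # sites spanning the origin
    wrap <- paste0(substring(rec$seq, L - nchar(enz$recognition) + 2L, L),
                   substring(rec$seq, 1L, nchar(enz$recognition) - 1L))
    wt <- Biostrings::start(Biostrings::matchPattern(enz$recognition,
                                                     Biostrings::DNAString(wrap)))
    off <- L - nchar(enz$recognition) + 1L
    cuts <- c(cuts, (off + wt - 1L + enz$cut_offset) %% L)
    if (!enz$palindromic) {
      wb <- Biostrings::start(Biostrings::matchPattern(revcomp(enz$recognition),
                                                       Biostrings::DNAString(wrap)))
      cuts <- c(cuts, (off + wb - 1L +
                         (nchar(enz$recognition) - enz$cut_offset)) %% L)
    }
  }
  cuts <- sort(unique(cuts[cuts >= 0L & cuts <= L]))
  if (rec$topology == "linear") {
    cuts <- cuts[cuts > 0L & cuts < L]
    bounds <- c(0L, cuts, L)
    fragments <- data.frame(start = bounds[-length(bounds)],
                            end = bounds[-1])
  } else {
    cuts <- unique(cuts %% L)
    if (length(cuts) == 0L) {
      fragments <- data.frame(start = 0L, end = L)
    } else {
      cuts <- sort(cuts)
      fragments <- data.frame(start = cuts,
                              end = c(cuts[-1], cuts[1] + L))
    }
  }
  fragments$size <- fragments$end - fragments$start
  structure(list(cuts = cuts, fragments = fragments,
                 topology = rec$topology, seq_len = L),
            class = "digest_result")
}

fragment_seq <- function(rec, start, end) {
  L <- nchar(rec$seq)
  if (end <= L) substring(rec$seq, start + 1L, end)
  else paste0(substring(rec$seq, start + 1L, L),
              substring(rec$seq, 1L, end - L))
}

#' Predict probe-positive Southern bands from a digest
#'
#' A fragment is probe-positive when its best local alignment to the
#' probe (either strand) reaches `min_identity` over at least `min_span`
#' alignment columns - a documented stand-in for hybridization
#' stringency.  Positive fragments whose sizes differ by less than
#' `gel_merge_tol` (relative) co-migrate as one band whose intensity is
#' the number of merged fragments.
#'
#' @param d a [digest()] result.
#' @param rec the digested [seq_record()].
#' @param probe probe [seq_record()].
#' @param min_identity hybridization identity threshold (default 0.80).
#' @param min_span minimum alignment span in bp (default 50).
#' @param gel_merge_tol relative size tolerance of the gel (default 0.05).
#' @param min_size smallest reportable fragment (default 200 bp).
#' @return data.frame of class `band_prediction`: size, intensity,
#'   best_probe_identity, fragment ids; sorted descending by size.
#' @export
probe_bands <- function(d, rec, probe, min_identity = 0.80, min_span = 50L,
                        gel_merge_tol = 0.05, min_size = 200L) {
  stopifnot(inherits(d, "digest_result"), inherits(probe, "seq_record"))
  if (nchar(probe$seq) < min_span) stop("probe shorter than min_span")
  frags <- d$fragments
  frags$id <- seq_len(nrow(frags))
  frags <- frags[frags$size >= min_size, , drop = FALSE]
  pos <- list()
  pr_f <- Biostrings::DNAString(probe$seq)
  pr_r <- Biostrings::DNAString(revcomp(probe$seq))
  for (i in seq_len(nrow(frags))) {
    fs <- fragment_seq(rec, frags$start[i], frags$end[i])
    best <- NULL
    for (pp in list(pr_f, pr_r)) {
      al <- Biostrings::pairwiseAlignment(
        pp, Biostrings::DNAString(fs), type = "local",
        substitutionMatrix = dna_subst_matrix(2, -3),
        gapOpening = 5, gapExtension = 2)
      idn <- alignment_identity(al)
      if (is.null(best) || idn$matches > best$matches) best <- idn
    }
    if (best$columns >= min_span && best$identity >= min_identity) {
      pos[[length(pos) + 1L]] <- data.frame(
        id = frags$id[i], size = frags$size[i], identity = best$identity)
    }
  }
  if (length(pos) == 0L) {
    out <- data.frame(size = numeric(0), intensity = integer(0),
                      best_probe_identity = numeric(0),
                      fragment_ids = character(0))
    class(out) <- c("band_prediction", "data.frame")
    return(out)
  }
  pos <- do.call(rbind, pos)
  pos <- pos[order(pos$size), , drop = FALSE]
  grp <- cumsum(c(1L, diff(pos$size) / pos$size[-nrow(pos)] >=
                    gel_merge_tol))
  agg <- lapply(split(pos, grp), function(p) {
    data.frame(size = mean(p$size), intensity = nrow(p),
               best_probe_identity = max(p$identity),
               fragment_ids = paste(p$id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$size), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("band_prediction", "data.frame")
  out
}

#' Score observed band sizes against candidate allele predictions
#'
#' Greedy one-to-one matching of observed to predicted bands within a
#' relative log-size tolerance; score = matched observed / total
#' observed, coverage = matched predicted / total predicted; unexplained
#' observed bands are reported.
#'
#' @param predicted named list: allele -> [probe_bands()] prediction (or
#'   numeric size vector).
#' @param observed numeric vector of observed band sizes (bp).
#' @param size_tol relative size tolerance (default 0.10).
#' @return data.frame of class `allele_match`: allele, score, coverage,
#'   n_matched, unexplained (comma-joined sizes); best allele first.
#' @export
match_alleles <- function(predicted, observed, size_tol = 0.10) {
  stopifnot(length(observed) > 0L, length(predicted) > 0L,
            !is.null(names(predicted)))
  res <- lapply(names(predicted), function(nm) {
    p <- predicted[[nm]]
    sizes <- if (is.data.frame(p)) p$size else as.numeric(p)
    used <- rep(FALSE, length(sizes))
    matched <- logical(length(observed))
    for (i in order(-observed)) {
      if (length(sizes) == 0L) break
      dd <- abs(log(observed[i]) - log(sizes))
      dd[used] <- Inf
      j <- which.min(dd)
      if (is.finite(dd[j]) && dd[j] <= log(1 + size_tol)) {
        used[j] <- TRUE
        matched[i] <- TRUE
      }
    }
    data.frame(allele = nm,
               score = mean(matched),
               coverage = if (length(sizes) > 0L) mean(used) else 0,
               n_matched = sum(matched),
               unexplained = paste(observed[!matched], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$score, -out$coverage), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("allele_match", "data.frame")
  out
}
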