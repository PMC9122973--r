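# Gene models, mature-peptide derivation and isoform classification for
# AFP-locus genes: skin / liver / Midi / Maxi / pseudogene / Gig2-like.
#
# Signal and propeptide boundaries come from annotation, never de novo
# prediction.  Classification is a pure function of (gene model, sequence):
# the rules are applied in a fixed order and every fired rule is recorded
# as evidence.

#' Assemble a gene model from an annotated locus
#'
#' Collects the exon, CDS, signal-peptide and propeptide features sharing
#' a `gene_name` attribute and derives the structural flags used by the
#' classifier.  `has_frameshift` and `missing_exon1` honour explicit
#' attribute overrides (`frameshift=true`, `missing_exon1=true`) so that
#' pseudogene annotations from upstream tools are respected; otherwise a
#' CDS length not divisible by three implies a frameshift and a gene with
#' a single exon whose CDS starts at the exon start implies a missing
#' first exon.
#'
#' @param locus an [annotated_locus()].
#' @param gene_name gene identifier (matched against `gene_name`).
#' @return list of class `gene_model`.
#' @export
gene_model <- function(locus, gene_name) {
  f <- locus$features
  gn <- feat_attr(f, "gene_name")
  mine <- f[!is.na(gn) & gn == gene_name, , drop = FALSE]
  if (nrow(mine) == 0L) stop("no features for gene '", gene_name, "'")
  pick <- function(kind) mine[mine$kind == kind, , drop = FALSE]
  exons <- pick("exon")
  cds <- pick("CDS")
  gene_row <- pick("gene")
  if (nrow(gene_row) == 0L) gene_row <- pick("pseudogene_fragment")
  attrs <- if (nrow(gene_row) > 0L) gene_row$attributes[[1]]
           else mine$attributes[[1]]
  flag <- function(key) identical(unname(attrs[key]), "true")

  cds_len <- sum(cds$end - cds$start)
  translation <- NULL
  has_internal_stop <- FALSE
  if (cds_len >= 3L) {
    translation <- translate_cds(locus, cds)
    has_internal_stop <- grepl("internal_stop=true", translation$description,
                               fixed = TRUE)
  }
  has_frameshift <- flag("frameshift") ||
    (cds_len > 0L && cds_len %% 3L != 0L)
  missing_exon1 <- flag("missing_exon1") ||
    (nrow(exons) == 1L && nrow(cds) > 0L &&
       exons$start[1] == min(cds$start))
  exon1_coding <- nrow(exons) > 0L && nrow(cds) > 0L &&
    any(cds$start < exons$end[1] & cds$end > exons$start[1])

  structure(list(gene_name = gene_name,
                 exons = exons, cds = cds,
                 signal = pick("signal_peptide"),
                 propeptide = pick("propeptide"),
                 flags = list(exon1_coding = exon1_coding,
                              has_internal_stop = has_internal_stop,
                              has_frameshift = has_frameshift,
                              missing_exon1 = missing_exon1),
                 translation = translation),
            class = "gene_model")
}

# amino-acid length of annotated signal/propeptide features, measured as
# their overlap with the CDS in transcript coordinates
peptide_region_aa <- function(g, region_features) {
  if (nrow(region_features) == 0L) return(0L)
  nt <- 0L
  for (i in seq_len(nrow(region_features))) {
    ov <- pmax(0L, pmin(g$cds$end, region_features$end[i]) -
                 pmax(g$cds$start, region_features$start[i]))
    nt <- nt + sum(ov)
  }
  as.integer(round(nt / 3))
}

#' Derive the mature peptide of a gene
#'
#' Removes the annotated signal peptide, then the annotated propeptide,
#' from the CDS translation; when `amidation_gly_removal` is set and the
#' last residue is Gly it is dropped (C-terminal amidation).  Genes
#' without a signal (skin isoforms) return the full translation with the
#' N-terminal Met retained: N-terminal acetylation is metadata, not a
#' sequence change.
#'
#' @param g a [gene_model()].
#' @param locus the parent [annotated_locus()].
#' @param amidation_gly_removal drop a C-terminal Gly (default TRUE).
#' @return a protein [seq_record()].
#' @export
mature_peptide <- function(g, locus, amidation_gly_removal = TRUE) {
  stopifnot(inherits(g, "gene_model"))
  if (is.null(g$translation)) stop("gene '", g$gene_name,
                                   "' has no translatable CDS")
  if (nrow(g$signal) > 0L && !g$flags$exon1_coding &&
        nrow(g$exons) >= 2L) {
    stop("model inconsistency: signal peptide annotated but exon 1 is ",
         "non-coding for gene '", g$gene_name, "'")
  }
  prot <- g$translation$seq
  n_sig <- peptide_region_aa(g, g$signal)
  n_pro <- peptide_region_aa(g, g$propeptide)
  mature <- substring(prot, n_sig + n_pro + 1L)
  removed_gly <- FALSE
  if (amidation_gly_removal && nrow(g$signal) > 0L &&
        endsWith(mature, "G")) {
    mature <- substring(mature, 1L, nchar(mature) - 1L)
    removed_gly <- TRUE
  }
  if (!nzchar(mature)) stop("mature peptide empty after processing")
  seq_record(id = paste0(g$gene_name, "_mature"), seq = mature, type = "AA",
             description = sprintf("signal=%daa pro=%daa gly_removed=%s",
                                   n_sig, n_pro, tolower(removed_gly)))
}

#' Threonine periodicity score of a peptide
#'
#' The score is the fraction of consecutive Thr-Thr spacings equal to
#' `period` (the 11-residue spacing along one helix face is diagnostic of
#' flounder type I AFPs).
#'
#' @param p protein [seq_record()] or string.
#' @param period expected spacing in residues (default 11).
#' @return list: `period_score`, `n_repeats` (spacings equal to the
#'   period), `best_phase`, `thr_positions` (1-based), `too_few_thr`.
#' @export
thr_period_score <- function(p, period = 11L) {
  seq <- if (inherits(p, "seq_record")) p$seq else toupper(p)
  thr <- which(strsplit(seq, "")[[1]] == "T")
  if (length(thr) < 2L) {
    return(list(period_score = 0, n_repeats = 0L, best_phase = NA_integer_,
                thr_positions = thr, too_few_thr = TRUE))
  }
  spacings <- diff(thr)
  hits <- spacings == period
  phase_tab <- table(thr %% period)
  list(period_score = mean(hits), n_repeats = sum(hits),
       best_phase = as.integer(names(phase_tab)[which.max(phase_tab)]),
       thr_positions = thr, too_few_thr = FALSE)
}

#' Alanine fraction of a peptide
#'
#' @param p protein [seq_record()] or string.
#' @return fraction of residues that are Ala.
#' @export
ala_fraction <- function(p) {
  seq <- if (inherits(p, "seq_record")) p$seq else toupper(p)
  if (!nzchar(seq)) stop("empty peptide")
  ch <- strsplit(seq, "")[[1]]
  sum(ch == "A") / length(ch)
}

#' Classify a gene into an AFP isoform class
#'
#' Decision rules, applied in order (every fired rule becomes evidence):
#' 1. `pseudogene` - missing exon 1, a frameshift, or a mature peptide
#'    shorter than the shortest skin isoform (37 aa) without Thr
#'    periodicity (`period_score < 0.5`).
#' 2. `gig2_like` - low-Ala (fraction < 0.15) protein of 100-200 aa.
#' 3. Ala-rich, Thr-periodic peptides (`ala_fraction >= 0.40`,
#'    `period_score >= 0.5`):
#'    `maxi` (signal, no propeptide, mature >= 120 aa), `midi` (signal +
#'    propeptide, mature 60-119 aa), `liver` (signal + propeptide,
#'    mature < 60 aa), `skin` (no signal, mature 37-60 aa).
#' 4. else `unclassified`.
#'
#' @param g a [gene_model()].
#' @param locus the parent [annotated_locus()].
#' @param thresholds named list overriding the documented defaults
#'   (`ala_afp` 0.40, `ala_gig2` 0.15, `midi_min` 60, `maxi_min` 120,
#'   `skin_min` 37, `skin_max` 60, `period_min` 0.5).
#' @return list of class `isoform_call`: `class`, `evidence`, `features`
#'   (a `peptide_features` list).
#' @export
classify_isoform <- function(g, locus, thresholds = list()) {
  stopifnot(inherits(g, "gene_model"))
  th <- utils::modifyList(
    list(ala_afp = 0.40, ala_gig2 = 0.15, midi_min = 60L, maxi_min = 120L,
         skin_min = 37L, skin_max = 60L, period_min = 0.5,
         gig2_len = c(100L, 200L)), thresholds)
  evidence <- character(0)
  note <- function(msg) evidence <<- c(evidence, msg)

  has_signal <- nrow(g$signal) > 0L
  has_pro <- nrow(g$propeptide) > 0L
  mature <- tryCatch(mature_peptide(g, locus), error = function(e) NULL)
  feats <- if (!is.null(mature)) {
    ps <- thr_period_score(mature)
    list(length = nchar(mature$seq), ala_fraction = ala_fraction(mature),
         thr_positions = ps$thr_positions, period_score = ps$period_score,
         n_11mer_repeats = ps$n_repeats, has_signal = has_signal,
         has_propeptide = has_pro)
  } else {
    list(length = 0L, ala_fraction = NA_real_, thr_positions = integer(0),
         period_score = 0, n_11mer_repeats = 0L, has_signal = has_signal,
         has_propeptide = has_pro)
  }
  class(feats) <- "peptide_features"
  len <- feats$length

  cls <- NULL
  if (g$flags$missing_exon1) note("missing exon 1")
  if (g$flags$has_frameshift) note("frameshift")
  if (is.null(mature)) note("no translatable CDS")
  if (g$flags$missing_exon1 || g$flags$has_frameshift || is.null(mature) ||
        (len < th$skin_min && feats$period_score < th$period_min)) {
    if (!is.null(mature) && len < th$skin_min &&
          feats$period_score < th$period_min) {
      note(sprintf("mature %d aa < %d with period score %.2f", len,
                   th$skin_min, feats$period_score))
    }
    cls <- "pseudogene"
  } else if (feats$ala_fraction < th$ala_gig2 &&
               len >= th$gig2_len[1] && len <= th$gig2_len[2]) {
    note(sprintf("Ala fraction %.2f < %.2f and length %d in [%d,%d]",
                 feats$ala_fraction, th$ala_gig2, len, th$gig2_len[1],
                 th$gig2_len[2]))
    cls <- "gig2_like"
  } else if (feats$ala_fraction >= th$ala_afp &&
               feats$period_score >= th$period_min) {
    note(sprintf("Ala-rich (%.2f) with Thr periodicity (%.2f)",
                 feats$ala_fraction, feats$period_score))
    if (has_signal && !has_pro && len >= th$maxi_min) {
      note(sprintf("signal, no propeptide, mature %d aa >= %d", len,
                   th$maxi_min))
      cls <- "maxi"
    } else if (has_signal && has_pro && len >= th$midi_min &&
                 len < th$maxi_min) {
      note(sprintf("signal + propeptide, mature %d aa in [%d,%d)", len,
                   th$midi_min, th$maxi_min))
      cls <- "midi"
    } else if (has_signal && has_pro && len < th$midi_min) {
      note(sprintf("signal + propeptide, mature %d aa < %d", len,
                   th$midi_min))
      cls <- "liver"
    } else if (!has_signal && len >= th$skin_min && len <= th$skin_max) {
      note(sprintf("no signal, mature %d aa in [%d,%d]", len, th$skin_min,
                   th$skin_max))
      cls <- "skin"
    }
  }
  if (is.null(cls)) {
    cls <- "unclassified"
    evidence <- character(0)
  }
  structure(list(class = cls, evidence = evidence, features = feats,
                 gene_name = g$gene_name),
            class = "isoform_call")
}

#' Classify every gene in a locus and tabulate the census
#'
#' AFP count = skin + liver + midi + maxi.  Pseudogene fragments
#' (features of kind `pseudogene_fragment`) are counted as pseudogenes.
#'
#' @param locus an [annotated_locus()].
#' @param thresholds passed to [classify_isoform()].
#' @return list of class `locus_census`: `calls` (data frame, sorted by
#'   gene start), `counts` (named vector per class), `afp_count`.
#' @export
census_locus <- function(locus, thresholds = list()) {
  f <- locus$features
  gene_rows <- f[f$kind %in% c("gene", "pseudogene_fragment"), ,
                 drop = FALSE]
  classes <- c("skin", "liver", "midi", "maxi", "pseudogene", "gig2_like",
               "unclassified")
  if (nrow(gene_rows) == 0L) {
    counts <- stats::setNames(integer(length(classes)), classes)
    return(structure(list(calls = data.frame(), counts = counts,
                          afp_count = 0L), class = "locus_census"))
  }
  gene_rows <- gene_rows[order(gene_rows$start), , drop = FALSE]
  calls <- lapply(seq_len(nrow(gene_rows)), function(i) {
    gn <- feat_attr(gene_rows[i, , drop = FALSE], "gene_name")
    if (is.na(gn)) gn <- sprintf("gene_%04d", i)
    if (gene_rows$kind[i] == "pseudogene_fragment") {
      return(data.frame(gene = gn, start = gene_rows$start[i],
                        class = "pseudogene", mature_len = NA_integer_,
                        ala_fraction = NA_real_, period_score = NA_real_,
                        stringsAsFactors = FALSE))
    }
    g <- gene_model(locus, gn)
    call <- classify_isoform(g, locus, thresholds)
    data.frame(gene = gn, start = gene_rows$start[i], class = call$class,
               mature_len = call$features$length,
               ala_fraction = call$features$ala_fraction,
               period_score = call$features$period_score,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  counts <- stats::setNames(
    vapply(classes, function(cc) sum(calls$class == cc), integer(1)),
    classes)
  structure(list(calls = calls, counts = counts,
                 afp_count = unname(sum(counts[c("skin", "liver", "midi",
                                                 "maxi")]))),
            class = "locus_census")
}

#' @export
print.locus_census <- function(x, ...) {
  cat("Locus census:", x$afp_count, "AFP genes\n")
  print(x$counts)
  invisible(x)
}
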