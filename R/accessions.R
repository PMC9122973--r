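# Integration checks against deposited locus records.  These are opt-in:
# the records (GenBank flat files or FASTA + GFF3 sidecars for the two AFP
# alleles and the Gig2 locus) must have been downloaded once into a cache
# directory; nothing is ever downloaded implicitly.

#' Load a cached accession record
#'
#' Looks for `<acc>.gb` (GenBank feature table) or `<acc>.fasta` +
#' `<acc>.gff3` in the cache directory.
#'
#' @param cache_dir directory of pre-downloaded records.
#' @param acc accession string.
#' @return an [annotated_locus()].
#' @export
load_accession <- function(cache_dir, acc) {
  gb <- file.path(cache_dir, paste0(acc, ".gb"))
  fa <- file.path(cache_dir, paste0(acc, ".fasta"))
  gff <- file.path(cache_dir, paste0(acc, ".gff3"))
  if (file.exists(gb)) return(read_annotation(gb, "genbank_feature_table"))
  if (file.exists(fa) && file.exists(gff)) {
    return(read_annotation(gff, "gff3", fasta = fa))
  }
  stop("accession record not available offline: ", acc,
       " (expected ", gb, " or ", fa, " + ", gff, "); ",
       "download it once into the cache directory to enable this check")
}

#' Run the accession-based integration measurements
#'
#' Recomputes, from cached copies of the two AFP-locus alleles and the
#' Gig2 locus, the headline quantities of the source loci: AFP census of
#' both alleles, tandem period of the allele-1 repeat region, Maxi-1 vs
#' Maxi-2 protein identity, mean best identity of the allele-2 coding
#' sequences against allele 1, Gig2 translation lengths, Midi mature
#' length, and the skin exon-1 match against Gig2.
#'
#' @param cache_dir directory with `allele1`, `allele2`, `gig2` records
#'   (see [load_accession()]); default `"accession_cache"`.
#' @return named list of measured values.
#' @export
accession_integration <- function(cache_dir = "accession_cache") {
  allele1 <- load_accession(cache_dir, "allele1")
  allele2 <- load_accession(cache_dir, "allele2")
  gig2 <- load_accession(cache_dir, "gig2")

  cen1 <- census_locus(allele1)
  cen2 <- census_locus(allele2)

  tp <- tandem_period(allele1)

  prots <- function(locus) {
    f <- locus$features
    genes <- unique(stats::na.omit(feat_attr(f[f$kind == "gene", ,
                                               drop = FALSE], "gene_name")))
    out <- list()
    for (g in genes) {
      tr <- tryCatch(translate_cds(locus, g), error = function(e) NULL)
      if (!is.null(tr)) out[[g]] <- tr
    }
    out
  }
  p1 <- prots(allele1)
  p2 <- prots(allele2)
  pg <- prots(gig2)

  find1 <- function(plist, pattern) {
    hit <- grep(pattern, names(plist), ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    plist[[hit[1]]]
  }
  maxi1 <- find1(p1, "^maxi-?1$"); maxi2 <- find1(p1, "^maxi-?2$")
  maxi_identity <- if (!is.null(maxi1) && !is.null(maxi2)) {
    global_identity(maxi1, maxi2)$identity
  } else NA_real_

  cds_seqs <- function(locus) {
    f <- locus$features
    genes <- unique(stats::na.omit(feat_attr(f[f$kind == "CDS", ,
                                               drop = FALSE], "gene_name")))
    Filter(Negate(is.null), lapply(genes, function(g) {
      tryCatch(extract_feature_seq(
        locus, f[f$kind == "CDS" & !is.na(feat_attr(f, "gene_name")) &
                   feat_attr(f, "gene_name") == g, , drop = FALSE]),
        error = function(e) NULL)
    }))
  }
  cmi <- tryCatch(
    closest_match_identity(cds_seqs(allele2), cds_seqs(allele1)),
    error = function(e) NULL)

  gig2_lengths <- sort(vapply(pg, function(p) nchar(p$seq), integer(1)),
                       decreasing = TRUE)

  midi <- find1(p1, "midi")
  midi_mature_len <- if (!is.null(midi)) {
    g <- gene_model(allele1, midi$id)
    nchar(mature_peptide(g, allele1)$seq)
  } else NA_integer_

  f1 <- allele1$features
  s1_exon1 <- f1[f1$kind == "exon" &
                   !is.na(feat_attr(f1, "gene_name")) &
                   grepl("^S-?1$", feat_attr(f1, "gene_name")), ,
                 drop = FALSE]
  exon1_match <- if (nrow(s1_exon1) > 0L) {
    exon_window_matches(allele1, s1_exon1[1, , drop = FALSE], gig2)
  } else list(matches = NA_integer_, columns = NA_integer_)

  list(afp_count_allele1 = cen1$afp_count,
       afp_count_allele2 = cen2$afp_count,
       tandem_period = tp$period,
       maxi_identity = maxi_identity,
       allele2_cds_mean_best_identity =
         if (is.null(cmi)) NA_real_ else cmi$mean_identity,
       gig2_full_lengths = gig2_lengths,
       midi_mature_len = midi_mature_len,
       s1_exon1_matches = exon1_match$matches,
       s1_exon1_columns = exon1_match$columns)
}
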