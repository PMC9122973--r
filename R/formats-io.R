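# Sequence records, typed features and annotated loci.
#
# All internal coordinates are 0-based half-open on the forward strand.
# I/O boundaries convert explicitly: GFF3 and GenBank feature tables are
# 1-based inclusive, BED is already 0-based half-open.  User-facing reports
# echo 1-based inclusive positions.

FEATURE_KINDS <- c("gene", "exon", "CDS", "intron", "five_prime_UTR",
                   "three_prime_UTR", "repeat_unit", "signal_peptide",
                   "propeptide", "mature_peptide", "probe",
                   "pseudogene_fragment", "misc")

#' Construct a sequence record
#'
#' The universal sequence container: an id, an uppercase sequence over a
#' declared alphabet (`ACGTN` for DNA) and an explicit topology.
#'
#' @param id record identifier.
#' @param seq sequence string; lowercase input is uppercased.
#' @param type `"DNA"` or `"AA"`.
#' @param topology `"linear"` or `"circular"`.
#' @param description free text.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, seq, type = c("DNA", "AA"),
                       topology = c("linear", "circular"),
                       description = "") {
  type <- match.arg(type)
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  pattern <- if (type == "DNA") "[^ACGTN]" else "[^ACDEFGHIKLMNPQRSTVWY*X]"
  if (grepl(pattern, seq)) {
    alpha <- if (type == "DNA") DNA_ALPHABET else AA_ALPHABET
    bad <- setdiff(unique(strsplit(seq, "")[[1]]), alpha)
    stop("illegal ", type, " characters in record '", id, "': ",
         paste(bad, collapse = ""))
  }
  structure(list(id = id, seq = seq, type = type, topology = topology,
                 description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  %s  %s  %d %s\n", x$id, x$type, x$topology,
              nchar(x$seq), if (x$type == "DNA") "bp" else "aa"))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$seq)

#' Construct a feature table
#'
#' Features are rows of a data frame with 0-based half-open coordinates.
#' `attributes` is a list column of named character vectors and must
#' support at least the keys `isoform_class`, `gene_name` and `unit_index`.
#'
#' @param seq_id id of the parent sequence.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param kind one of the closed feature-kind vocabulary
#'   (see `FEATURE_KINDS`).
#' @param attributes list of named character vectors (recycled if length 1).
#' @return a `data.frame` with class `feature_table`.
#' @export
feature_table <- function(seq_id, start, end, strand = "+", kind = "misc",
                          attributes = list(character(0))) {
  n <- max(length(start), length(end))
  df <- data.frame(seq_id = rep_len(seq_id, n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(strand, n),
                   kind = rep_len(kind, n),
                   stringsAsFactors = FALSE)
  if (!all(df$kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind(s): ",
         paste(setdiff(df$kind, FEATURE_KINDS), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("invalid strand")
  if (any(df$start < 0L) || any(df$start >= df$end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  if (length(attributes) == 1L) attributes <- rep(attributes, n)
  stopifnot(length(attributes) == n)
  df$attributes <- I(attributes)
  class(df) <- c("feature_table", "data.frame")
  df
}

empty_features <- function(seq_id = character(0)) {
  df <- data.frame(seq_id = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   kind = character(0), stringsAsFactors = FALSE)
  df$attributes <- I(list())
  class(df) <- c("feature_table", "data.frame")
  df
}

rbind_features <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (length(parts) == 0L) return(empty_features())
  out <- do.call(rbind, lapply(parts, function(p) { class(p) <- "data.frame"; p }))
  class(out) <- c("feature_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Fetch one attribute across a feature table
#'
#' @param features a `feature_table`.
#' @param key attribute name.
#' @return character vector (NA where absent).
#' @export
feat_attr <- function(features, key) {
  vapply(features$attributes, function(a) {
    if (length(a) == 0L || is.null(names(a))) return(NA_character_)
    v <- unname(a[key])
    if (length(v) == 0L) NA_character_ else as.character(v)
  }, character(1))
}

#' An annotated locus: sequence plus features
#'
#' @param record a [seq_record()] (DNA).
#' @param features a [feature_table()]; may be empty.
#' @return object of class `annotated_locus`.
#' @export
annotated_locus <- function(record, features = empty_features()) {
  stopifnot(inherits(record, "seq_record"))
  if (nrow(features) > 0L) {
    if (any(features$end > nchar(record$seq))) {
      bad <- which(features$end > nchar(record$seq))[1]
      stop("feature out of bounds: row ", bad, " (", features$kind[bad],
           " ", features$start[bad], "-", features$end[bad], ")")
    }
    # exons of one gene must be non-overlapping; store sorted by start
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
    ex <- features[features$kind == "exon", , drop = FALSE]
    if (nrow(ex) > 1L) {
      for (g in unique(stats::na.omit(feat_attr(ex, "gene_name")))) {
        gi <- ex[which(feat_attr(ex, "gene_name") == g), , drop = FALSE]
        if (nrow(gi) > 1L && any(gi$start[-1] < gi$end[-nrow(gi)])) {
          stop("overlapping exons for gene '", g, "'")
        }
      }
    }
  }
  structure(list(record = record, features = features),
            class = "annotated_locus")
}

#' @export
print.annotated_locus <- function(x, ...) {
  cat(sprintf("<annotated_locus> %s (%s, %d bp) with %d features\n",
              x$record$id, x$record$topology, nchar(x$record$seq),
              nrow(x$features)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# FASTA / FASTQ

#' Read a FASTA file
#'
#' @param path file path.
#' @param type `"DNA"` or `"AA"`.
#' @return list of [seq_record()] in file order.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    if (type == "DNA") Biostrings::readBStringSet(path)
    else Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA format error in ", path, ": ",
                             conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  desc <- sub("^\\S+\\s*", "", names(set))
  lapply(seq_along(set), function(i) {
    seq_record(ids[i], as.character(set[[i]]), type = type,
               description = desc[i])
  })
}

#' Write records to FASTA
#'
#' Deterministic output: 70-column wrap, records in the order given.
#'
#' @param records list of [seq_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    n <- nchar(r$seq)
    starts <- seq(1L, n, by = 70L)
    writeLines(substring(r$seq, starts, pmin(starts + 69L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file (qualities ignored)
#'
#' @param path file path.
#' @return list of DNA [seq_record()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(set) == 0L) stop("FASTQ format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    seq_record(ids[i], as.character(set[[i]]))
  })
}

#' Write DNA records to FASTQ with uniform placeholder qualities
#'
#' @param records list of DNA [seq_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(c(paste0("@", r$id), r$seq, "+",
                 strrep("I", nchar(r$seq))), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotation I/O

#' Read locus annotation in one of the supported dialects
#'
#' Coordinates are converted to the internal 0-based half-open convention.
#' For GenBank feature tables, `join(a..b,c..d)` CDS locations are expanded
#' into per-exon `CDS` features sharing a `gene_name` attribute.
#'
#' @param path annotation file.
#' @param dialect `"gff3"`, `"genbank_feature_table"` or `"bed"`.
#' @param fasta sidecar FASTA with the sequence (required for GFF3/BED;
#'   GenBank files embed the sequence in their ORIGIN block).
#' @return an [annotated_locus()].
#' @export
read_annotation <- function(path,
                            dialect = c("gff3", "genbank_feature_table", "bed"),
                            fasta = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect: ", dialect[1]))
  switch(dialect,
         gff3 = read_gff3_locus(path, fasta),
         bed = read_bed_locus(path, fasta),
         genbank_feature_table = read_genbank_ft(path))
}

grange_to_features <- function(gr) {
  if (length(gr) == 0L) return(empty_features())
  mc <- as.data.frame(S4Vectors::mcols(gr))
  kind <- as.character(mc$type %||% rep("misc", length(gr)))
  kind[!(kind %in% FEATURE_KINDS)] <- "misc"
  drop_cols <- c("type", "source", "score", "phase")
  attr_cols <- setdiff(names(mc), drop_cols)
  attrs <- lapply(seq_along(gr), function(i) {
    a <- character(0)
    for (cn in attr_cols) {
      v <- mc[[cn]][i]
      if (is(v, "List") || is.list(v)) v <- unlist(v)
      v <- as.character(v)
      if (length(v) >= 1L && !all(is.na(v))) {
        a[cn] <- paste(v[!is.na(v)], collapse = "|")
      }
    }
    a
  })
  feature_table(seq_id = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
                kind = kind, attributes = attrs)
}

read_gff3_locus <- function(path, fasta) {
  if (is.null(fasta)) stop("GFF3 input needs a sidecar FASTA")
  rec <- read_fasta(fasta)[[1]]
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- grange_to_features(gr)
  if (nrow(feats) > 0L && any(feats$end > nchar(rec$seq))) {
    bad <- which(feats$end > nchar(rec$seq))[1]
    stop("feature out of bounds in ", path, ": ",
         feat_attr(feats, "ID")[bad] %||% bad)
  }
  annotated_locus(rec, feats)
}

read_bed_locus <- function(path, fasta) {
  if (is.null(fasta)) stop("BED input needs a sidecar FASTA")
  rec <- read_fasta(fasta)[[1]]
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED format error: fewer than 3 columns")
  name <- if (ncol(bed) >= 4L) bed[[4]] else rep(NA_character_, nrow(bed))
  strand <- if (ncol(bed) >= 6L) bed[[6]] else rep(".", nrow(bed))
  attrs <- lapply(name, function(nm) {
    if (is.na(nm)) character(0) else c(gene_name = nm)
  })
  kind <- ifelse(!is.na(name) & name %in% FEATURE_KINDS, name, "misc")
  feats <- feature_table(seq_id = bed[[1]], start = bed[[2]], end = bed[[3]],
                         strand = strand, kind = kind, attributes = attrs)
  annotated_locus(rec, feats)
}

# Minimal GenBank feature-table reader: LOCUS / FEATURES / ORIGIN blocks,
# join() and complement() locations, /key="value" qualifiers.
read_genbank_ft <- function(path) {
  lines <- readLines(path)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) == 0L) stop("GenBank format error: no LOCUS line")
  locus_id <- strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]][1]
  topology <- if (grepl("circular", locus_line[1])) "circular" else "linear"

  fi <- grep("^FEATURES", lines)
  oi <- grep("^ORIGIN", lines)
  if (length(fi) == 0L || length(oi) == 0L) {
    stop("GenBank format error: FEATURES or ORIGIN block missing")
  }
  seq_lines <- lines[(oi[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
  rec <- seq_record(locus_id, seq, topology = topology)

  ft <- lines[(fi[1] + 1L):(oi[1] - 1L)]
  # a new feature starts at column 6 with a key; continuations are deeper
  is_key <- grepl("^ {5}\\S", ft)
  idx <- cumsum(is_key)
  feats <- empty_features()
  for (i in seq_len(max(idx, 0))) {
    block <- ft[idx == i]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    rest <- paste(c(strsplit(trimws(block[1]), "\\s+")[[1]][-1],
                    trimws(block[-1])), collapse = "")
    # split location from qualifiers (qualifiers start at the first "/")
    qual_start <- regexpr("/", rest, fixed = TRUE)
    loc_str <- if (qual_start > 0) substr(rest, 1, qual_start - 1L) else rest
    quals <- if (qual_start > 0) substring(rest, qual_start) else ""
    loc <- parse_genbank_location(loc_str)
    attrs <- parse_genbank_qualifiers(quals)
    kind <- if (key %in% FEATURE_KINDS) key
            else if (key == "sig_peptide") "signal_peptide"
            else if (key == "mat_peptide") "mature_peptide"
            else "misc"
    gene_attr <- attrs[["gene"]] %||% attrs[["gene_name"]] %||%
      attrs[["locus_tag"]]
    n_seg <- nrow(loc)
    a <- attrs
    if (!is.null(gene_attr)) a[["gene_name"]] <- gene_attr
    feats <- rbind_features(feats, feature_table(
      seq_id = locus_id, start = loc$start, end = loc$end,
      strand = if (loc$complement[1]) "-" else "+",
      kind = kind,
      attributes = rep(list(unlist(a)), n_seg)))
  }
  if (nrow(feats) > 0L && any(feats$end > nchar(seq))) {
    stop("feature out of bounds in ", path)
  }
  annotated_locus(rec, feats)
}

# "join(5..10,20..30)" / "complement(5..10)" -> data.frame of 0-based spans
parse_genbank_location <- function(s) {
  s <- gsub("\\s", "", s)
  complement <- grepl("^complement\\(", s)
  s <- gsub("^complement\\(|^join\\(|\\)$", "", s)
  s <- gsub("^join\\(|\\)", "", s)
  parts <- strsplit(s, ",")[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$|^(\\d+)$", parts))
  spans <- t(vapply(m, function(g) {
    if (length(g) == 0L) stop("unparseable GenBank location: ", s)
    if (nzchar(g[2])) c(as.integer(g[2]), as.integer(g[3]))
    else c(as.integer(g[4]), as.integer(g[4]))
  }, integer(2)))
  data.frame(start = spans[, 1] - 1L, end = spans[, 2],
             complement = complement)
}

parse_genbank_qualifiers <- function(s) {
  if (!nzchar(s)) return(list())
  m <- regmatches(s, gregexpr('/([A-Za-z_]+)=(("[^"]*")|([^/"]+))', s))[[1]]
  out <- list()
  for (q in m) {
    key <- sub("^/([A-Za-z_]+)=.*$", "\\1", q)
    val <- sub('^/[A-Za-z_]+=', "", q)
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Write an annotated locus to GFF3 (plus optional sidecar FASTA)
#'
#' Emits deterministic, coordinate-sorted GFF3; internal 0-based half-open
#' intervals are converted to the 1-based inclusive convention of the
#' format.
#'
#' @param locus an [annotated_locus()].
#' @param path output GFF3 path.
#' @param fasta optional path for a sidecar FASTA.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(locus, path, fasta = NULL) {
  f <- locus$features
  lines <- "##gff-version 3"
  if (nrow(f) > 0L) {
    f <- f[order(f$start, f$end, f$kind), , drop = FALSE]
    attr_str <- vapply(seq_len(nrow(f)), function(i) {
      a <- f$attributes[[i]]
      a <- a[order(names(a))]
      if (length(a) == 0L) return(sprintf("ID=f%04d", i))
      paste(c(sprintf("ID=f%04d", i),
              paste0(names(a), "=", gsub("[;=,\t\n]", "_", a))),
            collapse = ";")
    }, character(1))
    lines <- c(lines, sprintf("%s\tafptools\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              f$seq_id, f$kind, f$start + 1L, f$end,
                              f$strand, attr_str))
  }
  writeLines(lines, path)
  if (!is.null(fasta)) write_fasta(locus$record, fasta)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature sequence extraction and translation

#' Extract the sequence of a feature (or exon set) from a locus
#'
#' Minus-strand features are reverse-complemented.  When `feature` has
#' several rows (a multi-exon gene) the exon sequences are concatenated in
#' transcript order (5' to 3').
#'
#' @param locus an [annotated_locus()].
#' @param feature one or more rows of a [feature_table()].
#' @return a DNA [seq_record()].
#' @export
extract_feature_seq <- function(locus, feature) {
  stopifnot(nrow(feature) >= 1L)
  if (any(feature$end > nchar(locus$record$seq))) stop("feature out of bounds")
  strand <- unique(feature$strand)
  if (length(strand) != 1L) stop("mixed strands in feature group")
  if (strand == ".") {
    if (nrow(feature) > 1L) {
      stop("strand error: cannot orient multi-exon feature on strand '.'")
    }
    strand <- "+"
  }
  feature <- feature[order(feature$start), , drop = FALSE]
  pieces <- substring(locus$record$seq, feature$start + 1L, feature$end)
  if (strand == "-") {
    pieces <- rev(vapply(pieces, revcomp, character(1), USE.NAMES = FALSE))
  }
  nm <- feat_attr(feature, "gene_name")[1]
  seq_record(id = if (!is.na(nm)) nm else paste0(locus$record$id, "_feat"),
             seq = paste(pieces, collapse = ""))
}

#' Translate the CDS of a gene in a locus
#'
#' Concatenates the gene's `CDS` features in transcript order and applies
#' the standard genetic code.  The trailing stop codon is removed; internal
#' stops are retained and flagged in the description (pseudogene evidence).
#'
#' @param locus an [annotated_locus()].
#' @param gene gene name (matched against the `gene_name` attribute) or a
#'   subset of CDS feature rows.
#' @return a protein [seq_record()]; the description carries
#'   `internal_stop=true` and/or `frame_warning=true` flags when relevant.
#' @export
translate_cds <- function(locus, gene) {
  if (is.character(gene)) {
    f <- locus$features
    cds <- f[f$kind == "CDS" & !is.na(feat_attr(f, "gene_name")) &
               feat_attr(f, "gene_name") == gene, , drop = FALSE]
    if (nrow(cds) == 0L) stop("no CDS features for gene '", gene, "'")
  } else {
    cds <- gene
  }
  if (sum(cds$end - cds$start) < 3L) stop("concatenated CDS shorter than 3 bp")
  dna <- extract_feature_seq(locus, cds)
  prot <- withCallingHandlers(
    translate_dna(dna$seq),
    warning = function(w) invokeRestart("muffleWarning"))
  flags <- c(if (attr(prot, "internal_stop")) "internal_stop=true",
             if (attr(prot, "frame_warning")) "frame_warning=true")
  seq_record(id = dna$id, seq = as.character(prot), type = "AA",
             description = paste(flags, collapse = " "))
}
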