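# Microsynteny around a focal gene family: flanking-gene rows, rendered
# tables and the relocation signature.  Gene identity is by name string,
# case-insensitive; orthology resolution is out of scope.

#' A species' gene order around a focal family
#'
#' @param species species label.
#' @param genes character vector of gene names in chromosomal order
#'   (prefix `-` marks minus strand; ignored for comparisons).
#' @param focal_family focal family name (default `"Gig2"`).
#' @param locus_id optional locus label.
#' @return list of class `gene_order`.
#' @export
gene_order <- function(species, genes, focal_family = "Gig2",
                       locus_id = species) {
  stopifnot(is.character(species), length(genes) >= 1L,
            all(nzchar(sub("^-", "", genes))))
  structure(list(species = species, locus_id = locus_id,
                 genes = sub("^-", "", genes),
                 strands = ifelse(startsWith(genes, "-"), "-", "+"),
                 focal_family = focal_family),
            class = "gene_order")
}

#' Gene order extracted from an annotated locus
#'
#' @param locus an [annotated_locus()] with gene features.
#' @param species species label.
#' @param focal_family focal family name.
#' @return a [gene_order()].
#' @export
gene_order_from_locus <- function(locus, species, focal_family = "Gig2") {
  f <- locus$features
  g <- f[f$kind == "gene", , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  nm <- feat_attr(g, "gene_name")
  gene_order(species, paste0(ifelse(g$strand == "-", "-", ""), nm),
             focal_family)
}

is_focal <- function(names, focal) tolower(names) == tolower(focal)

#' Flanking genes of the focal family
#'
#' Returns the `depth` nearest non-focal genes on each side of the focal
#' block (contiguous focal genes are one block; with several separated
#' blocks the span from first to last occurrence is used), nearest first.
#' A species without the focal family yields a flagged row with
#' `focal_count` 0 and undefined flanks.
#'
#' @param order a [gene_order()].
#' @param depth flank depth (>= 1, default 2).
#' @return list of class `synteny_row`: `species`, `focal_count`,
#'   `flank5`, `flank3`, `focal_absent`.
#' @export
flanks <- function(order, depth = 2L) {
  stopifnot(inherits(order, "gene_order"), depth >= 1L)
  foc <- is_focal(order$genes, order$focal_family)
  if (!any(foc)) {
    return(structure(list(species = order$species, focal_count = 0L,
                          flank5 = character(0), flank3 = character(0),
                          focal_absent = TRUE,
                          focal_family = order$focal_family),
                     class = "synteny_row"))
  }
  first <- which(foc)[1]
  last <- max(which(foc))
  up <- order$genes[seq_len(first - 1L)]
  up <- up[!is_focal(up, order$focal_family)]
  down <- if (last < length(order$genes)) {
    order$genes[(last + 1L):length(order$genes)]
  } else character(0)
  down <- down[!is_focal(down, order$focal_family)]
  structure(list(species = order$species, focal_count = sum(foc),
                 flank5 = rev(utils::tail(up, depth)),
                 flank3 = utils::head(down, depth),
                 focal_absent = FALSE,
                 focal_family = order$focal_family),
            class = "synteny_row")
}

#' Build a microsynteny table across species
#'
#' Rows are kept in the input (phylogeny) order.
#'
#' @param orders list of [gene_order()].
#' @param depth flank depth.
#' @return data.frame of class `synteny_table` with columns species,
#'   focal_count, flank5, flank3, focal_absent; `attr(,"rows")` carries
#'   the underlying `synteny_row` objects.
#' @export
synteny_table <- function(orders, depth = 2L) {
  stopifnot(length(orders) >= 1L)
  key <- vapply(orders, function(o) paste(o$species, o$locus_id),
                character(1))
  if (anyDuplicated(key)) stop("duplicate species+locus in input")
  rows <- lapply(orders, flanks, depth = depth)
  df <- data.frame(
    species = vapply(rows, `[[`, "", "species"),
    focal_count = vapply(rows, function(r) r$focal_count, integer(1)),
    flank5 = vapply(rows, function(r) paste(r$flank5, collapse = " "),
                    character(1)),
    flank3 = vapply(rows, function(r) paste(r$flank3, collapse = " "),
                    character(1)),
    focal_absent = vapply(rows, function(r) r$focal_absent, logical(1)),
    stringsAsFactors = FALSE)
  attr(df, "rows") <- rows
  class(df) <- c("synteny_table", "data.frame")
  df
}

#' Write / read a synteny table as TSV
#'
#' @param tab a `synteny_table`.
#' @param path file path.
#' @return `path` (write) or the re-read data.frame (read).
#' @export
write_synteny_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[, c("species", "focal_count",
                                            "flank5", "flank3",
                                            "focal_absent")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synteny_tsv
#' @export
read_synteny_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character",
                                   "character", "logical"))
}

#' Compare two synteny rows for relocation of the focal family
#'
#' `same_context` when the two species share at least one flank gene on
#' each side (a single shared side is still scored as shared context);
#' `relocated` when both carry the family but share no flank gene on
#' either side; `absent_in_one` when either row lacks the family.
#'
#' @param a,b `synteny_row` objects for the same focal family.
#' @return list of class `relocation_call`: `verdict`, `shared_flank5`,
#'   `shared_flank3`, `evidence`.
#' @export
relocation_call <- function(a, b) {
  stopifnot(inherits(a, "synteny_row"), inherits(b, "synteny_row"))
  if (tolower(a$focal_family) != tolower(b$focal_family)) {
    stop("rows describe different focal families")
  }
  s5 <- intersect(tolower(a$flank5), tolower(b$flank5))
  s3 <- intersect(tolower(a$flank3), tolower(b$flank3))
  verdict <- if (a$focal_count == 0L || b$focal_count == 0L) {
    "absent_in_one"
  } else if (length(s5) > 0L && length(s3) > 0L) {
    "same_context"
  } else if (length(s5) == 0L && length(s3) == 0L) {
    "relocated"
  } else {
    "same_context"          # one shared side: still shared context
  }
  structure(list(species_pair = c(a$species, b$species), verdict = verdict,
                 shared_flank5 = s5, shared_flank3 = s3,
                 evidence = sprintf(
                   "%s vs %s: shared 5' {%s}, shared 3' {%s}",
                   a$species, b$species, paste(s5, collapse = ","),
                   paste(s3, collapse = ","))),
            class = "relocation_call")
}
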