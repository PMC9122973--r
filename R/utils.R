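#' @useDynLib afptools, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods is
#' @importFrom stats runif rbinom rlnorm quantile sd median setNames
#' @importFrom utils read.table write.table head tail modifyList
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*", "X")

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over the ACGTN alphabet.
#' @return character scalar.
#' @export
#' @examples
#' revcomp("AAC")   # "GTT"
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#'
#' Uniform ACGT (50% GC).  Uses the current RNG stream; wrap in
#' [with_seed()] for reproducibility.
#'
#' @param n length in bp.
#' @return character scalar.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## integer base codes used by the mutation machinery (A=0 C=1 G=2 T=3)
dna_to_int <- function(x) {
  code <- integer(128)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  code[utf8ToInt("N")] <- 4L
  code[utf8ToInt(x)]
}

int_to_dna <- function(v) {
  intToUtf8(utf8ToInt("ACGTN")[v + 1L])
}

#' Translate a coding sequence
#'
#' Standard genetic code; codons containing N translate to `X`.  Length not
#' divisible by three is tolerated: translation proceeds on the first
#' `floor(n/3)` codons and the result carries a `frame_warning` attribute.
#'
#' @param cds character scalar, DNA.
#' @return character scalar protein; attributes `internal_stop` (logical)
#'   and `frame_warning` (logical).  The trailing stop, when present, is
#'   removed before the internal-stop check.
#' @export
translate_dna <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  frame_warning <- (n %% 3L) != 0L
  if (frame_warning) {
    warning("CDS length not divisible by 3; translating floor(n/3) codons")
  }
  n_cod <- n %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_cod)
  codons <- substring(cds, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  if (n_cod > 0L && aa[n_cod] == "*") aa <- aa[-n_cod]
  prot <- paste(aa, collapse = "")
  structure(prot,
            internal_stop = grepl("*", prot, fixed = TRUE),
            frame_warning = frame_warning)
}
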