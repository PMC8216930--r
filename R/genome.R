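#' Construct a mitochondrial genome object
#'
#' A `mito_genome` stores one circular mitochondrial DNA molecule as plain
#' text on the major (J) strand, linearized at an arbitrary origin
#' (conventionally the start of *trnM* for lepidopterans). Only the four
#' unambiguous bases are accepted: every downstream composition and skew
#' statistic assumes a strict A/C/G/T alphabet, so ambiguity codes are
#' rejected rather than silently counted.
#'
#' @param sequence Character scalar, the J-strand sequence (case-insensitive).
#' @param id Genome identifier.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `mito_genome` with fields `id`, `sequence`
#'   (upper case), `topology` and `length`.
#' @examples
#' g <- mito_genome("ATGCATGC", id = "toy")
#' g$length
#' @export
mito_genome <- function(sequence, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single character string", call. = FALSE)
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop("empty genome sequence", call. = FALSE)
  bad <- unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]])
  if (length(bad))
    stop("mito_genome: ambiguity codes or non-DNA characters not allowed: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(id = as.character(id), sequence = sequence,
         topology = topology, length = nchar(sequence)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s\n", x$id, x$length, x$topology))
  cat("  ", substr(x$sequence, 1, 60),
      if (x$length > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

# reverse complement of an A/C/G/T string
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE))
}

#' Sense-strand sequence of a feature
#'
#' Extracts the coding/sense-strand text of a feature: the J-strand
#' subsequence `from..to` as-is for J-strand features, its reverse
#' complement for N-strand (minority strand) features. Start and stop
#' codons in architecture tables are always reported on this strand.
#'
#' @param genome A [mito_genome].
#' @param feature A list or one-row data frame with fields `from`, `to`
#'   (1-based inclusive) and `strand` (`"J"` or `"N"`).
#' @return Character scalar of length `to - from + 1`.
#' @examples
#' g <- mito_genome("ATGC")
#' sense_sequence(g, list(from = 1, to = 4, strand = "N"))  # "GCAT"
#' @export
sense_sequence <- function(genome, feature) {
  stopifnot(inherits(genome, "mito_genome"))
  from <- as.integer(feature$from); to <- as.integer(feature$to)
  strand <- as.character(feature$strand)
  if (is.na(from) || is.na(to) || from < 1L || to > genome$length || from > to)
    stop(sprintf("feature coordinates [%s..%s] out of bounds for genome of %d bp",
                 feature$from, feature$to, genome$length), call. = FALSE)
  s <- substr(genome$sequence, from, to)
  if (identical(strand, "N")) revcomp(s) else s
}
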