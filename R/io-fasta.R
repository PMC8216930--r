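#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line width (default 70).
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("FASTA records must be named", call. = FALSE)
  if (any(!nzchar(records))) stop("empty sequence in FASTA records", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::BStringSet(records), path, width = width)
  invisible(path)
}

#' Write a character matrix in FASTA, relaxed PHYLIP or NEXUS format
#'
#' @param sequences Named character vector of equal-length aligned rows,
#'   or a `mito_supermatrix`.
#' @param path Output path.
#' @param format One of `"fasta"`, `"phylip"` (relaxed: full names,
#'   whitespace-separated) or `"nexus"`.
#' @export
write_alignment <- function(sequences, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (inherits(sequences, "mito_supermatrix")) sequences <- sequences$sequences
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L)
    stop("ragged alignment: row lengths ", paste(lens, collapse = ", "),
         call. = FALSE)
  if (format == "fasta") {
    write_fasta(sequences, path)
  } else if (format == "phylip") {
    pad <- max(nchar(names(sequences))) + 2L
    writeLines(c(sprintf(" %d %d", length(sequences), lens),
                 sprintf("%-*s%s", pad, names(sequences), sequences)), path)
  } else {
    ape::write.nexus.data(strsplit(sequences, ""), path,
                          format = "dna", interleaved = FALSE)
  }
  invisible(path)
}

#' Read an aligned matrix written by [write_alignment()]
#'
#' @param path Input path.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @return Named character vector of equal-length rows.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (format == "fasta") return(read_fasta(path))
  if (format == "phylip") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    body <- strsplit(trimws(lines[-1L]), "\\s+")
    out <- toupper(vapply(body, `[[`, "", 2L))
    names(out) <- vapply(body, `[[`, "", 1L)
    return(out)
  }
  x <- ape::read.nexus.data(path)
  vapply(x, function(s) toupper(paste0(s, collapse = "")), "")
}

#' Write partition definitions
#'
#' Emits one partition per gene as `name = start-end` ranges, in
#' RAxML-style text (`DNA, name = 1-1014`) or as a NEXUS `sets` block.
#' With `stripe_codons = TRUE` each protein-coding partition is split
#' into per-codon-position subsets using stride notation
#' (`nad2_pos1 = 1-1014\3`); for a `12PRT` supermatrix, where third
#' positions have been removed, the stride is 2. An empty scheme
#' produces an empty file with no header.
#'
#' @param x A `mito_supermatrix`, or a data frame with columns `gene`,
#'   `class`, `start`, `end`.
#' @param path Output path.
#' @param style `"raxml"` or `"nexus"`.
#' @param stripe_codons Split PCG partitions by codon position?
#' @return The partition lines, invisibly.
#' @export
write_partitions <- function(x, path, style = c("raxml", "nexus"),
                             stripe_codons = FALSE) {
  style <- match.arg(style)
  scheme <- "PRT"
  if (inherits(x, "mito_supermatrix")) { scheme <- x$scheme; x <- x$partitions }
  defs <- character(); nms <- character()
  if (!is.null(x) && nrow(x)) {
    stride <- if (identical(scheme, "12PRT")) 2L else 3L
    for (i in seq_len(nrow(x))) {
      if (stripe_codons && x$class[i] == "PCG") {
        for (k in seq_len(stride)) {
          nms <- c(nms, sprintf("%s_pos%d", x$gene[i], k))
          defs <- c(defs, sprintf("%d-%d\\%d", x$start[i] + k - 1L, x$end[i], stride))
        }
      } else {
        nms <- c(nms, x$gene[i])
        defs <- c(defs, sprintf("%d-%d", x$start[i], x$end[i]))
      }
    }
  }
  if (!length(defs)) { writeLines(character(), path); return(invisible(character())) }
  lines <- switch(style,
    raxml = sprintf("DNA, %s = %s", nms, defs),
    nexus = c("#NEXUS", "begin sets;",
              sprintf("    charset %s = %s;", nms, defs), "end;"))
  writeLines(lines, path)
  invisible(lines)
}
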