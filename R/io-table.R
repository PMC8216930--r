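#' Write an NCBI 5-column feature table
#'
#' One `gene` feature per annotated region, with the coordinate pair
#' emitted reversed (`to` before `from`) for N-strand features, per TBL
#' convention, followed by a `gene` qualifier line carrying the
#' canonical name.
#'
#' @param annotation A [mito_annotation].
#' @param path Optional output path; when `NULL` the TBL text is
#'   returned as a character vector.
#' @return The TBL lines (invisibly when written to a file).
#' @export
write_feature_table <- function(annotation, path = NULL) {
  lines <- sprintf(">Feature %s", attr(annotation, "genome_id"))
  for (i in seq_len(nrow(annotation))) {
    f <- annotation[i, ]
    coords <- if (f$strand == "N") c(f$to, f$from) else c(f$from, f$to)
    lines <- c(lines,
               sprintf("%d\t%d\tgene", coords[1L], coords[2L]),
               sprintf("\t\t\tgene\t%s", f$gene))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read an NCBI 5-column feature table
#'
#' @param x Path to a TBL file, or its lines as a character vector.
#' @param genome The [mito_genome] the table annotates (supplies the
#'   sequence for codon classification and the genome length).
#' @return A [mito_annotation]. Reversed coordinate pairs become
#'   N-strand features; gene classes are resolved from the canonical
#'   gene list. A malformed line raises a parse error naming the line.
#' @export
read_feature_table <- function(x, genome) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  id <- genome$id
  rows <- list(); pending <- NULL
  cls_map <- canonical_gene_classes()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">Feature")) {
      id <- trimws(sub("^>Feature", "", ln))
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) >= 3L && nzchar(parts[1L])) {
      a <- suppressWarnings(as.integer(parts[1L]))
      b <- suppressWarnings(as.integer(parts[2L]))
      if (is.na(a) || is.na(b))
        stop("TBL parse error at line ", i, ": non-numeric coordinates", call. = FALSE)
      pending <- list(a = a, b = b)
    } else if (length(parts) == 5L && identical(parts[4L], "gene")) {
      if (is.null(pending))
        stop("TBL parse error at line ", i, ": qualifier before coordinates", call. = FALSE)
      name <- canonical_gene_name(parts[5L])
      if (is.na(name)) {
        warning("skipping unmappable gene label: ", parts[5L])
        pending <- NULL
        next
      }
      strand <- if (pending$a > pending$b) "N" else "J"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = name, class = unname(cls_map[name]),
        from = min(pending$a, pending$b), to = max(pending$a, pending$b),
        strand = strand, start_codon = NA_character_,
        stop_codon = NA_character_, stringsAsFactors = FALSE)
      pending <- NULL
    } else {
      stop("TBL parse error at line ", i, ": unrecognized line", call. = FALSE)
    }
  }
  if (!length(rows)) stop("no features in table", call. = FALSE)
  ann <- mito_annotation(do.call(rbind, rows), genome_id = id,
                         genome_length = genome$length)
  for (i in which(ann$class == "PCG")) {
    cls <- classify_codons(sense_sequence(genome, ann[i, ]))
    ann$start_codon[i] <- cls$start_codon
    ann$stop_codon[i] <- cls$stop_codon
  }
  ann
}

#' Read an architecture specification table
#'
#' An architecture spec is a TSV transcription of a mitogenome
#' organization table: columns `gene`, `class`, `from`, `to`, `size`,
#' `ign` (blank for the first feature; source-table blanks are 0),
#' `strand`, `start_codon`, `stop_codon`. The declared `size` and `ign`
#' columns are checked against the coordinates; any inconsistency is a
#' spec error naming the offending row.
#'
#' @param path Path to the TSV (lines starting with `#` are comments).
#' @return Data frame with the spec columns, validated.
#' @export
read_architecture_spec <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(start_codon = "character",
                                         stop_codon = "character"))
  need <- c("gene", "class", "from", "to", "size", "ign", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("architecture spec missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(df$size != df$to - df$from + 1L)
  if (length(bad))
    stop("architecture spec error: declared size != to - from + 1 for ",
         paste(df$gene[bad], collapse = ", "), call. = FALSE)
  ign_calc <- c(NA_integer_, df$from[-1L] - df$to[-nrow(df)] - 1L)
  bad <- which(!is.na(df$ign) & !is.na(ign_calc) & df$ign != ign_calc)
  if (length(bad))
    stop("architecture spec error: declared ign inconsistent with coordinates for ",
         paste(df$gene[bad], collapse = ", "), call. = FALSE)
  df
}

#' Packaged skipper mitogenome architectures
#'
#' Architecture specification tables for the three Aeromachini skipper
#' mitogenomes shipped with the package: *Ampittia virgata* (15,333 bp),
#' *Halpe nephele* (15,291 bp) and *Onryza maga* (15,381 bp). These are
#' transcriptions of the published organization tables (coordinates,
#' strands, start/stop codons); sequence content is synthesized by
#' [replicate_architecture()], not deposited data.
#'
#' @param species One of `"ampittia_virgata"`, `"halpe_nephele"`,
#'   `"onryza_maga"`, or `NULL` to list available names.
#' @return The spec data frame (see [read_architecture_spec()]), or the
#'   vector of available names.
#' @export
skipper_architecture <- function(species = NULL) {
  files <- list.files(system.file("extdata", package = "mitoarch"),
                      pattern = "\\.tsv$")
  avail <- sub("\\.tsv$", "", files)
  if (is.null(species)) return(avail)
  species <- match.arg(species, avail)
  read_architecture_spec(system.file("extdata", paste0(species, ".tsv"),
                                     package = "mitoarch"))
}
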