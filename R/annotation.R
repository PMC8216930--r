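#' Canonical lepidopteran mitochondrial gene order
#'
#' The fixed 37-gene order (13 protein-coding genes, 22 tRNAs, 2 rRNAs)
#' plus the terminal A+T-rich noncoding region (NCR), linearized at
#' *trnM*, as found across lepidopteran mitogenomes. The two leucine and
#' serine tRNAs are disambiguated as trnL1 (CUN) / trnL2 (UUR) and
#' trnS1 (AGN) / trnS2 (UCN).
#'
#' @return Character vector of 38 region names in genomic order.
#' @export
canonical_gene_order <- function() {
  c("trnM", "trnI", "trnQ", "nad2", "trnW", "trnC", "trnY", "cox1",
    "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3", "trnG",
    "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF", "nad5",
    "trnH", "nad4", "nad4L", "trnT", "trnP", "nad6", "cytb", "trnS2",
    "nad1", "trnL1", "rrnL", "trnV", "rrnS", "NCR")
}

# class of each canonical region
canonical_gene_classes <- function() {
  ord <- canonical_gene_order()
  cls <- rep("tRNA", length(ord))
  cls[ord %in% c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                 "cox1", "cox2", "cox3", "atp6", "atp8", "cytb")] <- "PCG"
  cls[ord %in% c("rrnL", "rrnS")] <- "rRNA"
  cls[ord == "NCR"] <- "NCR"
  names(cls) <- ord
  cls
}

#' Construct an annotation table
#'
#' The in-memory form of a mitogenome organization table: one row per
#' feature with 1-based inclusive coordinates on the J strand, the strand
#' the gene is read from, and (for protein-coding genes) the start and
#' stop codon as annotated. Features are sorted by `from`-coordinate.
#'
#' @param features Data frame with columns `gene`, `class` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"NCR"`), `from`, `to`, `strand`
#'   (`"J"`/`"N"`) and optionally `start_codon`, `stop_codon`
#'   (`NA`/empty for non-PCGs).
#' @param genome_id Identifier of the genome the table annotates.
#' @param genome_length Genome length in bp.
#' @return A data frame of class `mito_annotation` with attributes
#'   `genome_id` and `genome_length`.
#' @export
mito_annotation <- function(features, genome_id = "genome", genome_length = max(features$to)) {
  need <- c("gene", "class", "from", "to", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(features$start_codon)) features$start_codon <- NA_character_
  if (is.null(features$stop_codon))  features$stop_codon  <- NA_character_
  features$start_codon[!nzchar(features$start_codon) | is.na(features$start_codon)] <- NA_character_
  features$stop_codon[!nzchar(features$stop_codon) | is.na(features$stop_codon)] <- NA_character_
  features$from <- as.integer(features$from)
  features$to <- as.integer(features$to)
  features <- features[order(features$from), , drop = FALSE]
  rownames(features) <- NULL
  structure(features,
            genome_id = as.character(genome_id),
            genome_length = as.integer(genome_length),
            class = c("mito_annotation", "data.frame"))
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("<mito_annotation> %s: %d features, genome %d bp\n",
              attr(x, "genome_id"), nrow(x), attr(x, "genome_length")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Validate an annotation table
#'
#' Checks an annotation against the canonical 37-gene + NCR model:
#' missing or duplicated canonical genes, coordinate sanity
#' (`1 <= from <= to <= genome length`), strictly increasing feature
#' order, exactly one NCR, and start/stop codons present exactly for
#' PCGs. Validation reports issues; it never throws.
#'
#' @param annotation A [mito_annotation].
#' @return Data frame with columns `type`, `gene`, `message`; zero rows
#'   for a complete, consistent table.
#' @export
validate_annotation <- function(annotation) {
  issues <- list()
  add <- function(type, gene, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, gene = gene, message = msg, stringsAsFactors = FALSE)

  glen <- attr(annotation, "genome_length")
  missing <- setdiff(canonical_gene_order(), annotation$gene)
  for (m in missing) add("missing_gene", m, paste0("canonical region ", m, " absent"))
  dup <- unique(annotation$gene[duplicated(annotation$gene)])
  for (d in dup) add("duplicate_gene", d, paste0(d, " annotated more than once"))

  for (i in seq_len(nrow(annotation))) {
    f <- annotation[i, ]
    if (is.na(f$from) || is.na(f$to) || f$from > f$to)
      add("coordinate", f$gene, sprintf("to (%s) < from (%s)", f$to, f$from))
    else if (f$from < 1L || (!is.null(glen) && f$to > glen))
      add("bounds", f$gene, sprintf("[%d..%d] outside 1..%d", f$from, f$to, glen))
    if (!f$strand %in% c("J", "N"))
      add("strand", f$gene, paste0("unknown strand ", f$strand))
    if (identical(f$class, "PCG")) {
      if (is.na(f$start_codon) || is.na(f$stop_codon))
        add("codon", f$gene, "PCG lacks annotated start/stop codon")
    } else if (!is.na(f$start_codon) || !is.na(f$stop_codon)) {
      add("codon", f$gene, "non-PCG carries start/stop codon")
    }
  }
  if (is.unsorted(annotation$from, strictly = FALSE))
    add("order", NA_character_, "features not sorted by from-coordinate")
  n_ncr <- sum(annotation$class == "NCR")
  if (n_ncr != 1L)
    add("ncr", NA_character_, sprintf("expected exactly one NCR, found %d", n_ncr))

  if (!length(issues))
    return(data.frame(type = character(), gene = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
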