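#' Construct a per-gene alignment
#'
#' @param gene Gene name (canonical where possible).
#' @param sequences Named character vector, taxon -> aligned sequence;
#'   all rows must have equal length. For PCGs the alignment length must
#'   be divisible by 3 (incomplete stops trimmed before alignment).
#' @param class Gene class, `"PCG"`, `"tRNA"` or `"rRNA"`; inferred from
#'   the canonical gene list when omitted.
#' @return Object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene, sequences, class = NULL) {
  if (!length(sequences)) stop("empty alignment for ", gene, call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("alignment rows must be named by taxon", call. = FALSE)
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("ragged alignment for ", gene, ": row lengths ",
         paste(len, collapse = ", "), call. = FALSE)
  if (is.null(class)) {
    cls <- canonical_gene_classes()
    class <- if (gene %in% names(cls)) unname(cls[gene]) else "PCG"
  }
  if (class == "PCG" && len %% 3L != 0L)
    stop("PCG alignment ", gene, " length ", len, " not divisible by 3",
         call. = FALSE)
  structure(list(gene = gene, class = class,
                 sequences = toupper(sequences), length = len),
            class = "gene_alignment")
}

#' Extract per-gene sense-strand sequences across genomes
#'
#' Pulls the (unaligned) sense-strand sequence of each requested gene
#' from each genome; protein-coding genes are trimmed of incomplete stop
#' nucleotides so their lengths are divisible by 3. A gene missing from
#' one genome is recorded as a gap taxon (`NA`), not an error.
#'
#' @param genomes List of [mito_genome] objects.
#' @param annotations List of matching [mito_annotation] objects.
#' @param genes Gene names to extract (default: all 37 genes).
#' @return Named list, one element per gene: a named character vector
#'   taxon -> sequence with `NA` for missing taxa.
#' @export
extract_gene_set <- function(genomes, annotations,
                             genes = setdiff(canonical_gene_order(), "NCR")) {
  stopifnot(length(genomes) == length(annotations))
  taxa <- vapply(genomes, function(g) g$id, "")
  out <- list()
  for (gene in genes) {
    seqs <- rep(NA_character_, length(genomes))
    names(seqs) <- taxa
    for (i in seq_along(genomes)) {
      ann <- annotations[[i]]
      row <- ann[ann$gene == gene, , drop = FALSE]
      if (!nrow(row)) next
      s <- sense_sequence(genomes[[i]], row[1L, ])
      if (identical(row$class[1L], "PCG")) {
        trim <- stop_trim(row$stop_codon[1L])
        if (trim == 0L && nchar(s) %% 3L != 0L) trim <- nchar(s) %% 3L
        s <- substr(s, 1L, nchar(s) - trim)
      }
      seqs[i] <- s
    }
    out[[gene]] <- seqs
  }
  out
}

#' Split an alignment by codon position
#'
#' Position-k sub-alignment takes columns k, k+3, k+6, ... of each row;
#' indexing is relative to the gene's own reading frame (column 1 is
#' codon position 1).
#'
#' @param sequences Named character vector of equal-length aligned rows
#'   with length divisible by 3, or a `gene_alignment`.
#' @return List of three named character vectors (`pos1`, `pos2`,
#'   `pos3`), each of length `L/3` per row.
#' @export
stripe_codon_positions <- function(sequences) {
  if (inherits(sequences, "gene_alignment")) sequences <- sequences$sequences
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("ragged alignment", call. = FALSE)
  if (len %% 3L != 0L)
    stop("alignment length ", len, " not divisible by 3", call. = FALSE)
  out <- lapply(1:3, function(k) vapply(sequences, stripe_string, "", k = k))
  names(out) <- paste0("pos", 1:3)
  out
}

# column indices kept per scheme for one gene alignment
scheme_columns <- function(len, class, scheme) {
  if (scheme == "PCG") {
    if (class != "PCG") return(integer())
    seq_len(len)
  } else if (scheme == "PRT") {
    seq_len(len)
  } else { # 12PRT: drop third codon positions of PCGs
    if (class == "PCG") setdiff(seq_len(len), seq(3L, len, by = 3L))
    else seq_len(len)
  }
}

#' Build a concatenated phylogenetic supermatrix
#'
#' Assembles one of the three standard mitogenomic datasets from
#' per-gene alignments:
#' \describe{
#'   \item{PCG}{the 13 protein-coding genes, all codon positions;}
#'   \item{PRT}{PCGs plus the 22 tRNAs and 2 rRNAs;}
#'   \item{12PRT}{as PRT but with every third codon position of the
#'     PCGs removed.}
#' }
#' Genes are concatenated in canonical genomic order (non-canonical
#' names keep their input order afterwards), taxa are sorted by
#' identifier, and taxa missing a gene are padded with gap characters.
#' Every output column is tracked back to its source
#' (gene, gene column, codon position).
#'
#' @param alignments List of [gene_alignment] objects.
#' @param scheme `"PCG"`, `"PRT"` or `"12PRT"`.
#' @param gap Padding character for missing taxa (default `"-"`).
#' @return Object of class `mito_supermatrix`: list with `scheme`,
#'   `sequences` (named character vector), `length`, `partitions`
#'   (data frame: gene, class, start, end), and `provenance`
#'   (data frame: column, gene, gene_column, codon_pos).
#' @export
build_supermatrix <- function(alignments, scheme = c("PCG", "PRT", "12PRT"),
                              gap = "-") {
  scheme <- match.arg(scheme)
  if (!length(alignments)) stop("empty gene set", call. = FALSE)
  genes <- vapply(alignments, function(a) a$gene, "")
  ord <- order(match(genes, canonical_gene_order()), seq_along(genes))
  alignments <- alignments[ord]
  taxa <- sort(unique(unlist(lapply(alignments, function(a) names(a$sequences)))))

  pieces <- stats::setNames(vector("list", length(taxa)), taxa)
  parts <- list(); prov <- list(); pos <- 0L
  for (a in alignments) {
    keep <- scheme_columns(a$length, a$class, scheme)
    if (!length(keep)) next
    chunk_len <- length(keep)
    for (tx in taxa) {
      s <- if (tx %in% names(a$sequences)) a$sequences[[tx]] else NA_character_
      piece <- if (is.na(s)) strrep(gap, chunk_len)
               else paste0(strsplit(s, "")[[1]][keep], collapse = "")
      pieces[[tx]] <- c(pieces[[tx]], piece)
    }
    parts[[length(parts) + 1L]] <- data.frame(
      gene = a$gene, class = a$class,
      start = pos + 1L, end = pos + chunk_len, stringsAsFactors = FALSE)
    prov[[length(prov) + 1L]] <- data.frame(
      column = pos + seq_len(chunk_len), gene = a$gene, gene_column = keep,
      codon_pos = if (a$class == "PCG") ((keep - 1L) %% 3L) + 1L else NA_integer_,
      stringsAsFactors = FALSE)
    pos <- pos + chunk_len
  }
  if (!pos) stop("scheme ", scheme, " selects no columns from the gene set",
                 call. = FALSE)
  seqs <- vapply(pieces, paste0, "", collapse = "")
  structure(list(scheme = scheme, sequences = seqs, length = pos,
                 partitions = do.call(rbind, parts),
                 provenance = do.call(rbind, prov)),
            class = "mito_supermatrix")
}

#' @export
print.mito_supermatrix <- function(x, ...) {
  cat(sprintf("<mito_supermatrix> %s: %d taxa x %d columns, %d partitions\n",
              x$scheme, length(x$sequences), x$length, nrow(x$partitions)))
  invisible(x)
}
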