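#' Gene size in base pairs
#'
#' @param feature List or one-row data frame with 1-based inclusive
#'   `from` and `to`.
#' @return Integer size `to - from + 1`.
#' @examples
#' gene_size(list(from = 250, to = 1263))  # 1014
#' @export
gene_size <- function(feature) {
  from <- as.integer(feature$from); to <- as.integer(feature$to)
  if (any(is.na(from)) || any(is.na(to)) || any(to < from))
    stop("invalid feature coordinates", call. = FALSE)
  to - from + 1L
}

#' Intergenic nucleotide profile
#'
#' For every pair of adjacent features computes the signed number of
#' intergenic nucleotides, `IGN = from(next) - to(previous) - 1`:
#' positive values are spacers, negative values overlaps, zero abutting
#' genes. Optionally includes the circular junction from the last
#' feature back to the first across the origin.
#'
#' @param annotation A [mito_annotation], sorted by `from`.
#' @param circular Include the wrap-around junction (last -> first)?
#' @return Data frame with columns `junction` (e.g. `"atp8-atp6"`),
#'   `gene_prev`, `gene_next`, `ign`.
#' @export
intergenic_profile <- function(annotation, circular = FALSE) {
  if (is.unsorted(annotation$from))
    stop("annotation must be sorted by from-coordinate", call. = FALSE)
  n <- nrow(annotation)
  if (n < 2L)
    return(data.frame(junction = character(), gene_prev = character(),
                      gene_next = character(), ign = integer()))
  prev <- annotation[-n, ]; nxt <- annotation[-1L, ]
  out <- data.frame(
    junction = paste0(prev$gene, "-", nxt$gene),
    gene_prev = prev$gene, gene_next = nxt$gene,
    ign = nxt$from - prev$to - 1L,
    stringsAsFactors = FALSE)
  if (circular) {
    glen <- attr(annotation, "genome_length")
    out <- rbind(out, data.frame(
      junction = paste0(annotation$gene[n], "-", annotation$gene[1L]),
      gene_prev = annotation$gene[n], gene_next = annotation$gene[1L],
      ign = annotation$from[1L] + glen - annotation$to[n] - 1L,
      stringsAsFactors = FALSE))
  }
  out
}

#' Census of gene overlaps and intergenic spacers
#'
#' Counts junctions with negative intergenic values (overlaps, reported
#' with their magnitude in bp) and positive values (spacers); zero-gap
#' junctions count in neither. Ties for the longest overlap or spacer
#' are broken by first occurrence in gene order.
#'
#' @param profile Output of [intergenic_profile()].
#' @return List with `n_overlaps`, `n_spacers`, `overlap_bp` (total
#'   overlapping bp), `longest_overlap` and `longest_spacer` (each a
#'   list with `junction` and `bp`, or `NULL` when absent).
#' @export
overlap_spacer_census <- function(profile) {
  ov <- profile[profile$ign < 0L, , drop = FALSE]
  sp <- profile[profile$ign > 0L, , drop = FALSE]
  pick <- function(df, value) {
    if (!nrow(df)) return(NULL)
    i <- which.max(value)  # first occurrence wins ties
    list(junction = df$junction[i], bp = as.integer(value[i]))
  }
  list(n_overlaps = nrow(ov), n_spacers = nrow(sp),
       overlap_bp = sum(-ov$ign),
       longest_overlap = pick(ov, -ov$ign),
       longest_spacer = pick(sp, sp$ign))
}

#' Strand census over the 37 genes
#'
#' Counts how many genes are encoded on the majority (J) and minority
#' (N) strand. The noncoding region is excluded.
#'
#' @param annotation A [mito_annotation].
#' @param classes Gene classes to include (default all of PCG/tRNA/rRNA).
#' @return Named integer vector `c(J = ..., N = ...)`.
#' @export
strand_census <- function(annotation, classes = c("PCG", "tRNA", "rRNA")) {
  genes <- annotation[annotation$class %in% classes, , drop = FALSE]
  c(J = sum(genes$strand == "J"), N = sum(genes$strand == "N"))
}

#' Classify start and stop codon of a protein-coding gene
#'
#' Operates on the sense-strand CDS text, annotated length included (the
#' incomplete stop, if any, is part of the gene). The start codon is the
#' first triplet, flagged non-canonical unless one of ATA/ATT/ATG/ATC or
#' the cox1-style CGA. The stop is read off the length modulo 3: a
#' complete TAA/TAG triplet, or an incomplete single `T` / `TA`
#' completed to TAA by polyadenylation of the mRNA.
#'
#' @param cds Sense-strand CDS sequence (character scalar, length >= 6).
#' @return List with `start_codon`, `start_canonical`, `stop_codon`
#'   (`"TAA"`, `"TAG"`, `"TA"` or `"T"`, `NA` when unclassifiable),
#'   `complete` (logical) and `issue` (`NA` or a message; classification
#'   problems are recorded, not thrown).
#' @export
classify_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6L) stop("CDS shorter than 6 nt", call. = FALSE)
  start <- substr(cds, 1L, 3L)
  res <- list(start_codon = start,
              start_canonical = start %in% c("ATA", "ATT", "ATG", "ATC", "CGA"),
              stop_codon = NA_character_, complete = NA, issue = NA_character_)
  r <- n %% 3L
  if (r == 0L) {
    last3 <- substr(cds, n - 2L, n)
    if (last3 %in% c("TAA", "TAG")) {
      res$stop_codon <- last3; res$complete <- TRUE
    } else {
      res$complete <- FALSE
      res$issue <- paste0("length divisible by 3 but final codon ", last3,
                          " is not a stop")
    }
  } else if (r == 1L) {
    tail1 <- substr(cds, n, n)
    if (tail1 == "T") { res$stop_codon <- "T"; res$complete <- FALSE }
    else res$issue <- paste0("trailing nucleotide ", tail1,
                             " cannot form an incomplete stop")
  } else {
    tail2 <- substr(cds, n - 1L, n)
    if (tail2 == "TA") { res$stop_codon <- "TA"; res$complete <- FALSE }
    else res$issue <- paste0("trailing dinucleotide ", tail2,
                             " cannot form an incomplete stop")
  }
  res
}

#' Full architecture report for one genome
#'
#' Recomputes the derived columns of a mitogenome organization table:
#' per-feature sizes and intergenic nucleotides, plus strand and
#' overlap/spacer censuses. When a genome sequence is supplied, start
#' and stop codons of PCGs are classified from the sequence itself;
#' otherwise the annotated codons are carried through.
#'
#' @param annotation A [mito_annotation].
#' @param genome Optional [mito_genome] for sequence-based codon
#'   classification.
#' @return Object of class `mito_architecture`: list with `genome_id`,
#'   `features` (data frame: gene, class, from, to, size, ign, strand,
#'   start_codon, stop_codon), `profile`, `census` (overlap/spacer census
#'   augmented with strand counts), and `circular_ign` (the NCR->first
#'   gene wrap junction, reported separately from the linear census).
#' @export
architecture_report <- function(annotation, genome = NULL) {
  feats <- as.data.frame(annotation)
  feats$size <- feats$to - feats$from + 1L
  prof <- intergenic_profile(annotation)
  feats$ign <- c(NA_integer_, prof$ign)
  if (!is.null(genome)) {
    for (i in which(feats$class == "PCG")) {
      cls <- classify_codons(sense_sequence(genome, feats[i, ]))
      feats$start_codon[i] <- cls$start_codon
      feats$stop_codon[i] <- cls$stop_codon
    }
  }
  census <- overlap_spacer_census(prof)
  census$strand <- strand_census(annotation)
  census$strand_trna <- strand_census(annotation, classes = "tRNA")
  glen <- attr(annotation, "genome_length")
  circ <- feats$from[1L] + glen - feats$to[nrow(feats)] - 1L
  structure(list(genome_id = attr(annotation, "genome_id"),
                 genome_length = glen,
                 features = feats[, c("gene", "class", "from", "to", "size",
                                      "ign", "strand", "start_codon", "stop_codon")],
                 profile = prof, census = census, circular_ign = circ),
            class = "mito_architecture")
}

#' @export
print.mito_architecture <- function(x, ...) {
  cat(sprintf("<mito_architecture> %s (%d bp)\n", x$genome_id, x$genome_length))
  cat(sprintf("  genes: %d J-strand, %d N-strand; %d overlaps (%d bp), %d spacers\n",
              x$census$strand[["J"]], x$census$strand[["N"]],
              x$census$n_overlaps, x$census$overlap_bp, x$census$n_spacers))
  print(utils::head(x$features, 5))
  if (nrow(x$features) > 5) cat("  ... ", nrow(x$features) - 5, " more features\n")
  invisible(x)
}

#' Overlap junctions shared by several genomes
#'
#' Given architecture reports for two or more genomes with the same gene
#' order, returns the junctions that overlap (negative intergenic value)
#' in every genome, with the per-genome overlap magnitudes.
#'
#' @param reports List of [architecture_report()] outputs.
#' @return Data frame: `junction` plus one bp-magnitude column per genome.
#' @export
shared_overlaps <- function(reports) {
  if (length(reports) < 1L) stop("need at least one report", call. = FALSE)
  junctions <- reports[[1L]]$profile$junction
  for (r in reports[-1L])
    if (!identical(r$profile$junction, junctions))
      stop("gene orders differ between genomes; reports are not comparable",
           call. = FALSE)
  mags <- sapply(reports, function(r) -r$profile$ign)
  if (is.null(dim(mags))) mags <- matrix(mags, nrow = length(junctions))
  keep <- apply(mags > 0L, 1L, all)
  out <- data.frame(junction = junctions[keep], stringsAsFactors = FALSE)
  ids <- vapply(reports, function(r) r$genome_id, "")
  ids[!nzchar(ids) | duplicated(ids)] <-
    paste0("genome", seq_along(ids))[!nzchar(ids) | duplicated(ids)]
  for (j in seq_along(reports)) out[[ids[j]]] <- as.integer(mags[keep, j])
  out
}

#' Rebuild coordinates from sizes and intergenic values
#'
#' The inverse of the size/IGN derivation: given the first feature's
#' start coordinate, all sizes, and the signed intergenic values for the
#' junctions, reconstructs every `from`/`to` pair. Used to verify that an
#' architecture table is internally consistent.
#'
#' @param first_from Start coordinate of the first feature.
#' @param sizes Integer vector of feature sizes (bp).
#' @param ign Integer vector of length `length(sizes) - 1` of signed
#'   intergenic values.
#' @return Data frame with columns `from` and `to`.
#' @export
reconstruct_coordinates <- function(first_from, sizes, ign) {
  n <- length(sizes)
  stopifnot(length(ign) == n - 1L)
  from <- integer(n); to <- integer(n)
  from[1L] <- as.integer(first_from)
  to[1L] <- from[1L] + sizes[1L] - 1L
  for (i in seq_len(n - 1L)) {
    from[i + 1L] <- to[i] + ign[i] + 1L
    to[i + 1L] <- from[i + 1L] + sizes[i + 1L] - 1L
  }
  data.frame(from = from, to = to)
}
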