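# nucleotides trimmed off a CDS that ends in an incomplete stop
stop_trim <- function(stop_codon) {
  ifelse(is.na(stop_codon), 0L,
         ifelse(stop_codon == "T", 1L, ifelse(stop_codon == "TA", 2L, 0L)))
}

#' Base composition and strand skew of a sequence
#'
#' Computes base counts, percentages, A+T content and the two strand
#' asymmetry measures AT-skew = (A - T)/(A + T) and
#' GC-skew = (G - C)/(G + C), both from raw counts. Values are kept at
#' full precision; printing rounds percentages to one decimal and skews
#' to three, the conventional reporting precision.
#'
#' @param sequence Character scalar over A/C/G/T.
#' @param region Label for the region the sequence represents.
#' @return One-row data frame of class `mito_composition`: `region`,
#'   `size`, `T_pct`, `C_pct`, `A_pct`, `G_pct`, `AT_pct`, `AT_skew`,
#'   `GC_skew` plus raw counts `A`, `C`, `G`, `T`. Skews are `NaN`
#'   (flagged undefined) when A+T or G+C is zero.
#' @examples
#' base_composition("AAAA")$AT_skew  # 1
#' @export
base_composition <- function(sequence, region = "sequence") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains non-ACGT characters", call. = FALSE)
  n <- nchar(sequence)
  cnt <- vapply(c("A", "C", "G", "T"), function(b)
    nchar(sequence) - nchar(gsub(b, "", sequence, fixed = TRUE)), 0L)
  at <- cnt[["A"]] + cnt[["T"]]; gc <- cnt[["G"]] + cnt[["C"]]
  out <- data.frame(
    region = region, size = n,
    T_pct = 100 * cnt[["T"]] / n, C_pct = 100 * cnt[["C"]] / n,
    A_pct = 100 * cnt[["A"]] / n, G_pct = 100 * cnt[["G"]] / n,
    AT_pct = 100 * at / n,
    AT_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NaN,
    GC_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NaN,
    A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
    stringsAsFactors = FALSE)
  class(out) <- c("mito_composition", "data.frame")
  out
}

#' @export
print.mito_composition <- function(x, digits_pct = 1, digits_skew = 3, ...) {
  y <- as.data.frame(x)
  for (cl in c("T_pct", "C_pct", "A_pct", "G_pct", "AT_pct"))
    y[[cl]] <- round(y[[cl]], digits_pct)
  for (cl in c("AT_skew", "GC_skew")) y[[cl]] <- round(y[[cl]], digits_skew)
  print(y[, !(names(y) %in% c("A", "C", "G", "T"))], row.names = FALSE)
  invisible(x)
}

# pooled sense-strand PCG concatenation, incomplete stop nucleotides removed
pooled_pcg_sequence <- function(genome, annotation) {
  pcg <- annotation[annotation$class == "PCG", , drop = FALSE]
  pcg <- pcg[order(match(pcg$gene, canonical_gene_order())), , drop = FALSE]
  seqs <- character(nrow(pcg))
  for (i in seq_len(nrow(pcg))) {
    s <- sense_sequence(genome, pcg[i, ])
    trim <- stop_trim(pcg$stop_codon[i])
    # unannotated stop: fall back to the length remainder
    if (trim == 0L && nchar(s) %% 3L != 0L) trim <- nchar(s) %% 3L
    seqs[i] <- substr(s, 1L, nchar(s) - trim)
  }
  names(seqs) <- pcg$gene
  seqs
}

# every third character starting at k
stripe_string <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  paste0(chars[seq(k, length(chars), by = 3L)], collapse = "")
}

#' Region-wise composition statistics
#'
#' Reproduces a region composition table for one genome: the pooled
#' protein-coding genes, the three codon positions, the A+T-rich
#' noncoding region, the pooled tRNAs, the pooled rRNAs, and the full
#' genome. Pooled PCG/tRNA/rRNA statistics use sense-strand sequences;
#' the full genome is measured on the major (J) strand. Incomplete stop
#' nucleotides (`T`/`TA`) are excluded from the PCG pool, which makes the
#' pool length divisible by three; codon positions are striped from the
#' pooled, trimmed sense concatenation (equivalently, per gene in its own
#' reading frame).
#'
#' @param genome A [mito_genome].
#' @param annotation A [mito_annotation].
#' @return Data frame of class `mito_composition` with one row per
#'   region, in the order PCGs, 1st/2nd/3rd codon position, NCR, tRNAs,
#'   rRNAs, full genome. Regions absent from the annotation are omitted
#'   with a warning.
#' @export
region_stats <- function(genome, annotation) {
  pool <- function(classes) {
    f <- annotation[annotation$class %in% classes, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    f <- f[order(match(f$gene, canonical_gene_order())), , drop = FALSE]
    paste0(vapply(seq_len(nrow(f)), function(i)
      sense_sequence(genome, f[i, ]), ""), collapse = "")
  }
  rows <- list()
  pcg <- paste0(pooled_pcg_sequence(genome, annotation), collapse = "")
  if (nzchar(pcg)) {
    rows$PCGs <- base_composition(pcg, "PCGs")
    for (k in 1:3)
      rows[[paste0("codon", k)]] <- base_composition(
        stripe_string(pcg, k), paste0(c("1st", "2nd", "3rd")[k], " codon position"))
  } else warning("no PCGs annotated; PCG and codon-position rows omitted")
  ncr <- annotation[annotation$class == "NCR", , drop = FALSE]
  if (nrow(ncr)) rows$NCR <- base_composition(sense_sequence(genome, ncr[1L, ]), "NCR")
  else warning("no NCR annotated; NCR row omitted")
  trna <- pool("tRNA")
  if (!is.null(trna)) rows$tRNAs <- base_composition(trna, "tRNAs")
  else warning("no tRNAs annotated; tRNA row omitted")
  rrna <- pool("rRNA")
  if (!is.null(rrna)) rows$rRNAs <- base_composition(rrna, "rRNAs")
  else warning("no rRNAs annotated; rRNA row omitted")
  rows$full <- base_composition(genome$sequence, "Full genome")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mito_composition", "data.frame")
  out
}

#' A+T content of a composition row
#'
#' @param stats A `mito_composition` row (or data frame of rows).
#' @return `A% + T%` as a numeric vector.
#' @export
at_content <- function(stats) stats$A_pct + stats$T_pct
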