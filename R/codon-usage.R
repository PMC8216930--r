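#' Count codons over pooled protein-coding genes
#'
#' Tallies in-frame codons (frame 0, stride 3) over a set of
#' sense-strand CDS sequences that have already been trimmed of
#' incomplete stop nucleotides. Complete stop codons (TAA/TAG) are
#' counted but excluded from synonymous families, so they never enter
#' RSCU.
#'
#' @param sequences Named character vector of sense-strand CDS
#'   sequences, each of length divisible by 3.
#' @param codon_table Codon table, by default [mito_codon_table()].
#' @return Data frame of class `mito_codon_usage`: one row per codon
#'   with `codon`, `aa`, `family`, `family_size`, `is_stop`, `count`.
#' @export
count_codons <- function(sequences, codon_table = mito_codon_table()) {
  sequences <- toupper(sequences)
  bad <- which(nchar(sequences) %% 3L != 0L)
  if (length(bad))
    stop("sequence length not divisible by 3 for: ",
         paste(if (is.null(names(sequences))) bad else names(sequences)[bad],
               collapse = ", "), call. = FALSE)
  counts <- integer(nrow(codon_table))
  names(counts) <- codon_table$codon
  for (s in sequences) {
    if (!nzchar(s)) next
    cod <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                     seq(3L, nchar(s), by = 3L))
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- codon_table
  out$count <- unname(counts[out$codon])
  class(out) <- c("mito_codon_usage", "data.frame")
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count of
#' its synonymous family: `count * family_size / family_total`. Families
#' follow the invertebrate mitochondrial code with leucine and serine
#' split into their two codon boxes. A family observed zero times has no
#' defined RSCU (`NaN`).
#'
#' @param usage Output of [count_codons()].
#' @return The usage table with an added `rscu` column (`NA` for stop
#'   codons, `NaN` for unobserved families).
#' @export
rscu <- function(usage) {
  fam_tot <- tapply(usage$count[!usage$is_stop],
                    usage$family[!usage$is_stop], sum)
  usage$rscu <- ifelse(usage$is_stop, NA_real_,
                       usage$count * usage$family_size /
                         as.numeric(fam_tot[usage$family]))
  usage$rscu[!usage$is_stop & fam_tot[usage$family] == 0] <- NaN
  class(usage) <- c("mito_codon_usage", "data.frame")
  usage
}

#' @export
print.mito_codon_usage <- function(x, n = 10, ...) {
  y <- as.data.frame(x)
  y$codon <- codon_to_rna(y$codon)
  if ("rscu" %in% names(y)) {
    y <- y[order(-ifelse(is.na(y$rscu) | is.nan(y$rscu), -Inf, y$rscu)), ]
    y$rscu <- round(y$rscu, 2)
  }
  cat("<mito_codon_usage> ", sum(x$count), " codons\n", sep = "")
  print(utils::head(y, n), row.names = FALSE)
  invisible(x)
}

#' Most heavily used codons by RSCU
#'
#' Deterministic ranking: RSCU descending, ties broken by raw count
#' descending, then codon alphabetically. Stop codons and unobserved
#' families are excluded.
#'
#' @param usage Output of [count_codons()] (RSCU is computed if absent).
#' @param k Number of codons to return; a `k` beyond the table is
#'   truncated.
#' @param alphabet `"RNA"` (default, e.g. `"UUA"`) or `"DNA"` codon
#'   spelling in the result.
#' @return Data frame with `codon`, `family`, `count`, `rscu`, ranked.
#' @export
top_codons <- function(usage, k = 3, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!"rscu" %in% names(usage)) usage <- rscu(usage)
  u <- usage[!usage$is_stop & is.finite(usage$rscu), , drop = FALSE]
  u <- u[order(-u$rscu, -u$count, u$codon), , drop = FALSE]
  u <- utils::head(u, max(0L, as.integer(k)))
  out <- data.frame(codon = if (alphabet == "RNA") codon_to_rna(u$codon) else u$codon,
                    family = u$family, count = u$count, rscu = u$rscu,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Codon usage of an annotated genome
#'
#' Convenience wrapper: pools the sense-strand protein-coding sequences
#' (incomplete stops trimmed), counts codons and computes RSCU.
#'
#' @param genome A [mito_genome].
#' @param annotation A [mito_annotation].
#' @return A `mito_codon_usage` table with RSCU.
#' @export
codon_usage <- function(genome, annotation) {
  rscu(count_codons(pooled_pcg_sequence(genome, annotation)))
}
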