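#' Extract the A+T-rich control region
#'
#' Returns the J-strand text of the noncoding control region (NCR),
#' the longest noncoding stretch of the mitogenome, located between
#' *rrnS* and *trnM* in the lepidopteran gene order.
#'
#' @param genome A [mito_genome].
#' @param annotation A [mito_annotation] containing an NCR feature.
#' @return Character scalar.
#' @export
extract_ncr <- function(genome, annotation) {
  ncr <- annotation[annotation$class == "NCR", , drop = FALSE]
  if (!nrow(ncr))
    stop("annotation has no NCR / A+T-rich region", call. = FALSE)
  sense_sequence(genome, ncr[1L, ])
}

#' Find poly-A / poly-T runs allowing short interruptions
#'
#' Detects homopolymer stretches of `base`, tolerating interruptions of
#' at most `max_interruptions` consecutive other bases at a time —
#' mitochondrial control-region poly-A stretches are often interrupted
#' by single T residues. A run starts and ends on the run base, is
#' extended left-greedily as far as the interruption rule allows
#' (maximal windows), runs never overlap, and a run is reported only if
#' it contains at least `min_pure` copies of the run base.
#'
#' @param sequence Character scalar.
#' @param base The run base, `"A"` or `"T"`.
#' @param min_pure Minimum count of the run base within the window.
#' @param max_interruptions Maximum consecutive non-`base` characters
#'   tolerated inside a run; `0` reduces to classical homopolymer
#'   detection.
#' @return Data frame with columns `base`, `start`, `end`, `length`
#'   (window span), `pure_count` and `interruptions` (count of tolerated
#'   other-base positions).
#' @examples
#' find_poly_runs("AAAATAAAA", "A", min_pure = 8, max_interruptions = 1)
#' @export
find_poly_runs <- function(sequence, base, min_pure = 10, max_interruptions = 1) {
  stopifnot(min_pure >= 1, max_interruptions >= 0)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (chars[i] != base) { i <- i + 1L; next }
    last_hit <- i; pure <- 1L; gap <- 0L
    k <- i + 1L
    while (k <= n) {
      if (chars[k] == base) { pure <- pure + 1L; last_hit <- k; gap <- 0L }
      else { gap <- gap + 1L; if (gap > max_interruptions) break }
      k <- k + 1L
    }
    if (pure >= min_pure) {
      len <- last_hit - i + 1L
      runs[[length(runs) + 1L]] <- data.frame(
        base = base, start = i, end = last_hit, length = len,
        pure_count = pure, interruptions = len - pure,
        stringsAsFactors = FALSE)
    }
    i <- last_hit + 1L
  }
  if (!length(runs))
    return(data.frame(base = character(), start = integer(), end = integer(),
                      length = integer(), pure_count = integer(),
                      interruptions = integer(), stringsAsFactors = FALSE))
  do.call(rbind, runs)
}

#' Control-region run report
#'
#' Extracts the NCR and reports its poly-T and poly-A runs along with
#' its base composition.
#'
#' @inheritParams extract_ncr
#' @inheritParams find_poly_runs
#' @return List with `sequence`, `composition` (one
#'   [base_composition()] row) and `runs` (poly-T and poly-A combined).
#' @export
control_region_report <- function(genome, annotation, min_pure = 10,
                                  max_interruptions = 1) {
  ncr <- extract_ncr(genome, annotation)
  runs <- rbind(find_poly_runs(ncr, "T", min_pure, max_interruptions),
                find_poly_runs(ncr, "A", min_pure, max_interruptions))
  list(sequence = ncr, composition = base_composition(ncr, "NCR"), runs = runs)
}
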