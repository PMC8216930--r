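comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Default codon sampling weights
#'
#' Codon weights for filling protein-coding interiors. Each codon's
#' weight is the product of independent base probabilities at the target
#' A+T fraction (`P(A) = P(T) = target_at/2`), with stop codons removed,
#' optionally multiplied by per-codon enrichment factors. The default
#' enrichment boosts TTA (Leu2), TCT (Ser2) and CGA (Arg), the three
#' codons observed to dominate relative synonymous codon usage in
#' skipper mitogenomes, so generated genomes show the same usage
#' signature.
#'
#' @param target_at Target A+T fraction (default 0.80, the typical
#'   lepidopteran mitogenome value).
#' @param enrich Named numeric vector of multiplicative boosts
#'   (DNA-alphabet codons); `NULL` for none.
#' @return Named numeric vector over the 64 codons summing to 1 (stop
#'   codons have weight 0).
#' @export
default_codon_weights <- function(target_at = 0.80,
                                  enrich = c(TTA = 3, TCT = 3, CGA = 3)) {
  ct <- mito_codon_table()
  p <- c(A = target_at / 2, T = target_at / 2,
         C = (1 - target_at) / 2, G = (1 - target_at) / 2)
  w <- vapply(ct$codon, function(cod) {
    prod(p[strsplit(cod, "")[[1]]])
  }, 0)
  w[ct$is_stop] <- 0
  if (!is.null(enrich)) w[names(enrich)] <- w[names(enrich)] * enrich
  w / sum(w)
}

#' Synthetic mitogenome profile
#'
#' Bundles everything [random_mitogenome()] needs: the gene layout
#' (coordinates, strands, per-PCG start/stop codons), the target A+T
#' fraction for unconstrained positions, the codon model for
#' protein-coding interiors, and the control-region run specification.
#'
#' @param features Data frame with columns `gene`, `class`, `from`,
#'   `to`, `strand`, `start_codon`, `stop_codon` (as in a
#'   [mito_annotation]).
#' @param id Genome identifier.
#' @param target_at Target A+T fraction for unconstrained positions.
#' @param codon_weights Codon sampling weights
#'   (default [default_codon_weights()] at `target_at`).
#' @param ncr_runs `NULL`, or a list with `poly_t` (pure T count of the
#'   poly-T stretch), `poly_a` (pure A count of the poly-A stretch) and
#'   `poly_a_interruptions` (number of single-T interruptions inside the
#'   poly-A).
#' @return Object of class `synth_profile`.
#' @export
synth_profile <- function(features, id = "synthetic", target_at = 0.80,
                          codon_weights = NULL,
                          ncr_runs = list(poly_t = 19, poly_a = 18,
                                          poly_a_interruptions = 1)) {
  stopifnot(all(c("gene", "class", "from", "to", "strand") %in% names(features)))
  if (is.null(features$start_codon)) features$start_codon <- NA_character_
  if (is.null(features$stop_codon)) features$stop_codon <- NA_character_
  features$start_codon[!is.na(features$start_codon) & !nzchar(features$start_codon)] <- NA_character_
  features$stop_codon[!is.na(features$stop_codon) & !nzchar(features$stop_codon)] <- NA_character_
  sizes <- features$to - features$from + 1L
  if (any(sizes < 1L)) stop("profile error: non-positive gene length", call. = FALSE)
  if (is.unsorted(features$from))
    stop("profile error: features not in increasing from-coordinate order", call. = FALSE)
  pcg <- which(features$class == "PCG")
  trim <- stop_trim(features$stop_codon[pcg])
  bad <- pcg[(sizes[pcg] - trim) %% 3L != 0L]
  if (length(bad))
    stop("profile error: PCG length inconsistent with declared stop completeness for ",
         paste(features$gene[bad], collapse = ", "), call. = FALSE)
  if (is.null(codon_weights)) codon_weights <- default_codon_weights(target_at)
  structure(list(features = features, id = id, target_at = target_at,
                 codon_weights = codon_weights, ncr_runs = ncr_runs,
                 genome_length = max(features$to)),
            class = "synth_profile")
}

# sense position -> J-strand index for one feature
sense_to_j <- function(feat, p) {
  if (feat$strand == "N") feat$to - p + 1L else feat$from + p - 1L
}

#' Generate a random annotated mitogenome from a profile
#'
#' Synthesizes a genome whose architecture (coordinates, strands,
#' start/stop codons) matches the profile exactly. Protein-coding genes
#' begin with their declared start codon, end with their declared
#' (possibly incomplete) stop, contain no in-frame premature TAA/TAG on
#' the sense strand, and have interiors drawn codon-wise from the
#' profile's codon model. Positions shared by overlapping genes are
#' written once and respected by every later gene: codon sampling is
#' restricted to codons consistent with already-fixed bases. Remaining
#' positions (tRNAs, rRNAs, spacers, NCR) are drawn i.i.d. at the target
#' A+T fraction, after the control-region poly-T/poly-A stretches are
#' placed. Deterministic for a fixed profile and seed.
#'
#' @param profile A [synth_profile].
#' @param seed Integer seed.
#' @return List with `genome` ([mito_genome]) and `annotation`
#'   ([mito_annotation]).
#' @export
random_mitogenome <- function(profile, seed = 1) {
  stopifnot(inherits(profile, "synth_profile"))
  set.seed(seed)
  feats <- profile$features
  L <- profile$genome_length
  ct <- mito_codon_table()
  sense_codons <- ct$codon[!ct$is_stop]
  w_all <- profile$codon_weights
  w_sense <- w_all[sense_codons]

  for (attempt in seq_len(25L)) {
    b <- rep(NA_character_, L)
    set_sense <- function(feat, p, base) {
      j <- sense_to_j(feat, p)
      val <- if (feat$strand == "N") comp_base[[base]] else base
      if (!is.na(b[j]) && b[j] != val)
        stop("infeasible constraints: conflicting bases required at position ", j,
             " (gene ", feat$gene, ")", call. = FALSE)
      b[j] <<- val
    }
    get_sense <- function(feat, p) {
      j <- sense_to_j(feat, p)
      if (is.na(b[j])) NA_character_
      else if (feat$strand == "N") comp_base[[b[j]]] else b[j]
    }

    pcg_idx <- which(feats$class == "PCG")
    # hard constraints: every start and (possibly incomplete) stop codon
    for (i in pcg_idx) {
      feat <- feats[i, ]
      n <- feat$to - feat$from + 1L
      sc <- strsplit(feat$start_codon, "")[[1L]]
      for (p in 1:3) set_sense(feat, p, sc[p])
      st <- feat$stop_codon
      if (st %in% c("TAA", "TAG")) {
        stc <- strsplit(st, "")[[1L]]
        for (p in 1:3) set_sense(feat, n - 3L + p, stc[p])
      } else if (identical(st, "TA")) {
        set_sense(feat, n - 1L, "T"); set_sense(feat, n, "A")
      } else if (identical(st, "T")) {
        set_sense(feat, n, "T")
      }
    }

    # codon-wise interior fill, consistent with already-fixed bases
    failed <- FALSE
    for (i in pcg_idx) {
      feat <- feats[i, ]
      n <- feat$to - feat$from + 1L
      ncod <- (n - stop_trim(feat$stop_codon)) %/% 3L
      last_interior <- if (feat$stop_codon %in% c("TAA", "TAG")) ncod - 1L else ncod
      for (ci in seq(2L, length.out = max(0L, last_interior - 1L))) {
        pp <- 3L * (ci - 1L) + 1:3
        fixed <- vapply(pp, function(p) get_sense(feat, p), "")
        if (all(is.na(fixed))) {  # fast path: unconstrained codon
          cod <- sample(sense_codons, 1L, prob = w_sense)
          codc <- strsplit(cod, "")[[1L]]
          for (k in 1:3) set_sense(feat, pp[k], codc[k])
          next
        }
        if (!anyNA(fixed)) {
          cod <- paste0(fixed, collapse = "")
          if (cod %in% c("TAA", "TAG")) { failed <- TRUE; break }
          next
        }
        pat <- paste0(ifelse(is.na(fixed), ".", fixed), collapse = "")
        cand <- sense_codons[grepl(paste0("^", pat, "$"), sense_codons)]
        w <- w_all[cand]
        if (all(w == 0)) w <- rep(1, length(cand))
        cod <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
        codc <- strsplit(cod, "")[[1L]]
        for (k in 1:3) if (is.na(fixed[k])) set_sense(feat, pp[k], codc[k])
      }
      if (failed) break
    }
    if (failed) next  # resample from the continuing random stream

    # control-region poly-T / poly-A stretches
    ncr_i <- which(feats$class == "NCR")
    if (length(ncr_i) && !is.null(profile$ncr_runs)) {
      feat <- feats[ncr_i[1L], ]
      nlen <- feat$to - feat$from + 1L
      rs <- profile$ncr_runs
      put <- function(offsets, bases) {
        j <- feat$from + offsets - 1L
        ok <- is.na(b[j])
        b[j[ok]] <<- bases[ok]
      }
      lt <- min(rs$poly_t, max(0L, nlen %/% 3L))
      if (lt > 0L) put(seq_len(lt) + max(1L, nlen %/% 6L),
                       rep("T", lt))
      ni <- if (is.null(rs$poly_a_interruptions)) 0L else rs$poly_a_interruptions
      la <- rs$poly_a
      win <- character(la + ni)
      win[] <- "A"
      if (ni > 0L)
        win[round(seq_len(ni) * (la + ni) / (ni + 1L))] <- "T"
      end_off <- nlen - 5L
      if (la + ni > 0L && end_off - (la + ni) + 1L > lt + nlen %/% 6L + 2L)
        put(seq(end_off - length(win) + 1L, end_off), win)
    }

    # everything still free: i.i.d. draw at the target composition
    free <- which(is.na(b))
    at <- profile$target_at
    b[free] <- sample(c("A", "T", "G", "C"), length(free), replace = TRUE,
                      prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))

    genome <- mito_genome(paste0(b, collapse = ""), id = profile$id)
    ann <- mito_annotation(feats, genome_id = profile$id, genome_length = L)

    # verify: every PCG classifies cleanly with no premature stops
    clean <- TRUE
    for (i in pcg_idx) {
      s <- sense_sequence(genome, ann[ann$gene == feats$gene[i], ][1L, ])
      cls <- classify_codons(s)
      trimmed <- substr(s, 1L, nchar(s) - stop_trim(cls$stop_codon))
      ncod <- nchar(trimmed) %/% 3L
      cods <- substring(trimmed, seq(1L, by = 3L, length.out = ncod),
                        seq(3L, by = 3L, length.out = ncod))
      interior <- if (cls$complete %in% TRUE) cods[-ncod] else cods
      if (!is.na(cls$issue) || any(interior %in% c("TAA", "TAG"))) {
        clean <- FALSE; break
      }
    }
    if (clean) return(list(genome = genome, annotation = ann))
  }
  stop("constraint error: could not generate a stop-free genome for this profile",
       call. = FALSE)
}

#' Replicate a published mitogenome architecture
#'
#' Builds a synthetic genome whose recomputed architecture report equals
#' an architecture specification exactly — same coordinates, sizes,
#' intergenic values, strands and start/stop codons — while the sequence
#' content is drawn from the profile's composition model. Two seeds give
#' the same architecture but different sequences.
#'
#' @param spec A spec name from [skipper_architecture()], or a spec data
#'   frame (see [read_architecture_spec()]).
#' @param seed Integer seed.
#' @param ... Passed to [synth_profile()] (`target_at`, `codon_weights`,
#'   `ncr_runs`).
#' @return List with `genome` and `annotation`.
#' @examples
#' \donttest{
#' av <- replicate_architecture("ampittia_virgata", seed = 1)
#' av$genome$length  # 15333
#' }
#' @export
replicate_architecture <- function(spec, seed = 1, ...) {
  id <- "synthetic"
  if (is.character(spec) && length(spec) == 1L) {
    id <- spec
    spec <- skipper_architecture(spec)
  } else if (!is.null(spec$size)) {
    bad <- which(spec$size != spec$to - spec$from + 1L)
    if (length(bad))
      stop("architecture spec error: declared size != to - from + 1 for ",
           paste(spec$gene[bad], collapse = ", "), call. = FALSE)
  }
  dots <- list(...)
  if (!"id" %in% names(dots)) dots$id <- id
  profile <- do.call(synth_profile, c(list(features = spec), dots))
  random_mitogenome(profile, seed = seed)
}

#' Generate aligned per-gene sequence sets
#'
#' Simulates gap-free alignments for a set of genes: one random root
#' sequence per gene (codon-sampled without stops for PCGs, i.i.d.
#' bases otherwise), from which each taxon's row is derived by i.i.d.
#' per-site substitution. `divergence` parameterizes the expected
#' pairwise difference fraction between any two taxa; the per-row
#' substitution rate is solved from it.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param gene_lengths Named integer vector of alignment lengths.
#' @param divergence Expected pairwise difference fraction in `[0, 0.7]`.
#' @param seed Integer seed.
#' @param classes Optional named classes for the genes; inferred from
#'   canonical names otherwise (unknown names: `"PCG"` when the length
#'   is divisible by 3, else `"tRNA"`).
#' @param target_at Root composition A+T fraction.
#' @return List of [gene_alignment] objects.
#' @export
generate_aligned_genes <- function(n_taxa, gene_lengths, divergence = 0.1,
                                   seed = 1, classes = NULL, target_at = 0.80) {
  stopifnot(n_taxa >= 2, divergence >= 0, divergence <= 0.7)
  set.seed(seed)
  if (is.null(names(gene_lengths)))
    names(gene_lengths) <- paste0("gene", seq_along(gene_lengths))
  if (is.null(classes)) {
    cls_map <- canonical_gene_classes()
    classes <- vapply(names(gene_lengths), function(g) {
      if (g %in% names(cls_map)) unname(cls_map[g])
      else if (gene_lengths[[g]] %% 3L == 0L) "PCG" else "tRNA"
    }, "")
  }
  # per-row substitution rate r with pairwise expectation
  # 2r(1-r) + (2/3)r^2 = divergence
  r <- if (divergence == 0) 0 else (2 - sqrt(4 - (16 / 3) * divergence)) / (8 / 3)
  w <- default_codon_weights(target_at, enrich = NULL)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  bases <- c("A", "C", "G", "T")
  p_base <- c(target_at / 2, (1 - target_at) / 2, (1 - target_at) / 2, target_at / 2)
  out <- list()
  for (g in names(gene_lengths)) {
    len <- as.integer(gene_lengths[[g]])
    root <- if (classes[[g]] == "PCG") {
      paste0(sample(names(w), len %/% 3L, replace = TRUE, prob = w), collapse = "")
    } else paste0(sample(bases, len, replace = TRUE, prob = p_base), collapse = "")
    rootc <- strsplit(root, "")[[1L]]
    rows <- vapply(taxa, function(tx) {
      s <- rootc
      hit <- which(stats::runif(len) < r)
      for (i in hit) s[i] <- sample(setdiff(bases, s[i]), 1L)
      paste0(s, collapse = "")
    }, "")
    out[[g]] <- gene_alignment(g, rows, class = classes[[g]])
  }
  out
}
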