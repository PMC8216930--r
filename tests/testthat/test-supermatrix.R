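toy_alignments <- function() {
  list(
    gene_alignment("pcgA", c(t1 = "ATGAAA", t2 = "ATGTTA"), class = "PCG"),
    gene_alignment("pcgB", c(t1 = "ATGAAATTT", t2 = "ATGAAATTC"), class = "PCG"),
    gene_alignment("trnX", c(t1 = "ACGTA", t2 = "ACGTT"), class = "tRNA"))
}

test_that("gene alignments enforce equal rows and PCG frame", {
  expect_error(gene_alignment("g", c(a = "AAA", b = "AAAA")), "ragged")
  expect_error(gene_alignment("g", c(a = "AAAA", b = "AAAT"), class = "PCG"),
               "divisible by 3")
  expect_error(gene_alignment("g", c("AAA", "AAT")), "named")
  a <- gene_alignment("nad2", c(a = "ATGAAA", b = "ATGAAT"))
  expect_identical(a$class, "PCG")   # inferred from the canonical list
})

test_that("gene extraction returns trimmed sense-strand sequences", {
  reps <- lapply(all_species, replica)
  genomes <- lapply(reps, `[[`, "genome")
  annots <- lapply(reps, `[[`, "annotation")
  gs <- extract_gene_set(genomes, annots, genes = c("nad2", "cox1", "nad5"))
  expect_identical(unname(nchar(gs$nad2)), rep(1014L, 3))
  # cox1 (1531 bp, single-T stop) is trimmed to 1530
  expect_identical(unname(nchar(gs$cox1)), rep(1530L, 3))
  expect_true(all(nchar(gs$nad5) %% 3 == 0))

  # N-strand extraction is the reverse complement of the J-strand slice
  av <- reps[[1]]
  nad5 <- av$annotation[av$annotation$gene == "nad5", ]
  jslice <- substr(av$genome$sequence, nad5$from, nad5$to)
  expect_identical(sense_sequence(av$genome, nad5),
                   chartr("ACGT", "TGCA", paste(rev(strsplit(jslice, "")[[1]]),
                                                collapse = "")))

  # a gene missing from one taxon is flagged, not fatal
  annots2 <- annots
  annots2[[2]] <- mito_annotation(
    as.data.frame(annots[[2]])[annots[[2]]$gene != "nad2", ],
    genome_id = attr(annots[[2]], "genome_id"),
    genome_length = attr(annots[[2]], "genome_length"))
  gs2 <- extract_gene_set(genomes, annots2, genes = "nad2")
  expect_true(is.na(gs2$nad2[[2]]))
  expect_false(anyNA(gs2$nad2[-2]))
})

test_that("codon striping is a bijection on alignment columns", {
  rows <- c(a = "ATGAAATTT", b = "CTGAATTTA")
  st <- stripe_codon_positions(rows)
  expect_identical(st$pos1[["a"]], "AAT")
  expect_identical(vapply(st, function(x) nchar(x[[1]]), 0L),
                   c(pos1 = 3L, pos2 = 3L, pos3 = 3L))
  # re-interleaving restores the original rows
  rebuilt <- vapply(names(rows), function(tx) {
    chars <- character(9)
    for (k in 1:3) chars[seq(k, 9, 3)] <- strsplit(st[[k]][[tx]], "")[[1]]
    paste0(chars, collapse = "")
  }, "")
  expect_identical(rebuilt, rows)
  expect_error(stripe_codon_positions(c(a = "ATGA")), "divisible")
})

test_that("the three schemes have the defining lengths", {
  aln <- toy_alignments()
  expect_identical(build_supermatrix(aln, "PCG")$length, 15L)
  expect_identical(build_supermatrix(aln, "PRT")$length, 20L)
  expect_identical(build_supermatrix(aln, "12PRT")$length, 15L)  # 20 - 15/3
  expect_error(build_supermatrix(list()), "empty")
})

test_that("12PRT length identity holds on random gene sets", {
  set.seed(23)
  for (i in 1:10) {
    n_pcg <- sample(1:5, 1); n_rna <- sample(0:4, 1)
    lens <- c(3 * sample(2:30, n_pcg, replace = TRUE),
              if (n_rna) sample(40:80, n_rna, replace = TRUE))
    names(lens) <- paste0("g", seq_along(lens))
    classes <- c(rep("PCG", n_pcg), rep("tRNA", n_rna))
    names(classes) <- names(lens)
    aln <- generate_aligned_genes(3, lens, divergence = 0.1, seed = i,
                                  classes = classes)
    pcg <- build_supermatrix(aln[classes == "PCG"], "PCG")
    prt <- build_supermatrix(aln, "PRT")
    prt12 <- build_supermatrix(aln, "12PRT")
    expect_identical(prt12$length, prt$length - pcg$length %/% 3L)
  }
})

test_that("column provenance is a bijection onto included columns", {
  aln <- toy_alignments()
  for (scheme in c("PCG", "PRT", "12PRT")) {
    sm <- build_supermatrix(aln, scheme)
    expect_identical(sm$provenance$column, seq_len(sm$length))
    key <- paste(sm$provenance$gene, sm$provenance$gene_column)
    expect_false(any(duplicated(key)))
    if (scheme == "12PRT")
      expect_false(any(sm$provenance$codon_pos %in% 3L))
    # provenance recovers the original characters
    for (k in seq_len(sm$length)) {
      src <- aln[[which(vapply(aln, function(a) a$gene, "") ==
                          sm$provenance$gene[k])]]
      expect_identical(substr(sm$sequences[["t1"]], k, k),
                       substr(src$sequences[["t1"]],
                              sm$provenance$gene_column[k],
                              sm$provenance$gene_column[k]))
    }
  }
})

test_that("genes concatenate in canonical order with gap padding for missing taxa", {
  aln <- list(
    gene_alignment("cox1", c(tb = "ATGAAA", ta = "ATGAAT")),
    gene_alignment("nad2", c(ta = "ATGCCC")))   # tb lacks nad2
  sm <- build_supermatrix(aln, "PCG")
  expect_identical(sm$partitions$gene, c("nad2", "cox1"))  # nad2 precedes cox1
  expect_identical(names(sm$sequences), c("ta", "tb"))     # taxa sorted
  expect_identical(sm$sequences[["tb"]], "------ATGAAA")
  sm_q <- build_supermatrix(aln, "PCG", gap = "?")
  expect_identical(substr(sm_q$sequences[["tb"]], 1, 6), "??????")
})

test_that("generated alignments obey divergence and determinism", {
  a1 <- generate_aligned_genes(4, c(g1 = 6, g2 = 9), divergence = 0, seed = 3)
  rows <- a1$g1$sequences
  expect_true(all(rows == rows[[1]]))                      # divergence 0
  expect_identical(build_supermatrix(a1, "PCG")$length, 15L)
  expect_length(a1$g1$sequences, 4L)

  b1 <- generate_aligned_genes(3, c(g = 300), divergence = 0.1, seed = 5)
  b2 <- generate_aligned_genes(3, c(g = 300), divergence = 0.1, seed = 5)
  expect_identical(b1$g$sequences, b2$g$sequences)         # seeded determinism

  # pairwise difference fraction ~ divergence (binomial tolerance)
  big <- generate_aligned_genes(2, c(g = 3000), divergence = 0.1, seed = 11)
  x <- strsplit(big$g$sequences, "")
  diff_frac <- mean(x[[1]] != x[[2]])
  expect_lt(abs(diff_frac - 0.1), 3 * sqrt(0.1 * 0.9 / 3000))
})
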