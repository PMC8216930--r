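test_that("gene sizes are inclusive coordinate spans", {
  expect_identical(gene_size(list(from = 250, to = 1263)), 1014L)   # nad2
  expect_identical(gene_size(list(from = 5, to = 5)), 1L)
  expect_identical(gene_size(list(from = 14241, to = 15012)), 772L) # rrnS
  expect_error(gene_size(list(from = 10, to = 9)), "invalid")
})

test_that("intergenic profile computes signed gaps, overlaps and junction names", {
  ann <- mito_annotation(toy_features(), genome_length = 100L)
  prof <- intergenic_profile(ann)
  expect_identical(prof$junction, c("nad2-trnW", "trnW-atp6", "atp6-NCR"))
  expect_identical(prof$ign, c(0L, 0L, 6L))

  om <- skipper_architecture("onryza_maga")
  prof <- intergenic_profile(mito_annotation(om, genome_length = 15381L))
  expect_identical(prof$ign[prof$junction == "trnM-trnI"], 30L)
  expect_identical(prof$ign[prof$junction == "atp8-atp6"], -7L)

  circ <- intergenic_profile(ann, circular = TRUE)
  expect_identical(circ$ign[circ$junction == "NCR-nad2"], 0L)
})

test_that("overlap/spacer census counts signed junctions with magnitudes", {
  prof <- data.frame(junction = c("a-b", "b-c", "c-d", "d-e"),
                     gene_prev = letters[1:4], gene_next = letters[2:5],
                     ign = c(-7L, 0L, 12L, -2L))
  cen <- overlap_spacer_census(prof)
  expect_identical(cen$n_overlaps, 2L)
  expect_identical(cen$n_spacers, 1L)
  expect_identical(cen$overlap_bp, 9L)
  expect_identical(cen$longest_overlap, list(junction = "a-b", bp = 7L))
  expect_identical(cen$longest_spacer, list(junction = "c-d", bp = 12L))
  zero <- overlap_spacer_census(prof[prof$ign == 0, ])
  expect_identical(zero$n_overlaps, 0L)
  expect_null(zero$longest_overlap)
})

test_that("strand census matches the skipper counts", {
  av <- replica("ampittia_virgata")
  expect_identical(strand_census(av$annotation), c(J = 23L, N = 14L))
  expect_identical(strand_census(av$annotation, classes = "tRNA"), c(J = 14L, N = 8L))
  expect_identical(strand_census(av$annotation, classes = "PCG"), c(J = 9L, N = 4L))
  all_j <- toy_features(); all_j$strand <- "J"
  expect_identical(strand_census(mito_annotation(all_j, genome_length = 100L)),
                   c(J = 3L, N = 0L))
})

test_that("codon classification handles complete and incomplete stops", {
  full <- classify_codons("ATGAAATTTTAA")
  expect_identical(full$start_codon, "ATG")
  expect_identical(full$stop_codon, "TAA")
  expect_true(full$complete)
  expect_true(full$start_canonical)

  # cox1-style: CGA start, single-T incomplete stop (length = 1 mod 3)
  cox1ish <- classify_codons("CGAAAATTTT")
  expect_identical(cox1ish$start_codon, "CGA")
  expect_true(cox1ish$start_canonical)
  expect_identical(cox1ish$stop_codon, "T")
  expect_false(cox1ish$complete)

  expect_identical(classify_codons("ATTAAATAG")$stop_codon, "TAG")
  expect_identical(classify_codons("ATGAAAATTTA")$stop_codon, "TA")

  # problems are recorded, not thrown
  bad <- classify_codons("ATGAAAGGG")
  expect_match(bad$issue, "not a stop")
  expect_false(classify_codons("GTGAAATAA")$start_canonical)
})

test_that("architecture reports reproduce every derived replica column", {
  for (sp in all_species) {
    r <- replica(sp)
    spec <- skipper_architecture(sp)
    rep <- architecture_report(r$annotation, r$genome)
    expect_identical(rep$features$size, spec$size, label = sp)
    expect_identical(rep$features$ign[-1], spec$ign[-1], label = sp)
    pcg <- spec$class == "PCG"
    expect_identical(rep$features$start_codon[pcg], spec$start_codon[pcg], label = sp)
    expect_identical(rep$features$stop_codon[pcg], spec$stop_codon[pcg], label = sp)
    # the circular NCR->trnM junction is separate from the linear census
    expect_identical(rep$circular_ign, 0L)
  }
})

test_that("coordinate reconstruction from sizes + IGN is exact on the replicas", {
  for (sp in all_species) {
    spec <- skipper_architecture(sp)
    rec <- reconstruct_coordinates(spec$from[1], spec$size, spec$ign[-1])
    expect_identical(rec$from, spec$from, label = sp)
    expect_identical(rec$to, spec$to, label = sp)
  }
})

test_that("sum of sizes plus linear IGN equals the annotated span", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    sizes <- sample(50:2000, n, replace = TRUE)
    ign <- sample(-25:80, n - 1, replace = TRUE)
    rec <- reconstruct_coordinates(1L, sizes, ign)
    expect_identical(sum(sizes) + sum(ign),
                     rec$to[n] - rec$from[1] + 1L)
  }
})

test_that("shared overlaps across the three genomes are the four known junctions", {
  reports <- lapply(all_species, function(sp) {
    r <- replica(sp)
    architecture_report(r$annotation, r$genome)
  })
  sh <- shared_overlaps(reports)
  expect_setequal(sh$junction, c("nad2-trnW", "trnW-trnC", "atp8-atp6", "atp6-cox3"))
  expect_identical(sh$ampittia_virgata[sh$junction == "trnW-trnC"], 8L)
  expect_identical(sh$onryza_maga[sh$junction == "atp8-atp6"], 7L)
  expect_identical(sh$halpe_nephele[sh$junction == "atp6-cox3"], 1L)

  # compared with itself a report returns its own overlap set
  self <- shared_overlaps(reports[c(1, 1)])
  expect_identical(nrow(self),
                   sum(reports[[1]]$profile$ign < 0))

  # disjoint overlap sets yield nothing
  a <- toy_features(); b <- toy_features()
  a$from[2] <- 28L   # nad2-trnW overlap only in a
  b$from[4] <- 62L   # atp6-NCR overlap only in b
  ra <- architecture_report(mito_annotation(a, genome_length = 100L))
  rb <- architecture_report(mito_annotation(b, genome_length = 100L))
  expect_identical(nrow(shared_overlaps(list(ra, rb))), 0L)

  bad <- toy_features()[c(2, 1, 3, 4), ]
  bad$from <- c(1L, 31L, 41L, 71L); bad$to <- c(30L, 40L, 64L, 100L)
  rc <- architecture_report(mito_annotation(bad, genome_length = 100L))
  expect_error(shared_overlaps(list(ra, rc)), "not comparable")
})
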