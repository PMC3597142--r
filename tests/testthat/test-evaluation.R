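test_that("permutation conserves counts per block and is seed-reproducible", {
  set.seed(9)
  centers <- data.table::data.table(
    chrom = "chr1", pos = sort(sample.int(5000L, 400L, replace = TRUE)) - 1L)
  sizes <- c(chr1 = 5000L)
  perm <- permute_reads(centers, sizes, window = 1000L, seed = 4)
  expect_equal(nrow(perm), 400L)
  expect_equal(tabulate(perm$pos %/% 1000L + 1L, 5),
               tabulate(centers$pos %/% 1000L + 1L, 5))
  expect_true(all(perm$pos >= 0L & perm$pos < 5000L))
  perm2 <- permute_reads(centers, sizes, window = 1000L, seed = 4)
  expect_identical(perm, perm2)
  perm3 <- permute_reads(centers, sizes, window = 1000L, seed = 5)
  expect_false(identical(perm, perm3))
})

test_that("permuted positions are uniform within blocks", {
  # strongly phased input: every centre at the same within-block offset
  centers <- data.table::data.table(chrom = "chr1",
                                    pos = rep(500L, 2000L))
  sizes <- c(chr1 = 1000L)
  pvals <- vapply(1:40, function(s) {
    perm <- permute_reads(centers, sizes, window = 1000L, seed = s)
    obs <- tabulate(perm$pos %/% 100L + 1L, 10L)
    suppressWarnings(stats::chisq.test(obs)$p.value)
  }, numeric(1))
  # goodness-of-fit should only rarely reject at alpha = 0.01
  expect_lte(sum(pvals < 0.01), 3L)
})

test_that("specificity follows TN / (TN + FP)", {
  rep <- compute_specificity(1, 100)
  expect_equal(rep$specificity, 0.99)
  expect_equal(compute_specificity(0, 50)$specificity, 1)
  expect_equal(compute_specificity(50, 50)$specificity, 0)
  # scale consistency
  expect_equal(compute_specificity(6, 300)$specificity,
               compute_specificity(12, 600)$specificity)
  expect_error(compute_specificity(1, 0), "candidate")
  expect_error(compute_specificity(10, 5), "more false positives")
})

test_that("average profile of a single call reproduces its own counts", {
  centers <- data.table::data.table(
    chrom = "chrT", pos = c(495L, 495L, 502L, 513L))
  calls <- calls_from_centers(500)
  prof <- average_profile(calls, centers, c(chrT = 1000L), flank = 60L)
  expect_length(prof, 27L)  # (150 + 120) / 10
  # window starts at 500 - 135 = 365; centres fall in bins 14 and 15
  expected <- numeric(27L)
  expected[14] <- 3; expected[15] <- 1
  expect_equal(prof, expected)
  # two identical windows: mean equals either window
  calls2 <- calls_from_centers(c(500, 500))
  expect_equal(average_profile(calls2, centers, c(chrT = 1000L)), expected)
})

test_that("profiles of phased synthetic nucleosomes peak in the centre", {
  sim <- simulate_reads(sim_config(n_nucleosomes = 50L, seed = 12))
  centers <- compute_centers(sim$signal, sim$chrom_sizes)
  calls <- calls_from_centers(sim$truth$centers,
                              chrom = sim$truth$config$chrom)
  prof <- suppressMessages(
    average_profile(calls, centers, sim$chrom_sizes))
  central <- 13:15  # the 30 bp centre of the 270 bp window
  expect_equal(which.max(prof) %in% central, TRUE)
  expect_gt(mean(prof[central]), 3 * mean(prof[c(1:5, 23:27)]))
})

test_that("spacing is exact on arithmetic progressions, with or without gaps", {
  calls <- calls_from_centers(c(90, 270, 450, 630, 810))
  tss <- data.frame(chrom = "chrT", pos = 0L, strand = "+", rpkm = 50)
  est <- estimate_spacing(calls, tss)
  expect_equal(est$mean_spacing, 180, tolerance = 1e-10)
  expect_equal(est$n_genes, 1L)

  gap <- calls_from_centers(c(90, 450, 630, 810))
  est2 <- estimate_spacing(gap, tss)
  expect_equal(est2$mean_spacing, 180, tolerance = 1e-10)
})

test_that("spacing respects the expression filter and the strand", {
  calls <- calls_from_centers(c(90, 270, 450, 630, 810))
  tss_low <- data.frame(chrom = "chrT", pos = 0L, strand = "+", rpkm = 5)
  expect_error(estimate_spacing(calls, tss_low), "expression filter")

  # a minus-strand gene with its array upstream of the TSS
  calls_minus <- calls_from_centers(2000 - c(90, 270, 450, 630, 810))
  tss_minus <- data.frame(chrom = "chrT", pos = 2000L, strand = "-", rpkm = 50)
  est <- estimate_spacing(calls_minus, tss_minus)
  expect_equal(est$mean_spacing, 180, tolerance = 1e-10)
})

test_that("genes with a single call are skipped and counted", {
  calls <- calls_from_centers(c(90, 270, 450, 5090))
  tss <- data.frame(chrom = "chrT", pos = c(0L, 5000L), strand = "+",
                    rpkm = c(50, 50))
  est <- estimate_spacing(calls, tss)
  expect_equal(est$n_genes, 1L)
  expect_equal(est$n_skipped, 1L)
})

test_that("dinucleotide frequencies honour their definitions on repeats", {
  # all-G sequence: neither GC nor AA/TT dinucleotides occur
  gen <- Biostrings::DNAStringSet(paste(rep("G", 2000), collapse = ""))
  names(gen) <- "chrT"
  calls <- calls_from_centers(c(500, 1200))
  prof <- dinucleotide_profile(calls, gen)
  expect_equal(prof$D, 0)
  expect_true(all(prof$f_gc == 0) && all(prof$f_at == 0))

  # GCGCGC...: GC at even offsets, CG at odd, and the reverse complement
  # carries the opposite phase for an odd window width, so pooling the
  # two strands gives exactly 0.5 at every dinucleotide position
  gen2 <- Biostrings::DNAStringSet(paste(rep("GC", 1000), collapse = ""))
  names(gen2) <- "chrT"
  prof2 <- dinucleotide_profile(calls, gen2, span = 151L)
  expect_true(all(prof2$f_gc == 0.5))
  expect_true(all(prof2$f_at == 0))
})

test_that("the dinucleotide profile is reverse-complement invariant", {
  cfg <- sim_config(n_nucleosomes = 30L, seed = 21)
  gen <- simulate_genome(cfg)
  rc <- Biostrings::reverseComplement(gen)
  names(rc) <- names(gen)
  centers <- nucleofinder:::planted_centers(cfg)
  calls <- calls_from_centers(centers, chrom = cfg$chrom)
  # a call at position p on the forward genome sits at L - p on the
  # reverse-complemented genome; window centres must map accordingly
  L <- cfg$chrom_length
  calls_rc <- calls_from_centers(L - centers, chrom = cfg$chrom)
  prof <- dinucleotide_profile(calls, gen)
  prof_rc <- dinucleotide_profile(calls_rc, rc)
  expect_equal(prof_rc$D, prof$D, tolerance = 1e-12)
})

test_that("calls near contig edges are dropped with a message", {
  gen <- Biostrings::DNAStringSet(paste(rep("ACGT", 500), collapse = ""))
  names(gen) <- "chrT"
  calls <- calls_from_centers(c(30, 500, 1200))
  expect_message(prof <- dinucleotide_profile(calls, gen), "dropped")
  expect_equal(prof$n, 2L)
})
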