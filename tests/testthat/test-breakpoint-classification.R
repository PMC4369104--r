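# toy contig: a G20 homopolymer and a C16 run planted far apart in a
# signature-free background
fixture_genome <- function() {
  set.seed(55)
  cfg <- simulation_config(genome_length = 2e4, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 2),
                           minus_strand_fraction = 0)
  built <- build_toy_genome(cfg)
  # force one plant to the minus strand (a C run on the forward strand)
  m <- built$truth$motifs
  chars <- strsplit(as.character(built$genome[[1]]), "")[[1]]
  chars[m$start[2]:m$end[2]] <- "C"
  genome <- as_genome(stats::setNames(paste0(chars, collapse = ""),
                                      names(built$genome)))
  m$strand[2] <- "-"
  list(genome = genome, motifs = m,
       annotation = annotate_motifs(genome))
}

test_that("a deletion ending at a G-run 3' end initiates there", {
  fx <- fixture_genome()
  g20 <- fx$motifs[1, ]
  del <- GenomicRanges::GRanges(g20$contig,
                                IRanges::IRanges(g20$end - 98, g20$end))
  hit <- initiating_site(del, fx$annotation, fx$genome)
  expect_false(is.na(hit$site))
  expect_equal(hit$side, "g_run_3prime")
  cls <- classify_deletions(del, fx$annotation, fx$genome)
  expect_equal(cls$class, "MONO_TRACT")
  expect_equal(cls$size, 99L)
})

test_that("the strand-mirrored rule holds for C-run initiation", {
  fx <- fixture_genome()
  c16 <- fx$motifs[2, ]
  del <- GenomicRanges::GRanges(c16$contig,
                                IRanges::IRanges(c16$start, c16$start + 98))
  hit <- initiating_site(del, fx$annotation, fx$genome)
  expect_equal(hit$side, "c_run_5prime")
  expect_equal(classify_deletions(del, fx$annotation, fx$genome)$class,
               "MONO_TRACT")
})

test_that("deletions far from any motif are non-G-rich", {
  fx <- fixture_genome()
  far <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(10, 120))
  hit <- initiating_site(far, fx$annotation, fx$genome)
  expect_true(is.na(hit$site))
  expect_equal(hit$side, "none")
  expect_equal(classify_deletions(far, fx$annotation, fx$genome)$class,
               "NON_G_RICH")
})

test_that("initiation is directional unless orientation is relaxed", {
  fx <- fixture_genome()
  g20 <- fx$motifs[1, ]
  # breakpoint at the G run's 3' end but extending 3'-ward (the wrong way)
  del <- GenomicRanges::GRanges(g20$contig,
                                IRanges::IRanges(g20$end - 2, g20$end + 96))
  expect_equal(classify_deletions(del, fx$annotation, fx$genome)$class,
               "NON_G_RICH")
  expect_equal(classify_deletions(del, fx$annotation, fx$genome,
                                  require_orientation = FALSE)$class,
               "MONO_TRACT")
})

test_that("breakpoint tolerance is honoured around the initiation end", {
  fx <- fixture_genome()
  g20 <- fx$motifs[1, ]
  near <- GenomicRanges::GRanges(g20$contig,
                                 IRanges::IRanges(g20$end - 95, g20$end + 4))
  expect_equal(classify_deletions(near, fx$annotation, fx$genome,
                                  tolerance = 5)$class, "MONO_TRACT")
  beyond <- GenomicRanges::GRanges(g20$contig,
                                   IRanges::IRanges(g20$end - 89, g20$end + 10))
  expect_equal(classify_deletions(beyond, fx$annotation, fx$genome,
                                  tolerance = 5)$class, "NON_G_RICH")
})

test_that("deletion classes partition and are order-invariant", {
  set.seed(66)
  cfg <- simulation_config(genome_length = 1.2e5, generations = 200,
                           sample_points = 200, n_genes = 0,
                           mu_sbs = 0, mu_indel = 0, mu_dup = 0,
                           mu_del_nong4 = 5e-9, mu_del_g4 = 1.2e-3)
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  ann <- annotate_motifs(built$genome)
  dels <- select_homozygous_deletions(
    sim$tables[["200"]][sim$tables[["200"]]$kind == "DEL_LARGE", ])
  cls <- classify_deletions(dels, ann, built$genome)
  summ <- classification_summary(cls)
  expect_equal(sum(summ$counts), summ$n_total)
  expect_equal(summ$n_g_rich, summ$n_total - summ$counts[["NON_G_RICH"]])
  shuffled <- classify_deletions(dels[sample(nrow(dels)), ], ann,
                                 built$genome)
  expect_equal(classification_summary(shuffled)$fraction_g_rich,
               summ$fraction_g_rich)
})

test_that("classification recovers every planted deletion class", {
  set.seed(77)
  cfg <- simulation_config(genome_length = 2e5, generations = 250,
                           sample_points = 250, n_genes = 0,
                           mu_sbs = 0, mu_indel = 0, mu_dup = 0,
                           mu_del_nong4 = 0, mu_del_g4 = 1.5e-3,
                           plant_counts = c(MONO_TRACT = 10,
                                            MONO_LIKE_LE2 = 6,
                                            INTERRUPTED_GE3 = 6,
                                            RELAXED_4TRACT = 6,
                                            RELAXED_3TRACT = 6))
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  ann <- annotate_motifs(built$genome)
  tab <- sim$tables[["250"]]
  dels <- select_homozygous_deletions(tab[tab$kind == "DEL_LARGE", ])
  cls <- classify_deletions(dels, ann, built$genome)
  truth <- sim$truth$variants[sim$truth$variants$kind == "DEL_LARGE", ]
  truth <- truth[order(truth$contig, truth$pos), ]
  expect_gt(nrow(cls), 5L)
  expect_identical(cls$class, truth$class)
})

test_that("strand mirror leaves every classification unchanged", {
  fx <- fixture_genome()
  n <- length(fx$genome[[1]])
  g20 <- fx$motifs[1, ]
  del <- GenomicRanges::GRanges(g20$contig,
                                IRanges::IRanges(g20$end - 98, g20$end))
  rc_genome <- as_genome(stats::setNames(revcomp(as.character(fx$genome[[1]])),
                                         "ctg1"))
  rc_ann <- annotate_motifs(rc_genome)
  rc_del <- GenomicRanges::GRanges(g20$contig,
                                   IRanges::IRanges(n - GenomicRanges::end(del) + 1,
                                                    n - GenomicRanges::start(del) + 1))
  expect_equal(classify_deletions(del, fx$annotation, fx$genome)$class,
               classify_deletions(rc_del, rc_ann, rc_genome)$class)
})

test_that("deleted-tract census uses majority overlap of single deletions", {
  set.seed(88)
  tracts <- GenomicRanges::GRanges("I", IRanges::IRanges(
    start = seq(1000, by = 1000, length.out = 10), width = 20), strand = "+")
  # deletion covering 40% of tract 1: not deleted; covering all of tract 2
  dels <- GenomicRanges::GRanges("I", IRanges::IRanges(
    start = c(1000, 1990), end = c(1007, 2025)))
  cen <- deleted_tract_census(tracts, dels)
  expect_equal(cen$n_deleted, 1L)
  expect_equal(cen$n_total, 10L)
  expect_false(cen$deleted[1])
  expect_true(cen$deleted[2])
  # exactly half counts (inclusive threshold)
  half <- GenomicRanges::GRanges("I", IRanges::IRanges(3000, 3009))
  expect_true(deleted_tract_census(tracts, half)$deleted[3])
  # no deletions
  none <- deleted_tract_census(tracts, dels[0])
  expect_equal(none$n_deleted, 0L)
  expect_equal(none$fraction, 0)
  expect_error(deleted_tract_census(tracts[0], dels), "undefined")
})

test_that("size distribution counts strictly-below-threshold deletions", {
  sd <- size_distribution(c(100, 200, 299, 300, 5000))
  expect_equal(sd$fraction_below, 3 / 5)
  expect_equal(sum(sd$histogram), 5L)

  sd <- size_distribution(rep(49, 10))
  expect_equal(sd$fraction_below, 1)

  sd <- size_distribution(numeric(0))
  expect_true(is.na(sd$fraction_below))
  expect_equal(sd$n, 0L)

  # 106 of 123 below 300 prints as 86%
  set.seed(99)
  sizes <- c(sample(49:299, 106, replace = TRUE),
             sample(300:10228, 17, replace = TRUE))
  sd <- size_distribution(sizes)
  expect_equal(round(100 * sd$fraction_below), 86)
})
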