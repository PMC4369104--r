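small_cfg <- function(n_genes = 2, ...) {
  simulation_config(genome_length = 3e4, n_genes = n_genes,
                    plant_counts = c(MONO_TRACT = 3, MONO_LIKE_LE2 = 2,
                                     INTERRUPTED_GE3 = 2, RELAXED_4TRACT = 2,
                                     RELAXED_3TRACT = 2), ...)
}

test_that("toy genomes are byte-identical under the same seed", {
  set.seed(5)
  a <- build_toy_genome(small_cfg())
  set.seed(5)
  b <- build_toy_genome(small_cfg())
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$motifs, b$truth$motifs)

  set.seed(6)
  c_ <- build_toy_genome(small_cfg())
  expect_false(identical(as.character(a$genome), as.character(c_$genome)))
})

test_that("planted motifs round-trip through scan and classification", {
  set.seed(15)
  cfg <- simulation_config(genome_length = 4e4, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 10))
  built <- build_toy_genome(cfg)
  ann <- annotate_motifs(built$genome)
  expect_equal(length(ann), 10L)
  expect_true(all(ann$motif_class == "MONO_TRACT"))
  expect_equal(GenomicRanges::start(ann), built$truth$motifs$start)
  expect_equal(GenomicRanges::end(ann), built$truth$motifs$end)

  # and the mixed-class case recovers the full planted annotation
  set.seed(16)
  built <- build_toy_genome(small_cfg())
  ann <- annotate_motifs(built$genome)
  expect_equal(length(ann), nrow(built$truth$motifs))
  expect_identical(ann$motif_class, built$truth$motifs$class)
})

test_that("a genome with zero plants scans clean", {
  set.seed(25)
  cfg <- simulation_config(genome_length = 2e4, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 0))
  built <- build_toy_genome(cfg)
  expect_equal(nrow(built$truth$motifs), 0L)
  expect_equal(length(annotate_motifs(built$genome)), 0L)
  expect_equal(length(find_mono_gc_tracts(built$genome)), 0L)
})

test_that("infeasible packing errors with the required length", {
  cfg <- simulation_config(genome_length = 1500, n_genes = 3,
                           plant_counts = c(MONO_TRACT = 5))
  expect_error(build_toy_genome(cfg), "at least")
})

test_that("all-zero rates give empty variant tables at every sample point", {
  set.seed(35)
  cfg <- small_cfg(mu_sbs = 0, mu_indel = 0, mu_del_g4 = 0,
                   mu_del_nong4 = 0, mu_dup = 0, generations = 50,
                   sample_points = c(20, 50))
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  expect_true(all(vapply(sim$tables, nrow, integer(1)) == 0L))
  expect_equal(nrow(sim$truth$variants), 0L)
})

test_that("sample-point variant sets are nested and never revert", {
  set.seed(45)
  cfg <- small_cfg(mu_sbs = 3e-6, mu_indel = 1e-6, mu_del_g4 = 8e-4,
                   mu_del_nong4 = 2e-8, mu_dup = 1e-3,
                   generations = 300, sample_points = c(100, 200, 300))
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  filt <- lapply(sim$tables, function(tab) {
    small <- filter_small_variants(tab[tab$kind %in% c("SBS", "INS",
                                                       "DEL_SMALL"), ])
    dels <- select_homozygous_deletions(tab[tab$kind == "DEL_LARGE", ])
    dels$hom_stat <- NULL
    rbind(small, dels)
  })
  keys <- lapply(filt, variant_key)
  expect_true(all(keys[["100"]] %in% keys[["200"]]))
  expect_true(all(keys[["200"]] %in% keys[["300"]]))

  acc <- accumulation_matrix(filt)
  for (k in c("SBS", "INS", "DEL_SMALL", "DEL_LARGE")) {
    expect_true(all(acc$reversions[k, ] == 0))
  }
  expect_equal(sum(acc$new), length(unique(keys[["300"]])))
})

test_that("emitted tables mix in decoy calls that fail the filters", {
  set.seed(55)
  cfg <- small_cfg(mu_sbs = 5e-6, mu_indel = 0, mu_del_g4 = 0,
                   mu_del_nong4 = 0, mu_dup = 0, generations = 100,
                   sample_points = 100, decoy_fraction = 0.5)
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  tab <- sim$tables[["100"]]
  n_true <- nrow(sim$truth$variants)
  expect_gt(nrow(tab), n_true)
  kept <- filter_small_variants(tab)
  expect_equal(sort(variant_key(kept)),
               sort(variant_key(variant_calls(sim$truth$variants$contig,
                                              sim$truth$variants$pos,
                                              sim$truth$variants$ref,
                                              sim$truth$variants$alt,
                                              sim$truth$variants$kind,
                                              sim$truth$variants$size))))
})

test_that("without non-G4 deletions every deletion carries a G-rich class", {
  set.seed(65)
  cfg <- small_cfg(mu_sbs = 0, mu_indel = 0, mu_del_g4 = 1.5e-3,
                   mu_del_nong4 = 0, mu_dup = 0, generations = 200,
                   sample_points = 200, n_genes = 0)
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  truth_del <- sim$truth$variants[sim$truth$variants$kind == "DEL_LARGE", ]
  expect_gt(nrow(truth_del), 0L)
  expect_true(all(truth_del$class != "NON_G_RICH"))
  ann <- annotate_motifs(built$genome)
  dels <- select_homozygous_deletions(
    sim$tables[["200"]][sim$tables[["200"]]$kind == "DEL_LARGE", ])
  cls <- classify_deletions(dels, ann, built$genome)
  expect_true(all(cls$class != "NON_G_RICH"))
})

test_that("deleted-tract census matches truth target-loss bookkeeping", {
  set.seed(75)
  cfg <- simulation_config(genome_length = 1e5, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 12),
                           mu_sbs = 0, mu_indel = 0, mu_del_g4 = 1e-3,
                           mu_del_nong4 = 0, mu_dup = 0,
                           generations = 200, sample_points = 200)
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  mono <- find_mono_gc_tracts(built$genome)
  dels <- sim$truth$variants[sim$truth$variants$kind == "DEL_LARGE", ]
  cen <- deleted_tract_census(mono, deletions_as_granges(
    data.frame(contig = dels$contig, pos = dels$pos, size = dels$size)))
  # truth: tracts whose planted site index was hit
  expect_equal(cen$n_deleted, length(unique(dels$site_idx)))
  expect_equal(cen$fraction, length(unique(dels$site_idx)) / 12)
})

test_that("mean substitution counts track the configured rate", {
  set.seed(85)
  cfg <- simulation_config(genome_length = 5e4, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 2),
                           mu_sbs = 2e-6, mu_indel = 0, mu_del_g4 = 0,
                           mu_del_nong4 = 0, mu_dup = 0,
                           generations = 100, sample_points = 100)
  built <- build_toy_genome(cfg)
  n_rep <- 30
  counts <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_line(built$genome, built$truth, cfg)
    sum(sim$truth$variants$kind == "SBS")
  }, numeric(1))
  expected <- cfg$mu_sbs * 5e4 * 100
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("duplications can amplify and revert in the event log", {
  set.seed(95)
  cfg <- small_cfg(mu_sbs = 0, mu_indel = 0, mu_del_g4 = 0,
                   mu_del_nong4 = 0, mu_dup = 2e-2, p_dup_loss = 2e-2,
                   generations = 300, sample_points = c(150, 300))
  built <- build_toy_genome(cfg)
  sim <- simulate_line(built$genome, built$truth, cfg)
  log <- sim$truth$dup_log
  expect_gt(sum(log$event == "amplification"), 0L)
  expect_gt(sum(log$event == "loss"), 0L)
  # emitted copy numbers reflect the log at each sample point
  tab <- sim$tables[["300"]]
  dup_rows <- tab[tab$kind == "DUP", ]
  expect_true(all(dup_rows$copy_number >= 2))
})

test_that("parameter recovery brackets the configured rates", {
  set.seed(105)
  cfg <- simulation_config(genome_length = 1e5, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 8, MONO_LIKE_LE2 = 4,
                                            INTERRUPTED_GE3 = 4,
                                            RELAXED_4TRACT = 4,
                                            RELAXED_3TRACT = 4),
                           mu_sbs = 2e-6, mu_indel = 1e-7, mu_del_g4 = 1e-3,
                           mu_del_nong4 = 0, mu_dup = 0,
                           generations = 200, sample_points = 200)
  rec <- recover_parameters(cfg, n_replicates = 12)
  expect_equal(rec$parameter, c("mu_sbs", "mu_del_g4"))
  expect_true(all(abs(rec$z) < 4))
  expect_true(all(rec$mean_estimate > 0))
})
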