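test_that("homopolymer tract finder reports maximal runs", {
  tr <- find_homopolymer_tracts("GGGGG", "G", 3)
  expect_equal(length(tr), 1L)
  expect_equal(GenomicRanges::start(tr), 1L)
  expect_equal(GenomicRanges::end(tr), 5L)
  expect_equal(tr$tract_len, 5L)

  expect_equal(length(find_homopolymer_tracts("ATATAT", "G", 3)), 0L)

  seq <- paste0("AA", strrep("G", 20), "TT")
  tr <- find_homopolymer_tracts(seq, "G", 15)
  expect_equal(GenomicRanges::width(tr), 20L)
  expect_equal(GenomicRanges::start(tr), 3L)

  expect_error(find_homopolymer_tracts("ACGT", "X", 3), "X")
})

test_that("homopolymer finder agrees with character-by-character oracle", {
  set.seed(101)
  for (i in 1:40) {
    seq <- random_dna(sample(500:2000, 1), gc = stats::runif(1, 0.3, 0.7))
    for (ml in c(2, 3, 5)) {
      got <- granges_to_pairs(find_homopolymer_tracts(seq, "G", ml))
      expect_identical(got, oracle_homopolymer(seq, "G", ml))
    }
  }
})

test_that("monoG/C census unions G and C runs with strand bookkeeping", {
  seq <- paste0("AATT", strrep("C", 16), "AATT")
  tr <- find_mono_gc_tracts(seq, 15)
  expect_equal(length(tr), 1L)
  expect_equal(as.character(GenomicRanges::strand(tr)), "-")
  expect_equal(GenomicRanges::width(tr), 16L)

  # larger than 14 bp means at least 15: a 14-mer is excluded
  expect_equal(length(find_mono_gc_tracts(paste0("AA", strrep("G", 14), "TT"),
                                          15)), 0L)
  expect_equal(length(find_mono_gc_tracts(paste0("AA", strrep("G", 15), "TT"),
                                          15)), 1L)
})

test_that("planted monoG/C tracts are recovered exactly from a toy genome", {
  set.seed(202)
  cfg <- simulation_config(genome_length = 3e4, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 7),
                           minus_strand_fraction = 0.4)
  built <- build_toy_genome(cfg)
  tr <- find_mono_gc_tracts(built$genome, 15)
  expect_equal(length(tr), 7L)
  expect_equal(GenomicRanges::start(tr), built$truth$motifs$start)
  expect_equal(GenomicRanges::end(tr), built$truth$motifs$end)
  expect_equal(as.character(GenomicRanges::strand(tr)),
               built$truth$motifs$strand)
})

test_that("strict signature scan handles canonical worked examples", {
  s <- scan_signature("GGGAGGGAGGGAGGG", "strict")
  expect_equal(length(s), 1L)
  expect_equal(c(GenomicRanges::start(s), GenomicRanges::end(s)), c(1L, 15L))

  # loop nucleotides may be G, so a G15 homopolymer carries the signature
  s <- scan_signature(strrep("G", 15), "strict")
  expect_equal(length(s), 1L)
  expect_equal(GenomicRanges::width(s), 15L)

  # G14 cannot host four G3 tracts with nonempty loops
  expect_equal(length(scan_signature(strrep("G", 14), "strict")), 0L)
})

test_that("relaxed-family signatures match as stated, strict does not", {
  g2ng12 <- expand_signature(expand_n("G_2NG_12"))
  expect_equal(length(scan_signature(g2ng12, "strict")), 0L)
  expect_gt(length(scan_signature(g2ng12, "relaxed4")), 0L)

  starred <- expand_signature(expand_n("G_2NG_3N_6G_3"))
  expect_equal(length(scan_signature(starred, "relaxed4")), 0L)
  expect_gt(length(scan_signature(starred, "relaxed3")), 0L)
})

test_that("signature scan agrees with the brute-force oracle", {
  set.seed(303)
  specs <- list(signature_spec("strict"), signature_spec("relaxed4"),
                signature_spec("relaxed3"))
  for (i in 1:60) {
    # G-enriched draws make matches common enough to exercise merging
    seq <- random_dna(sample(200:1200, 1), gc = stats::runif(1, 0.4, 0.7))
    for (spec in specs) {
      got <- scan_signature(seq, spec)
      oracle <- oracle_scan_both(seq, spec)
      expect_identical(granges_to_pairs(got, "+"), oracle$plus)
      expect_identical(granges_to_pairs(got, "-"), oracle$minus)
    }
  }
})

test_that("scan respects N bases as tract and loop terminators", {
  # an N inside the only possible loop breaks the match
  seq <- "GGGNGGGAGGGAGGG"
  expect_equal(length(scan_signature(seq, "strict")), 0L)
  # with a clean loop elsewhere the remaining 3-tract stretch has no match
  expect_equal(length(scan_signature("GGGNGGGAGGG", "relaxed3")), 0L)
  expect_equal(length(scan_signature("GGNGGAGGTGG", "relaxed3")), 1L)
})

test_that("scanning the reverse complement mirrors sites and strands", {
  set.seed(404)
  for (i in 1:10) {
    seq <- random_dna(800, gc = 0.6)
    n <- nchar(seq)
    fwd <- scan_signature(seq, "relaxed3")
    rc <- scan_signature(revcomp(seq), "relaxed3")
    mirrored_start <- sort(n - GenomicRanges::end(rc) + 1L)
    expect_equal(sort(GenomicRanges::start(fwd)), mirrored_start)
    flip <- c(`+` = "-", `-` = "+")
    expect_equal(sort(unname(flip[as.character(GenomicRanges::strand(rc))])),
                 sort(as.character(GenomicRanges::strand(fwd))))
  }
})

test_that("merged sites are disjoint and counts survive contig reordering", {
  set.seed(505)
  seqs <- vapply(1:3, function(i) random_dna(600, gc = 0.65), character(1))
  g1 <- as_genome(c(a = seqs[1], b = seqs[2], c = seqs[3]))
  g2 <- as_genome(c(c = seqs[3], a = seqs[1], b = seqs[2]))
  s1 <- scan_signature(g1, "relaxed3")
  s2 <- scan_signature(g2, "relaxed3")
  expect_equal(length(s1), length(s2))
  expect_equal(length(merge_sites_across_strands(s1)),
               length(merge_sites_across_strands(s2)))
  for (str in c("+", "-")) {
    per <- s1[as.character(GenomicRanges::strand(s1)) == str]
    expect_true(GenomicRanges::isDisjoint(per, ignore.strand = TRUE))
  }
})

test_that("strict sites classify into exactly one tract class", {
  expect_equal(classify_motif(strrep("G", 20)), "MONO_TRACT")
  expect_equal(classify_motif(strrep("G", 15)), "MONO_TRACT")
  expect_equal(classify_motif(expand_signature("G_14TG_6AGAAG_3")),
               "MONO_LIKE_LE2")
  expect_equal(classify_motif("GGGTGGGGAAGTTATGGGAGGG"), "INTERRUPTED_GE3")

  # vectorised classification partitions every strict site
  set.seed(606)
  genome <- as_genome(random_dna(5000, gc = 0.7))
  sites <- classify_motifs(scan_signature(genome, "strict"), genome)
  expect_true(all(sites$motif_class %in%
                    c("MONO_TRACT", "MONO_LIKE_LE2", "INTERRUPTED_GE3")))
})

test_that("every monoG/C tract of 15+ carries the strict signature", {
  for (k in 15:25) {
    s <- scan_signature(strrep("G", k), "strict")
    expect_equal(length(s), 1L)
    expect_equal(classify_motif(strrep("G", k)), "MONO_TRACT")
  }
})

test_that("signature strings re-expand to the strand sequence", {
  expect_equal(signature_string("GGGGGGGGGGGGGGTGGGGGGAGAAGGG"),
               "G_14TG_6AGAAG_3")
  expect_equal(expand_signature("G_14TG_6AGAAG_3"),
               "GGGGGGGGGGGGGGTGGGGGGAGAAGGG")
  set.seed(707)
  genome <- as_genome(random_dna(4000, gc = 0.7))
  sites <- scan_signature(genome, "strict")
  for (i in seq_along(sites)) {
    s <- GenomicRanges::start(sites)[i]
    e <- GenomicRanges::end(sites)[i]
    sub <- substr(as.character(genome[[1]]), s, e)
    if (as.character(GenomicRanges::strand(sites))[i] == "-") sub <- revcomp(sub)
    expect_equal(expand_signature(sites$signature_string[i]), sub)
  }
})

test_that("calibration sensitivity table brackets counting conventions", {
  set.seed(808)
  cfg <- simulation_config(genome_length = 3e4, n_genes = 0,
                           plant_counts = c(MONO_TRACT = 4, MONO_LIKE_LE2 = 2))
  built <- build_toy_genome(cfg)
  tab <- calibration_sensitivity(built$genome)
  expect_setequal(unique(tab$quantity), c("signature_sites", "mono_gc_tracts"))
  sig <- tab[tab$quantity == "signature_sites", ]
  collapsed <- sig$count[sig$convention == "merged_strand_collapsed"]
  per_strand <- sig$count[sig$convention == "merged_per_strand"]
  expect_lte(collapsed, per_strand)
  expect_equal(per_strand,
               sig$count[sig$convention == "plus_strand_only"] +
                 sig$count[sig$convention == "minus_strand_only"])
  expect_equal(collapsed, 6L)   # planted strict loci, one site each
})
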