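#' Simulation configuration for a synthetic mutation-accumulation line
#'
#' Bundles and validates the parameters of the toy-genome builder and the
#' line simulator. Defaults mirror the study conditions of a
#' checkpoint/helicase-deficient C. elegans mutation-accumulation
#' experiment: per-generation rates equal to the estimates obtained over
#' the 300-generation observation window (base substitutions 3.1e-9 and
#' small InDels 5.7e-10 per base, G4-site deletions 1.7e-4 per site,
#' non-G4 deletions 5.0e-10 per base, duplications 6.5e-7 per gene), 470
#' generations of propagation with samples at 170, 270 and 470, and a
#' log-normal deletion-size model calibrated so that about 86% of G-rich
#' deletions remove less than 300 bp within the observed 49-10,228 bp
#' range.
#'
#' @param genome_length Total background length in bases.
#' @param n_contigs Number of contigs (length split evenly).
#' @param plant_counts Named integer vector of motif plants per class
#'   (names from [MOTIF_CLASSES], excluding `NON_G_RICH`).
#' @param minus_strand_fraction Probability a plant goes on the minus
#'   strand.
#' @param n_genes,gene_length Planted single-exon protein-coding genes.
#' @param mu_sbs,mu_indel,mu_del_g4,mu_del_nong4,mu_dup Per-generation
#'   event rates (per base, per base, per live G4 site, per base, per
#'   gene).
#' @param p_dup_loss Per-generation probability that an existing
#'   duplication reverts to single copy.
#' @param del_size_meanlog,del_size_sdlog,del_size_range Log-normal
#'   deletion-size model for G4-initiated deletions, truncated to the
#'   given range.
#' @param nong4_size_range Size range for non-G4 deletions (truncated to
#'   below 300 bp, as observed).
#' @param generations Total generations of single-lineage propagation.
#' @param sample_points Generations at which variant tables are emitted.
#' @param breakpoint_jitter_max Maximum bases by which an emitted deletion
#'   breakpoint may sit inside the initiating tract's 3' end.
#' @param decoy_fraction Fraction (relative to true calls) of decoy calls
#'   added to each emitted table that fail the homozygosity filters.
#' @param mono_min_len Minimum monoG/C tract length.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1e6,
                              n_contigs = 1L,
                              plant_counts = c(MONO_TRACT = 8L,
                                               MONO_LIKE_LE2 = 4L,
                                               INTERRUPTED_GE3 = 4L,
                                               RELAXED_4TRACT = 4L,
                                               RELAXED_3TRACT = 4L),
                              minus_strand_fraction = 0.5,
                              n_genes = 8L, gene_length = 300L,
                              mu_sbs = 3.1e-9, mu_indel = 5.7e-10,
                              mu_del_g4 = 1.7e-4, mu_del_nong4 = 5.0e-10,
                              mu_dup = 6.5e-7, p_dup_loss = 1e-3,
                              del_size_meanlog = 4.75, del_size_sdlog = 0.8,
                              del_size_range = c(49L, 10228L),
                              nong4_size_range = c(21L, 299L),
                              generations = 470L,
                              sample_points = c(170L, 270L, 470L),
                              breakpoint_jitter_max = 2L,
                              decoy_fraction = 0.3,
                              mono_min_len = 15L) {
  full <- stats::setNames(rep(0L, 5L), setdiff(MOTIF_CLASSES, "NON_G_RICH"))
  bad <- setdiff(names(plant_counts), names(full))
  if (length(bad)) stop("unknown motif class in plant_counts: ",
                        paste(bad, collapse = ", "))
  full[names(plant_counts)] <- as.integer(plant_counts)
  rates <- c(mu_sbs, mu_indel, mu_del_g4, mu_del_nong4, mu_dup)
  stopifnot(all(rates >= 0), p_dup_loss >= 0, p_dup_loss <= 1,
            genome_length >= 1000, n_contigs >= 1L,
            gene_length %% 3L == 0L, gene_length >= 30L,
            generations >= 1L,
            !is.unsorted(sample_points, strictly = TRUE),
            max(sample_points) <= generations,
            decoy_fraction >= 0, minus_strand_fraction >= 0,
            minus_strand_fraction <= 1, mono_min_len >= 2L)
  structure(list(genome_length = genome_length, n_contigs = as.integer(n_contigs),
                 plant_counts = full,
                 minus_strand_fraction = minus_strand_fraction,
                 n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
                 mu_sbs = mu_sbs, mu_indel = mu_indel, mu_del_g4 = mu_del_g4,
                 mu_del_nong4 = mu_del_nong4, mu_dup = mu_dup,
                 p_dup_loss = p_dup_loss,
                 del_size_meanlog = del_size_meanlog,
                 del_size_sdlog = del_size_sdlog,
                 del_size_range = as.integer(del_size_range),
                 nong4_size_range = as.integer(nong4_size_range),
                 generations = as.integer(generations),
                 sample_points = as.integer(sample_points),
                 breakpoint_jitter_max = as.integer(breakpoint_jitter_max),
                 decoy_fraction = decoy_fraction,
                 mono_min_len = as.integer(mono_min_len)),
            class = "simulation_config")
}

# sample a sequence in which G and C never run to length 2, optionally
# conditioned on fixed neighbour characters; used for redrawn background
# windows, plant buffers and gene bodies so that no G-run signature can
# arise there
clean_seq <- function(len, prev = "", nxt = "") {
  if (len <= 0L) return(character(0))
  out <- character(len)
  last <- prev
  for (i in seq_len(len)) {
    choices <- c("A", "C", "G", "T")
    if (last %in% c("G", "C")) choices <- setdiff(choices, last)
    if (i == len && nxt %in% c("G", "C")) choices <- setdiff(choices, nxt)
    out[i] <- choices[sample.int(length(choices), 1L)]
    last <- out[i]
  }
  out
}

# motif sequence generators (G-space); each guarantees its class under the
# scanner conventions: strict-matching with the right interruption
# structure, or relaxed-family-only membership
plant_sequence <- function(class, mono_min_len = 15L) {
  non_g <- function(k) paste0(sample(c("A", "C", "T"), k, TRUE), collapse = "")
  gs <- function(k) strrep("G", k)
  switch(class,
    MONO_TRACT = gs(sample(mono_min_len:(mono_min_len + 9L), 1L)),
    MONO_LIKE_LE2 = {
      if (stats::runif(1) < 0.5) {   # one interruption run
        paste0(gs(sample(13:14, 1L)), non_g(sample(1:4, 1L)),
               gs(sample(3:8, 1L)))
      } else {                       # two interruption runs
        paste0(gs(sample(10:14, 1L)), non_g(1L), gs(sample(5:8, 1L)),
               non_g(sample(2:5, 1L)), gs(sample(3:6, 1L)))
      }
    },
    INTERRUPTED_GE3 = {
      n_runs <- sample(4:5, 1L)      # n_runs - 1 >= 3 interruptions
      runs <- vapply(seq_len(n_runs), function(i) gs(sample(3:6, 1L)),
                     character(1L))
      loops <- vapply(seq_len(n_runs - 1L), function(i)
        non_g(sample(1:7, 1L)), character(1L))
      paste0(runs, c(loops, ""), collapse = "")
    },
    RELAXED_4TRACT = {
      if (stats::runif(1) < 0.5) {   # short tract + one long (sub-15) run
        paste0(gs(2L), non_g(sample(1:3, 1L)), gs(sample(8:14, 1L)))
      } else {                       # four short tracts
        paste0(gs(2L), non_g(sample(1:3, 1L)), gs(2L), non_g(sample(1:5, 1L)),
               gs(2L), non_g(sample(1:2, 1L)), gs(2L))
      }
    },
    RELAXED_3TRACT = paste0(gs(2L), non_g(1L), gs(sample(3:4, 1L)),
                            non_g(sample(5:7, 1L)), gs(sample(3:4, 1L))),
    stop("no generator for class ", class)
  )
}

# remove every accidental G-run signature from a random background by
# redrawing matched windows from the constrained alphabet; scanning with
# the most permissive family (three tracts of G2+) covers all families and
# monoG/C tracts, on both strands
clean_background <- function(chars, max_iter = 30L) {
  spec <- signature_spec("relaxed3")
  for (iter in seq_len(max_iter)) {
    hits <- c(scan_signature_contig(chars, "G", spec),
              scan_signature_contig(chars, "C", spec))
    hits <- IRanges::reduce(hits)
    if (!length(hits)) return(chars)
    for (i in seq_along(hits)) {
      s <- max(1L, IRanges::start(hits)[i] - 1L)
      e <- min(length(chars), IRanges::end(hits)[i] + 1L)
      prev <- if (s > 1L) chars[s - 1L] else ""
      nxt <- if (e < length(chars)) chars[e + 1L] else ""
      chars[s:e] <- clean_seq(e - s + 1L, prev, nxt)
    }
  }
  stop("failed to produce a signature-free background after ", max_iter,
       " redraw rounds")
}

# gene body: ATG + clean codons with internal stops patched + TAA
gene_sequence <- function(len) {
  body <- clean_seq(len - 6L, prev = "G", nxt = "T")
  seq <- c("A", "T", "G", body, "T", "A", "A")
  for (i in seq(4L, len - 5L, by = 3L)) {
    codon <- paste0(seq[i:(i + 2L)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) seq[i + 2L] <- "C"
  }
  seq
}

#' Build a toy genome with planted G-rich motifs and genes
#'
#' Generates a random background sequence, rejection-checks it to contain
#' no accidental match of any configured G-run signature family or monoG/C
#' tract (matched windows are redrawn until the scan is clean), then
#' plants the configured numbers of motifs of each class and single-exon
#' genes at well-separated positions (at least 200 bp apart, flanked by
#' short G/C-free buffers so each planted locus scans as exactly one
#' site). Deterministic under the session RNG state.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (a `DNAStringSet`) and `truth`, a list of
#'   `motifs` (data.frame: contig, start, end, strand, class, signature)
#'   and `genes` (data.frame: gene_id, contig, strand, start, end).
#' @export
build_toy_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  buffer <- 12L                      # exceeds max loop + min tract: no bridging
  spacing <- 200L
  margin <- 300L
  classes <- rep(names(config$plant_counts), config$plant_counts)
  items <- c(classes, rep("GENE", config$n_genes))
  contig_len <- rep(config$genome_length %/% config$n_contigs,
                    config$n_contigs)
  contig_ids <- paste0("ctg", seq_len(config$n_contigs))
  # round-robin assignment of items to contigs
  item_contig <- rep(seq_len(config$n_contigs), length.out = length(items))
  motif_rows <- list()
  gene_rows <- list()
  contigs <- stats::setNames(vector("list", config$n_contigs), contig_ids)
  for (ci in seq_len(config$n_contigs)) {
    L <- contig_len[ci]
    mine <- items[item_contig == ci]
    mine <- mine[sample.int(length(mine))]     # shuffle plant order
    seqs <- lapply(mine, function(it) {
      if (it == "GENE") gene_sequence(config$gene_length)
      else {
        s <- plant_sequence(it, config$mono_min_len)
        str <- if (stats::runif(1) < config$minus_strand_fraction) "-" else "+"
        sq <- if (str == "-") revcomp(s) else s
        attr_seq <- strsplit(sq, "", fixed = TRUE)[[1L]]
        attr(attr_seq, "strand") <- str
        attr(attr_seq, "gspace") <- s
        attr_seq
      }
    })
    lens <- vapply(seqs, length, integer(1L)) + 2L * buffer
    need <- 2L * margin + sum(lens) + spacing * max(length(mine) - 1L, 0L)
    if (need > L) {
      stop("infeasible packing: contig of ", L, " bases cannot hold ",
           length(mine), " planted items; needs at least ", need, " bases")
    }
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    chars <- clean_background(chars)
    if (length(mine)) {
      slack <- L - need
      u <- stats::runif(length(mine) + 1L)
      extra <- floor(slack * u / sum(u))
      pos <- margin + 1L
      for (k in seq_along(mine)) {
        pos <- pos + extra[k]
        item_chars <- if (mine[k] == "GENE") seqs[[k]] else seqs[[k]]
        start <- pos + buffer
        end <- start + length(item_chars) - 1L
        chars[pos:(pos + buffer - 1L)] <- sample(c("A", "T"), buffer, TRUE)
        chars[start:end] <- as.character(item_chars)
        chars[(end + 1L):(end + buffer)] <- sample(c("A", "T"), buffer, TRUE)
        if (mine[k] == "GENE") {
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = sprintf("gene%03d", length(gene_rows) + 1L),
            contig = contig_ids[ci], strand = "+", start = start, end = end,
            stringsAsFactors = FALSE)
        } else {
          motif_rows[[length(motif_rows) + 1L]] <- data.frame(
            contig = contig_ids[ci], start = start, end = end,
            strand = attr(seqs[[k]], "strand"), class = mine[k],
            signature = signature_string(attr(seqs[[k]], "gspace")),
            stringsAsFactors = FALSE)
        }
        pos <- end + buffer + spacing + 1L
      }
    }
    contigs[[ci]] <- paste0(chars, collapse = "")
  }
  genome <- as_genome(unlist(contigs))
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), class = character(0),
               signature = character(0), stringsAsFactors = FALSE)
  motifs <- motifs[order(motifs$contig, motifs$start), , drop = FALSE]
  rownames(motifs) <- NULL
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(0), contig = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  list(genome = genome,
       truth = list(motifs = motifs, genes = genes, config = config))
}

truth_motif_granges <- function(truth) {
  m <- truth$motifs
  GenomicRanges::GRanges(m$contig, IRanges::IRanges(m$start, m$end),
                         strand = m$strand, class = m$class)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(n - length(out), meanlog, sdlog))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out
}

overlaps_any <- function(contig, start, end, df) {
  if (!nrow(df)) return(FALSE)
  any(df$contig == contig & start <= df$end & end >= df$start)
}

#' Simulate a mutation-accumulation line
#'
#' Single-lineage model of long-term propagation with immediate fixation:
#' each generation draws Poisson counts of substitutions and small InDels
#' (uniform over undeleted bases), G4-site deletions (a uniformly chosen
#' live motif site; the deletion removes the tract, save for up to
#' `breakpoint_jitter_max` bases at its 3' end, together with 5'-flanking
#' sequence, with size from the truncated log-normal model), non-G4
#' deletions (uniform positions away from any motif), and gene
#' duplications (amplification of already-duplicated genes and reversion
#' to single copy are both possible). Every other event class persists
#' once fixed, and a deleted region cannot be hit again (target-loss
#' bookkeeping). At each configured sample point a variant-call table is
#' emitted whose true calls carry depth/VF/BQ (and breakpoint-support)
#' fields that pass the homozygosity filters, mixed with a configured
#' fraction of decoy calls that fail them.
#'
#' @param genome,truth Output of [build_toy_genome()].
#' @param config The [simulation_config()] used to build them.
#' @return An object of class `ma_simulation`: a list with `tables` (one
#'   variant-call data frame per sample point, named by generation) and
#'   `truth` (per-variant ground truth, duplication event log, and the
#'   planted motif and gene tables).
#' @export
simulate_line <- function(genome, truth, config = truth$config) {
  stopifnot(inherits(config, "simulation_config"))
  motifs <- truth$motifs
  genes <- truth$genes
  contig_lens <- stats::setNames(Biostrings::width(genome), names(genome))
  L_total <- sum(contig_lens)
  alive <- rep(TRUE, nrow(motifs))
  copies <- rep(1L, nrow(genes))
  dels <- data.frame(contig = character(0), start = integer(0),
                     end = integer(0), origin_gen = integer(0),
                     class = character(0), site_idx = integer(0),
                     side = character(0), stringsAsFactors = FALSE)
  sbs <- data.frame(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    origin_gen = integer(0), stringsAsFactors = FALSE)
  indels <- data.frame(contig = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       kind = character(0), size = integer(0),
                       origin_gen = integer(0), stringsAsFactors = FALSE)
  dup_log <- data.frame(gene_id = character(0), gen = integer(0),
                        event = character(0), stringsAsFactors = FALSE)
  # zones non-G4 deletions must avoid so they never classify as G-rich
  zone_pad <- 30L
  zones <- if (nrow(motifs)) data.frame(contig = motifs$contig,
                                        start = pmax(motifs$start - zone_pad, 1L),
                                        end = motifs$end + zone_pad)
           else data.frame(contig = character(0), start = integer(0),
                           end = integer(0))
  draw_pos <- function() {
    ctg <- names(contig_lens)[sample.int(length(contig_lens), 1L,
                                         prob = contig_lens)]
    list(contig = ctg, pos = sample.int(contig_lens[[ctg]], 1L))
  }
  base_at <- function(ctg, pos) contig_substring(genome, ctg, pos, pos)
  tables <- stats::setNames(vector("list", length(config$sample_points)),
                            as.character(config$sample_points))
  for (gen in seq_len(config$generations)) {
    # substitutions
    for (i in seq_len(stats::rpois(1L, config$mu_sbs * L_total))) {
      for (try in 1:100) {
        p <- draw_pos()
        if (overlaps_any(p$contig, p$pos, p$pos, dels)) next
        if (any(sbs$contig == p$contig & sbs$pos == p$pos)) next
        ref <- base_at(p$contig, p$pos)
        if (ref == "N") next
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        sbs <- rbind(sbs, data.frame(contig = p$contig, pos = p$pos,
                                     ref = ref, alt = alt, origin_gen = gen,
                                     stringsAsFactors = FALSE))
        break
      }
    }
    # small InDels (1-20 bp)
    for (i in seq_len(stats::rpois(1L, config$mu_indel * L_total))) {
      for (try in 1:100) {
        p <- draw_pos()
        sz <- sample.int(20L, 1L)
        ins <- stats::runif(1) < 0.5
        endp <- if (ins) p$pos else min(p$pos + sz, contig_lens[[p$contig]])
        if (overlaps_any(p$contig, p$pos, endp, dels)) next
        if (any(indels$contig == p$contig & indels$pos == p$pos)) next
        anchor <- base_at(p$contig, p$pos)
        if (ins) {
          insert <- paste0(sample(c("A", "C", "T"), sz, TRUE), collapse = "")
          row <- data.frame(contig = p$contig, pos = p$pos, ref = anchor,
                            alt = paste0(anchor, insert), kind = "INS",
                            size = sz, origin_gen = gen,
                            stringsAsFactors = FALSE)
        } else {
          if (p$pos + sz > contig_lens[[p$contig]]) next
          ref <- contig_substring(genome, p$contig, p$pos, p$pos + sz)
          row <- data.frame(contig = p$contig, pos = p$pos, ref = ref,
                            alt = anchor, kind = "DEL_SMALL", size = sz,
                            origin_gen = gen, stringsAsFactors = FALSE)
        }
        indels <- rbind(indels, row)
        break
      }
    }
    # G4-site deletions with target loss
    n_live <- sum(alive)
    for (i in seq_len(stats::rpois(1L, config$mu_del_g4 * n_live))) {
      live_idx <- which(alive)
      if (!length(live_idx)) break
      placed <- FALSE
      for (try in 1:50) {
        si <- live_idx[sample.int(length(live_idx), 1L)]
        sz <- rtrunc_lnorm(1L, config$del_size_meanlog, config$del_size_sdlog,
                           config$del_size_range[1L], config$del_size_range[2L])
        jit <- sample.int(config$breakpoint_jitter_max + 1L, 1L) - 1L
        if (motifs$strand[si] == "+") {
          dend <- motifs$end[si] - jit
          dstart <- dend - sz + 1L
          side <- "g_run_3prime"
          extends <- dstart < motifs$start[si]  # into the 5' flank
        } else {
          dstart <- motifs$start[si] + jit
          dend <- dstart + sz - 1L
          side <- "c_run_5prime"
          extends <- dend > motifs$end[si]
        }
        if (dstart < 1L || dend > contig_lens[[motifs$contig[si]]]) next
        if (!extends) next
        if (overlaps_any(motifs$contig[si], dstart, dend, dels)) next
        dels <- rbind(dels, data.frame(contig = motifs$contig[si],
                                       start = dstart, end = dend,
                                       origin_gen = gen,
                                       class = motifs$class[si],
                                       site_idx = si, side = side,
                                       stringsAsFactors = FALSE))
        swept <- motifs$contig == motifs$contig[si] &
          motifs$start <= dend & motifs$end >= dstart
        alive[swept] <- FALSE
        placed <- TRUE
        break
      }
      if (!placed && !length(live_idx)) {
        stop("genome exhausted: no live G4 site accepts a deletion")
      }
    }
    # non-G4 deletions, away from every motif
    for (i in seq_len(stats::rpois(1L, config$mu_del_nong4 * L_total))) {
      for (try in 1:100) {
        p <- draw_pos()
        sz <- rtrunc_lnorm(1L, config$del_size_meanlog, config$del_size_sdlog,
                           config$nong4_size_range[1L],
                           config$nong4_size_range[2L])
        dend <- p$pos + sz - 1L
        if (dend > contig_lens[[p$contig]]) next
        if (overlaps_any(p$contig, p$pos, dend, zones)) next
        if (overlaps_any(p$contig, p$pos, dend, dels)) next
        dels <- rbind(dels, data.frame(contig = p$contig, start = p$pos,
                                       end = dend, origin_gen = gen,
                                       class = "NON_G_RICH",
                                       site_idx = NA_integer_, side = "none",
                                       stringsAsFactors = FALSE))
        break
      }
    }
    # duplications: amplification and loss
    for (i in seq_len(stats::rpois(1L, config$mu_dup * nrow(genes)))) {
      gi <- sample.int(nrow(genes), 1L)
      copies[gi] <- copies[gi] + 1L
      dup_log <- rbind(dup_log, data.frame(gene_id = genes$gene_id[gi],
                                           gen = gen, event = "amplification",
                                           stringsAsFactors = FALSE))
    }
    for (gi in which(copies > 1L)) {
      if (stats::runif(1) < config$p_dup_loss) {
        copies[gi] <- 1L
        dup_log <- rbind(dup_log, data.frame(gene_id = genes$gene_id[gi],
                                             gen = gen, event = "loss",
                                             stringsAsFactors = FALSE))
      }
    }
    if (gen %in% config$sample_points) {
      tables[[as.character(gen)]] <-
        emit_call_table(genome, config, sbs, indels, dels, genes, copies)
    }
  }
  truth_variants <- build_truth_table(sbs, indels, dels)
  structure(list(tables = tables,
                 truth = list(variants = truth_variants, dup_log = dup_log,
                              motifs = motifs, genes = genes,
                              final_copies = stats::setNames(copies,
                                                             genes$gene_id)),
                 config = config),
            class = "ma_simulation")
}

build_truth_table <- function(sbs, indels, dels) {
  parts <- list()
  if (nrow(sbs)) {
    parts$sbs <- data.frame(kind = "SBS", contig = sbs$contig, pos = sbs$pos,
                            ref = sbs$ref, alt = sbs$alt, size = 0L,
                            origin_gen = sbs$origin_gen,
                            class = NA_character_, site_idx = NA_integer_,
                            side = NA_character_, stringsAsFactors = FALSE)
  }
  if (nrow(indels)) {
    parts$ind <- data.frame(kind = indels$kind, contig = indels$contig,
                            pos = indels$pos, ref = indels$ref,
                            alt = indels$alt, size = indels$size,
                            origin_gen = indels$origin_gen,
                            class = NA_character_, site_idx = NA_integer_,
                            side = NA_character_, stringsAsFactors = FALSE)
  }
  if (nrow(dels)) {
    parts$del <- data.frame(kind = "DEL_LARGE", contig = dels$contig,
                            pos = dels$start, ref = NA_character_,
                            alt = NA_character_,
                            size = dels$end - dels$start + 1L,
                            origin_gen = dels$origin_gen, class = dels$class,
                            site_idx = dels$site_idx, side = dels$side,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(kind = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), size = integer(0),
                      origin_gen = integer(0), class = character(0),
                      site_idx = integer(0), side = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# emitted call table: true calls pass the homozygosity filters, decoys fail
emit_call_table <- function(genome, config, sbs, indels, dels, genes, copies) {
  rows <- list()
  n_small <- nrow(sbs) + nrow(indels)
  if (nrow(sbs)) {
    rows$sbs <- variant_calls(sbs$contig, sbs$pos, sbs$ref, sbs$alt, "SBS", 0L,
                              depth = sample(30:90, nrow(sbs), TRUE),
                              vf = stats::runif(nrow(sbs), 0.92, 1),
                              bq = sample(32:40, nrow(sbs), TRUE))
  }
  if (nrow(indels)) {
    rows$ind <- variant_calls(indels$contig, indels$pos, indels$ref,
                              indels$alt, indels$kind, indels$size,
                              depth = sample(30:90, nrow(indels), TRUE),
                              vf = stats::runif(nrow(indels), 0.92, 1),
                              bq = sample(32:40, nrow(indels), TRUE))
  }
  n_decoy <- round(config$decoy_fraction * n_small)
  if (n_decoy > 0L) {
    contig_lens <- stats::setNames(Biostrings::width(genome), names(genome))
    ctg <- names(contig_lens)[sample.int(length(contig_lens), n_decoy,
                                         replace = TRUE, prob = contig_lens)]
    pos <- vapply(ctg, function(cc) sample.int(contig_lens[[cc]], 1L),
                  integer(1L))
    ref <- vapply(seq_len(n_decoy), function(i)
      contig_substring(genome, ctg[i], pos[i], pos[i]), character(1L))
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))
    mode <- sample(c("depth_low", "depth_high", "vf", "bq"), n_decoy, TRUE)
    rows$decoy <- variant_calls(ctg, pos, ref, alt, "SBS", 0L,
      depth = ifelse(mode == "depth_low", sample(1:5, n_decoy, TRUE),
                     ifelse(mode == "depth_high", sample(201:400, n_decoy, TRUE),
                            sample(30:90, n_decoy, TRUE))),
      vf = ifelse(mode == "vf", stats::runif(n_decoy, 0.3, 0.85),
                  stats::runif(n_decoy, 0.92, 1)),
      bq = ifelse(mode == "bq", sample(10:29, n_decoy, TRUE),
                  sample(32:40, n_decoy, TRUE)))
  }
  if (nrow(dels)) {
    a <- sample(10:40, nrow(dels), TRUE)
    b <- sample(0:2, nrow(dels), TRUE)
    rows$del <- variant_calls(dels$contig, dels$start, NA, NA, "DEL_LARGE",
                              dels$end - dels$start + 1L,
                              support_a = a, internal_b = b)
    n_het <- round(config$decoy_fraction * nrow(dels))
    if (n_het > 0L) {
      contig_lens <- stats::setNames(Biostrings::width(genome), names(genome))
      ctg <- names(contig_lens)[sample.int(length(contig_lens), n_het,
                                           replace = TRUE, prob = contig_lens)]
      pos <- vapply(ctg, function(cc)
        sample.int(contig_lens[[cc]] - 400L, 1L), integer(1L))
      a2 <- sample(3:10, n_het, TRUE)
      rows$het <- variant_calls(ctg, pos, NA, NA, "DEL_LARGE",
                                sample(50:300, n_het, TRUE),
                                support_a = a2,
                                internal_b = a2 + sample(1:10, n_het, TRUE))
    }
  }
  amp <- which(copies > 1L)
  if (length(amp)) {
    rows$dup <- variant_calls(genes$contig[amp], genes$start[amp], NA, NA,
                              "DUP", genes$end[amp] - genes$start[amp] + 1L,
                              copy_number = copies[amp])
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- variant_calls(character(0), integer(0))[0L, ]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recover simulation parameters through the full pipeline
#'
#' Runs the scan-filter-classify-estimate pipeline on replicate simulated
#' lines of one toy genome and compares the recovered per-generation rates
#' with the configured ones. The substitution rate is estimated as events
#' per base-generation from the filtered final-generation table; the
#' per-G4-site deletion rate uses the fraction of planted sites hit, with
#' target-loss correction `mu = -log(1 - k/n) / generations` (each live
#' site is an exponential target that is removed once hit) and a
#' second-order bias correction for the convexity of the log.
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of independent simulated lines.
#' @param built Optionally, a pre-built [build_toy_genome()] result to
#'   reuse across calls.
#' @return A data.frame with one row per parameter: configured value, mean
#'   estimate, Monte-Carlo standard error of the mean, and z-score.
#' @export
recover_parameters <- function(config = simulation_config(),
                               n_replicates = 20L, built = NULL) {
  if (is.null(built)) built <- build_toy_genome(config)
  genome <- built$genome
  truth <- built$truth
  annotation <- annotate_motifs(genome, config$mono_min_len)
  L <- sum(Biostrings::width(genome))
  G <- config$generations
  n_sites <- nrow(truth$motifs)
  est_sbs <- numeric(n_replicates)
  est_g4 <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_line(genome, truth, config)
    final <- sim$tables[[as.character(max(config$sample_points))]]
    small <- filter_small_variants(final[final$kind %in%
                                           c("SBS", "INS", "DEL_SMALL"), ,
                                         drop = FALSE])
    est_sbs[r] <- sum(small$kind == "SBS") / (L * G)
    dels <- select_homozygous_deletions(final[final$kind == "DEL_LARGE", ,
                                              drop = FALSE])
    cls <- classify_deletions(dels, annotation,
                              tolerance = max(5L, config$breakpoint_jitter_max))
    k <- length(unique(cls$initiating_site[cls$class != "NON_G_RICH"]))
    k <- min(k, n_sites - 1L)        # guard the log at full saturation
    p_hat <- k / n_sites
    # maximum-likelihood estimate with second-order bias correction for
    # the convexity of -log(1 - p) in the hit fraction
    est_g4[r] <- if (n_sites > 0L) {
      (-log(1 - p_hat) - p_hat / (2 * n_sites * (1 - p_hat))) / G
    } else NA_real_
  }
  summarise <- function(configured, est) {
    se <- stats::sd(est) / sqrt(n_replicates)
    data.frame(configured = configured, mean_estimate = mean(est),
               mc_se = se,
               z = if (se > 0) (mean(est) - configured) / se else NA_real_)
  }
  out <- rbind(cbind(parameter = "mu_sbs",
                     summarise(config$mu_sbs, est_sbs)),
               cbind(parameter = "mu_del_g4",
                     summarise(config$mu_del_g4, est_g4)))
  rownames(out) <- NULL
  out
}
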