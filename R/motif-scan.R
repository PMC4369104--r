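#' G-run signature specification
#'
#' Describes a family of G-rich motifs: `n_tracts` runs of at least
#' `min_tract_len` guanines, separated by loops of `min_loop` to `max_loop`
#' nucleotides of any type (loop nucleotides may themselves be G).
#'
#' Three named families are provided:
#' * `"strict"` — the G-quadruplex signature
#'   G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+ (four tracts of three or more G).
#' * `"relaxed4"` — G2+ N1-7 G2+ N1-7 G2+ N1-7 G2+ (four tracts of two or
#'   more G).
#' * `"relaxed3"` — G2+ N1-7 G2+ N1-7 G2+ (three such tracts).
#'
#' @param family One of `"strict"`, `"relaxed4"`, `"relaxed3"`, or
#'   `"custom"`.
#' @param min_tract_len Minimum guanines per tract (>= 2).
#' @param min_loop,max_loop Loop length bounds (1 <= min_loop <= max_loop).
#' @param n_tracts Number of G tracts (>= 3).
#' @return An object of class `signature_spec`.
#' @examples
#' signature_spec("strict")
#' signature_spec("custom", min_tract_len = 2, max_loop = 5, n_tracts = 3)
#' @export
signature_spec <- function(family = c("strict", "relaxed4", "relaxed3", "custom"),
                           min_tract_len = NULL, min_loop = 1L,
                           max_loop = 7L, n_tracts = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    strict   = list(min_tract_len = 3L, n_tracts = 4L),
    relaxed4 = list(min_tract_len = 2L, n_tracts = 4L),
    relaxed3 = list(min_tract_len = 2L, n_tracts = 3L),
    custom   = list(min_tract_len = min_tract_len, n_tracts = n_tracts)
  )
  if (is.null(min_tract_len)) min_tract_len <- defaults$min_tract_len
  if (is.null(n_tracts)) n_tracts <- defaults$n_tracts
  if (is.null(min_tract_len) || is.null(n_tracts)) {
    stop("custom signature_spec requires min_tract_len and n_tracts")
  }
  min_tract_len <- as.integer(min_tract_len)
  min_loop <- as.integer(min_loop)
  max_loop <- as.integer(max_loop)
  n_tracts <- as.integer(n_tracts)
  stopifnot(min_tract_len >= 2L, min_loop >= 1L, max_loop >= min_loop,
            n_tracts >= 3L)
  structure(list(family = family, min_tract_len = min_tract_len,
                 min_loop = min_loop, max_loop = max_loop,
                 n_tracts = n_tracts),
            class = "signature_spec")
}

#' @export
print.signature_spec <- function(x, ...) {
  cat(sprintf("<signature_spec %s> %d tracts of G%d+, loops %d-%d nt\n",
              x$family, x$n_tracts, x$min_tract_len, x$min_loop, x$max_loop))
  invisible(x)
}

# For each position, length of the maximal run of `base` starting there
# (0 where the character differs).
run_length_from <- function(is_base) {
  r <- rle(is_base)
  tot <- rep.int(r$lengths, r$lengths)
  within <- sequence(r$lengths)
  ifelse(rep.int(r$values, r$lengths), tot - within + 1L, 0L)
}

#' Find maximal homopolymer runs of one base
#'
#' Reports every maximal run of `base` of length at least `min_len`, in
#' coordinate order. Maximality means the flanking characters differ from
#' `base` (or the run abuts a contig boundary).
#'
#' @param genome A genome (see [as_genome()]).
#' @param base A single nucleotide in \{A,C,G,T\}.
#' @param min_len Minimum run length (>= 1).
#' @return A [GenomicRanges::GRanges] on strand `"+"` with metadata columns
#'   `tract_len`, `n_interruption_runs` (always 0) and `interruption_bases`
#'   (always 0).
#' @export
find_homopolymer_tracts <- function(genome, base, min_len) {
  genome <- as_genome(genome)
  base <- toupper(as.character(base))
  if (!base %in% c("A", "C", "G", "T")) {
    stop("unknown base symbol: ", base)
  }
  stopifnot(min_len >= 1L)
  si <- genome_seqinfo(genome)
  hits <- lapply(names(genome), function(ctg) {
    chars <- contig_chars(genome, ctg)
    r <- rle(chars == base)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(ctg, IRanges::IRanges(starts[keep], ends[keep]),
                           strand = "+", seqinfo = si)
  })
  gr <- do.call(c, c(list(GenomicRanges::GRanges(seqinfo = si)),
                     hits[!vapply(hits, is.null, TRUE)]))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$tract_len <- GenomicRanges::width(gr)
  S4Vectors::mcols(gr)$n_interruption_runs <- rep.int(0L, length(gr))
  S4Vectors::mcols(gr)$interruption_bases <- rep.int(0L, length(gr))
  gr
}

#' Census of monoG/C homopolymer tracts
#'
#' Finds all maximal G runs (reported on strand `"+"`) and C runs (a C run
#' is a G run on the reverse strand, reported on strand `"-"`) of length at
#' least `min_len`. The default of 15 selects tracts larger than 14 bp,
#' the class with the highest G-quadruplex-forming potential.
#'
#' @inheritParams find_homopolymer_tracts
#' @param min_len Minimum tract length; default 15.
#' @return A sorted [GenomicRanges::GRanges]; `strand` gives the strand on
#'   which the run is guanine.
#' @export
find_mono_gc_tracts <- function(genome, min_len = 15L) {
  genome <- as_genome(genome)
  g <- find_homopolymer_tracts(genome, "G", min_len)
  c_ <- find_homopolymer_tracts(genome, "C", min_len)
  GenomicRanges::strand(c_) <- "-"
  out <- c(g, c_)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = Biostrings::width(genome))
}

# Core scan of one contig, one strand. `base` is "G" for the forward-strand
# pattern and "C" for the pattern whose G-runs lie on the reverse strand
# (the signature is structurally palindromic, so scanning the forward
# sequence for the C-version is equivalent to scanning the reverse
# complement for the G-version).
#
# Dynamic programme over candidate tract starts. For a fixed start s the
# union of all matches starting at s is [s, maxend(s)], because match
# intervals share s and [s, maxend(s)] is itself a match; so the union of
# all matches is obtained from per-start maximal ends, then merging
# overlapping or bookended intervals.
scan_signature_contig <- function(chars, base, spec) {
  n <- length(chars)
  m <- spec$min_tract_len
  g <- run_length_from(chars == base)
  cand <- which(g >= m)
  if (!length(cand)) return(IRanges::IRanges())
  gc_ <- g[cand]
  run_after <- cand + gc_            # first position after the G run
  idx_n <- which(chars == "N")
  # first N at or after run_after; loops never span an N
  if (length(idx_n)) {
    k <- findInterval(run_after - 1L, idx_n) + 1L
    next_n <- ifelse(k > length(idx_n), n + 1L, idx_n[pmin(k, length(idx_n))])
  } else {
    next_n <- rep.int(n + 1L, length(cand))
  }
  best <- cand + gc_ - 1L            # one tract: consume the whole run
  if (spec$n_tracts > 1L) {
    lo <- cand + m + spec$min_loop   # earliest start of the next tract
    hi <- pmin(cand + gc_ + spec$max_loop, next_n, n)
    a <- findInterval(lo - 1L, cand) + 1L
    b <- findInterval(hi, cand)
    for (k in seq_len(spec$n_tracts - 1L)) {
      prev <- best
      best <- vapply(seq_along(cand), function(i) {
        if (a[i] > b[i]) return(NA_integer_)
        v <- prev[a[i]:b[i]]
        v <- v[!is.na(v)]
        if (!length(v)) NA_integer_ else max(v)
      }, integer(1L))
    }
  }
  ok <- !is.na(best)
  if (!any(ok)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(cand[ok], best[ok]))
}

#' Scan a genome for a G-run signature
#'
#' Finds every locus matching `spec`: `n_tracts` runs of at least
#' `min_tract_len` guanines separated by loops of 1-7 (by default)
#' nucleotides of any type, including G. Both strands are scanned (the
#' C-version of the pattern on the forward strand is the G-pattern on the
#' reverse strand). Overlapping or bookended matches of the same spec on
#' the same strand are merged into one maximal site, so one biological
#' locus yields one record. Ambiguity (N) bases terminate tracts and never
#' count as loop nucleotides.
#'
#' @inheritParams find_homopolymer_tracts
#' @param spec A [signature_spec()], or a family name passed to it.
#' @return A sorted [GenomicRanges::GRanges] of per-strand merged sites with
#'   metadata columns `signature_string` (see [signature_string()]) and
#'   `family`. Use [merge_sites_across_strands()] to collapse overlapping
#'   plus/minus sites into double-stranded loci for site counting.
#' @examples
#' scan_signature("GGGAGGGAGGGAGGG", signature_spec("strict"))
#' @export
scan_signature <- function(genome, spec = signature_spec("strict")) {
  genome <- as_genome(genome)
  if (is.character(spec)) spec <- signature_spec(spec)
  stopifnot(inherits(spec, "signature_spec"))
  si <- genome_seqinfo(genome)
  per_contig <- lapply(names(genome), function(ctg) {
    chars <- contig_chars(genome, ctg)
    plus <- scan_signature_contig(chars, "G", spec)
    minus <- scan_signature_contig(chars, "C", spec)
    grs <- list()
    if (length(plus)) {
      grs <- c(grs, GenomicRanges::GRanges(ctg, plus, strand = "+",
                                           seqinfo = si))
    }
    if (length(minus)) {
      grs <- c(grs, GenomicRanges::GRanges(ctg, minus, strand = "-",
                                           seqinfo = si))
    }
    if (!length(grs)) NULL else do.call(c, grs)
  })
  gr <- do.call(c, c(list(GenomicRanges::GRanges(seqinfo = si)),
                     per_contig[!vapply(per_contig, is.null, TRUE)]))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$signature_string <-
    vapply(seq_along(gr), function(i) {
      signature_string(site_strand_sequence(gr[i], genome))
    }, character(1L))
  S4Vectors::mcols(gr)$family <- rep.int(spec$family, length(gr))
  gr
}

# sequence of a site in "G-space": forward sequence for + sites, reverse
# complement for - sites (so G runs read as G)
site_strand_sequence <- function(site, genome) {
  s <- contig_substring(genome, as.character(GenomicRanges::seqnames(site)),
                        GenomicRanges::start(site), GenomicRanges::end(site))
  if (as.character(GenomicRanges::strand(site)) == "-") revcomp(s) else s
}

#' Collapse overlapping plus- and minus-strand sites
#'
#' A G-rich locus on one strand is a C-rich locus on the other; for
#' genome-wide "site" counts, overlapping sites from the two strands are
#' merged into one double-stranded locus. Per-strand records (the input)
#' should be retained for breakpoint-orientation work.
#'
#' @param sites Per-strand sites from [scan_signature()].
#' @return A [GenomicRanges::GRanges] on strand `"*"`, one row per merged
#'   locus, with a `revmap` column linking back to the input rows.
#' @export
merge_sites_across_strands <- function(sites) {
  merged <- GenomicRanges::reduce(sites, ignore.strand = TRUE,
                                  with.revmap = TRUE)
  merged
}

#' Compact signature string for a G-rich sequence
#'
#' Writes runs of two or more G as `G_n` and all other characters
#' literally, e.g. `G_14TG_6AGAAG_3`. [expand_signature()] inverts this.
#'
#' @param seq A sequence string in G-space (for minus-strand sites, the
#'   reverse complement of the genomic subsequence).
#' @return A character scalar.
#' @export
signature_string <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  parts <- ifelse(r$values == "G" & r$lengths >= 2L,
                  paste0("G_", r$lengths),
                  strrep(r$values, r$lengths))
  paste0(parts, collapse = "")
}

#' Expand a compact signature string back to sequence
#'
#' Inverts [signature_string()]: `G_n` becomes a run of n G, `N_k` a run of
#' k N, and all other characters stand for themselves.
#'
#' @param sig A compact signature such as `"G_2NG_12"`.
#' @return The expanded sequence string.
#' @export
expand_signature <- function(sig) {
  sig <- toupper(sig)
  toks <- regmatches(sig, gregexpr("[A-Z]_\\d+|[A-Z]", sig))[[1L]]
  paste0(vapply(toks, function(t) {
    if (grepl("_", t, fixed = TRUE)) {
      strrep(substr(t, 1L, 1L), as.integer(sub(".*_", "", t)))
    } else t
  }, character(1L)), collapse = "")
}

#' Site-count sensitivity to counting conventions
#'
#' Genome-wide "site" counts depend on conventions a scan report rarely
#' states: whether overlapping matches are merged into maximal loci, and
#' whether a locus found on both strands is counted once or twice. This
#' helper tabulates the strict-signature site count and the monoG/C tract
#' count under each convention so a count reported elsewhere can be
#' bracketed and the convention that reproduces it identified.
#'
#' @inheritParams find_homopolymer_tracts
#' @param spec Signature family to tabulate (default strict).
#' @param mono_min_len Minimum monoG/C tract length.
#' @return A data.frame with columns `quantity`, `convention` and `count`.
#' @export
calibration_sensitivity <- function(genome, spec = signature_spec("strict"),
                                    mono_min_len = 15L) {
  genome <- as_genome(genome)
  sites <- scan_signature(genome, spec)
  strand <- as.character(GenomicRanges::strand(sites))
  mono <- find_mono_gc_tracts(genome, mono_min_len)
  mstrand <- as.character(GenomicRanges::strand(mono))
  rbind(
    data.frame(quantity = "signature_sites",
               convention = c("merged_strand_collapsed", "merged_per_strand",
                              "plus_strand_only", "minus_strand_only"),
               count = c(length(merge_sites_across_strands(sites)),
                         length(sites), sum(strand == "+"),
                         sum(strand == "-"))),
    data.frame(quantity = "mono_gc_tracts",
               convention = c("both_strands", "g_runs_only", "c_runs_only"),
               count = c(length(mono), sum(mstrand == "+"),
                         sum(mstrand == "-"))))
}

#' Subclassify a strict-signature site
#'
#' Assigns each strict G4-signature site exactly one of three classes,
#' based on the structure of the G runs within the site (read in G-space,
#' i.e. on the strand carrying the G runs):
#' * `MONO_TRACT` — the site contains a pure G homopolymer of at least
#'   `mono_min_len` (default 15, i.e. larger than 14 bp);
#' * `MONO_LIKE_LE2` — otherwise, at most two runs of non-G nucleotides
#'   interrupt the homopolymer;
#' * `INTERRUPTED_GE3` — three or more interruption runs.
#'
#' Interruptions are counted as *runs*, not nucleotides: the G runs of a
#' site are its maximal runs of two or more G (exactly the subscripted
#' segments of the compact signature string), and each maximal segment
#' between two successive G runs is one interruption run. A lone G inside
#' such a segment is part of the interruption: `G_14TG_6AGAAG_3` has five
#' interrupting nucleotides, one of them a single G, but two interruption
#' runs (`T` and `AGAA`).
#'
#' @param sites Strict-signature sites ([scan_signature()] output).
#' @param genome The genome the sites were scanned from.
#' @param mono_min_len Minimum pure-run length for `MONO_TRACT`.
#' @return For `classify_motifs`, the input with `motif_class` and
#'   interruption-count columns added; for `classify_motif`, a single class
#'   label.
#' @export
classify_motifs <- function(sites, genome, mono_min_len = 15L) {
  genome <- as_genome(genome)
  n <- length(sites)
  cls <- character(n)
  n_runs <- integer(n)
  n_bases <- integer(n)
  for (i in seq_len(n)) {
    s <- site_strand_sequence(sites[i], genome)
    tr <- gregexpr("G{2,}", s)[[1L]]
    if (tr[1L] == -1L) {
      n_runs[i] <- 0L
      n_bases[i] <- 0L
      max_g <- 0L
    } else {
      lens <- attr(tr, "match.length")
      # interruptions: the segments between successive G runs
      gaps <- if (length(tr) > 1L)
        tr[-1L] - (tr[-length(tr)] + lens[-length(lens)]) else integer(0)
      n_runs[i] <- length(gaps)
      n_bases[i] <- sum(gaps)
      max_g <- max(lens)
    }
    cls[i] <- if (max_g >= mono_min_len) "MONO_TRACT"
              else if (n_runs[i] <= 2L) "MONO_LIKE_LE2"
              else "INTERRUPTED_GE3"
  }
  S4Vectors::mcols(sites)$motif_class <- cls
  S4Vectors::mcols(sites)$n_interruption_runs <- n_runs
  S4Vectors::mcols(sites)$interruption_bases <- n_bases
  sites
}

#' @rdname classify_motifs
#' @param site A single site (length-1 `GRanges`) or a sequence string.
#' @export
classify_motif <- function(site, genome = NULL, mono_min_len = 15L) {
  if (is.character(site)) {
    genome <- as_genome(site)
    site <- GenomicRanges::GRanges("seq",
              IRanges::IRanges(1L, Biostrings::width(genome)[1L]),
              strand = "+")
  }
  stopifnot(length(site) == 1L)
  out <- classify_motifs(site, genome, mono_min_len)
  S4Vectors::mcols(out)$motif_class
}

#' Build the full motif annotation of a genome
#'
#' Scans for the strict G4 signature, the relaxed four-tract and relaxed
#' three-tract signatures, and subclassifies strict sites. Relaxed sites
#' that overlap a site of a higher-priority family are dropped, so each
#' locus is annotated once, under the most specific family that matches:
#' strict (subclassified as `MONO_TRACT` / `MONO_LIKE_LE2` /
#' `INTERRUPTED_GE3`), then `RELAXED_4TRACT`, then `RELAXED_3TRACT`.
#'
#' @inheritParams find_homopolymer_tracts
#' @param mono_min_len Minimum pure-run length for the `MONO_TRACT` class.
#' @return A sorted [GenomicRanges::GRanges] with columns `family`,
#'   `motif_class` and `signature_string`.
#' @export
annotate_motifs <- function(genome, mono_min_len = 15L) {
  genome <- as_genome(genome)
  strict <- classify_motifs(scan_signature(genome, signature_spec("strict")),
                            genome, mono_min_len)
  r4 <- scan_signature(genome, signature_spec("relaxed4"))
  r3 <- scan_signature(genome, signature_spec("relaxed3"))
  drop_overlapping <- function(x, higher) {
    if (!length(x) || !length(higher)) return(x)
    hit <- GenomicRanges::findOverlaps(x, higher, ignore.strand = TRUE)
    if (!length(hit)) x else x[-unique(S4Vectors::queryHits(hit))]
  }
  r4 <- drop_overlapping(r4, strict)
  r3 <- drop_overlapping(r3, c(GenomicRanges::granges(strict),
                               GenomicRanges::granges(r4)))
  if (length(r4)) S4Vectors::mcols(r4)$motif_class <- "RELAXED_4TRACT"
  if (length(r3)) S4Vectors::mcols(r3)$motif_class <- "RELAXED_3TRACT"
  keep <- c("family", "motif_class", "signature_string")
  pad <- function(x) {
    mc <- S4Vectors::mcols(x)
    for (col in setdiff(keep, colnames(mc))) {
      mc[[col]] <- rep(NA_character_, length(x))
    }
    S4Vectors::mcols(x) <- mc[, keep, drop = FALSE]
    x
  }
  out <- c(pad(strict), pad(r4), pad(r3))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
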