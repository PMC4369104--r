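#' Motif / deletion class labels, in priority order
#' @export
MOTIF_CLASSES <- c("MONO_TRACT", "MONO_LIKE_LE2", "INTERRUPTED_GE3",
                   "RELAXED_4TRACT", "RELAXED_3TRACT", "NON_G_RICH")

#' Convert deletion calls to genomic ranges
#'
#' @param deletions Either a `GRanges`, or a variant-call data frame whose
#'   `pos` is the first deleted base and `size` the deletion length.
#' @return A [GenomicRanges::GRanges].
#' @export
deletions_as_granges <- function(deletions) {
  if (methods::is(deletions, "GRanges")) return(deletions)
  GenomicRanges::GRanges(deletions$contig,
                         IRanges::IRanges(deletions$pos,
                                          width = pmax(deletions$size, 1L)))
}

# geometry of deletion initiation at one motif family.
#
# In the helicase-deficient background, a replication-blocking G4 lesion
# leaves the deletion's breakpoint at the 3' end of the G tract with the
# deleted segment extending into the tract's 5'-flanking DNA. For a
# plus-strand G run, the relevant breakpoint is therefore the deletion's
# *right* end, which must lie inside the motif or within `tolerance` bases
# of the motif's right (3') end, while the deletion extends leftward past
# the motif start. Minus-strand G runs (C runs on the forward strand)
# mirror this.
initiation_candidates <- function(del, motifs, tolerance, require_orientation) {
  if (!length(motifs)) return(data.frame(site = integer(0), side = character(0),
                                         dist = integer(0)))
  same <- which(as.character(GenomicRanges::seqnames(motifs)) ==
                  as.character(GenomicRanges::seqnames(del)))
  if (!length(same)) return(data.frame(site = integer(0), side = character(0),
                                       dist = integer(0)))
  ms <- GenomicRanges::start(motifs)[same]
  me <- GenomicRanges::end(motifs)[same]
  mstr <- as.character(GenomicRanges::strand(motifs))[same]
  ds <- GenomicRanges::start(del)
  de <- GenomicRanges::end(del)
  plus <- mstr != "-"
  if (require_orientation) {
    # the strand-appropriate breakpoint must sit at the initiation end and
    # the deletion must extend into the tract's 5' flank
    ok_plus <- plus & de >= ms & de <= me + tolerance & ds < ms
    ok_minus <- !plus & ds <= me & ds >= ms - tolerance & de > me
    ok <- ok_plus | ok_minus
    dist <- ifelse(plus, abs(de - me), abs(ds - ms))
  } else {
    # orientation-free mode: any breakpoint inside the motif or within
    # tolerance of the initiation end qualifies
    init_end <- ifelse(plus, me, ms)
    inside <- function(bp) bp >= ms & bp <= me
    near <- function(bp) abs(bp - init_end) <= tolerance
    ok <- inside(ds) | inside(de) | near(ds) | near(de)
    dist <- pmin(abs(ds - init_end), abs(de - init_end))
  }
  data.frame(site = same[ok],
             side = ifelse(plus[ok], "g_run_3prime", "c_run_5prime"),
             dist = dist[ok],
             stringsAsFactors = FALSE)
}

#' Find the motif at which a deletion initiates
#'
#' Searches `motifs` for a site compatible with the deletion's breakpoints
#' under the initiation geometry (see Details of [classify_deletions()]).
#' When several motifs qualify, the one whose initiation end is nearest the
#' breakpoint wins; ties are broken toward the higher-priority class in
#' `MOTIF_CLASSES` order.
#'
#' @param deletion A length-1 `GRanges` (or one-row deletion call table).
#' @param motifs Motif annotation (`GRanges` with a `motif_class` column).
#' @param genome Optional genome for bounds checking.
#' @param tolerance Breakpoint slack in bases around the initiation end
#'   (default 5).
#' @param require_orientation If `TRUE` (default), the deletion must extend
#'   5'-ward of the G run; a deletion extending the wrong way does not
#'   qualify.
#' @return A list with `site` (the motif row index, or `NA`) and `side`
#'   (`"g_run_3prime"`, `"c_run_5prime"`, or `"none"`).
#' @export
initiating_site <- function(deletion, motifs, genome = NULL, tolerance = 5L,
                            require_orientation = TRUE) {
  deletion <- deletions_as_granges(deletion)
  stopifnot(length(deletion) == 1L)
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    ctg <- as.character(GenomicRanges::seqnames(deletion))
    if (!ctg %in% names(genome) ||
        GenomicRanges::end(deletion) > length(genome[[ctg]]) ||
        GenomicRanges::start(deletion) < 1L) {
      stop("deletion outside genome bounds: ", ctg, ":",
           GenomicRanges::start(deletion), "-", GenomicRanges::end(deletion))
    }
  }
  cand <- initiation_candidates(deletion, motifs, tolerance,
                                require_orientation)
  if (!nrow(cand)) return(list(site = NA_integer_, side = "none"))
  cls <- S4Vectors::mcols(motifs)$motif_class[cand$site]
  pri <- match(cls, MOTIF_CLASSES)
  best <- order(cand$dist, pri)[1L]
  list(site = cand$site[best], side = cand$side[best])
}

#' Classify large deletions by initiating motif
#'
#' Assigns each deletion larger than 20 bp exactly one class against the
#' motif annotation, with family priority strict > relaxed four-tract >
#' relaxed three-tract > none: a deletion initiating at a strict
#' G4-signature site takes that site's subclass (`MONO_TRACT`,
#' `MONO_LIKE_LE2` or `INTERRUPTED_GE3`); failing that, `RELAXED_4TRACT`,
#' then `RELAXED_3TRACT`, else `NON_G_RICH`.
#'
#' @param deletions Deletion intervals (`GRanges` or call table).
#' @param motifs Annotation from [annotate_motifs()] (needs `family` and
#'   `motif_class` columns).
#' @param genome Optional genome for bounds checking.
#' @inheritParams initiating_site
#' @return A data.frame with one row per deletion: `contig`, `start`,
#'   `end`, `size`, `class`, `initiating_site` (motif row index or `NA`),
#'   `breakpoint_side`, `signature_string`.
#' @export
classify_deletions <- function(deletions, motifs, genome = NULL,
                               tolerance = 5L, require_orientation = TRUE) {
  gr <- deletions_as_granges(deletions)
  fam_order <- list(strict = c("MONO_TRACT", "MONO_LIKE_LE2", "INTERRUPTED_GE3"),
                    relaxed4 = "RELAXED_4TRACT",
                    relaxed3 = "RELAXED_3TRACT")
  fam <- S4Vectors::mcols(motifs)$family
  if (is.null(fam)) fam <- rep("strict", length(motifs))
  n <- length(gr)
  cls <- rep("NON_G_RICH", n)
  site <- rep(NA_integer_, n)
  side <- rep("none", n)
  sig <- rep(NA_character_, n)
  sigs <- S4Vectors::mcols(motifs)$signature_string
  for (i in seq_len(n)) {
    for (f in names(fam_order)) {
      idx <- which(fam == f)
      if (!length(idx)) next
      hit <- initiating_site(gr[i], motifs[idx], genome, tolerance,
                             require_orientation)
      if (!is.na(hit$site)) {
        j <- idx[hit$site]
        cls[i] <- S4Vectors::mcols(motifs)$motif_class[j]
        site[i] <- j
        side[i] <- hit$side
        if (!is.null(sigs)) sig[i] <- sigs[j]
        break
      }
    }
  }
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             size = GenomicRanges::width(gr), class = cls,
             initiating_site = site, breakpoint_side = side,
             signature_string = sig, stringsAsFactors = FALSE)
}

#' Summarise a deletion classification
#'
#' @param classified Output of [classify_deletions()].
#' @param size_threshold Threshold for the small-deletion fraction
#'   (default 300 bp, strictly below).
#' @return A list: per-class `counts`, `n_total`, `n_g_rich`,
#'   `fraction_g_rich`, and the [size_distribution()] of the G-rich
#'   deletions.
#' @export
classification_summary <- function(classified, size_threshold = 300L) {
  counts <- table(factor(classified$class, levels = MOTIF_CLASSES))
  n_total <- nrow(classified)
  n_g_rich <- n_total - as.integer(counts[["NON_G_RICH"]])
  g_sizes <- classified$size[classified$class != "NON_G_RICH"]
  list(counts = counts, n_total = n_total, n_g_rich = n_g_rich,
       fraction_g_rich = if (n_total) n_g_rich / n_total else NA_real_,
       g_rich_sizes = size_distribution(g_sizes, threshold = size_threshold))
}

#' Census of deleted monoG/C tracts
#'
#' A tract counts as deleted when a single deletion covers at least
#' `min_overlap_frac` of it (default half; the observed pattern is that
#' initiating tracts are almost completely removed, so a majority-overlap
#' rule is used rather than a one-base touch).
#'
#' @param mono_tracts Tracts from [find_mono_gc_tracts()].
#' @param deletions Deletion intervals (`GRanges` or call table).
#' @param min_overlap_frac Minimum covered fraction, inclusive.
#' @return A list with `n_deleted`, `n_total`, `fraction`, and the logical
#'   vector `deleted` (one element per tract).
#' @export
deleted_tract_census <- function(mono_tracts, deletions,
                                 min_overlap_frac = 0.5) {
  n_total <- length(mono_tracts)
  if (!n_total) stop("no monoG/C tracts supplied: fraction undefined")
  del <- deletions_as_granges(deletions)
  deleted <- rep(FALSE, n_total)
  if (length(del)) {
    hits <- GenomicRanges::findOverlaps(mono_tracts, del, ignore.strand = TRUE)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::granges(mono_tracts)[qi],
        GenomicRanges::granges(del)[S4Vectors::subjectHits(hits)],
        ignore.strand = TRUE))
      frac <- ov / GenomicRanges::width(mono_tracts)[qi]
      deleted[unique(qi[frac >= min_overlap_frac])] <- TRUE
    }
  }
  list(n_deleted = sum(deleted), n_total = n_total,
       fraction = sum(deleted) / n_total, deleted = deleted)
}

#' Deletion size distribution
#'
#' @param sizes Deletion sizes in bases (or a classified/called table with
#'   a `size` column).
#' @param threshold Sizes strictly below this value count toward
#'   `fraction_below` (default 300 bp).
#' @param breaks Histogram breaks; the default spans the observed range of
#'   G-rich deletion sizes.
#' @return A list with `histogram` (counts per bin), `fraction_below`, and
#'   `n`. With empty input the histogram is empty and `fraction_below` is
#'   `NA`.
#' @export
size_distribution <- function(sizes, threshold = 300L,
                              breaks = c(0, 100, 200, 300, 500, 1000,
                                         5000, Inf)) {
  if (is.data.frame(sizes)) sizes <- sizes$size
  if (!length(sizes)) {
    return(list(histogram = table(cut(numeric(0), breaks)),
                fraction_below = NA_real_, n = 0L))
  }
  list(histogram = table(cut(sizes, breaks)),
       fraction_below = mean(sizes < threshold),
       n = length(sizes))
}
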