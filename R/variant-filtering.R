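VARIANT_KINDS <- c("SBS", "INS", "DEL_SMALL", "DEL_LARGE", "DUP")

# Required columns of the variant-call table dialect. `size` is 0 for SBS.
VARIANT_COLUMNS <- c("contig", "pos", "ref", "alt", "kind", "size",
                     "depth", "vf", "bq", "support_a", "internal_b",
                     "copy_number")

#' Construct a variant-call table
#'
#' Builds a data frame in the package's variant-call dialect, filling
#' optional columns with `NA`. `pos` is the 1-based coordinate of the
#' reference-anchor base; `vf` is the variant frequency in `[0, 1]`; `bq`
#' the Phred base quality; `support_a` / `internal_b` the
#' breakpoint-supporting and deletion-internal read counts used for the
#' homozygosity statistic of large deletions.
#'
#' @param contig,pos,ref,alt,kind Variant key fields.
#' @param size Event size in bases (0 for SBS).
#' @param depth,vf,bq Small-variant call statistics.
#' @param support_a,internal_b Large-deletion read support.
#' @param copy_number Copy number (duplications).
#' @return A data.frame with the columns listed in `VARIANT_COLUMNS`.
#' @export
variant_calls <- function(contig, pos, ref = NA_character_,
                          alt = NA_character_, kind = "SBS", size = 0L,
                          depth = NA_real_, vf = NA_real_, bq = NA_real_,
                          support_a = NA_real_, internal_b = NA_real_,
                          copy_number = NA_integer_) {
  n <- max(length(contig), length(pos))
  df <- data.frame(contig = rep_len(as.character(contig), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   kind = rep_len(as.character(kind), n),
                   size = rep_len(as.integer(size), n),
                   depth = rep_len(as.numeric(depth), n),
                   vf = rep_len(as.numeric(vf), n),
                   bq = rep_len(as.numeric(bq), n),
                   support_a = rep_len(as.numeric(support_a), n),
                   internal_b = rep_len(as.numeric(internal_b), n),
                   copy_number = rep_len(as.integer(copy_number), n),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% VARIANT_KINDS
  if (any(bad)) stop("unknown variant kind: ", df$kind[which(bad)[1L]])
  if (any(!is.na(df$vf) & (df$vf < 0 | df$vf > 1))) {
    stop("variant frequency outside [0, 1]")
  }
  df
}

#' Variant identity key
#'
#' Exact-match identity used to compare variants across generations and
#' against background strains: `(contig, pos, ref, alt, kind)`.
#'
#' @param calls A variant-call data frame.
#' @return A character vector of keys.
#' @export
variant_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, calls$kind, sep = ":")
}

require_fields <- function(calls, fields, context) {
  for (f in fields) {
    if (!f %in% names(calls)) {
      stop(context, ": missing required field '", f, "'")
    }
    miss <- which(is.na(calls[[f]]))
    if (length(miss)) {
      stop(context, ": field '", f, "' missing in record ", miss[1L],
           " (", calls$contig[miss[1L]], ":", calls$pos[miss[1L]], ")")
    }
  }
}

#' Filter small-variant calls to fixed homozygous calls
#'
#' Keeps exactly the calls with depth of coverage strictly greater than
#' `min_depth_exclusive` and at most `max_depth`, variant frequency at
#' least `min_vf`, and base quality at least `min_bq` — the thresholds used
#' to select fixed homozygous substitutions and small InDels from
#' pileup-based caller output. The result is additionally deduplicated so
#' that each coordinate corresponds to one variant, keeping the higher-VF
#' record (ties broken toward the lexicographically smallest alt allele).
#' Input order is preserved.
#'
#' @param calls A variant-call data frame (see [variant_calls()]).
#' @param min_depth_exclusive Depth must be `>` this value (default 5).
#' @param max_depth Depth must be `<=` this value (default 200).
#' @param min_vf Minimum variant frequency (default 0.9).
#' @param min_bq Minimum Phred base quality (default 30).
#' @return The surviving rows of `calls`.
#' @export
filter_small_variants <- function(calls, min_depth_exclusive = 5,
                                  max_depth = 200, min_vf = 0.9,
                                  min_bq = 30) {
  if (!nrow(calls)) return(calls)
  require_fields(calls, c("contig", "pos", "depth", "vf", "bq"),
                 "filter_small_variants")
  keep <- calls$depth > min_depth_exclusive & calls$depth <= max_depth &
    calls$vf >= min_vf & calls$bq >= min_bq
  out <- calls[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  # one variant per coordinate: highest VF wins, then smallest alt allele
  coord <- paste(out$contig, out$pos, sep = ":")
  ord <- order(coord, -out$vf, out$alt)
  first <- !duplicated(coord[ord])
  keep_idx <- sort(ord[first])
  out[keep_idx, , drop = FALSE]
}

#' Select fixed homozygous large deletions
#'
#' Applies the homozygosity statistic for breakpoint-supported deletion
#' calls: with `a` the number of unique reads supporting the breakpoints
#' and `b` the number of reads mapped within the deleted region, a call is
#' kept when `a / (a + b) > 0.5` (strictly) and its size is strictly
#' greater than `min_size_exclusive` bp. Calls with `a + b == 0` are
#' dropped with a message.
#'
#' @param calls A variant-call data frame with `support_a`, `internal_b`
#'   and `size`.
#' @param min_size_exclusive Size must exceed this value (default 20).
#' @return The surviving rows, with a `hom_stat` column appended.
#' @export
select_homozygous_deletions <- function(calls, min_size_exclusive = 20) {
  if (!nrow(calls)) {
    calls$hom_stat <- numeric(0)
    return(calls)
  }
  require_fields(calls, c("support_a", "internal_b", "size"),
                 "select_homozygous_deletions")
  if (any(calls$support_a < 0 | calls$internal_b < 0)) {
    stop("negative read counts in deletion calls")
  }
  tot <- calls$support_a + calls$internal_b
  zero <- tot == 0
  if (any(zero)) {
    message(sum(zero), " deletion call(s) dropped: no supporting reads (a + b = 0)")
  }
  stat <- ifelse(zero, NA_real_, calls$support_a / tot)
  keep <- !zero & stat > 0.5 & calls$size > min_size_exclusive
  out <- calls[keep, , drop = FALSE]
  out$hom_stat <- stat[keep]
  out
}

#' Subtract background-strain variants
#'
#' Removes from `sample` every variant whose identity key appears in any
#' of the background sets — the set logic used to discard variants already
#' present in reference-strain isolates, which did not accumulate during
#' the experiment.
#'
#' @param sample A variant-call data frame.
#' @param backgrounds A list of variant-call data frames (possibly empty).
#' @return The rows of `sample` not matched by any background.
#' @export
subtract_background <- function(sample, backgrounds = list()) {
  if (!length(backgrounds) || !nrow(sample)) return(sample)
  bg_keys <- unique(unlist(lapply(backgrounds, variant_key)))
  sample[!variant_key(sample) %in% bg_keys, , drop = FALSE]
}

# Match large interval events (DEL_LARGE, DUP) between two call sets by
# reciprocal overlap; returns indices into `b` for each row of `a` (NA if
# unmatched). Used both for cross-generation identity (breakpoint
# re-estimation jitters between sequencing batches) and CNV-evidence
# merging.
match_by_reciprocal_overlap <- function(a, b, min_reciprocal_overlap) {
  if (!nrow(a) || !nrow(b)) return(rep(NA_integer_, nrow(a)))
  lv <- union(unique(a$contig), unique(b$contig))
  gra <- GenomicRanges::GRanges(factor(a$contig, lv),
                                IRanges::IRanges(a$pos, width = pmax(a$size, 1L)))
  grb <- GenomicRanges::GRanges(factor(b$contig, lv),
                                IRanges::IRanges(b$pos, width = pmax(b$size, 1L)))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  if (!length(hits)) return(rep(NA_integer_, nrow(a)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(gra[qi], grb[si]))
  frac <- pmin(ov / GenomicRanges::width(gra)[qi],
               ov / GenomicRanges::width(grb)[si])
  ok <- frac >= min_reciprocal_overlap
  out <- rep(NA_integer_, nrow(a))
  # best (largest reciprocal overlap) match per query
  for (i in order(-frac)) {
    if (ok[i] && is.na(out[qi[i]])) out[qi[i]] <- si[i]
  }
  out
}


#' Cross-generation accumulation matrix
#'
#' For each variant kind and each sampled generation, counts the variants
#' first seen at that generation (new counts) and, separately, variants
#' present at the previous sampled generation but absent now (reversions).
#' Substitutions, InDels and deletions are expected never to revert once
#' fixed; duplications may (copy-number loss back to wild type). Large
#' deletions and duplications are matched across generations by reciprocal
#' overlap (default 0.9) rather than exact coordinates.
#'
#' @param generation_sets A named list, one variant-call data frame per
#'   sampled generation; names are generation numbers, ascending.
#' @param kinds Variant kinds to tabulate.
#' @param min_reciprocal_overlap Interval-identity threshold for large
#'   events.
#' @return An object of class `accumulation_matrix`: a list with `new`
#'   (kinds x generations matrix of first-seen counts), `reversions`
#'   (same shape), and `window_total` (new counts summed over generations
#'   after the first).
#' @examples
#' g <- function(n) variant_calls("I", seq_len(n), "A", "T")
#' accumulation_matrix(list(`170` = g(431), `270` = g(463), `470` = g(525)))
#' @export
accumulation_matrix <- function(generation_sets, kinds = VARIANT_KINDS,
                                min_reciprocal_overlap = 0.9) {
  gens <- as.numeric(names(generation_sets))
  if (any(is.na(gens)) || is.unsorted(gens, strictly = TRUE)) {
    stop("generation_sets must be named by ascending generation numbers")
  }
  ngen <- length(gens)
  new_m <- matrix(0L, nrow = length(kinds), ncol = ngen,
                  dimnames = list(kinds, names(generation_sets)))
  rev_m <- new_m
  seen <- character(0)              # keys seen at any earlier generation
  prev_keys <- character(0)
  prev_kind <- character(0)
  # canonical coordinate frame for interval events: the first occurrence of
  # an event names it; later occurrences that reciprocally overlap inherit
  # its key, absorbing breakpoint re-estimation jitter between batches
  canon <- generation_sets[[1L]][0L, , drop = FALSE]
  for (j in seq_len(ngen)) {
    calls <- generation_sets[[j]]
    keys <- variant_key(calls)
    big <- which(calls$kind %in% c("DEL_LARGE", "DUP"))
    if (length(big)) {
      m <- match_by_reciprocal_overlap(calls[big, , drop = FALSE], canon,
                                       min_reciprocal_overlap)
      matched <- !is.na(m)
      keys[big[matched]] <- variant_key(canon)[m[matched]]
      canon <- rbind(canon, calls[big[!matched], , drop = FALSE])
    }
    for (k in kinds) {
      kk <- unique(keys[calls$kind == k])
      new_m[k, j] <- sum(!kk %in% seen)
      if (j > 1L) {
        gone <- setdiff(prev_keys[prev_kind == k], kk)
        rev_m[k, j] <- length(gone)
      }
    }
    seen <- union(seen, keys)
    prev_keys <- keys
    prev_kind <- calls$kind
  }
  structure(list(new = new_m, reversions = rev_m,
                 window_total = if (ngen > 1L)
                   rowSums(new_m[, -1L, drop = FALSE]) else new_m[, 0L],
                 generations = gens),
            class = "accumulation_matrix")
}

#' @export
print.accumulation_matrix <- function(x, ...) {
  cat("Accumulation matrix (new variants first seen at each generation)\n")
  print(x$new)
  if (length(x$window_total)) {
    cat(sprintf("\nWindow F%s-F%s totals:\n", x$generations[1L],
                x$generations[length(x$generations)]))
    print(x$window_total)
  }
  if (any(x$reversions > 0)) {
    cat("\nReversions:\n")
    print(x$reversions)
  }
  invisible(x)
}

#' Merge primary and orthogonal CNV evidence
#'
#' Unions two interval call sets (e.g. breakpoint-resolved deletion calls
#' and array-CGH-derived calls), deduplicating events that reciprocally
#' overlap by at least `min_reciprocal_overlap`. Merged events keep the
#' primary (coordinate-refined) breakpoints when available.
#'
#' @param primary_calls,orthogonal_calls Variant-call data frames of
#'   interval events.
#' @param min_reciprocal_overlap Fraction in `(0, 1]`; default 0.5.
#' @return A variant-call data frame with an `evidence` column
#'   (`"primary"`, `"orthogonal"`, or `"both"`).
#' @export
merge_cnv_evidence <- function(primary_calls, orthogonal_calls,
                               min_reciprocal_overlap = 0.5) {
  m <- match_by_reciprocal_overlap(orthogonal_calls, primary_calls,
                                   min_reciprocal_overlap)
  primary_calls$evidence <- rep("primary", nrow(primary_calls))
  if (nrow(primary_calls) && any(!is.na(m))) {
    primary_calls$evidence[m[!is.na(m)]] <- "both"
  }
  extra <- orthogonal_calls[is.na(m), , drop = FALSE]
  if (nrow(extra)) extra$evidence <- "orthogonal"
  out <- rbind(primary_calls, extra)
  out[order(out$contig, out$pos), , drop = FALSE]
}
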