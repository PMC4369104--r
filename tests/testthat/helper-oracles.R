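# Independent brute-force oracles, written directly from the pattern
# definitions, against which the production scanners are checked.

# all maximal runs of `base` of length >= min_len, by walking the sequence
# character by character
oracle_homopolymer <- function(seq, base, min_len) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  out <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == base) {
      j <- i
      while (j < n && chars[j + 1L] == base) j <- j + 1L
      if (j - i + 1L >= min_len) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# every end position of a signature match starting at `pos`: recursion over
# all tract lengths and loop lengths, memoised on (pos, tracts_left)
oracle_match_ends <- function(chars, spec) {
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  rec <- function(pos, k) {
    key <- paste0(pos, ":", k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    ends <- integer(0)
    run <- 0L
    while (pos + run <= n && chars[pos + run] == "G") run <- run + 1L
    if (run >= spec$min_tract_len) {
      for (tl in spec$min_tract_len:run) {
        if (k == 1L) {
          ends <- c(ends, pos + tl - 1L)
        } else {
          for (l in spec$min_loop:spec$max_loop) {
            nxt <- pos + tl + l
            if (nxt > n) break
            loop_chars <- chars[(pos + tl):(nxt - 1L)]
            if (any(loop_chars == "N")) next
            ends <- c(ends, rec(nxt, k - 1L))
          }
        }
      }
    }
    ends <- unique(ends)
    memo[[key]] <- ends
    ends
  }
  rec
}

# union of all matching substrings of the G-version of the pattern,
# merged when overlapping or bookended (manual merge)
oracle_scan_g <- function(seq, spec) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  rec <- oracle_match_ends(chars, spec)
  iv <- list()
  for (i in seq_along(chars)) {
    ends <- rec(i, spec$n_tracts)
    if (length(ends)) iv[[length(iv) + 1L]] <- c(i, max(ends))
  }
  if (!length(iv)) return(list())
  iv <- iv[order(vapply(iv, `[`, integer(1L), 1L))]
  merged <- list(iv[[1L]])
  for (x in iv[-1L]) {
    last <- merged[[length(merged)]]
    if (x[1L] <= last[2L] + 1L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], x[2L]))
    } else {
      merged[[length(merged) + 1L]] <- x
    }
  }
  merged
}

# both strands: the C-version of the pattern on the forward strand is the
# G-version on the reverse strand
oracle_scan_both <- function(seq, spec) {
  g <- oracle_scan_g(seq, spec)
  comp <- chartr("ACGT", "TGCA", toupper(seq))
  c_runs <- oracle_scan_g(comp, spec)   # complement turns C runs into G runs
  list(plus = g, minus = c_runs)
}

random_dna <- function(len, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

granges_to_pairs <- function(gr, strand_filter = NULL) {
  if (!is.null(strand_filter)) {
    gr <- gr[as.character(GenomicRanges::strand(gr)) == strand_filter]
  }
  unname(lapply(seq_along(gr), function(i) {
    c(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
  }))
}

# the nine G-rich signatures of the deletions that deviate from the strict
# G4 signature, with the family each is stated to match
relaxed_signature_table <- function() {
  data.frame(
    signature = c("G_2NG_12",
                  "G_3NG_3NG_3N_2G_2",
                  "G_2NG_2NG_2NG_2NG_2NG_2NG_2NG_2NG_2",
                  "G_2N_3G_2N_5G_2N_2G_2",
                  "G_2NG_14NG_2",
                  "G_11",
                  "G_14",
                  "G_3NG_3NG_3N_5G_2NG_2NG_3",
                  "G_2NG_3N_6G_3"),
    family = c(rep("relaxed4", 8L), "relaxed3"),
    stringsAsFactors = FALSE)
}

expand_n <- function(sig) gsub("N", "T", sig, fixed = TRUE)
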