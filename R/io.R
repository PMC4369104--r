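#' Write motif sites as BED6+
#'
#' BED uses 0-based half-open coordinates; columns are contig, start, end,
#' name (the compact signature string), score (0), strand, and motif
#' class. [write_motifs_tsv()] writes the same records with 1-based
#' inclusive `start..end` coordinates for human-readable reports.
#'
#' @param sites A `GRanges` of motif sites (e.g. [annotate_motifs()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motifs_bed <- function(sites, path) {
  mc <- S4Vectors::mcols(sites)
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(sites)),
                   start = GenomicRanges::start(sites) - 1L,
                   end = GenomicRanges::end(sites),
                   name = if ("signature_string" %in% colnames(mc))
                     mc$signature_string else ".",
                   score = 0L,
                   strand = as.character(GenomicRanges::strand(sites)),
                   motif_class = if ("motif_class" %in% colnames(mc))
                     mc$motif_class else ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motifs_bed
#' @export
write_motifs_tsv <- function(sites, path) {
  mc <- S4Vectors::mcols(sites)
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(sites)),
                   locus = sprintf("%d..%d", GenomicRanges::start(sites),
                                   GenomicRanges::end(sites)),
                   strand = as.character(GenomicRanges::strand(sites)),
                   family = if ("family" %in% colnames(mc)) mc$family else ".",
                   motif_class = if ("motif_class" %in% colnames(mc))
                     mc$motif_class else ".",
                   signature = if ("signature_string" %in% colnames(mc))
                     mc$signature_string else ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Converts 0-based half-open BED records to a 1-based `GRanges`.
#'
#' @param path BED file (3+ columns; column 6 used as strand if present).
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  strand <- if (ncol(df) >= 6L) df[[6L]] else "*"
  gr <- GenomicRanges::GRanges(df[[1L]],
                               IRanges::IRanges(df[[2L]] + 1L, df[[3L]]),
                               strand = strand)
  if (ncol(df) >= 4L) S4Vectors::mcols(gr)$name <- df[[4L]]
  if (ncol(df) >= 7L) S4Vectors::mcols(gr)$motif_class <- df[[7L]]
  gr
}

#' Read and write variant-call tables
#'
#' The TSV dialect has exactly the columns of `VARIANT_COLUMNS` (header
#' required): `contig, pos, ref, alt, kind, size, depth, vf, bq,
#' support_a, internal_b, copy_number`, with `NA` for inapplicable fields.
#'
#' @param path File path.
#' @return `read_variant_table`: a variant-call data frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(contig = "character",
                                         ref = "character",
                                         alt = "character",
                                         kind = "character"))
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("variant table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df[, VARIANT_COLUMNS, drop = FALSE]
}

#' @rdname read_variant_table
#' @param calls A variant-call data frame.
#' @export
write_variant_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read small-variant calls from VCF
#'
#' Maps VCF 4.x records into the variant-call dialect: depth from the
#' `DP` field (genotype `DP` preferred, then INFO `DP`), variant frequency
#' from genotype `FREQ` (percent, VarScan-style) or `AF`/INFO `AF`, and
#' base quality from genotype `ABQ`, INFO `BQ`, or the record QUAL as a
#' fallback. SNVs become `SBS`; insertions and deletions up to 20 bp
#' become `INS`/`DEL_SMALL`, larger deletions `DEL_LARGE`.
#'
#' @param path Path to a VCF file.
#' @return A variant-call data frame.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altl), function(i) as.character(altl[[i]][1L]),
                character(1L))
  size <- abs(nchar(alt) - nchar(ref))
  kind <- ifelse(size == 0L, "SBS",
                 ifelse(nchar(alt) > nchar(ref), "INS",
                        ifelse(size <= 20L, "DEL_SMALL", "DEL_LARGE")))
  geno <- VariantAnnotation::geno(vcf)
  info <- VariantAnnotation::info(vcf)
  first_geno <- function(field) {
    if (field %in% names(geno)) as.vector(geno[[field]][, 1L]) else NULL
  }
  depth <- first_geno("DP")
  if (is.null(depth)) depth <- if ("DP" %in% names(info)) info$DP else NA_real_
  vf <- first_geno("FREQ")
  if (!is.null(vf)) {
    vf <- as.numeric(sub("%", "", vf, fixed = TRUE)) / 100
  } else {
    vf <- first_geno("AF")
    if (is.null(vf)) {
      vf <- if ("AF" %in% names(info)) as.numeric(sapply(info$AF, `[`, 1L))
            else NA_real_
    }
  }
  bq <- first_geno("ABQ")
  if (is.null(bq)) {
    bq <- if ("BQ" %in% names(info)) info$BQ
          else as.numeric(S4Vectors::mcols(rr)$QUAL)
  }
  variant_calls(as.character(GenomicRanges::seqnames(rr)),
                GenomicRanges::start(rr), ref, alt, kind, size,
                depth = as.numeric(depth), vf = vf, bq = as.numeric(bq))
}

#' Write a genome to FASTA
#'
#' @param genome A genome (see [as_genome()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}
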