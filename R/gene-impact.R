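#' Build a gene-model table
#'
#' Lightweight gene models: one row per gene with its span, plus exon and
#' CDS intervals. For the simple single-exon genes used throughout the
#' package the exon and CDS tables can equal the gene table.
#'
#' @param genes A data.frame with columns `gene_id`, `contig`, `strand`,
#'   `start`, `end`.
#' @param exons,cds Optional data.frames with columns `gene_id`, `contig`,
#'   `start`, `end` (CDS rows may carry `phase`); default to the gene
#'   spans.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons = NULL, cds = NULL) {
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (is.null(exons)) exons <- genes[, c("gene_id", "contig", "start", "end")]
  if (is.null(cds)) cds <- genes[, c("gene_id", "contig", "start", "end")]
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' Read gene models from GFF3
#'
#' Extracts `gene`, `exon` and `CDS` features from a GFF3 file. Exons and
#' CDS are assigned to genes through their `Parent`/`ID` chain when
#' present, falling back to coordinate containment.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gff <- rtracklayer::import(path, format = "gff3")
  gtab <- function(x, id) {
    data.frame(gene_id = id,
               contig = as.character(GenomicRanges::seqnames(x)),
               strand = as.character(GenomicRanges::strand(x)),
               start = GenomicRanges::start(x), end = GenomicRanges::end(x),
               stringsAsFactors = FALSE)
  }
  genes <- gff[gff$type == "gene"]
  gid <- if (!is.null(genes$ID)) as.character(genes$ID) else
    as.character(seq_along(genes))
  assign_gene <- function(x) {
    ov <- GenomicRanges::findOverlaps(x, genes, type = "within",
                                      select = "first", ignore.strand = TRUE)
    gid[ov]
  }
  exons <- gff[gff$type == "exon"]
  cds <- gff[gff$type == "CDS"]
  gene_models(gtab(genes, gid),
              exons = if (length(exons))
                gtab(exons, assign_gene(exons))[, -3L] else NULL,
              cds = if (length(cds))
                gtab(cds, assign_gene(cds))[, -3L] else NULL)
}

models_granges <- function(tab) {
  GenomicRanges::GRanges(tab$contig, IRanges::IRanges(tab$start, tab$end))
}

#' Genes affected by a variant set
#'
#' A gene counts as affected when any substitution or small InDel overlaps
#' one of its exons, or any large deletion or duplication overlaps its
#' span. Returns the distinct affected-gene set plus one impact record per
#' (variant, gene) overlap.
#'
#' @param variants A variant-call data frame.
#' @param models A [gene_models()] object.
#' @param genome Optional genome: when supplied, CDS-overlapping variants
#'   get a coding-effect label from [classify_cds_effect()].
#' @return A list with `genes` (character vector of affected gene ids) and
#'   `records` (data.frame: `key`, `gene_id`, `effect`).
#' @export
variants_affecting_genes <- function(variants, models, genome = NULL) {
  stopifnot(inherits(models, "gene_models"))
  empty <- data.frame(key = character(0), gene_id = character(0),
                      effect = character(0), stringsAsFactors = FALSE)
  if (!nrow(variants)) return(list(genes = character(0), records = empty))
  unmatched <- setdiff(unique(variants$contig), unique(models$genes$contig))
  if (length(unmatched) && !all(variants$contig %in% models$genes$contig)) {
    # contigs with variants but no annotated gene are fine; a full mismatch
    # indicates incompatible inputs
    if (!any(variants$contig %in% models$genes$contig)) {
      stop("no variant contig matches the gene models; unmatched: ",
           paste(unmatched, collapse = ", "))
    }
  }
  vgr <- GenomicRanges::GRanges(variants$contig,
                                IRanges::IRanges(variants$pos,
                                                 width = pmax(variants$size, 1L)))
  small <- variants$kind %in% c("SBS", "INS", "DEL_SMALL")
  targets_small <- models_granges(models$exons)
  targets_big <- models_granges(models$genes)
  recs <- list()
  hit_small <- GenomicRanges::findOverlaps(vgr[small], targets_small)
  if (length(hit_small)) {
    vi <- which(small)[S4Vectors::queryHits(hit_small)]
    recs$small <- data.frame(
      key = variant_key(variants)[vi],
      gene_id = models$exons$gene_id[S4Vectors::subjectHits(hit_small)],
      vidx = vi, stringsAsFactors = FALSE)
  }
  hit_big <- GenomicRanges::findOverlaps(vgr[!small], targets_big)
  if (length(hit_big)) {
    vi <- which(!small)[S4Vectors::queryHits(hit_big)]
    recs$big <- data.frame(
      key = variant_key(variants)[vi],
      gene_id = models$genes$gene_id[S4Vectors::subjectHits(hit_big)],
      vidx = vi, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) return(list(genes = character(0), records = empty))
  records <- records[!duplicated(records[, c("key", "gene_id")]), , drop = FALSE]
  records$effect <- vapply(seq_len(nrow(records)), function(r) {
    v <- variants[records$vidx[r], , drop = FALSE]
    impact_effect(v, records$gene_id[r], models, genome)
  }, character(1L))
  records$vidx <- NULL
  rownames(records) <- NULL
  list(genes = sort(unique(records$gene_id)), records = records)
}

impact_effect <- function(variant, gene_id, models, genome) {
  gene <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  if (variant$kind == "DUP") return("gene_duplicated")
  vstart <- variant$pos
  vend <- variant$pos + max(variant$size, 1L) - 1L
  if (variant$kind == "DEL_LARGE") {
    if (vstart <= gene$start && vend >= gene$end) return("gene_deleted")
  }
  cds <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  in_cds <- nrow(cds) && any(vstart <= cds$end & vend >= cds$start)
  if (!in_cds) return("non_coding")
  if (is.null(genome)) {
    return(switch(variant$kind,
                  SBS = "coding_sbs",
                  INS = , DEL_SMALL = if (variant$size %% 3L == 0L)
                    "inframe_indel" else "frameshift",
                  DEL_LARGE = "coding_deletion"))
  }
  classify_cds_effect(variant, gene_id, models, genome)
}

#' Coding effect of a variant on one gene
#'
#' Substitutions in CDS are translated on the coding strand with the
#' standard nuclear genetic code and labelled `synonymous`, `missense` or
#' `nonsense`; CDS InDels are `frameshift` when the size is not a multiple
#' of three, else `inframe_indel`; a deletion covering the whole gene span
#' is `gene_deleted`. A CDS whose total length is not divisible by three
#' is translated on its frame-complete prefix and the result flagged with
#' a trailing `*`.
#'
#' @param variant One row of a variant-call data frame.
#' @param gene_id The gene to assess.
#' @param models A [gene_models()] object.
#' @param genome The genome sequence.
#' @return An effect label.
#' @export
classify_cds_effect <- function(variant, gene_id, models, genome) {
  genome <- as_genome(genome)
  gene <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  stopifnot(nrow(gene) == 1L)
  vstart <- variant$pos
  vend <- variant$pos + max(variant$size, 1L) - 1L
  if (variant$kind == "DEL_LARGE") {
    if (vstart <= gene$start && vend >= gene$end) return("gene_deleted")
    return("coding_deletion")
  }
  if (variant$kind == "DUP") return("gene_duplicated")
  if (variant$kind %in% c("INS", "DEL_SMALL")) {
    return(if (variant$size %% 3L == 0L) "inframe_indel" else "frameshift")
  }
  # SBS: locate the codon on the coding strand
  cds <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  segs <- lapply(seq_len(nrow(cds)), function(i)
    contig_substring(genome, cds$contig[i], cds$start[i], cds$end[i]))
  coding <- paste0(unlist(segs), collapse = "")
  offs <- unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
  pos_in_cds <- match(vstart, offs)
  if (is.na(pos_in_cds)) return("non_coding")
  minus <- identical(gene$strand, "-")
  if (minus) {
    coding <- revcomp(coding)
    pos_in_cds <- nchar(coding) - pos_in_cds + 1L
  }
  flag <- ""
  usable <- nchar(coding) - nchar(coding) %% 3L
  if (nchar(coding) %% 3L != 0L) flag <- "*"  # incomplete CDS: prefix frame
  if (pos_in_cds > usable) return(paste0("coding_sbs", flag))
  alt_base <- if (minus) revcomp(variant$alt) else variant$alt
  codon_i <- (pos_in_cds - 1L) %/% 3L
  within <- (pos_in_cds - 1L) %% 3L + 1L
  codon <- substr(coding, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_base
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(alt_codon)))
  eff <- if (aa_alt == aa_ref) "synonymous"
         else if (aa_alt == "*") "nonsense"
         else "missense"
  paste0(eff, flag)
}
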