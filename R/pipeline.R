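CONFIG_DEFAULTS <- list(
  mode = "files",
  fasta = NULL,
  variant_tables = NULL,           # named list: generation -> TSV path
  background_tables = list(),      # list of TSV paths
  orthogonal_cnv_table = NULL,     # optional array-derived interval calls
  gff = NULL,                      # optional gene models
  generations = c(170, 270, 470),
  window = c(170, 470),
  thresholds = list(min_depth_exclusive = 5, max_depth = 200, min_vf = 0.9,
                    min_bq = 30, min_del_size = 20, min_mono_len = 15,
                    tolerance = 5, min_overlap_frac = 0.5,
                    require_orientation = TRUE,
                    cnv_reciprocal_overlap = 0.5,
                    generation_reciprocal_overlap = 0.9),
  denominators = list(genome_bases = "paper", n_genes = 20400,
                      n_g4_sites = "scan", n_generations = NULL),
  counts = NULL,                   # counts mode: printed numerators
  out_dir = NULL,
  seed = NULL
)

#' Validate a pipeline configuration
#'
#' Reads a JSON configuration (or takes an equivalent list), fills
#' defaults, and schema-checks it. Unknown keys are rejected, listing
#' every offending key; thresholds must be in range; the analysis window
#' endpoints must be ordered and among the provided generations.
#'
#' In `denominators`, `genome_bases` may be the string `"paper"` (use the
#' round 1e8 figure) or a number (`"measured"` behaviour is obtained by
#' omitting it in files mode, which substitutes the FASTA length);
#' `n_g4_sites` may be `"scan"` (count strict sites in the FASTA) or a
#' number; `n_generations` defaults to the window span.
#'
#' @param config Path to a JSON file, or a list.
#' @return A validated config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  merged <- CONFIG_DEFAULTS
  for (k in setdiff(names(config), c("thresholds", "denominators"))) {
    merged[[k]] <- config[[k]]
  }
  for (nested in c("thresholds", "denominators")) {
    bad <- setdiff(names(config[[nested]]), names(CONFIG_DEFAULTS[[nested]]))
    if (length(bad)) {
      stop("unknown config keys: ",
           paste(paste0(nested, ".", bad), collapse = ", "))
    }
    for (k in names(config[[nested]])) {
      merged[[nested]][[k]] <- config[[nested]][[k]]
    }
  }
  th <- merged$thresholds
  if (th$min_vf < 0 || th$min_vf > 1) stop("min_vf must be in [0, 1]")
  if (th$min_overlap_frac <= 0 || th$min_overlap_frac > 1) {
    stop("min_overlap_frac must be in (0, 1]")
  }
  if (length(merged$window) != 2L || merged$window[1L] >= merged$window[2L]) {
    stop("window must be two ascending generation numbers")
  }
  if (!all(merged$window %in% merged$generations)) {
    stop("window endpoints must be among the provided generations")
  }
  if (!identical(merged$mode, "counts")) {
    for (p in c(merged$fasta, unlist(merged$variant_tables),
                unlist(merged$background_tables), merged$orthogonal_cnv_table,
                merged$gff)) {
      if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
    }
  }
  if (is.null(merged$denominators$n_generations)) {
    merged$denominators$n_generations <- diff(merged$window)
  }
  structure(merged, class = c("run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — motif annotation, per-generation variant
#' filtering, background subtraction, accumulation matrix, deletion
#' classification, deleted-tract census, rate estimation and mutation
#' spectrum — writing every intermediate table plus a JSON report to
#' `out_dir` (when set), so each reported number can be recomputed from
#' the staged files. Identical inputs and config produce an identical
#' report.
#'
#' In `counts` mode the pipeline skips the data stages and evaluates the
#' rate estimators directly on numerators supplied in `config$counts`
#' (fields `n_sbs`, `n_indel`, `n_del_genes_hit`, `n_del_g4`,
#' `n_dup_genes_hit`, `n_del_total`, optional `n_tstv_transitions` /
#' `n_tstv_transversions`), reproducing a printed-rate analysis.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @return A `run_report` list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  echo <- unclass(config)
  echo$out_dir <- NULL               # analytic config only: keeps reports
                                     # identical wherever they are written
  report <- list(config = echo,
                 package_version = as.character(utils::packageVersion("quadtractMA")))
  if (identical(config$mode, "counts")) {
    report$rates <- rates_from_counts(config$counts, config$denominators)
    report <- finish_report(report, out_dir)
    return(report)
  }
  th <- config$thresholds
  # stage 1: genome + motif annotation
  genome <- read_genome(config$fasta)
  stage_log("genome", "%d contig(s), %d bases", length(genome),
            sum(Biostrings::width(genome)))
  annotation <- annotate_motifs(genome, th$min_mono_len)
  strict <- annotation[S4Vectors::mcols(annotation)$family == "strict"]
  n_strict_sites <- length(merge_sites_across_strands(strict))
  mono <- find_mono_gc_tracts(genome, th$min_mono_len)
  stage_log("motif_scan", "%d annotated motifs, %d strict sites, %d monoG/C tracts",
            length(annotation), n_strict_sites, length(mono))
  if (!is.null(out_dir)) {
    write_motifs_bed(annotation, file.path(out_dir, "motifs.bed"))
    write_motifs_tsv(annotation, file.path(out_dir, "motifs.tsv"))
  }
  # stage 2: per-generation filtering + background subtraction
  backgrounds <- lapply(config$background_tables, read_variant_table)
  gen_sets <- list()
  for (g in as.character(config$generations)) {
    calls <- read_variant_table(config$variant_tables[[g]])
    small <- filter_small_variants(
      calls[calls$kind %in% c("SBS", "INS", "DEL_SMALL"), , drop = FALSE],
      th$min_depth_exclusive, th$max_depth, th$min_vf, th$min_bq)
    dels <- select_homozygous_deletions(
      calls[calls$kind == "DEL_LARGE", , drop = FALSE], th$min_del_size)
    dels$hom_stat <- NULL
    dups <- calls[calls$kind == "DUP", , drop = FALSE]
    kept <- subtract_background(rbind(small, dels, dups), backgrounds)
    stage_log("filter", "F%s: %d calls in, %d fixed homozygous kept",
              g, nrow(calls), nrow(kept))
    if (!is.null(out_dir)) {
      write_variant_table(kept, file.path(out_dir,
                                          sprintf("filtered_F%s.tsv", g)))
    }
    gen_sets[[g]] <- kept
  }
  # stage 3: accumulation matrix
  acc <- accumulation_matrix(gen_sets,
                             min_reciprocal_overlap = th$generation_reciprocal_overlap)
  stage_log("accumulate", "window totals: %s",
            paste(names(acc$window_total), acc$window_total, sep = "=",
                  collapse = ", "))
  # stage 4: window variant set (new within the window)
  win <- as.character(config$window)
  win_set <- window_new_variants(gen_sets, config$window,
                                 th$generation_reciprocal_overlap)
  dels_win <- win_set[win_set$kind == "DEL_LARGE", , drop = FALSE]
  if (!is.null(config$orthogonal_cnv_table)) {
    ortho <- read_variant_table(config$orthogonal_cnv_table)
    dels_win <- merge_cnv_evidence(dels_win, ortho, th$cnv_reciprocal_overlap)
    stage_log("cnv_merge", "%d deletions after orthogonal-evidence merge",
              nrow(dels_win))
  }
  # stage 5: deletion classification + census
  classified <- classify_deletions(dels_win, annotation, genome,
                                   th$tolerance, th$require_orientation)
  summ <- classification_summary(classified)
  census <- if (length(mono)) deleted_tract_census(mono, dels_win,
                                                   th$min_overlap_frac)
            else list(n_deleted = 0L, n_total = 0L, fraction = NA_real_)
  census$deleted <- NULL
  stage_log("classify", "%d/%d deletions G-rich; %d/%d monoG/C tracts deleted",
            summ$n_g_rich, summ$n_total, census$n_deleted, census$n_total)
  if (!is.null(out_dir)) {
    write_variant_table(classified, file.path(out_dir,
                                              "deletions_classified.tsv"))
  }
  # stage 6: rates + spectrum
  dn <- config$denominators
  genome_bases <- if (identical(dn$genome_bases, "paper")) 1e8
                  else if (is.null(dn$genome_bases))
                    sum(Biostrings::width(genome))
                  else as.numeric(dn$genome_bases)
  n_g4 <- if (identical(dn$n_g4_sites, "scan")) n_strict_sites
          else as.numeric(dn$n_g4_sites)
  denom <- rate_denominators(genome_bases, as.numeric(dn$n_genes),
                             max(n_g4, 1L), as.numeric(dn$n_generations))
  sbs_win <- win_set[win_set$kind == "SBS", , drop = FALSE]
  n_indel <- sum(win_set$kind %in% c("INS", "DEL_SMALL"))
  spectrum <- mutation_spectrum(sbs_win, genome,
                                n_generations = denom$n_generations)
  rates <- list(
    sbs_per_base = per_base_rate(nrow(sbs_win), denom),
    indel_per_base = per_base_rate(n_indel, denom),
    deletion_per_g4_site = per_site_rate(summ$n_g_rich, denom = denom),
    indel_sbs = indel_sbs_ratio(n_indel, nrow(sbs_win)),
    tstv = tstv_ratio(sbs_win))
  report$accumulation <- list(new = acc$new, reversions = acc$reversions,
                              window_total = acc$window_total)
  report$classification <- summ
  report$census <- census
  report$rates <- rates
  report$spectrum <- spectrum
  report$sites <- list(n_strict_sites = n_strict_sites,
                       n_mono_tracts = length(mono),
                       n_motifs_annotated = length(annotation))
  # stage 7: optional gene impact
  if (!is.null(config$gff)) {
    models <- read_gene_models(config$gff)
    impact <- variants_affecting_genes(win_set, models, genome)
    report$gene_impact <- list(n_genes_affected = length(impact$genes),
                               genes = impact$genes)
    del_genes <- unique(impact$records$gene_id[grepl(":DEL_LARGE$",
                                                     impact$records$key)])
    report$rates$deletion_per_gene <- per_gene_rate(length(del_genes), denom)
    if (!is.null(out_dir)) {
      write_variant_table(impact$records, file.path(out_dir, "gene_impact.tsv"))
    }
  }
  report$provenance <- list(
    inputs = tools::md5sum(c(config$fasta, unlist(config$variant_tables))))
  finish_report(report, out_dir)
}

# variants first seen strictly after window[1], present by window[2]
window_new_variants <- function(gen_sets, window, recip = 0.9) {
  gens <- as.numeric(names(gen_sets))
  base_idx <- which(gens <= window[1L])
  end_idx <- which(gens == window[2L])
  stopifnot(length(end_idx) == 1L)
  final <- gen_sets[[end_idx]]
  keys <- variant_key(final)
  seen <- character(0)
  for (i in base_idx) {
    prior <- gen_sets[[i]]
    pk <- variant_key(prior)
    # interval events in the base set claim matching final events
    big <- which(final$kind %in% c("DEL_LARGE", "DUP"))
    if (length(big) && nrow(prior)) {
      m <- match_by_reciprocal_overlap(final[big, , drop = FALSE],
                                       prior[prior$kind %in% c("DEL_LARGE", "DUP"), ,
                                             drop = FALSE], recip)
      seen <- c(seen, keys[big][!is.na(m)])
    }
    seen <- c(seen, intersect(keys, pk))
  }
  final[!keys %in% seen, , drop = FALSE]
}

rates_from_counts <- function(counts, dn) {
  stopifnot(is.list(counts))
  genome_bases <- if (is.null(dn$genome_bases) ||
                        identical(dn$genome_bases, "paper")) 1e8
                  else as.numeric(dn$genome_bases)
  n_g4 <- if (identical(dn$n_g4_sites, "scan") || is.null(dn$n_g4_sites)) 2372
          else as.numeric(dn$n_g4_sites)
  denom <- rate_denominators(genome_bases, as.numeric(dn$n_genes %||% 20400),
                             n_g4, as.numeric(dn$n_generations %||% 300))
  out <- list()
  if (!is.null(counts$n_sbs)) out$sbs_per_base <- per_base_rate(counts$n_sbs, denom)
  if (!is.null(counts$n_indel)) {
    out$indel_per_base <- per_base_rate(counts$n_indel, denom)
    if (!is.null(counts$n_sbs)) {
      out$indel_sbs <- indel_sbs_ratio(counts$n_indel, counts$n_sbs)
    }
  }
  if (!is.null(counts$n_del_genes_hit)) {
    out$deletion_per_gene <- per_gene_rate(counts$n_del_genes_hit, denom)
  }
  if (!is.null(counts$n_del_g4)) {
    out$deletion_per_g4_site <- per_site_rate(counts$n_del_g4, denom = denom)
    if (!is.null(counts$n_del_total)) {
      out$fraction_g_rich <- counts$n_del_g4 / counts$n_del_total
    }
  }
  if (!is.null(counts$n_dup_genes_hit)) {
    out$duplication_per_gene <- per_gene_rate(counts$n_dup_genes_hit, denom)
  }
  if (!is.null(counts$n_tstv_transitions) &&
        !is.null(counts$n_tstv_transversions)) {
    out$tstv <- counts$n_tstv_transitions / counts$n_tstv_transversions
  }
  out
}

finish_report <- function(report, out_dir) {
  class(report) <- c("run_report", "list")
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  report
}

# strip S4/complex members down to JSON-representable values
report_to_json <- function(x) {
  simplify <- function(v) {
    if (inherits(v, "rate_estimate")) {
      list(numerator = v$numerator, denominator = v$denominator,
           rate = v$rate, display = v$display)
    } else if (inherits(v, "table")) {
      as.list(stats::setNames(as.integer(v), names(v)))
    } else if (is.matrix(v)) {
      apply(v, 1L, identity, simplify = FALSE)
    } else if (is.list(v)) {
      lapply(v, simplify)
    } else if (is.function(v) || methods::is(v, "GRanges")) {
      NULL
    } else v
  }
  simplify(x)
}

#' @export
print.run_report <- function(x, ...) {
  cat("quadtractMA run report\n")
  if (!is.null(x$accumulation)) {
    cat("\nNew variants per generation:\n")
    print(x$accumulation$new)
  }
  if (!is.null(x$classification)) {
    cat(sprintf("\nDeletions: %d total, %d G-rich (%.1f%%)\n",
                x$classification$n_total, x$classification$n_g_rich,
                100 * x$classification$fraction_g_rich))
  }
  if (!is.null(x$census) && !is.null(x$census$n_total)) {
    cat(sprintf("monoG/C tracts deleted: %d of %d (%.1f%%)\n",
                x$census$n_deleted, x$census$n_total,
                100 * x$census$fraction))
  }
  if (!is.null(x$rates)) {
    cat("\nRates:\n")
    for (nm in names(x$rates)) {
      v <- x$rates[[nm]]
      if (inherits(v, "rate_estimate")) {
        cat(sprintf("  %-22s %s\n", nm, v$display))
      } else if (is.numeric(v)) {
        cat(sprintf("  %-22s %s\n", nm, format(signif(v, 2L))))
      } else if (is.list(v)) {
        cat(sprintf("  %-22s ratio %s, %s substitutions per InDel\n", nm,
                    format(signif(v$ratio, 2L)),
                    format(signif(v$substitutions_per_indel, 2L))))
      }
    }
  }
  invisible(x)
}
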