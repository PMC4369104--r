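#' Rate denominators
#'
#' Bundles the denominators of the per-generation mutation-rate
#' estimators: total genome size in bases, number of protein-coding genes,
#' number of G4-signature sites, and the number of generations in the
#' observation window. The defaults are the round figures conventionally
#' used for the C. elegans genome (1e8 bases, 20,400 protein-coding genes)
#' with a 300-generation window; `n_g4_sites` defaults to the
#' strict-signature site count of the reference genome.
#'
#' @param genome_bases,n_genes,n_g4_sites,n_generations Positive counts.
#' @return An object of class `rate_denominators`.
#' @export
rate_denominators <- function(genome_bases = 1e8, n_genes = 20400,
                              n_g4_sites = 2372, n_generations = 300) {
  vals <- c(genome_bases = genome_bases, n_genes = n_genes,
            n_g4_sites = n_g4_sites, n_generations = n_generations)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("rate denominators must all be positive: ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  }
  structure(as.list(vals), class = "rate_denominators")
}

new_rate_estimate <- function(numerator, denominator, kind, unit,
                              n_generations) {
  rate <- numerator / (denominator * n_generations)
  structure(list(numerator = numerator, denominator = denominator,
                 denominator_kind = kind, n_generations = n_generations,
                 rate = rate, unit = unit,
                 display = format_rate(rate, unit)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s  [%d / (%s x %s generations)]\n", x$display,
              x$numerator, format(x$denominator, big.mark = ","),
              format(x$n_generations)), sep = "")
  invisible(x)
}

#' Format a per-generation rate at two significant figures
#'
#' Rounds to two significant figures (round-half-even, via [signif()]) and
#' renders in scientific notation, e.g. `"3.1 x 10^-9 /base/generation"`.
#' Zero formats as `"0"`.
#'
#' @param rate A non-negative rate.
#' @param unit Optional unit suffix such as `"/base/generation"`.
#' @param digits Significant figures (default 2).
#' @return A character scalar.
#' @export
format_rate <- function(rate, unit = "", digits = 2L) {
  if (is.na(rate)) return(NA_character_)
  if (rate == 0) return(paste0("0", unit))
  r <- signif(rate, digits)
  expo <- floor(log10(abs(r)))
  mant <- r / 10^expo
  paste0(format(signif(mant, digits)), " x 10^", expo, unit)
}

#' Per-base mutation rate
#'
#' `n / (genome_bases x n_generations)`: the estimator behind the base
#' substitution rate (94 substitutions over 1e8 bases and 300 generations
#' gives 3.1 x 10^-9 /base/generation) and the small-InDel rate.
#'
#' @param n Event count over the window.
#' @param denom A [rate_denominators()].
#' @return A `rate_estimate`.
#' @export
per_base_rate <- function(n, denom = rate_denominators()) {
  stopifnot(n >= 0)
  new_rate_estimate(n, denom$genome_bases, "per_base", "/base/generation",
                    denom$n_generations)
}

#' Per-gene mutation rate
#'
#' `n_genes_hit / (n_genes x n_generations)`, e.g. 19 genes affected by
#' deletions over 20,400 genes and 300 generations gives
#' 3.1 x 10^-6 /gene/generation.
#'
#' @param n_genes_hit Number of genes affected over the window.
#' @inheritParams per_base_rate
#' @return A `rate_estimate`.
#' @export
per_gene_rate <- function(n_genes_hit, denom = rate_denominators()) {
  stopifnot(n_genes_hit >= 0)
  new_rate_estimate(n_genes_hit, denom$n_genes, "per_gene",
                    "/gene/generation", denom$n_generations)
}

#' Per-G4-site mutation rate
#'
#' `n_events / (n_sites x n_generations)`, e.g. 123 G-rich-initiated
#' deletions over 2,372 strict-signature sites and 300 generations gives
#' 1.7 x 10^-4 /site/generation.
#'
#' @param n_events Event count over the window.
#' @param n_sites Number of target sites; defaults to the denominator
#'   bundle's `n_g4_sites`.
#' @inheritParams per_base_rate
#' @return A `rate_estimate`.
#' @export
per_site_rate <- function(n_events, n_sites = NULL,
                          denom = rate_denominators()) {
  stopifnot(n_events >= 0)
  if (is.null(n_sites)) n_sites <- denom$n_g4_sites
  stopifnot(n_sites > 0)
  new_rate_estimate(n_events, n_sites, "per_site", "/site/generation",
                    denom$n_generations)
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

check_sbs_alleles <- function(sbs) {
  ok <- sbs$ref %in% c("A", "C", "G", "T") & sbs$alt %in% c("A", "C", "G", "T") &
    sbs$ref != sbs$alt
  if (any(!ok)) {
    i <- which(!ok)[1L]
    stop("invalid SBS allele pair in record ", i, ": ",
         sbs$ref[i], ">", sbs$alt[i], " at ", sbs$contig[i], ":", sbs$pos[i])
  }
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; all other substitutions are
#' transversions. With zero transversions the ratio is undefined and `NA`
#' is returned (small sets can legitimately contain no transversions).
#'
#' @param sbs A variant-call data frame of substitutions (`ref`, `alt`).
#' @return The ratio, or `NA` when undefined.
#' @export
tstv_ratio <- function(sbs) {
  if (!nrow(sbs)) return(NA_real_)
  check_sbs_alleles(sbs)
  ts <- sum(paste0(sbs$ref, ">", sbs$alt) %in% TRANSITIONS)
  tv <- nrow(sbs) - ts
  if (tv == 0L) return(NA_real_)
  ts / tv
}

SPECTRUM_CLASSES <- c("A:T>T:A", "A:T>C:G", "A:T>G:C",
                      "G:C>A:T", "G:C>T:A", "G:C>C:G")

#' Strand-collapsed mutation spectrum
#'
#' Collapses each substitution and its reverse complement into one of the
#' six pyrimidine/purine pair classes (`A:T>G:C` etc.) and tabulates
#' counts, transitions and transversions. When a genome is supplied,
#' per-class per-base rates are added using the genome's A:T versus G:C
#' base content as class-specific denominators.
#'
#' @param sbs A variant-call data frame of substitutions.
#' @param genome Optional genome for base-content-normalised rates.
#' @param n_generations Generations for the optional rates.
#' @return A list with `counts` (named by the six classes), `transitions`,
#'   `transversions`, `tstv`, and optionally `per_base_rates`.
#' @export
mutation_spectrum <- function(sbs, genome = NULL, n_generations = 300) {
  counts <- stats::setNames(integer(length(SPECTRUM_CLASSES)),
                            SPECTRUM_CLASSES)
  if (nrow(sbs)) {
    check_sbs_alleles(sbs)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- sbs$ref
    alt <- sbs$alt
    flip <- ref %in% c("T", "C")   # collapse onto the A/G reference strand
    ref[flip] <- comp[sbs$ref[flip]]
    alt[flip] <- comp[sbs$alt[flip]]
    lab <- ifelse(ref == "A",
                  paste0("A:T>", alt, ":", comp[alt]),
                  paste0("G:C>", alt, ":", comp[alt]))
    tab <- table(factor(lab, levels = SPECTRUM_CLASSES))
    counts[] <- as.integer(tab)
  }
  ts <- counts[["A:T>G:C"]] + counts[["G:C>A:T"]]
  tv <- sum(counts) - ts
  out <- list(counts = counts, transitions = ts, transversions = tv,
              tstv = if (tv > 0L) ts / tv else NA_real_)
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    freq <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"),
                                                          drop = FALSE])
    at <- freq[["A"]] + freq[["T"]]
    gc <- freq[["G"]] + freq[["C"]]
    base_denoms <- ifelse(startsWith(SPECTRUM_CLASSES, "A:T"), at, gc)
    out$per_base_rates <- counts / (base_denoms * n_generations)
  }
  out
}

#' InDel to substitution ratio
#'
#' @param n_indel,n_sbs Event counts over the same window.
#' @return A list with `ratio` (`n_indel / n_sbs`) and
#'   `substitutions_per_indel` (`n_sbs / n_indel`, `NA` when no InDels).
#' @export
indel_sbs_ratio <- function(n_indel, n_sbs) {
  stopifnot(n_indel >= 0, n_sbs >= 0)
  list(ratio = if (n_sbs > 0) n_indel / n_sbs else NA_real_,
       substitutions_per_indel = if (n_indel > 0) n_sbs / n_indel else NA_real_)
}
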