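#' Load a genome from FASTA
#'
#' Reads a (multi-contig) FASTA file into a `DNAStringSet`, uppercasing the
#' sequence. Contig ids are taken as the first whitespace-delimited token of
#' each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per contig.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna))) {
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "))
  }
  if (any(Biostrings::width(dna) == 0L)) stop("empty contig sequence in ", path)
  as_genome(dna)
}

#' Coerce to a genome object
#'
#' Accepts a `DNAStringSet`, a named character vector of sequences, or a
#' single unnamed string (given the contig id `"seq"`). Sequences are
#' uppercase-normalised and checked against the alphabet \{A,C,G,T,N\}.
#'
#' @param x Sequence input.
#' @return A [Biostrings::DNAStringSet].
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    dna <- x
  } else if (is.character(x)) {
    if (is.null(names(x))) {
      names(x) <- if (length(x) == 1L) "seq" else paste0("seq", seq_along(x))
    }
    dna <- Biostrings::DNAStringSet(toupper(x))
  } else {
    stop("cannot interpret object of class ", class(x)[1L], " as a genome")
  }
  bad <- grepl("[^ACGTN]", as.character(dna))
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: contig ",
         names(dna)[which(bad)[1L]])
  }
  dna
}

# character vector of one contig's bases
contig_chars <- function(genome, contig) {
  strsplit(as.character(genome[[contig]]), "", fixed = TRUE)[[1L]]
}

# genomic subsequence as a string, 1-based inclusive
contig_substring <- function(genome, contig, start, end) {
  w <- length(genome[[contig]])
  if (start < 1L || end > w || end < start) {
    stop("coordinates ", start, "..", end, " outside contig ", contig,
         " (length ", w, ")")
  }
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
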