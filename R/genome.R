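#' Genome sequence container
#'
#' A genome is stored as a named character vector of uppercase chromosome
#' sequences over the alphabet \{A, C, G, T, N\}. All coordinates used by
#' this package are 0-based half-open (`[start, end)`), the BED convention;
#' 1-based formats (GFF3, FASTA-relative positions) are converted at the
#' boundary.
#'
#' @param sequences named character vector of chromosome sequences.
#' @return An object of class `g4_genome`.
#' @export
g4_genome <- function(sequences) {
  if (length(sequences) == 0L) stop_g4("genome has no chromosomes")
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop_g4("chromosome names must be present and unique")
  }
  sequences <- toupper(sequences)
  bad <- gsub("[ACGTN]", "", sequences)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0L) {
    g4_log("mapped %d non-ACGTN character(s) to N", n_bad)
    sequences <- vapply(sequences, function(s) gsub("[^ACGTN]", "N", s), "")
    names(sequences) <- nm
  }
  structure(
    list(seq = sequences,
         lengths = setNames(nchar(sequences), nm),
         n_substituted = n_bad),
    class = "g4_genome")
}

#' @export
print.g4_genome <- function(x, ...) {
  cat(sprintf("g4_genome: %d chromosome(s), %s bp total\n",
              length(x$seq), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and any character outside \{A, C, G, T, N\} is
#' replaced by N (the substitution count is logged). Header lines are
#' truncated at the first whitespace, the usual FASTA convention.
#'
#' @param path path to a (multi-)FASTA file.
#' @return A [g4_genome()] object.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop_g4("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop_g4("duplicate FASTA header(s): %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- as.character(ss)
  names(seqs) <- nm
  g4_genome(seqs)
}

#' Total genome size in bp
#' @param genome a [g4_genome()].
#' @export
genome_size <- function(genome) sum(genome$lengths)

#' Extract reference-strand sequence of an interval
#' @param genome a [g4_genome()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  check_bounds(genome, chrom, start, end)
  substring(genome$seq[[chrom]], start + 1L, end)
}

check_bounds <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seq)) {
    stop_g4("chromosome '%s' not in genome (have: %s)",
            chrom, paste(names(genome$seq), collapse = ", "))
  }
  L <- genome$lengths[[chrom]]
  if (any(start < 0L) || any(end > L) || any(start >= end)) {
    stop_g4("interval out of bounds on %s (length %d)", chrom, L)
  }
  invisible(TRUE)
}

#' Reverse-complement every chromosome of a genome
#'
#' Used by the strand-symmetry checks: scanning the reverse complement must
#' give the same motifs with strands swapped and coordinates mirrored.
#' @param genome a [g4_genome()].
#' @export
revcomp_genome <- function(genome) {
  rc <- vapply(genome$seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "")
  g4_genome(rc)
}

#' Write a genome to FASTA
#' @param genome a [g4_genome()].
#' @param path output path.
#' @param width line width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
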