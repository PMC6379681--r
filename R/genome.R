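#' Genome sequence container
#'
#' A minimal single-contig genome model (bacterial chromosome): one named
#' sequence over the alphabet `A,C,G,T,N`, optionally circular. All public
#' coordinates in this package are 0-based, half-open; WIG output is 1-based.
#'
#' @param sequence Character scalar, the genome sequence (case-insensitive).
#' @param contig_id Name of the contig (default `"chr"`).
#' @param circular Logical; circular chromosome (default `TRUE`).
#' @return An object of class `genome_seq` with fields `contig_id`, `length`,
#'   `circular` and `sequence`.
#' @examples
#' g <- genome_seq("ACGTACGT", circular = TRUE)
#' g$length
#' @export
genome_seq <- function(sequence, contig_id = "chr", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("genome sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  structure(
    list(contig_id = as.character(contig_id),
         length = nchar(sequence),
         circular = isTRUE(circular),
         sequence = sequence),
    class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("genome_seq: %s, %d bp, %s\n", x$contig_id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-contig genome from a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @param circular Logical, whether to treat the chromosome as circular.
#' @return A [genome_seq] object.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-contig FASTA, found ", length(ss), " records")
  id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  genome_seq(as.character(ss[[1]]), contig_id = id, circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_seq].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$contig_id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract a (possibly origin-wrapping) subsequence
#'
#' @param genome A [genome_seq].
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; `end > start`. On a circular genome
#'   coordinates may run past either boundary and are wrapped.
#' @return Character scalar of length `end - start`.
#' @export
genome_subseq <- function(genome, start, end) {
  stopifnot(end > start)
  L <- genome$length
  if (start >= 0 && end <= L) {
    return(substr(genome$sequence, start + 1L, end))
  }
  if (!genome$circular)
    stop("subsequence [", start, ",", end, ") outside linear genome of length ", L)
  if (end - start > L) stop("subsequence longer than the circular genome")
  idx <- ((seq.int(start, end - 1L)) %% L) + 1L
  # at most one wrap point: two substr calls
  brk <- which(diff(idx) != 1L)
  if (length(brk) == 0L) return(substr(genome$sequence, idx[1], idx[length(idx)]))
  paste0(substr(genome$sequence, idx[1], L),
         substr(genome$sequence, 1L, idx[length(idx)]))
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
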