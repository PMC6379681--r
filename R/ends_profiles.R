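#' Per-position fragment end-count profiles
#'
#' The measurement underlying single-nucleotide cleavage mapping: for every
#' genome position, how many aligned fragments have their 3' end (N3E) or
#' 5' end (N5E) there, split by alignment orientation. A gyrase cleavage
#' complex pins fragment 3' ends at the two walls of the 4-bp gap, so N3E
#' carries the signal; N5E varies with sonication.
#'
#' @name end_profile
NULL

new_end_profile <- function(n3e_f, n3e_r, n5e_f, n5e_r, total, genome_length) {
  structure(
    list(n3e_forward = n3e_f, n3e_reverse = n3e_r,
         n5e_forward = n5e_f, n5e_reverse = n5e_r,
         total_fragments = total, genome_length = genome_length),
    class = "end_profile")
}

#' @export
print.end_profile <- function(x, ...) {
  cat(sprintf("end_profile: %d bp, %s fragments\n", x$genome_length,
              format(x$total_fragments)))
  invisible(x)
}

#' Validate an aligned-fragment table
#'
#' Fragments are 0-based half-open intervals with an orientation. On a
#' circular genome `end` may exceed the genome length (origin-spanning
#' fragment, wrapped at counting time); on a linear genome such fragments are
#' rejected.
#'
#' @param fragments `data.frame` with columns `start`, `end`, `orientation`
#'   (`"forward"`/`"reverse"`); an optional `contig` column is checked against
#'   the genome.
#' @param genome A [genome_seq].
#' @return List with elements `accepted` (the valid rows) and `rejected`.
#' @keywords internal
validate_fragments <- function(fragments, genome) {
  stopifnot(is.data.frame(fragments),
            all(c("start", "end", "orientation") %in% names(fragments)))
  if (nrow(fragments) == 0L) {
    return(list(accepted = fragments, rejected = fragments[0, ]))
  }
  if (!all(fragments$orientation %in% c("forward", "reverse")))
    stop("orientation must be 'forward' or 'reverse'")
  L <- genome$length
  ok <- fragments$start >= 0 & fragments$end > fragments$start
  if (genome$circular) {
    ok <- ok & fragments$start < L & (fragments$end - fragments$start) <= L
  } else {
    ok <- ok & fragments$end <= L
  }
  if ("contig" %in% names(fragments))
    ok <- ok & fragments$contig == genome$contig_id
  list(accepted = fragments[ok, , drop = FALSE],
       rejected = fragments[!ok, , drop = FALSE])
}

#' Count fragment 3'- and 5'-ends per genome position
#'
#' For a forward fragment `[s, e)` the 3' end sits at `e - 1` and the 5' end
#' at `s`; a reverse fragment mirrors this (3' end at `s`, 5' end at `e - 1`).
#' Circular genomes wrap coordinates; on a linear genome out-of-range
#' fragments are dropped and reported via the `rejects` attribute.
#'
#' @param fragments Fragment table (see [validate_fragments]).
#' @param genome A [genome_seq].
#' @return An `end_profile` whose four count vectors each have
#'   `genome$length` entries; the sum of 3'-end counts over both strands
#'   equals `total_fragments` (same for 5').
#' @examples
#' g <- genome_seq(strrep("A", 100))
#' fr <- data.frame(start = 10, end = 20, orientation = "forward")
#' p <- count_read_ends(fr, g)
#' which(p$n3e_forward > 0) - 1  # 0-based position 19
#' @export
count_read_ends <- function(fragments, genome) {
  v <- validate_fragments(fragments, genome)
  fr <- v$accepted
  L <- genome$length
  wrap <- function(pos0) (pos0 %% L) + 1L  # 0-based coord -> 1-based index
  fwd <- fr$orientation == "forward"
  p3 <- integer(0); p5 <- integer(0)
  # 1-based indices of 3' / 5' ends, split by strand
  i3f <- wrap(fr$end[fwd] - 1); i5f <- wrap(fr$start[fwd])
  i3r <- wrap(fr$start[!fwd]);  i5r <- wrap(fr$end[!fwd] - 1)
  prof <- new_end_profile(
    tabulate(i3f, nbins = L), tabulate(i3r, nbins = L),
    tabulate(i5f, nbins = L), tabulate(i5r, nbins = L),
    nrow(fr), L)
  attr(prof, "rejects") <- v$rejected
  if (nrow(v$rejected) > 0L)
    warning(nrow(v$rejected), " fragment(s) outside the genome were rejected")
  prof
}

#' Combined (forward + reverse) 3'-end track
#'
#' The paired-wall caller operates by default on the strand-summed N3E
#' track; its genome-wide sum equals the fragment count.
#'
#' @param profile An `end_profile`.
#' @return Integer (or numeric, after scaling) vector of genome length.
#' @export
combined_n3e <- function(profile) {
  profile$n3e_forward + profile$n3e_reverse
}

#' Read aligned fragments from a SAM/BAM file
#'
#' Each mapped read contributes its own aligned interval (the single-strand
#' library sequences each strand independently, so mates are not collapsed);
#' duplicates are kept on purpose, since signal height is the measurement.
#' Reads under the mapping-quality threshold are discarded.
#'
#' @param path SAM or BAM file.
#' @param genome A [genome_seq] (used to check the contig and length).
#' @param min_mapq Minimum mapping quality (default 20).
#' @return Fragment `data.frame` with columns `contig`, `start`, `end`
#'   (0-based half-open) and `orientation`.
#' @export
read_fragments_sam <- function(path, genome, min_mapq = 20) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(mapqFilter = min_mapq))
  if (length(ga) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), orientation = character()))
  }
  data.frame(
    contig = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    orientation = ifelse(as.character(GenomicAlignments::strand(ga)) == "-",
                         "reverse", "forward"))
}

#' Read aligned fragments from a plain TSV
#'
#' Column layout `contig, start, end, orientation` with a header line;
#' the simulator's native interchange format (lossless for origin-spanning
#' fragments, which SAM cannot represent).
#'
#' @param path TSV file.
#' @return Fragment `data.frame`.
#' @export
read_fragments_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "integer", "character"))
}

#' Write a per-position track as WIG or bedGraph
#'
#' WIG is fixedStep (step 1, span 1, 1-based start); bedGraph rows are
#' 0-based half-open with runs of equal value collapsed. Reading the file
#' back (e.g. with `rtracklayer`) returns the identical per-base values.
#'
#' @param values Numeric vector of genome length.
#' @param genome A [genome_seq].
#' @param path Output file.
#' @param format `"wig"` or `"bedgraph"`.
#' @param name Track name written in the header line.
#' @return Invisibly, `path`.
#' @export
write_track <- function(values, genome, path, format = c("wig", "bedgraph"),
                        name = "gyraseq") {
  format <- match.arg(format)
  if (length(values) == 0L) stop("empty track")
  if (length(values) != genome$length)
    stop("track length ", length(values), " != genome length ", genome$length)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "wig") {
    writeLines(c(sprintf("track type=wiggle_0 name=\"%s\"", name),
                 sprintf("fixedStep chrom=%s start=1 step=1 span=1",
                         genome$contig_id),
                 format(values, trim = TRUE, scientific = FALSE, digits = 15)),
               con)
  } else {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
    r <- rle(values)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%s", genome$contig_id, s, e,
                       format(r$values, trim = TRUE, scientific = FALSE,
                              digits = 15)),
               con)
  }
  invisible(path)
}

#' Write the raw end-count table
#'
#' TSV of `position` (0-based), `n3e_forward`, `n3e_reverse`, `n5e_forward`,
#' `n5e_reverse`.
#'
#' @param profile An `end_profile`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(position = seq_len(profile$genome_length) - 1L,
                   n3e_forward = profile$n3e_forward,
                   n3e_reverse = profile$n3e_reverse,
                   n5e_forward = profile$n5e_forward,
                   n5e_reverse = profile$n5e_reverse)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
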