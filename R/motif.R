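#' The 130-bp motif window
#'
#' Offsets run from -63 to 66 around the canonical site coordinate `p0`
#' (offset 0). The central part spans -16..19; the two flanks (-63..-17 and
#' 20..66) carry the periodic GC-content signal. Cleavage occurs between
#' -1/0 on one strand and +3/+4 on the other; offsets 0..3 (the overhang)
#' are the positions most biased by the trapping drug and are the default
#' mask range when building the combined motif.
#'
#' @param upstream,downstream Flank sizes (defaults 63 and 66).
#' @param mask_range Offsets replaced by background in the combined motif.
#' @return List of class `motif_window` with `offsets`, `width`,
#'   `central`, `flanks`, `mask_range`.
#' @export
motif_window <- function(upstream = 63L, downstream = 66L,
                         mask_range = 0:3) {
  offsets <- seq.int(-upstream, downstream)
  structure(list(offsets = offsets, width = length(offsets),
                 central = -16:19,
                 flanks = list(left = -upstream:-17, right = 20:downstream),
                 mask_range = mask_range),
            class = "motif_window")
}

DNA_BASES <- c("A", "C", "G", "T")

#' Extract aligned site windows from the genome
#'
#' Each call contributes the genome forward-strand sequence over
#' `[p0 - upstream, p0 + downstream + 1)` (length 130 by default). The site
#' is dyad-symmetric, so no orientation step is applied. On a linear genome,
#' windows running off an end are skipped with a warning; a circular genome
#' wraps.
#'
#' @param genome A [genome_seq].
#' @param calls Call `data.frame` with a `p0` column (0-based).
#' @param window A [motif_window].
#' @return Character vector of equal-length sequences, named by `p0`.
#' @export
extract_site_sequences <- function(genome, calls, window = motif_window()) {
  if (nrow(calls) == 0L) stop("empty call list")
  up <- -window$offsets[1]; down <- window$offsets[window$width]
  starts <- calls$p0 - up
  ends <- calls$p0 + down + 1L
  if (!genome$circular) {
    ok <- starts >= 0 & ends <= genome$length
    if (!all(ok))
      warning(sum(!ok), " site window(s) off the linear genome end, skipped")
    starts <- starts[ok]; ends <- ends[ok]; calls <- calls[ok, , drop = FALSE]
    if (length(starts) == 0L) stop("no site window fits the genome")
  }
  seqs <- vapply(seq_along(starts), function(k)
    genome_subseq(genome, starts[k], ends[k]), character(1))
  names(seqs) <- calls$p0
  seqs
}

#' Position probability matrix from aligned sequences
#'
#' Column-wise base frequencies over `A,C,G,T`; `N` bases are excluded from
#' that column's denominator. Columns are annotated with window offsets when
#' a [motif_window] of matching width is given.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param window Optional [motif_window] for column naming.
#' @return A 4 x width probability matrix (rows `A,C,G,T`), attributes
#'   `column_counts` (effective non-N count per column) and `offsets`.
#' @export
build_ppm <- function(sequences, window = NULL) {
  if (length(sequences) == 0L) stop("no sequences")
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must have equal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sequences))
  counts <- matrix(0, nrow = 4, ncol = nchar(sequences[1]),
                   dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
  denom <- colSums(counts)
  if (any(denom == 0))
    stop("column(s) with zero non-N bases: ",
         paste(which(denom == 0), collapse = ","))
  ppm <- sweep(counts, 2, denom, "/")
  attr(ppm, "column_counts") <- denom
  if (!is.null(window) && window$width == ncol(ppm))
    colnames(ppm) <- window$offsets
  ppm
}

#' GC-content track of a PPM
#'
#' @param ppm A PPM from [build_ppm].
#' @return Numeric vector `ppm["G", ] + ppm["C", ]`, one value per column.
#' @export
gc_track <- function(ppm) {
  ppm["G", ] + ppm["C", ]
}

#' Genome mononucleotide composition
#'
#' @param genome A [genome_seq].
#' @return Named probability vector over `A,C,G,T` (N excluded).
#' @export
genome_composition <- function(genome) {
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(genome$sequence),
                                     DNA_BASES)
  cnt / sum(cnt)
}

#' Combined cross-condition motif with drug-bias masking
#'
#' Per condition, the `top_n` strongest calls (by `n3e_strength`) are taken;
#' pooled across conditions with deduplication by genomic position `p0`
#' (optionally by sequence); the PPM is built from the pooled windows, and
#' the columns at the masked offsets (default 0..3, the drug-biased overhang)
#' are overwritten with the background base composition.
#'
#' @param per_condition_calls Named list of call `data.frame`s.
#' @param genome A [genome_seq].
#' @param top_n Calls kept per condition (default 732; all if fewer).
#' @param window A [motif_window].
#' @param background Composition over `A,C,G,T` used for masking (defaults
#'   to the genome composition).
#' @param dedup `"position"` (default) or `"sequence"`.
#' @return Masked PPM; attribute `n_pooled` records the pooled set size.
#' @export
build_combined_motif <- function(per_condition_calls, genome, top_n = 732L,
                                 window = motif_window(), background = NULL,
                                 dedup = c("position", "sequence")) {
  dedup <- match.arg(dedup)
  if (is.null(background)) background <- genome_composition(genome)
  background <- background / sum(background)
  picked <- lapply(per_condition_calls, function(cs) {
    if (nrow(cs) == 0L) stop("a condition has no calls")
    cs[order(-cs$n3e_strength), , drop = FALSE][seq_len(min(top_n, nrow(cs))), ,
                                                drop = FALSE]
  })
  pool <- do.call(rbind, lapply(picked, function(cs) cs[, "p0", drop = FALSE]))
  if (dedup == "position") pool <- pool[!duplicated(pool$p0), , drop = FALSE]
  seqs <- extract_site_sequences(genome, pool, window)
  if (dedup == "sequence") seqs <- seqs[!duplicated(seqs)]
  if (length(seqs) == 0L) stop("empty pooled sequence set")
  ppm <- build_ppm(seqs, window)
  mask_cols <- match(window$mask_range, window$offsets)
  ppm[, mask_cols] <- background[DNA_BASES]
  attr(ppm, "n_pooled") <- length(seqs)
  ppm
}

#' Convert a PPM to a log2-odds weight matrix
#'
#' `pwm[b, j] = log2((ppm[b, j] + pseudocount) / (background[b] + pseudocount))`.
#' With pseudocount 0 a zero PPM cell would give minus infinity, which is
#' refused with a pointer to set a positive pseudocount.
#'
#' @param ppm A PPM.
#' @param background Composition over `A,C,G,T` (default uniform 0.25, the
#'   convention that reproduces published fragment scores).
#' @param pseudocount Added to both numerator and denominator (default 1e-4).
#' @return A 4 x width matrix of log2-odds, attributes `background` and
#'   `pseudocount`.
#' @export
ppm_to_pwm <- function(ppm, background = rep(0.25, 4), pseudocount = 1e-4) {
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  if (any(background <= 0)) stop("background entries must be positive")
  if (pseudocount == 0 && any(ppm == 0))
    stop("PPM contains zero cells; use pseudocount > 0")
  pwm <- log2(sweep(ppm + pseudocount, 1, background + pseudocount, "/"))
  attr(pwm, "background") <- background
  attr(pwm, "pseudocount") <- pseudocount
  attr(pwm, "column_counts") <- NULL
  pwm
}

# integer-encode a sequence: A=1 C=2 G=3 T=4, anything else 5
encode_seq <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], c(DNA_BASES, "N"))
  m[is.na(m)] <- 5L
  m
}

#' Scan a sequence with a weight matrix on both strands
#'
#' For every start position the forward score is the sum of matched PWM
#' cells; the reverse score is obtained by scoring the reverse complement of
#' the same window. The per-position "score" is the strand maximum; the
#' sequence score is the maximum over positions. Ambiguous bases contribute
#' the background-weighted average of the column.
#'
#' @param seq Character scalar, length at least the motif width.
#' @param pwm A PWM from [ppm_to_pwm].
#' @return List with `positions` (0-based window starts), `forward`,
#'   `reverse`, `score` (per-position strand max) and `best` (max score).
#' @export
scan_sequence <- function(seq, pwm) {
  w <- ncol(pwm)
  n <- nchar(seq)
  if (n < w) stop("sequence shorter than the motif (", n, " < ", w, ")")
  bg <- attr(pwm, "background")
  if (is.null(bg)) bg <- rep(0.25, 4)
  lut <- rbind(pwm, colSums(pwm * bg))  # row 5: background-averaged cell
  score_one_strand <- function(s) {
    idx <- encode_seq(s)
    nw <- length(idx) - w + 1L
    sc <- numeric(nw)
    for (j in seq_len(w)) sc <- sc + lut[cbind(idx[j:(j + nw - 1L)], j)]
    sc
  }
  fwd <- score_one_strand(seq)
  rev_on_rc <- score_one_strand(reverse_complement(seq))
  rev <- rev(rev_on_rc)  # align window starts to the forward coordinate
  sc <- pmax(fwd, rev)
  list(positions = seq_along(fwd) - 1L, forward = fwd, reverse = rev,
       score = sc, best = max(sc))
}

#' Estimate the dominant GC-content period by sinusoid grid fit
#'
#' Least-squares fit of `a cos(2 pi x / P) + b sin(2 pi x / P) + c` over the
#' flank offsets for each candidate period `P` on a grid; returns the
#' residual-minimizing period. Significance of the fitted amplitude is
#' assessed against a permutation null (values shuffled within the flanks).
#'
#' @param gc GC track (one value per motif column).
#' @param window A [motif_window] giving the offsets and flank ranges.
#' @param period_grid Candidate periods (default `seq(8, 14, 0.01)`).
#' @param n_shuffle Permutations for the null (default 1000).
#' @param level Null quantile the observed amplitude must exceed (0.95).
#' @return List: `period` (NA when undefined), `amplitude`, `phase`,
#'   `significant` (logical flag), `null_quantile`.
#' @export
estimate_period <- function(gc, window = motif_window(),
                            period_grid = seq(8, 14, by = 0.01),
                            n_shuffle = 1000L, level = 0.95) {
  offs <- window$offsets
  stopifnot(length(gc) == length(offs))
  sel <- offs %in% c(window$flanks$left, window$flanks$right)
  x <- offs[sel]; y <- gc[sel]
  if (length(x) < 20) stop("fewer than 20 flank points")
  if (stats::sd(y) < 1e-12) {
    return(list(period = NA_real_, amplitude = 0, phase = NA_real_,
                significant = FALSE, null_quantile = NA_real_))
  }
  yc <- y - mean(y)
  Y <- matrix(yc, ncol = 1)
  if (n_shuffle > 0) {
    Yn <- vapply(seq_len(n_shuffle), function(k) sample(yc), numeric(length(yc)))
    Y <- cbind(Y, Yn)
  }
  best_rss <- Inf; best <- NULL
  null_amp <- rep(0, ncol(Y) - 1L)
  yty <- colSums(Y^2)
  for (P in period_grid) {
    X <- cbind(cos(2 * pi * x / P), sin(2 * pi * x / P), 1)
    cf <- qr.coef(qr(X), Y)               # 3 x (1 + n_shuffle)
    fitss <- colSums((X %*% cf) * Y)      # explained sum of products
    rss <- yty - fitss
    if (rss[1] < best_rss) {
      best_rss <- rss[1]
      best <- list(P = P, a = cf[1, 1], b = cf[2, 1])
    }
    if (n_shuffle > 0) {
      amp <- sqrt(cf[1, -1]^2 + cf[2, -1]^2)
      null_amp <- pmax(null_amp, amp)
    }
  }
  amplitude <- sqrt(best$a^2 + best$b^2)
  qn <- if (n_shuffle > 0) stats::quantile(null_amp, level, names = FALSE)
        else NA_real_
  list(period = best$P, amplitude = amplitude,
       phase = atan2(-best$b, best$a),
       significant = if (n_shuffle > 0) amplitude > qn else NA,
       null_quantile = qn)
}

#' Write a PPM/PWM as a TSV of offset, A, C, G, T
#' @param mat 4 x width matrix (rows `A,C,G,T`).
#' @param path Output file.
#' @param offsets Column offsets (defaults to the matrix colnames, else 0..).
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path, offsets = NULL) {
  if (is.null(offsets))
    offsets <- if (!is.null(colnames(mat))) as.integer(colnames(mat))
               else seq_len(ncol(mat)) - 1L
  df <- data.frame(offset = offsets, A = mat["A", ], C = mat["C", ],
                   G = mat["G", ], T = mat["T", ])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PPM/PWM TSV written by [write_matrix_tsv]
#' @param path Input file.
#' @return 4 x width matrix with offset colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  mat <- t(as.matrix(df[, DNA_BASES]))
  rownames(mat) <- DNA_BASES
  colnames(mat) <- df$offset
  mat
}

#' Consensus sequence of a PPM (column-wise argmax; ties -> first base)
#' @param ppm A PPM.
#' @return Character scalar.
#' @export
ppm_consensus <- function(ppm) {
  paste(DNA_BASES[apply(ppm, 2, which.max)], collapse = "")
}
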