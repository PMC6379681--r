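#' Simulation configuration
#'
#' States the synthetic world the generator draws from: genome composition,
#' planted cleavage sites with relative trapping weights (optionally with a
#' planted motif PPM), sonication fragment sizes (200-700 bp, matching the
#' assay's shearing), per-sample fragment counts, the fraction of treated-IP
#' fragments that carry signal, a replication copy-number gradient (linear,
#' 2 at the origin to 1 at the terminus) applied to every background
#' fragment, and a weak residual signal in the untreated IP sample.
#'
#' @param genome_length Genome length in bp.
#' @param circular Circular chromosome (default TRUE).
#' @param background_composition Probabilities over `A,C,G,T`.
#' @param planted_sites `data.frame` with `p0` (0-based canonical site
#'   coordinate) and `weight` (> 0, relative trapping propensity); optional
#'   list-column `ppm` of per-site motif PPMs.
#' @param fragment_range Sonication fragment length range (default 200-700).
#' @param n_fragments Fragments per sample.
#' @param signal_fraction Fraction of treated-IP fragments that are signal.
#' @param residual_signal_fraction Residual signal in the untreated IP
#'   (default 0.02; trapped complexes exist at low level without poison).
#' @param gradient_ratio Copy number at the origin relative to the terminus
#'   (default 2; 1 disables the gradient).
#' @param ori Origin position (default 0; the terminus sits half a genome
#'   away).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_length, circular = TRUE,
                       background_composition = c(A = 0.246, C = 0.254,
                                                  G = 0.254, T = 0.246),
                       planted_sites = NULL,
                       fragment_range = c(200L, 700L),
                       n_fragments = 1e5, signal_fraction = 0.5,
                       residual_signal_fraction = 0.02,
                       gradient_ratio = 2, ori = 0L) {
  stopifnot(genome_length > 0, length(fragment_range) == 2,
            fragment_range[1] >= 1, fragment_range[2] >= fragment_range[1],
            fragment_range[2] <= genome_length,
            signal_fraction >= 0, signal_fraction <= 1,
            residual_signal_fraction >= 0, residual_signal_fraction <= 1,
            gradient_ratio >= 1)
  background_composition <- background_composition / sum(background_composition)
  if (!is.null(planted_sites)) {
    stopifnot(is.data.frame(planted_sites), all(planted_sites$weight > 0),
              all(planted_sites$p0 >= 0), all(planted_sites$p0 < genome_length))
  }
  structure(list(genome_length = as.integer(genome_length), circular = circular,
                 background_composition = background_composition,
                 planted_sites = planted_sites,
                 fragment_range = as.integer(fragment_range),
                 n_fragments = n_fragments,
                 signal_fraction = signal_fraction,
                 residual_signal_fraction = residual_signal_fraction,
                 gradient_ratio = gradient_ratio, ori = as.integer(ori)),
            class = "sim_config")
}

#' Replication copy-number weight per position
#'
#' Piecewise-linear profile: `gradient_ratio` at the origin falling to 1 at
#' the terminus (half a genome away on the circle) and rising back.
#'
#' @param config A [sim_config].
#' @return Numeric vector of length `genome_length`.
#' @export
gradient_weights <- function(config) {
  L <- config$genome_length
  pos <- seq_len(L) - 1L
  d <- abs(((pos - config$ori + L / 2) %% L) - L / 2)  # circular distance to ori
  1 + (config$gradient_ratio - 1) * (1 - d / (L / 2))
}

#' Simulate a genome with planted motif windows
#'
#' Bases are drawn i.i.d. from the background composition; for each planted
#' site carrying a motif PPM, the 130-bp window centered at its `p0` is
#' redrawn column-wise from that PPM. Overlapping planted windows are an
#' error. Deterministic given the RNG state.
#'
#' @param config A [sim_config].
#' @param window A [motif_window] for motif planting.
#' @return List: `genome` (a [genome_seq]), `truth` (planted site table).
#' @export
simulate_genome <- function(config, window = motif_window()) {
  L <- config$genome_length
  bases <- sample(DNA_BASES, L, replace = TRUE,
                  prob = config$background_composition)
  sites <- config$planted_sites
  if (!is.null(sites) && nrow(sites) > 0 && !is.null(sites$ppm)) {
    up <- -window$offsets[1]
    starts0 <- sites$p0 - up
    ord <- order(starts0)
    if (any(diff(starts0[ord]) < window$width))
      stop("overlapping planted motif windows")
    for (k in seq_len(nrow(sites))) {
      ppm <- sites$ppm[[k]]
      if (is.null(ppm)) next
      idx <- ((starts0[k] + seq_len(window$width) - 1L) %% L) + 1L
      if (!config$circular && (starts0[k] < 0 ||
                               starts0[k] + window$width > L))
        stop("planted window off the linear genome")
      for (j in seq_len(window$width))
        bases[idx[j]] <- sample(DNA_BASES, 1, prob = ppm[, j])
    }
  }
  genome <- genome_seq(paste(bases, collapse = ""), contig_id = "simchr",
                       circular = config$circular)
  list(genome = genome, truth = sites)
}

# draw n background fragments under the copy-number gradient
draw_background <- function(n, config, grad_w) {
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(),
                      orientation = character()))
  L <- config$genome_length
  len <- sample.int(config$fragment_range[2] - config$fragment_range[1] + 1L,
                    n, replace = TRUE) + config$fragment_range[1] - 1L
  start <- sample.int(L, n, replace = TRUE, prob = grad_w) - 1L
  end <- start + len
  if (!config$circular) {
    shift <- pmax(end - L, 0L)  # slide fragments back inside a linear genome
    start <- start - shift; end <- end - shift
  }
  data.frame(start = start, end = end,
             orientation = sample(c("forward", "reverse"), n, replace = TRUE))
}

# draw n signal fragments pinned at the walls of weighted planted sites
draw_signal <- function(n, config) {
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(),
                      orientation = character()))
  sites <- config$planted_sites
  if (is.null(sites) || nrow(sites) == 0L)
    stop("signal requested but no planted sites in the configuration")
  L <- config$genome_length
  site <- sample.int(nrow(sites), n, replace = TRUE, prob = sites$weight)
  p0 <- sites$p0[site]
  len <- sample.int(config$fragment_range[2] - config$fragment_range[1] + 1L,
                    n, replace = TRUE) + config$fragment_range[1] - 1L
  fwd <- stats::runif(n) < 0.5
  i <- p0 - 1L  # left wall
  # forward: 3' end pinned at the left wall -> [i - len + 1, i + 1)
  # reverse: 3' end pinned at the right wall -> [i + 5, i + 5 + len)
  start <- ifelse(fwd, i - len + 1L, i + 5L)
  end <- ifelse(fwd, i + 1L, i + 5L + len)
  if (config$circular) {
    shift <- ifelse(start < 0L, L, 0L)  # wrap: represent as start in [0, L)
    start <- start + shift; end <- end + shift
  } else {
    ok <- start >= 0L & end <= L
    start <- start[ok]; end <- end[ok]; fwd <- fwd[ok]
  }
  data.frame(start = start, end = end,
             orientation = ifelse(fwd, "forward", "reverse"))
}

simulate_sample <- function(config, grad_w, signal_fraction) {
  n <- config$n_fragments
  n_sig <- stats::rbinom(1, n, signal_fraction)
  rbind(draw_signal(n_sig, config), draw_background(n - n_sig, config, grad_w))
}

#' Simulate one full sample quartet
#'
#' The treated IP carries wall-pinned signal fragments (a site chosen by
#' weight, orientation 50/50, fragment 3' end pinned at the left wall
#' `p0 - 1` for forward fragments and at the right wall `p0 + 4` for reverse
#' ones, so the overhang `[p0, p0 + 4)` receives no signal 3' ends) mixed
#' with gradient-weighted background. Both mocks are pure background; the
#' untreated IP adds the small residual signal fraction.
#'
#' @param genome A [genome_seq] (for the length check).
#' @param config A [sim_config].
#' @param condition,replicate Labels stored in the quartet.
#' @param keep_fragments Also return the raw fragment tables.
#' @return List: `quartet` (a [sample_quartet]), `truth` (planted sites and
#'   realized per-sample signal counts), optionally `fragments`.
#' @export
simulate_quartet <- function(genome, config, condition = "sim",
                             replicate = 1L, keep_fragments = FALSE) {
  stopifnot(genome$length == config$genome_length)
  if (config$signal_fraction > 0 &&
      (is.null(config$planted_sites) || nrow(config$planted_sites) == 0L))
    stop("signal_fraction > 0 but no planted sites")
  grad_w <- gradient_weights(config)
  frs <- list(
    treated_ip = simulate_sample(config, grad_w, config$signal_fraction),
    treated_mock = simulate_sample(config, grad_w, 0),
    untreated_ip = simulate_sample(config, grad_w,
                                   if (config$signal_fraction > 0)
                                     config$residual_signal_fraction else 0),
    untreated_mock = simulate_sample(config, grad_w, 0))
  profs <- lapply(frs, count_read_ends, genome = genome)
  quartet <- sample_quartet(profs$treated_ip, profs$treated_mock,
                            profs$untreated_ip, profs$untreated_mock,
                            condition = condition, replicate = replicate)
  truth <- list(planted = config$planted_sites,
                signal_counts = vapply(frs, nrow, 0L))
  out <- list(quartet = quartet, truth = truth)
  if (keep_fragments) out$fragments <- frs
  out
}

#' Write fragments as a minimal SAM or a TSV
#'
#' SAM records carry FLAG 0/16 for orientation, POS (1-based), MAPQ 60 and a
#' pure-match CIGAR; sequences are omitted (`*`). Origin-wrapping fragments
#' of a circular genome keep their unwrapped `end` past the genome length
#' (re-wrapped by [count_read_ends]); round-tripping through
#' [read_fragments_sam]/[read_fragments_tsv] and [count_read_ends]
#' reproduces the simulator's internal profile exactly.
#'
#' @param fragments Fragment `data.frame`.
#' @param genome A [genome_seq].
#' @param path Output file.
#' @param format `"sam"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(fragments, genome, path, format = c("sam", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(contig = genome$contig_id, start = fragments$start,
                     end = fragments$end, orientation = fragments$orientation)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  # SQ length must cover unwrapped ends; pad for origin-spanning fragments
  ln <- max(genome$length,
            if (nrow(fragments)) max(fragments$end) else 0L)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$contig_id, ln)), con)
  if (nrow(fragments) > 0L) {
    flag <- ifelse(fragments$orientation == "reverse", 16L, 0L)
    len <- fragments$end - fragments$start
    writeLines(sprintf("frag%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(fragments)), flag, genome$contig_id,
                       fragments$start + 1L, len), con)
  }
  invisible(path)
}

#' Write the planted ground truth as a TSV
#' @param truth Truth list from [simulate_quartet] (or a planted-site table).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  planted <- if (is.data.frame(truth)) truth else truth$planted
  df <- planted[, intersect(c("p0", "weight"), names(planted)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
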