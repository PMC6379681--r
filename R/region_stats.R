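#' Named genomic interval set
#'
#' @param intervals `data.frame` with `start`, `end` (0-based half-open) and
#'   optionally `strand`.
#' @param name Set name.
#' @param genome_length Genome length for bounds checking (optional).
#' @return List of class `interval_set` with merged-length accounting.
#' @export
interval_set <- function(intervals, name = "set", genome_length = NULL) {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0) {
    stopifnot(all(intervals$end > intervals$start), all(intervals$start >= 0))
    if (!is.null(genome_length) && any(intervals$end > genome_length))
      stop("interval(s) beyond the genome end")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals$start + 1L,
                                         end = intervals$end))
  structure(list(name = name, intervals = intervals,
                 merged = ir, total_length = sum(IRanges::width(ir))),
            class = "interval_set")
}

positions_in_set <- function(positions, iset) {
  q <- IRanges::IRanges(start = positions + 1L, width = 1L)
  IRanges::overlapsAny(q, iset$merged)
}

#' Exact binomial enrichment of positions in an interval set
#'
#' Under a uniform null each of the `n` positions falls inside the merged
#' intervals with probability `p` = merged length / genome length; the
#' observed inside count `k` is tested with exact binomial tails
#' (`p_over` = P(X >= k), `p_under` = P(X <= k)) and the minimum-likelihood
#' two-sided p-value.
#'
#' @param positions Integer vector of 0-based positions.
#' @param iset An [interval_set].
#' @param genome_length Genome length in bp.
#' @return List of class `enrichment_result`: `observed`, `expected`, `fold`,
#'   `p_over`, `p_under`, `p_two_sided`, `n`, `p`.
#' @export
binomial_enrichment <- function(positions, iset, genome_length) {
  n <- length(positions)
  if (n == 0L) stop("no positions supplied")
  p <- iset$total_length / genome_length
  if (!(p > 0 && p < 1))
    stop("interval set covers none or all of the genome (p = ", p, ")")
  k <- sum(positions_in_set(positions, iset))
  structure(list(observed = k, expected = n * p, fold = k / (n * p),
                 p_over = stats::pbinom(k - 1, n, p, lower.tail = FALSE),
                 p_under = stats::pbinom(k, n, p),
                 p_two_sided = stats::binom.test(k, n, p)$p.value,
                 n = n, p = p, set = iset$name),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment in %s: %d/%d observed, %.2f expected (fold %.3f)\n",
              x$set, x$observed, x$n, x$expected, x$fold))
  cat(sprintf("  p_over = %.3g, p_under = %.3g, two-sided = %.3g\n",
              x$p_over, x$p_under, x$p_two_sided))
  invisible(x)
}

#' Genome-wide bin scan with a binomial envelope
#'
#' The genome is cut into `bins` equal-width bins (the last absorbs the
#' remainder); per-bin position counts are compared with the exact
#' `Binomial(n, 1/bins)` inverse-CDF envelope at the given quantiles — bins
#' outside the envelope deviate significantly from uniformity.
#'
#' @param positions Integer vector of 0-based positions.
#' @param genome_length Genome length in bp.
#' @param bins Number of bins (default 10).
#' @param q Lower/upper envelope quantiles (default `c(0.0005, 0.9995)`).
#' @return List of class `bin_envelope`: `counts`, `lower`, `upper`,
#'   `flag` (`"low"`, `"ok"`, `"high"` per bin), bin boundaries.
#' @export
genome_bin_scan <- function(positions, genome_length, bins = 10L,
                            q = c(0.0005, 0.9995)) {
  n <- length(positions)
  if (n < 1L) stop("no positions supplied")
  if (bins < 2L) stop("need at least 2 bins")
  if (bins > genome_length) stop("more bins than genome positions")
  w <- genome_length %/% bins
  breaks <- c(seq(0, by = w, length.out = bins), genome_length)
  bin <- pmin(findInterval(positions, breaks, left.open = FALSE), bins)
  counts <- tabulate(bin, nbins = bins)
  lower <- stats::qbinom(q[1], n, 1 / bins)
  upper <- stats::qbinom(q[2], n, 1 / bins)
  flag <- ifelse(counts < lower, "low", ifelse(counts > upper, "high", "ok"))
  structure(list(counts = counts, lower = lower, upper = upper, flag = flag,
                 breaks = breaks, n = n, bins = bins, q = q),
            class = "bin_envelope")
}

#' Fisher exact test on a 2x2 table
#'
#' Full hypergeometric enumeration with fixed margins; the two-sided p-value
#' sums the probabilities of all tables at most as probable as the observed
#' one (the standard convention).
#'
#' @param a,b,c,d Cell counts, rows `(a, b)` and `(c, d)`.
#' @return List: `p_two_sided`, `p_greater`, `p_less` (tails on `a`),
#'   `odds_ratio` (sample).
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  n <- a + b + c + d
  if (n == 0) {
    warning("degenerate all-zero table; p = 1")
    return(list(p_two_sided = 1, p_greater = 1, p_less = 1, odds_ratio = NaN))
  }
  m1 <- a + b; c1 <- a + c
  lo <- max(0, c1 - (n - m1)); hi <- min(m1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, m1, n - m1, c1)
  p_obs <- stats::dhyper(a, m1, n - m1, c1)
  list(p_two_sided = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])),
       p_greater = sum(probs[support >= a]),
       p_less = sum(probs[support <= a]),
       odds_ratio = (a * d) / (b * c))
}

#' Exact conditional test for two Poisson counts
#'
#' Conditional on the total, `k1 ~ Binomial(k1 + k2, t1 / (t1 + t2))`;
#' exact binomial tails and a minimum-likelihood two-sided p-value. Real
#' valued inputs are rounded half-even (and this is reported).
#'
#' @param k1,k2 Observed counts.
#' @param t1,t2 Exposures (e.g. region lengths or library sizes).
#' @return List: `p_greater`, `p_less`, `p_two_sided`, `rounded` flag.
#' @export
poisson_conditional_test <- function(k1, k2, t1, t2) {
  stopifnot(k1 >= 0, k2 >= 0, t1 > 0, t2 > 0)
  rounded <- (k1 != round(k1)) || (k2 != round(k2))
  k1 <- round(k1); k2 <- round(k2)
  s <- k1 + k2
  if (s == 0) {
    return(list(p_greater = 1, p_less = 1, p_two_sided = 1, rounded = rounded))
  }
  p1 <- t1 / (t1 + t2)
  list(p_greater = stats::pbinom(k1 - 1, s, p1, lower.tail = FALSE),
       p_less = stats::pbinom(k1, s, p1),
       p_two_sided = stats::binom.test(k1, s, p1)$p.value,
       rounded = rounded)
}

# transcription-direction-aware compartments of one TU
tu_compartments <- function(tu, us_width, ds_width) {
  mid <- (tu$start + tu$end) %/% 2
  if (identical(tu$strand, "-")) {
    list(upstream = c(tu$end, tu$end + us_width),
         body_start = c(mid, tu$end),
         body_end = c(tu$start, mid),
         downstream = c(tu$start - ds_width, tu$start))
  } else {
    list(upstream = c(tu$start - us_width, tu$start),
         body_start = c(tu$start, mid),
         body_end = c(mid, tu$end),
         downstream = c(tu$end, tu$end + ds_width))
  }
}

#' Assign cleavage sites to transcription-unit compartments
#'
#' Each TU defines four strand-aware compartments: upstream (`us_width` bp
#' before the transcription start), the first and second halves of the gene
#' body, and downstream (`ds_width` bp past the end, the region where
#' transcription-driven positive supercoiling accumulates). Calls falling in
#' compartments of several TUs are resolved to the TU with the nearest gene
#' boundary (exact ties: both counted, flagged). Per-compartment enrichment
#' uses [binomial_enrichment] against the merged compartment lengths, and
#' counts are stratified by TU expression quantiles.
#'
#' @param calls Call `data.frame` with `p0`.
#' @param tus `data.frame` with `id`, `start`, `end`, `strand`, `expression`.
#' @param genome_length Genome length in bp.
#' @param us_width,ds_width Compartment widths (defaults 5000 bp).
#' @param expression_strata Quantile probabilities splitting TUs by
#'   expression (default terciles `c(1/3, 2/3)`).
#' @return List: `assignments` (per call: compartment, TU, stratum, tie
#'   flag), `counts` (stratum x compartment), `enrichment` (per-compartment
#'   [binomial_enrichment] over all strata), `n_intergenic_far`.
#' @export
associate_with_tus <- function(calls, tus, genome_length,
                               us_width = 5000L, ds_width = 5000L,
                               expression_strata = c(1 / 3, 2 / 3)) {
  stopifnot(all(c("id", "start", "end", "strand", "expression") %in% names(tus)))
  comp_names <- c("upstream", "body_start", "body_end", "downstream")
  qs <- stats::quantile(tus$expression, expression_strata, names = FALSE)
  tus$stratum <- findInterval(tus$expression, qs) + 1L
  n_strata <- length(expression_strata) + 1L
  # flatten all compartments into one table
  rows <- do.call(rbind, lapply(seq_len(nrow(tus)), function(i) {
    cp <- tu_compartments(tus[i, ], us_width, ds_width)
    data.frame(tu = tus$id[i], stratum = tus$stratum[i],
               compartment = comp_names,
               start = vapply(cp, `[`, 0, 1), end = vapply(cp, `[`, 0, 2),
               g_start = tus$start[i], g_end = tus$end[i])
  }))
  rows <- rows[rows$end > rows$start, , drop = FALSE]
  rows$start <- pmax(rows$start, 0)
  rows$end <- pmin(rows$end, genome_length)
  rows <- rows[rows$end > rows$start, , drop = FALSE]
  ir <- IRanges::IRanges(start = rows$start + 1L, end = rows$end)
  q <- IRanges::IRanges(start = calls$p0 + 1L, width = 1L)
  ov <- IRanges::findOverlaps(q, ir)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  assignments <- NULL
  if (length(qh) > 0) {
    d_boundary <- pmin(abs(calls$p0[qh] - rows$g_start[sh]),
                       abs(calls$p0[qh] - rows$g_end[sh]))
    df <- data.frame(call = qh, p0 = calls$p0[qh], tu = rows$tu[sh],
                     stratum = rows$stratum[sh],
                     compartment = rows$compartment[sh], dist = d_boundary)
    assignments <- do.call(rbind, lapply(split(df, df$call), function(g) {
      best <- g[g$dist == min(g$dist), , drop = FALSE]
      best$tie <- nrow(best) > 1
      best
    }))
    rownames(assignments) <- NULL
  } else {
    assignments <- data.frame(call = integer(), p0 = integer(),
                              tu = character(), stratum = integer(),
                              compartment = character(), dist = numeric(),
                              tie = logical())
  }
  counts <- matrix(0L, nrow = n_strata, ncol = length(comp_names),
                   dimnames = list(paste0("stratum", seq_len(n_strata)),
                                   comp_names))
  if (nrow(assignments) > 0) {
    tab <- table(factor(assignments$stratum, levels = seq_len(n_strata)),
                 factor(assignments$compartment, levels = comp_names))
    counts[] <- as.integer(tab)
  }
  enrichment <- lapply(stats::setNames(comp_names, comp_names), function(cn) {
    sub <- rows[rows$compartment == cn, , drop = FALSE]
    iset <- interval_set(sub[, c("start", "end")], name = cn, genome_length)
    binomial_enrichment(calls$p0, iset, genome_length)
  })
  assigned <- unique(assignments$call)
  list(assignments = assignments, counts = counts, enrichment = enrichment,
       n_intergenic_far = nrow(calls) - length(assigned))
}

#' Sign-type comparison of shared sites between two conditions
#'
#' Sites present in both call sets (exact `p0` match) and inside the region
#' are compared by their strength ratio `b / a`; under the null the ratio is
#' below 1 for half of them. Exact ties (ratio 1) are dropped, sign-test
#' style. `p_decrease` is the upper binomial tail on the number of ratios
#' below 1 (tendency of condition b to be weaker).
#'
#' @param calls_a,calls_b Call `data.frame`s with `p0`, `n3e_strength`.
#' @param region An [interval_set]; `NULL` uses every shared call.
#' @return List: `ratios` table, `m` (ratios < 1), `s` (non-tied shared),
#'   `p_decrease`, `p_increase`, `p_two_sided`, `n_ties`.
#' @export
compare_shared_gcs <- function(calls_a, calls_b, region = NULL) {
  shared <- merge(calls_a[, c("p0", "n3e_strength")],
                  calls_b[, c("p0", "n3e_strength")],
                  by = "p0", suffixes = c("_a", "_b"))
  if (!is.null(region))
    shared <- shared[positions_in_set(shared$p0, region), , drop = FALSE]
  if (nrow(shared) == 0L) stop("no shared calls in the region")
  shared$ratio <- shared$n3e_strength_b / shared$n3e_strength_a
  ties <- shared$ratio == 1
  kept <- shared[!ties, , drop = FALSE]
  s <- nrow(kept)
  m <- sum(kept$ratio < 1)
  if (s == 0L) {
    return(list(ratios = shared, m = 0L, s = 0L, p_decrease = 1,
                p_increase = 1, p_two_sided = 1, n_ties = sum(ties)))
  }
  list(ratios = shared, m = m, s = s,
       p_decrease = stats::pbinom(m - 1, s, 0.5, lower.tail = FALSE),
       p_increase = stats::pbinom(m, s, 0.5),
       p_two_sided = stats::binom.test(m, s, 0.5)$p.value,
       n_ties = sum(ties))
}

#' Read an interval BED (first three columns) as an [interval_set]
#' @param path BED/TSV file (no header): contig, start, end, ...
#' @param name Set name (default: file base name).
#' @param genome_length Optional bounds check.
#' @return An [interval_set].
#' @export
read_interval_bed <- function(path, name = NULL, genome_length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  interval_set(data.frame(start = df[[2]], end = df[[3]]),
               name = if (is.null(name)) basename(path) else name,
               genome_length = genome_length)
}

#' Read transcription units from a BED-like TSV with an expression column
#'
#' Columns (no header): contig, start, end, id, expression, strand.
#' Expression is the mean sequencing depth over the gene body.
#'
#' @param path Input file.
#' @return `data.frame` with `id`, `start`, `end`, `strand`, `expression`.
#' @export
read_tu_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end", "id",
                                        "expression", "strand"))
  df[, c("id", "start", "end", "strand", "expression")]
}
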