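#' Caller configuration
#'
#' @param alpha Significance level for the Audic-Claverie test at each wall
#'   (default 0.0025).
#' @param smoothing_window Sliding-window width (bp) for mock-profile
#'   smoothing before the copy-number normalization (default 200000).
#' @param gap Gap width between walls; fixed at 4 bp by the enzyme's
#'   staggered cleavage chemistry — any other value is an error.
#' @param count_policy `"continuous"` evaluates the count test on real-valued
#'   normalized signals through the log-gamma extension; `"rounded"` rounds
#'   (half-even) to integers first.
#' @param min_replicate_support Replicates a site must appear in to be kept
#'   (default 2).
#' @param strand_mode `"combined"` tests both walls on the strand-summed N3E
#'   track; `"split"` tests the left wall on forward-strand 3' ends only and
#'   the right wall on reverse-strand 3' ends only (the peak-shape model).
#' @param epsilon Smoothed-mock values at or below this are masked out.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(alpha = 0.0025, smoothing_window = 200000L,
                          gap = 4L, count_policy = c("continuous", "rounded"),
                          min_replicate_support = 2L,
                          strand_mode = c("combined", "split"),
                          epsilon = 1e-6) {
  count_policy <- match.arg(count_policy)
  strand_mode <- match.arg(strand_mode)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (gap != 4L)
    stop("gap must be 4: the 4-bp 5'-overhang is fixed by gyrase chemistry")
  if (smoothing_window < 1) stop("smoothing_window must be >= 1")
  structure(list(alpha = alpha, smoothing_window = as.integer(smoothing_window),
                 gap = 4L, count_policy = count_policy,
                 min_replicate_support = as.integer(min_replicate_support),
                 strand_mode = strand_mode, epsilon = epsilon),
            class = "caller_config")
}

#' Bundle the four linked samples of one replicate
#'
#' The assay yields a quartet per culture split: poison + IP (`treated_ip`),
#' poison without IP (`treated_mock`), untreated + IP (`untreated_ip`) and
#' untreated without IP (`untreated_mock`). The mocks capture the copy-number
#' gradient (ori-ter replication bias) and sonication structure, the
#' untreated IP the drug-independent background.
#'
#' @param treated_ip,treated_mock,untreated_ip,untreated_mock `end_profile`s
#'   of equal genome length.
#' @param condition Condition label (e.g. `"Cfx"`).
#' @param replicate Replicate identifier.
#' @return A list of class `sample_quartet`.
#' @export
sample_quartet <- function(treated_ip, treated_mock, untreated_ip,
                           untreated_mock, condition = "cond",
                           replicate = 1L) {
  profs <- list(treated_ip = treated_ip, treated_mock = treated_mock,
                untreated_ip = untreated_ip, untreated_mock = untreated_mock)
  lens <- vapply(profs, function(p) p$genome_length, numeric(1))
  if (length(unique(lens)) != 1L)
    stop("quartet profiles disagree on genome length")
  structure(c(profs, list(condition = condition, replicate = replicate)),
            class = "sample_quartet")
}

quartet_roles <- c("treated_ip", "treated_mock", "untreated_ip", "untreated_mock")

#' Library-size scaling of a quartet
#'
#' Each profile is divided by its own total fragment count and multiplied by
#' the smallest total in the quartet, so all four profiles sum to the same
#' (smallest) library size and the smallest-library sample is unchanged.
#' Idempotent.
#'
#' @param quartet A [sample_quartet].
#' @return The quartet with real-valued, scaled count vectors; each profile
#'   records the scaled sum in `total_fragments`.
#' @export
library_scale <- function(quartet) {
  totals <- vapply(quartet[quartet_roles],
                   function(p) p$total_fragments, numeric(1))
  if (any(totals == 0))
    stop("sample(s) with zero aligned fragments: ",
         paste(quartet_roles[totals == 0], collapse = ", "))
  m <- min(totals)
  for (role in quartet_roles) {
    f <- m / quartet[[role]]$total_fragments
    for (tr in c("n3e_forward", "n3e_reverse", "n5e_forward", "n5e_reverse"))
      quartet[[role]][[tr]] <- quartet[[role]][[tr]] * f
    quartet[[role]]$total_fragments <- m
  }
  quartet
}

#' Centered moving-average smoothing
#'
#' @param values Numeric vector.
#' @param window Window width in bp (clipped to the genome length; even
#'   widths are widened by one to stay centered).
#' @param circular Wrap around the origin (exact mean preservation) or
#'   shrink the window at linear ends.
#' @return Numeric vector of the same length.
#' @export
smooth_profile <- function(values, window, circular = TRUE) {
  n <- length(values)
  if (n == 0L) stop("empty profile")
  if (window < 1) stop("window must be >= 1")
  window <- min(as.integer(window), n)
  if (window %% 2L == 0L)
    window <- if (window < n) window + 1L else window - 1L
  if (window == 1L) return(as.numeric(values))
  h <- (window - 1L) %/% 2L
  if (circular) {
    ext <- c(values[(n - h + 1L):n], values, values[1L:h])
    cs <- cumsum(c(0, ext))
    (cs[(window + 1L):(window + n)] - cs[1L:n]) / window
  } else {
    cs <- cumsum(c(0, values))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
}

#' Divide an IP track by its smoothed mock control
#'
#' Removes the ori-ter copy-number / sequencing-depth gradient: the IP signal
#' is divided position-wise by the smoothed mock background. Positions where
#' the smoothed mock is at or below `epsilon` (deletions, unmappable runs)
#' are masked and excluded from calling rather than producing infinities.
#'
#' @param ip Numeric vector (library-scaled IP N3E track).
#' @param mock_smoothed Numeric vector from [smooth_profile].
#' @param epsilon Mask threshold (default 1e-6).
#' @return List with `values` (ratio, `NA` where masked) and logical `mask`
#'   (`TRUE` = masked out).
#' @export
normalize_to_mock <- function(ip, mock_smoothed, epsilon = 1e-6) {
  if (length(ip) != length(mock_smoothed))
    stop("ip and mock_smoothed lengths differ")
  mask <- !(mock_smoothed > epsilon)
  if (all(mask)) stop("mock library unusable: every position masked")
  out <- rep(NA_real_, length(ip))
  out[!mask] <- ip[!mask] / mock_smoothed[!mask]
  list(values = out, mask = mask)
}

# ---- Audic-Claverie count test -------------------------------------------

#' Audic-Claverie probability of observing y tags given x
#'
#' The probability of seeing `y` counts in a library of size `n2` given `x`
#' counts in a library of size `n1`, under a shared Poisson rate with a flat
#' prior: `p(y|x) = (n2/n1)^y (x+y)! / (x! y! (1+n2/n1)^(x+y+1))`, evaluated
#' in log-gamma form so real-valued (normalized) "counts" are admitted.
#'
#' @param x Count in the reference (control) library.
#' @param y Count in the compared (treated) library.
#' @param n1,n2 Library sizes of the control and treated libraries.
#' @return `p(y|x)`, vectorized over `x`/`y`.
#' @export
ac_pmf <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), n1 > 0, n2 > 0)
  r <- n2 / n1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

#' Upper-tail Audic-Claverie p-value
#'
#' `P(Y >= y | x)` under the Audic-Claverie posterior predictive, which is a
#' negative binomial with size `x + 1` and success probability
#' `n1 / (n1 + n2)`; its upper tail equals the regularized incomplete beta
#' `I_{n2/(n1+n2)}(y, x + 1)`, well defined for non-integer `x` and `y`
#' (the continuous count policy).
#'
#' @inheritParams ac_pmf
#' @return `P(Y >= y | x)`, vectorized.
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), n1 > 0, n2 > 0)
  p2 <- n2 / (n1 + n2)
  out <- rep(1, length(x + y))  # recycle to common length
  yy <- rep_len(as.numeric(y), length(out))
  xx <- rep_len(as.numeric(x), length(out))
  pos <- yy > 0
  out[pos] <- stats::pbeta(p2, yy[pos], xx[pos] + 1)
  out
}

#' Smallest treated count deemed significant
#'
#' Least integer `y` whose upper-tail Audic-Claverie p-value against a
#' control count `x` falls below `alpha`.
#'
#' @inheritParams ac_pmf
#' @param alpha Significance level in (0, 1).
#' @return Integer `y*`.
#' @export
ac_min_significant <- function(x, n1, n2, alpha) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  stopifnot(length(x) == 1L, x >= 0)
  y <- stats::qnbinom(alpha, size = x + 1, prob = n1 / (n1 + n2),
                      lower.tail = FALSE)
  # qnbinom gives a neighbourhood; walk to the exact strict-inequality boundary
  while (y > 0 && ac_pvalue(x, y, n1, n2) < alpha) y <- y - 1
  while (ac_pvalue(x, y, n1, n2) >= alpha) y <- y + 1
  as.integer(y)
}

# ---- paired-wall calling --------------------------------------------------

#' Call gyrase cleavage sites from a normalized treated/control pair
#'
#' A site is reported at left wall `i` when the treated signal at both `i`
#' and `i + 5` is significantly above the control by the Audic-Claverie test
#' (each wall tested at `alpha`). The cleaved 4-bp overhang spans
#' `[i + 1, i + 5)`; the canonical site coordinate `p0 = i + 1` is its first
#' base. Every passing `i` is reported; adjacent passes are not merged.
#'
#' @param pair Either a list with `treated_norm`, `control_norm`, `mask`
#'   (as produced by the normalization steps), where each element of
#'   `treated_norm`/`control_norm` is a numeric vector, or — in split-strand
#'   mode — vectors `treated_left`/`treated_right` tested at the left/right
#'   wall respectively.
#' @param config A [caller_config].
#' @param n1,n2 Library sizes for the test; after [library_scale] both equal
#'   the smallest quartet total (the equal-size form of the test).
#' @param circular Wrap `i + 5` past the origin.
#' @return `data.frame` of calls: `left_wall`, `right_wall`, `p0` (0-based),
#'   `n3e_strength` (mean of the two wall heights), `p_left`, `p_right`.
#' @export
call_gcs <- function(pair, config = caller_config(), n1, n2,
                     circular = TRUE) {
  stopifnot(inherits(config, "caller_config"))
  tl <- if (!is.null(pair$treated_left)) pair$treated_left else pair$treated_norm
  tr <- if (!is.null(pair$treated_right)) pair$treated_right else pair$treated_norm
  ctl <- pair$control_norm
  mask <- if (is.null(pair$mask)) rep(FALSE, length(tl)) else pair$mask
  L <- length(tl)
  stopifnot(length(tr) == L, length(ctl) == L, length(mask) == L)
  shift5 <- function(v) if (circular) v[((seq_len(L) + 4L) %% L) + 1L] else
    c(v[-(1:5)], rep(NA, 5))
  y_l <- tl; y_r <- shift5(tr)
  x_l <- ctl; x_r <- shift5(ctl)
  m_r <- shift5(ifelse(mask, 1, 0)) != 0
  if (config$count_policy == "rounded") {
    y_l <- round(y_l); y_r <- round(y_r); x_l <- round(x_l); x_r <- round(x_r)
  }
  ok <- !mask & !is.na(m_r) & !m_r & !is.na(y_r)
  p_l <- rep(NA_real_, L); p_r <- rep(NA_real_, L)
  p_l[ok] <- ac_pvalue(x_l[ok], y_l[ok], n1, n2)
  p_r[ok] <- ac_pvalue(x_r[ok], y_r[ok], n1, n2)
  hit <- which(ok & p_l < config$alpha & p_r < config$alpha)
  i0 <- hit - 1L  # 0-based left wall
  rw <- i0 + 5L; pp <- i0 + 1L
  if (circular) { rw <- rw %% L; pp <- pp %% L }
  data.frame(left_wall = i0, right_wall = rw, p0 = pp,
             n3e_strength = (tl[hit] + tr[((hit + 4L) %% L) + 1L]) / 2,
             p_left = p_l[hit], p_right = p_r[hit])
}

#' Full single-replicate calling pipeline on a quartet
#'
#' Library-scales the quartet, smooths both mock profiles, divides each IP
#' track by its own smoothed mock, and runs the paired-wall caller with the
#' treated-vs-untreated Audic-Claverie criterion.
#'
#' @param quartet A [sample_quartet] of raw integer profiles.
#' @param config A [caller_config].
#' @param circular Logical, circular chromosome.
#' @return `data.frame` of calls (see [call_gcs]) plus columns `condition`
#'   and `replicate`; the normalized treated track is attached as attribute
#'   `treated_norm`.
#' @export
call_quartet <- function(quartet, config = caller_config(), circular = TRUE) {
  q <- library_scale(quartet)
  n <- q$treated_ip$total_fragments  # equal across samples after scaling
  tm_s <- smooth_profile(combined_n3e(q$treated_mock), config$smoothing_window,
                         circular)
  um_s <- smooth_profile(combined_n3e(q$untreated_mock),
                         config$smoothing_window, circular)
  ctl <- normalize_to_mock(combined_n3e(q$untreated_ip), um_s, config$epsilon)
  if (config$strand_mode == "split") {
    trt_f <- normalize_to_mock(q$treated_ip$n3e_forward, tm_s / 2,
                               config$epsilon)
    trt_r <- normalize_to_mock(q$treated_ip$n3e_reverse, tm_s / 2,
                               config$epsilon)
    pair <- list(treated_left = trt_f$values, treated_right = trt_r$values,
                 control_norm = ctl$values,
                 mask = trt_f$mask | trt_r$mask | ctl$mask)
    tn <- (trt_f$values + trt_r$values) / 2
  } else {
    trt <- normalize_to_mock(combined_n3e(q$treated_ip), tm_s, config$epsilon)
    pair <- list(treated_norm = trt$values, control_norm = ctl$values,
                 mask = trt$mask | ctl$mask)
    tn <- trt$values
  }
  calls <- call_gcs(pair, config, n1 = n, n2 = n, circular = circular)
  if (nrow(calls) > 0L) {
    calls$condition <- quartet$condition
    calls$replicate <- quartet$replicate
  } else {
    calls$condition <- character(0)
    calls$replicate <- integer(0)
  }
  attr(calls, "treated_norm") <- tn
  calls
}

#' Merge replicate call sets into a reliable set
#'
#' A site survives when its canonical coordinate `p0` occurs (exact match) in
#' at least `min_support` replicate sets; its strength becomes the mean over
#' supporting replicates and the support count is recorded.
#'
#' @param call_sets List of call `data.frame`s, one per replicate.
#' @param min_support Minimum number of supporting replicates.
#' @return Merged call `data.frame` with `replicate_support`, sorted by `p0`.
#' @export
merge_replicates <- function(call_sets, min_support = 2L) {
  if (length(call_sets) < min_support)
    stop("only ", length(call_sets), " replicate set(s) supplied but ",
         min_support, " supporting replicates required")
  all <- do.call(rbind, lapply(seq_along(call_sets), function(k) {
    cs <- call_sets[[k]]
    if (nrow(cs) == 0L) return(NULL)
    # a p0 may appear once per replicate only
    cs <- cs[!duplicated(cs$p0), , drop = FALSE]
    cs$.rep <- k
    cs
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(p0 = integer(), left_wall = integer(),
                      right_wall = integer(), n3e_strength = numeric(),
                      replicate_support = integer()))
  }
  sp <- split(all, all$p0)
  keep <- sp[vapply(sp, nrow, 0L) >= min_support]
  out <- do.call(rbind, lapply(keep, function(g) {
    data.frame(p0 = g$p0[1], left_wall = g$left_wall[1],
               right_wall = g$right_wall[1],
               n3e_strength = mean(g$n3e_strength),
               p_left = min(g$p_left), p_right = min(g$p_right),
               replicate_support = nrow(g))
  }))
  if (is.null(out)) {
    return(data.frame(p0 = integer(), left_wall = integer(),
                      right_wall = integer(), n3e_strength = numeric(),
                      replicate_support = integer()))
  }
  rownames(out) <- NULL
  out[order(out$p0), , drop = FALSE]
}

#' Write calls as a BED-like TSV
#'
#' Columns: contig, p0, p0+4 (the overhang interval, 0-based half-open), id,
#' n3e_strength, '.', p_left, p_right, replicate_support.
#'
#' @param calls Merged call `data.frame`.
#' @param genome A [genome_seq].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gcs_bed <- function(calls, genome, path) {
  df <- data.frame(contig = genome$contig_id, start = calls$p0,
                   end = calls$p0 + 4L,
                   id = sprintf("gcs_%d", calls$p0),
                   score = calls$n3e_strength, strand = ".",
                   p_left = if (!is.null(calls$p_left)) calls$p_left else NA,
                   p_right = if (!is.null(calls$p_right)) calls$p_right else NA,
                   support = if (!is.null(calls$replicate_support))
                     calls$replicate_support else NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a GCS BED-like TSV back
#' @param path File written by [write_gcs_bed].
#' @return Call `data.frame` with `p0`, `n3e_strength`, `replicate_support`.
#' @export
read_gcs_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end", "id",
                                        "score", "strand", "p_left", "p_right",
                                        "support"))
  data.frame(p0 = df$start, left_wall = df$start - 1L,
             right_wall = df$start + 4L, n3e_strength = df$score,
             p_left = df$p_left, p_right = df$p_right,
             replicate_support = df$support)
}
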