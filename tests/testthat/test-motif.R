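test_that("site windows are extracted at [p0-63, p0+67) and wrap when circular", {
  g <- random_genome(300, seed = 9)
  seqs <- extract_site_sequences(g, data.frame(p0 = 100))
  expect_equal(nchar(seqs), 130L, ignore_attr = TRUE)
  expect_equal(unname(seqs), substr(g$sequence, 38, 167))  # 0-based [37, 167)

  wrapped <- extract_site_sequences(g, data.frame(p0 = 10))
  expect_equal(nchar(wrapped), 130L, ignore_attr = TRUE)
  expect_equal(unname(substr(wrapped, 54, 130)),
               substr(g$sequence, 1, 77))  # offsets -10.. map to genome 0..

  lin <- genome_seq(g$sequence, circular = FALSE)
  expect_warning(kept <- extract_site_sequences(
    lin, data.frame(p0 = c(10, 150))), "skipped")
  expect_length(kept, 1)
  expect_error(extract_site_sequences(g, data.frame(p0 = integer())), "empty")
})

test_that("PPM columns are frequencies over non-N bases and sum to one", {
  seqs <- rep("ACGGT", 10)
  ppm <- build_ppm(seqs)
  expect_equal(colSums(ppm), rep(1, 5), ignore_attr = TRUE)
  expect_equal(unname(ppm["A", 1]), 1)
  expect_equal(gc_track(ppm), c(0, 1, 1, 1, 0), ignore_attr = TRUE)

  two <- c("AACAA", "AATAA")
  p2 <- build_ppm(two)
  expect_equal(p2[, 3], c(A = 0, C = 0.5, G = 0, T = 0.5))

  withN <- c("ANG", "AAG", "ACG")
  pn <- build_ppm(withN)
  expect_equal(pn[, 2], c(A = 0.5, C = 0.5, G = 0, T = 0))
  expect_equal(attr(pn, "column_counts")[2], 2, ignore_attr = TRUE)
  expect_error(build_ppm(c("AN", "AN")), "zero non-N")
  expect_error(build_ppm(c("AC", "ACG")), "equal length")
})

test_that("a PPM rebuilt from sequences drawn from it is close to truth", {
  ppm <- toy_ppm(width = 40, seed = 13)
  seqs <- withr::with_seed(14, draw_from_ppm(ppm, 2000))
  rebuilt <- build_ppm(seqs)
  expect_lt(max(abs(rebuilt - ppm)), 0.05)
})

test_that("combined motif pools top-n by strength, dedups by position, masks 0..3", {
  g <- random_genome(5000, seed = 15)
  w <- motif_window()
  mk <- function(p0s, strengths) data.frame(p0 = p0s, n3e_strength = strengths)
  # three conditions sharing no positions
  conds <- list(a = mk(c(200, 400, 600), 3:1),
                b = mk(c(1200, 1400, 1600), 3:1),
                c = mk(c(2200, 2400, 2600), 3:1))
  ppm <- build_combined_motif(conds, g, top_n = 10, window = w)
  expect_equal(attr(ppm, "n_pooled"), 9)
  # identical call positions collapse to one condition's worth
  dup <- list(a = mk(c(200, 400), c(2, 1)), b = mk(c(200, 400), c(5, 1)))
  expect_equal(attr(build_combined_motif(dup, g, window = w), "n_pooled"), 2)
  # top_n keeps the strongest
  many <- list(a = mk(seq(200, 2000, by = 200), 10:1))
  p_top <- build_combined_motif(many, g, top_n = 3, window = w)
  expect_equal(attr(p_top, "n_pooled"), 3)
  # masked columns equal the genome background exactly
  bgc <- genome_composition(g)
  mask_cols <- match(0:3, w$offsets)
  for (j in mask_cols)
    expect_equal(unname(ppm[, j]), unname(bgc[c("A", "C", "G", "T")]))
  expect_equal(colSums(ppm), rep(1, 130), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("ppm_to_pwm is the log2-odds with pseudocount and refuses -Inf", {
  ppm <- matrix(c(0.25, 0.25, 0.25, 0.25,
                  0.5, 0.25, 0.125, 0.125),
                nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- ppm_to_pwm(ppm, background = rep(0.25, 4), pseudocount = 0)
  expect_equal(pwm[, 1], c(A = 0, C = 0, G = 0, T = 0))
  expect_equal(unname(pwm["A", 2]), 1)   # log2(0.5 / 0.25)
  zero <- ppm; zero["A", 1] <- 0; zero["C", 1] <- 0.5
  expect_error(ppm_to_pwm(zero, pseudocount = 0), "pseudocount")
  expect_error(ppm_to_pwm(ppm, background = c(0, 0.5, 0.25, 0.25)),
               "positive")
})

test_that("scanning agrees with the per-window oracle and is strand-symmetric", {
  ppm <- toy_ppm(width = 12, seed = 17)
  pwm <- ppm_to_pwm(ppm)
  seq <- withr::with_seed(18, paste(sample(c("A", "C", "G", "T", "N"), 60,
                                           replace = TRUE,
                                           prob = c(.24, .24, .24, .24, .04)),
                                    collapse = ""))
  got <- scan_sequence(seq, pwm)
  expect_length(got$score, 60 - 12 + 1)
  oracle <- vapply(got$positions, function(s)
    oracle_window_score(substr(seq, s + 1, s + 12), pwm), 0)
  expect_equal(got$score, oracle, tolerance = 1e-12)
  # reverse-complement invariance of the per-sequence score
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  expect_equal(scan_sequence(rc, pwm)$best, got$best, tolerance = 1e-12)
  expect_equal(rev(scan_sequence(rc, pwm)$score), got$score, tolerance = 1e-12)

  # uniform PPM vs uniform background scores zero everywhere
  uni <- matrix(0.25, 4, 12, dimnames = list(c("A", "C", "G", "T"), NULL))
  z <- scan_sequence(seq, ppm_to_pwm(uni, pseudocount = 0))
  expect_equal(max(abs(z$score)), 0)
  expect_error(scan_sequence("ACGT", pwm), "shorter")
})

test_that("a palindromic PWM scores both strands identically", {
  # build a PWM whose matrix equals its own reverse complement
  half <- toy_ppm(width = 6, seed = 19)
  rc_half <- half[c("T", "G", "C", "A"), 6:1]
  rownames(rc_half) <- c("A", "C", "G", "T")
  pal <- cbind(half, rc_half)
  pwm <- ppm_to_pwm(pal)
  seq <- withr::with_seed(20, paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                                    collapse = ""))
  got <- scan_sequence(seq, pwm)
  expect_equal(got$forward, got$reverse, tolerance = 1e-12)
})

test_that("period estimation recovers planted periods and flags flat tracks", {
  w <- motif_window()
  offs <- w$offsets
  flank <- offs %in% c(w$flanks$left, w$flanks$right)
  gc10 <- ifelse(flank, 0.5 + 0.2 * cos(2 * pi * offs / 10), 0.5)
  expect_equal(estimate_period(gc10, w, n_shuffle = 0)$period, 10)

  noisy <- withr::with_seed(23,
    ifelse(flank, 0.5 + 0.2 * cos(2 * pi * offs / 10.75) + rnorm(130, 0, 0.05),
           0.5))
  est <- withr::with_seed(24, estimate_period(noisy, w, n_shuffle = 200))
  expect_lt(abs(est$period - 10.75), 0.25)
  expect_true(est$significant)

  flat <- estimate_period(rep(0.5, 130), w, n_shuffle = 0)
  expect_true(is.na(flat$period))
  expect_false(flat$significant)
})

test_that("matrix TSV round-trips and consensus reads off the argmax", {
  ppm <- toy_ppm(width = 130, seed = 25)
  colnames(ppm) <- motif_window()$offsets
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(ppm, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, ppm, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(nchar(ppm_consensus(ppm)), 130)
  one_hot <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  one_hot["G", ] <- 1
  expect_equal(ppm_consensus(one_hot), "GGG")
})
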