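# shared fixtures: everything built in code, deterministic under withr seeds

random_genome <- function(n, seed = 1, circular = TRUE) {
  withr::with_seed(seed, {
    genome_seq(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     collapse = ""), circular = circular)
  })
}

# a small planted-site world used by several caller tests
small_sim_world <- function(seed = 11, L = 50000L, n_sites = 8L,
                            n_fragments = 5e4, signal_fraction = 0.5) {
  withr::with_seed(seed, {
    sites <- data.frame(p0 = sort(sample(100:(L - 800L), n_sites)),
                        weight = exp(stats::runif(n_sites, 0, log(10))))
    cfg <- sim_config(L, planted_sites = sites, n_fragments = n_fragments,
                      signal_fraction = signal_fraction)
    g <- simulate_genome(cfg)
    list(config = cfg, genome = g$genome, sites = sites)
  })
}

# profile built from an explicit fragment table on an all-A genome
profile_of <- function(frags, L = 100L, circular = TRUE) {
  count_read_ends(frags, genome_seq(strrep("A", L), circular = circular))
}

# quartet of four profiles over the same tiny genome
toy_quartet <- function(L = 100L, seed = 3) {
  withr::with_seed(seed, {
    g <- genome_seq(strrep("A", L))
    mk <- function(n) {
      s <- sample.int(L, n, replace = TRUE) - 1L
      count_read_ends(data.frame(start = s, end = s + 10L,
                                 orientation = sample(c("forward", "reverse"),
                                                      n, replace = TRUE)), g)
    }
    sample_quartet(mk(100), mk(200), mk(400), mk(50))
  })
}

# uniform-ish PPM with a distinctive consensus for scanning tests
toy_ppm <- function(width = 130L, seed = 5, peak = 0.7) {
  withr::with_seed(seed, {
    m <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
    hot <- sample.int(4, width, replace = TRUE)
    for (j in seq_len(width)) {
      m[, j] <- (1 - peak) / 3
      m[hot[j], j] <- peak
    }
    m
  })
}

draw_from_ppm <- function(ppm, n) {
  vapply(seq_len(n), function(k) {
    paste(vapply(seq_len(ncol(ppm)), function(j)
      sample(rownames(ppm), 1, prob = ppm[, j]), ""), collapse = "")
  }, "")
}

# brute-force per-window PWM scoring oracle (independent of scan_sequence)
oracle_window_score <- function(window_seq, pwm, bg = rep(0.25, 4)) {
  score <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(seq_along(ch), function(j) {
      if (ch[j] %in% rownames(pwm)) pwm[ch[j], j]
      else sum(bg * pwm[, j])
    }, 0))
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(window_seq, "")[[1]]),
                                     collapse = ""))
  max(score(window_seq), score(rc))
}
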