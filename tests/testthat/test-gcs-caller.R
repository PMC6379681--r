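test_that("library_scale matches the min-total arithmetic and is idempotent", {
  q <- toy_quartet()  # totals 100, 200, 400, 50
  s <- library_scale(q)
  expect_equal(vapply(s[quartet_roles], function(p) sum(combined_n3e(p)),
                      0), rep(50, 4), ignore_attr = TRUE)
  # scale factors 0.5, 0.25, 0.125, 1.0
  expect_equal(s$treated_ip$n3e_forward, q$treated_ip$n3e_forward * 0.5)
  expect_equal(s$untreated_mock$n3e_forward, q$untreated_mock$n3e_forward)
  s2 <- library_scale(s)
  expect_equal(s2, s)

  zero <- q
  zero$treated_mock$total_fragments <- 0
  expect_error(library_scale(zero), "treated_mock")
})

test_that("smooth_profile: identity, constants, impulse, mean preservation", {
  expect_equal(smooth_profile(c(4, 2, 9), 1), c(4, 2, 9))
  expect_equal(smooth_profile(rep(3.5, 50), 21), rep(3.5, 50))
  # circular impulse: height w spread over window w -> flat 1
  w <- 11
  v <- numeric(w); v[4] <- w
  expect_equal(smooth_profile(v, w, circular = TRUE), rep(1, w))
  x <- withr::with_seed(8, runif(101))
  expect_equal(mean(smooth_profile(x, 31, circular = TRUE)), mean(x))
  expect_error(smooth_profile(numeric(0), 5), "empty")
})

test_that("normalize_to_mock divides where the mock is informative and masks elsewhere", {
  r <- normalize_to_mock(c(2, 4), c(1, 2))
  expect_equal(r$values, c(2, 2))
  same <- normalize_to_mock(c(3, 3), c(3, 3))
  expect_equal(same$values, c(1, 1))
  del <- normalize_to_mock(c(5, 5), c(1, 0))
  expect_true(del$mask[2])
  expect_true(is.na(del$values[2]))
  expect_error(normalize_to_mock(c(1, 1), c(0, 0)), "unusable")
})

test_that("Audic-Claverie machinery matches the log-gamma formula and closed forms", {
  # independent oracle: the reference formula evaluated directly
  ref_pmf <- function(x, y, n1, n2) {
    r <- n2 / n1
    exp(y * log(r) + lfactorial(x + y) - lfactorial(x) - lfactorial(y) -
          (x + y + 1) * log(1 + r))
  }
  for (x in c(0, 1, 5, 20)) {
    expect_lt(abs(sum(ac_pmf(x, 0:3000, 1, 1)) - 1), 1e-9)
    for (y in c(0, 3, 17)) {
      expect_equal(ac_pmf(x, y, 3, 7), ref_pmf(x, y, 3, 7), tolerance = 1e-12)
      # tail equals the summed pmf
      expect_equal(ac_pvalue(x, y, 3, 7),
                   sum(ref_pmf(x, y:5000, 3, 7)), tolerance = 1e-9)
    }
  }
  expect_equal(ac_pmf(0, 0, 1, 1), 0.5)
  expect_equal(ac_pmf(5, 5, 1, 1), 252 / 2048)
  expect_equal(ac_min_significant(0, 1, 1, 0.0025), 9L)
  expect_equal(ac_pvalue(0, 8, 1, 1), 2^-8)
  expect_error(ac_min_significant(0, 1, 1, 1.5), "alpha")
})

test_that("call_gcs requires both walls and respects the minimal significant count", {
  L <- 200L
  ctl <- rep(0, L)
  mk_pair <- function(trt) list(treated_norm = trt, control_norm = ctl,
                                mask = rep(FALSE, L))
  trt <- rep(0, L); trt[51] <- 10; trt[56] <- 10  # i = 50, i+5 = 55 (0-based)
  calls <- call_gcs(mk_pair(trt), caller_config(), n1 = 100, n2 = 100)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$p0, 51)
  expect_equal(calls$left_wall, 50)
  expect_equal(calls$right_wall, 55)
  expect_equal(calls$n3e_strength, 10)

  # 10 >= 9 = minimal significant count at alpha 0.0025; 8 is not enough
  trt8 <- rep(0, L); trt8[51] <- 8; trt8[56] <- 8
  expect_equal(nrow(call_gcs(mk_pair(trt8), caller_config(),
                             n1 = 100, n2 = 100)), 0)

  one_wall <- rep(0, L); one_wall[51] <- 10
  expect_equal(nrow(call_gcs(mk_pair(one_wall), caller_config(),
                             n1 = 100, n2 = 100)), 0)

  flat <- rep(5, L)
  expect_equal(nrow(call_gcs(list(treated_norm = flat, control_norm = flat,
                                  mask = rep(FALSE, L)),
                             caller_config(), n1 = 100, n2 = 100)), 0)

  expect_error(caller_config(gap = 3), "4")
})

test_that("calling is monotone in treated signal and in alpha", {
  L <- 300L
  withr::with_seed(21, {
    ctl <- rpois(L, 1)
    trt <- rpois(L, 1)
  })
  trt[101] <- 14; trt[106] <- 14
  pair <- list(treated_norm = trt, control_norm = ctl, mask = rep(FALSE, L))
  base <- call_gcs(pair, caller_config(), n1 = 300, n2 = 300)
  # raise both walls: call set can only grow
  trt_up <- trt; trt_up[101] <- 30; trt_up[106] <- 30
  up <- call_gcs(list(treated_norm = trt_up, control_norm = ctl,
                      mask = rep(FALSE, L)),
                 caller_config(), n1 = 300, n2 = 300)
  expect_true(all(base$p0 %in% up$p0))
  # smaller alpha never adds a call
  tight <- call_gcs(pair, caller_config(alpha = 1e-5), n1 = 300, n2 = 300)
  expect_true(all(tight$p0 %in% base$p0))
})

test_that("rounded count policy rounds before testing", {
  L <- 100L
  trt <- rep(0, L); trt[11] <- 8.6; trt[16] <- 8.6
  pair <- list(treated_norm = trt, control_norm = rep(0, L),
               mask = rep(FALSE, L))
  cont <- call_gcs(pair, caller_config(count_policy = "continuous"),
                   n1 = 50, n2 = 50)
  rnd <- call_gcs(pair, caller_config(count_policy = "rounded"),
                  n1 = 50, n2 = 50)
  expect_equal(nrow(rnd), 1)          # rounds to 9 = minimal significant
  expect_equal(nrow(cont), 0)         # continuous tail at 8.6 is above alpha
})

test_that("merge_replicates keeps exact-coordinate majorities and averages strength", {
  mk <- function(p0s, str = 4) data.frame(
    left_wall = p0s - 1L, right_wall = p0s + 4L, p0 = p0s,
    n3e_strength = str, p_left = 1e-4, p_right = 1e-4)
  merged <- merge_replicates(list(mk(c(10, 50)), mk(10, str = 6), mk(99)), 2)
  expect_equal(merged$p0, 10)
  expect_equal(merged$n3e_strength, 5)  # mean(4, 6)
  expect_equal(merged$replicate_support, 2)
  expect_error(merge_replicates(list(mk(10)), 2), "replicate")
})

test_that("planted sites are recovered with 4-bp gaps at exact coordinates", {
  world <- small_sim_world(seed = 31)
  calls <- withr::with_seed(32, lapply(1:3, function(r) {
    sq <- simulate_quartet(world$genome, world$config, replicate = r)
    call_quartet(sq$quartet, caller_config())
  }))
  m <- merge_replicates(calls, 2)
  expect_gt(nrow(m), 0)
  expect_true(all(m$right_wall - m$left_wall == 5))
  expect_true(all(m$p0 %in% world$sites$p0))           # precision 1 here
  expect_true(all(world$sites$p0 %in% m$p0))           # recall 1 here
})

test_that("split-strand mode recovers the same planted sites", {
  world <- small_sim_world(seed = 41, n_sites = 5L)
  sq <- withr::with_seed(42,
    simulate_quartet(world$genome, world$config))
  calls <- call_quartet(sq$quartet, caller_config(strand_mode = "split"))
  expect_true(all(world$sites$p0 %in% calls$p0))
})

test_that("GCS BED round-trips", {
  g <- random_genome(200, seed = 6)
  calls <- data.frame(left_wall = c(9, 49), right_wall = c(14, 54),
                      p0 = c(10, 50), n3e_strength = c(4.5, 2.0),
                      p_left = c(1e-5, 1e-4), p_right = c(2e-5, 3e-4),
                      replicate_support = c(3L, 2L))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gcs_bed(calls, g, bed)
  back <- read_gcs_bed(bed)
  expect_equal(back$p0, calls$p0)
  expect_equal(back$n3e_strength, calls$n3e_strength)
  expect_equal(back$replicate_support, calls$replicate_support)
})
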