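test_that("pre/post counting separates clonal multiplicities and
           subclonal mutations", {
  calls <- data.frame(m = c(rep(2L, 10), rep(1L, 20), rep(1L, 5)),
                      clonal = c(rep(TRUE, 30), rep(FALSE, 5)))
  cc <- count_pre_post(calls, major = 2)
  expect_equal(cc, list(n_pre = 10, n_post = 20, n_subclonal = 5))
  # clock filter restricts the counts
  clock <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 25))
  cc2 <- count_pre_post(calls, major = 2, clock = clock)
  expect_equal(cc2$n_pre, 5)
  expect_error(count_pre_post(calls, major = 1), "not gained")
})

test_that("molecular time closed forms hit the boundary and worked
           examples", {
  expect_equal(molecular_time(0, 100, 2, 0)$pi, 0)
  expect_equal(molecular_time(50, 0, 2, 0)$pi, 1)
  expect_equal(molecular_time(30, 140, 2, 0)$pi, 0.3)
  expect_equal(molecular_time(20, 60, 2, 1)$pi, 3 * 20 / (2 * 20 + 60))
  expect_equal(molecular_time(30, 140, 2, 2)$pi, 0.3)
  # (2,1) can overflow: capped at 1 with a flag
  ov <- molecular_time(100, 50, 2, 1)
  expect_equal(ov$pi, 1)
  expect_true("overflow" %in% ov$flags)
  expect_true("low_confidence" %in% molecular_time(3, 4, 2, 0)$flags)
  expect_error(molecular_time(10, 10, 3, 0), "unsupported")
})

test_that("molecular time is monotone in the pre-gain count and stays
           in [0,1]", {
  for (state in list(c(2, 0), c(2, 1), c(2, 2))) {
    pis <- vapply(0:50, function(n2)
      molecular_time(n2, 30, state[1], state[2], min_count = 0)$pi,
      numeric(1))
    expect_true(all(diff(pis) >= 0))
    expect_true(all(pis >= 0 & pis <= 1))
  }
})

test_that("closed forms agree with forward lineage simulation", {
  set.seed(77)
  for (state in list(c(2, 0), c(2, 1), c(2, 2))) {
    for (pi_true in c(0.2, 0.5, 0.8)) {
      cc <- lineage_forward_sim(state[1], state[2], pi_true)
      pi_hat <- molecular_time(cc$n2, cc$n1, state[1], state[2])$pi
      expect_equal(pi_hat, pi_true, tolerance = 0.02,
                   label = sprintf("(%d,%d) pi=%.1f", state[1],
                                   state[2], pi_true))
    }
  }
})

test_that("bootstrap CI is deterministic under a seed and degenerate on
           all-pre-gain input", {
  calls <- data.frame(m = rep(2L, 40), clonal = TRUE)
  ci <- bootstrap_ci(calls, 2, 0, B = 50, seed = 3)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  calls2 <- data.frame(m = c(rep(2L, 15), rep(1L, 25)), clonal = TRUE)
  a <- bootstrap_ci(calls2, 2, 0, B = 100, seed = 42)
  b <- bootstrap_ci(calls2, 2, 0, B = 100, seed = 42)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$ci_high)
  tiny <- data.frame(m = 2L, clonal = TRUE)
  expect_equal(bootstrap_ci(tiny, 2, 0, B = 10)$flags, "undefined_ci")
})

test_that("ML mixture estimator and its bootstrap agree with planted
           truth on one simulated tumor", {
  sim <- sim_one_segment(2, 0, 0.4, n = 2000, seed = 15)
  calls <- assign_multiplicity(sim$snvs$tumor_alt, sim$snvs$tumor_depth,
                               0.7, 2, 2)
  tg <- time_gain(calls, 2, 0, B = 100, seed = 2,
                  tumor_alt = sim$snvs$tumor_alt,
                  tumor_depth = sim$snvs$tumor_depth, purity = 0.7)
  expect_equal(tg$method, "ml")
  expect_equal(tg$pi, 0.4, tolerance = 0.05)
  expect_true(tg$ci_low <= tg$pi && tg$pi <= tg$ci_high)
  # without read counts the wrapper falls back to hard counting
  tg2 <- time_gain(calls, 2, 0, B = 50, seed = 2)
  expect_equal(tg2$method, "counts")
  expect_equal(tg2$pi, 0.4, tolerance = 0.08)
})

test_that("first gain over the locus is the earliest one", {
  mk <- function(chrom, start, end, major, minor, pi) {
    list(segment = data.frame(chrom = chrom, start = start, end = end,
                              major = major, minor = minor),
         timing = structure(list(pi = pi), class = "gain_timing"))
  }
  locus <- tp53_locus()
  ts <- list(mk("17", 0, 81195210, 2, 0, 0.6),
             mk("17", 7e6, 9e6, 2, 1, 0.2),
             mk("3", 0, 1e8, 2, 0, 0.05))
  expect_equal(first_gain_time_over_locus(ts, locus)$timing$pi, 0.2)
  expect_equal(first_gain_time_over_locus(ts[1], locus)$timing$pi, 0.6)
  expect_message(res <- first_gain_time_over_locus(ts[3], locus),
                 "no timed gain")
  expect_null(res)
})

test_that("group comparison reproduces exact rank-sum enumeration", {
  expect_equal(compare_timing_groups(c(0.1, 0.2, 0.3),
                                     c(0.1, 0.2, 0.3))$p_value, 1.0)
  # 3 vs 3 complete separation: enumerate all C(6,3) = 20 assignments
  x <- c(0.1, 0.2, 0.3); y <- c(0.7, 0.8, 0.9)
  obs_w <- sum(rank(c(x, y))[1:3])
  combos <- combn(6, 3)
  ws <- apply(combos, 2, function(idx) sum(rank(c(x, y))[idx]))
  p_enum <- 2 * min(mean(ws <= obs_w), mean(ws >= obs_w))
  expect_equal(compare_timing_groups(x, y)$p_value, 0.1)
  expect_equal(p_enum, 0.1)
  expect_error(compare_timing_groups(numeric(0), y), "non-empty")
})

test_that("age correlation handles perfect, inverted and degenerate
           inputs", {
  t <- c(0.1, 0.3, 0.5, 0.7)
  expect_equal(correlate_age(t, 2 * t + 1)$r, 1)
  expect_equal(correlate_age(t, -t)$r, -1)
  z <- correlate_age(rep(0.5, 4), t)
  expect_equal(z$flag, "zero_variance")
  expect_error(correlate_age(t[1:2], t[1:2]), "at least 3")
})

test_that("null-distributed correlations show no systematic signal", {
  set.seed(99)
  ps <- replicate(200, {
    correlate_age(runif(30), runif(30))$p_value
  })
  expect_gt(mean(ps < 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps < 0.05), 0.12)   # ~5% expected under the null
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("chronological bound scales molecular clock time by age", {
  expect_equal(chronological_bound(50, 0, 2, 0, age_at_dx = 8)$
                 age_at_gain_years, 8)
  expect_equal(chronological_bound(0, 60, 2, 0, age_at_dx = 8)$
                 age_at_gain_years, 0)
  expect_message(res <- chronological_bound(0, 0, 2, 0, age_at_dx = 8),
                 "no clock")
  expect_null(res)
  # gain planted at 20% of mutational history, age 10 -> about 2 years
  sim <- sim_one_segment(2, 0, 0.2, n = 3000, seed = 31)
  calls <- assign_multiplicity(sim$snvs$tumor_alt, sim$snvs$tumor_depth,
                               0.7, 2, 2)
  cc <- count_pre_post(calls, 2)
  cb <- chronological_bound(cc$n_pre, cc$n_post, 2, 0, age_at_dx = 10)
  expect_equal(cb$age_at_gain_years, 2, tolerance = 0.5)
  expect_equal(cb$assumption, "linear-clock")
})
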