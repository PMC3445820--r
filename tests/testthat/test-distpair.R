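# Distribution-pair construction, moments, sampling, and P(X < Y).

FULL_GRID <- expand.grid(family = c("gamma", "lognormal"),
                         skewness = skew_grid(), sd_ratio = sd_ratio_grid(),
                         stringsAsFactors = FALSE)

test_that("gamma shape and lognormal sigma solve the skewness equations", {
  # closed form k = (2/gamma1)^2
  expect_equal(solve_gamma_shape(2), 1)        # exponential
  expect_equal(solve_gamma_shape(1), 4)
  expect_equal(solve_gamma_shape(4), 0.25)
  # (w+2)^2 (w-1) = 16 has exact root w = 2
  expect_equal(solve_lognormal_sigma(4), sqrt(log(2)), tolerance = 1e-12)
  # against an independent bisection oracle on the same skewness equation
  for (s in c(0.5, 1, 2, 3, 4, 10, 50)) {
    expect_equal(solve_lognormal_sigma(s), oracle_lognormal_sigma(s),
                 tolerance = 1e-9)
  }
  # symmetric limit: sigma -> 0 as skewness -> 0+
  expect_lt(solve_lognormal_sigma(1e-4), 0.01)
  for (bad in list(0, -1, NA_real_, "a", c(1, 2))) {
    expect_error(solve_gamma_shape(bad))
    expect_error(solve_lognormal_sigma(bad))
  }
})

test_that("pairs are mean-matched, skewness-matched, and SD-ratio exact", {
  for (i in seq_len(nrow(FULL_GRID))) {
    p <- make_pair(FULL_GRID$family[i], FULL_GRID$skewness[i],
                   FULL_GRID$sd_ratio[i])
    expect_equal(member_mean(p$x), member_mean(p$y), tolerance = 1e-12)
    expect_equal(member_sd(p$y), 1, tolerance = 1e-12)
    expect_equal(member_sd(p$x) / member_sd(p$y), FULL_GRID$sd_ratio[i],
                 tolerance = 1e-12)
    # exact by construction: shared shape parameter
    expect_identical(p$x$shape, p$y$shape)
    expect_equal(member_skewness(p$x), FULL_GRID$skewness[i], tolerance = 1e-9)
    expect_equal(member_skewness(p$y), member_skewness(p$x))
  }
  # sd_ratio = 1: X and Y are the same distribution
  p1 <- make_pair("gamma", 2.5, 1)
  expect_identical(unclass(p1$x), unclass(p1$y))
  expect_error(make_pair("weibull", 1, 1.1), "family")
  expect_error(make_pair("gamma", 1, 0.9), "sd_ratio")
})

test_that("analytic moments agree with Monte Carlo draws", {
  # moment closure, scaled down from the 64-cell 1e7-draw version for the
  # unit suite: 4 corner pairs x 4e5 draws, batch-based MC standard errors
  set.seed(4821)
  cases <- list(c("gamma", 1, 1.05), c("gamma", 4, 1.5),
                c("lognormal", 1, 1.05), c("lognormal", 4, 1.5))
  for (cs in cases) {
    p <- make_pair(cs[1], as.numeric(cs[2]), as.numeric(cs[3]))
    s <- sample_pair(p, 4e5)
    for (member in list(p$x, p$y)) {
      v <- if (identical(member, p$x)) s$x else s$y
      bm <- batch_estimate(v, 40, mean)
      expect_lt(abs(bm$est - member_mean(member)), 4 * bm$se)
      bs <- batch_estimate(v, 40, sd)
      expect_lt(abs(bs$est - member_sd(member)), 5 * bs$se)
      bk <- batch_estimate(v, 40, sample_skewness)
      # batch skewness is slightly biased low at batch size 1e4; allow 6 SE
      expect_lt(abs(bk$est - member_skewness(member)), 6 * bk$se)
    }
  }
})

test_that("sample_pair is deterministic and respects the pair law", {
  p <- make_pair("lognormal", 2, 1.25)
  set.seed(99); a <- sample_pair(p, 1000)
  set.seed(99); b <- sample_pair(p, 1000)
  expect_identical(a, b)
  expect_error(sample_pair(p, 0), "positive integer")
  # sd_ratio = 1: the two arrays share one distribution
  p1 <- make_pair("gamma", 3, 1)
  set.seed(7); s <- sample_pair(p1, 2e4)
  expect_gt(suppressWarnings(ks.test(s$x, s$y))$p.value, 0.001)
})

test_that("member pdf/cdf/quantile are coherent", {
  members <- list(dist_member("gamma", 1, 1, 0),          # exponential
                  dist_member("gamma", 0.25, 2, -1),      # singular at shift
                  dist_member("lognormal", 0.8, 1.5, 2))
  for (m in members) {
    lo <- member_quantile(m, 1e-12); hi <- member_quantile(m, 1 - 1e-12)
    expect_equal(integrate(function(t) member_pdf(m, t), lo, hi,
                           rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
    expect_equal(member_cdf(m, member_quantile(m, c(.1, .5, .9))),
                 c(.1, .5, .9), tolerance = 1e-10)
    expect_equal(member_cdf(m, -1e12), 0)
    expect_equal(member_cdf(m, 1e12), 1)
  }
  # exponential closed form
  t <- c(0.1, 1, 5)
  expect_equal(member_pdf(members[[1]], t), exp(-t), tolerance = 1e-12)
  # lognormal median = shift + scale
  m <- members[[3]]
  expect_equal(member_cdf(m, m$shift + m$scale), 0.5, tolerance = 1e-12)
})

test_that("prob_x_less_y matches oracle values and is well behaved", {
  # frozen values from an independent adaptive-quadrature oracle run in
  # t-space (scipy.integrate.quad on f_X (1 - F_Y), epsabs 1e-12)
  oracle <- list(list("gamma", 3, 1.10, 0.5552777211),
                 list("gamma", 4, 1.50, 0.6785772466),
                 list("lognormal", 3, 1.10, 0.5174170470),
                 list("gamma", 1, 1.05, 0.5038063042),
                 list("lognormal", 4, 1.25, 0.5481619969))
  for (o in oracle) {
    expect_equal(prob_x_less_y(make_pair(o[[1]], o[[2]], o[[3]])), o[[4]],
                 tolerance = 1e-7)
  }
  # identical distributions: exactly 1/2
  for (fam in c("gamma", "lognormal")) {
    for (s in c(1, 4)) {
      expect_equal(prob_x_less_y(make_pair(fam, s, 1)), 0.5,
                   tolerance = 1e-8)
    }
  }
  # nondecreasing in the SD ratio at fixed family and skewness
  for (fam in c("gamma", "lognormal")) {
    for (s in c(1, 4)) {
      probs <- vapply(sd_ratio_grid(),
                      function(r) prob_x_less_y(make_pair(fam, s, r)),
                      numeric(1))
      expect_true(all(diff(probs) > 0))
    }
  }
})

test_that("prob_x_less_y agrees with paired Monte Carlo draws", {
  # spot-check of the quadrature against direct sampling (the full 64-cell
  # sweep runs in the acceptance suite)
  set.seed(3141)
  for (cs in list(c("gamma", 3, 1.10), c("lognormal", 2, 1.4))) {
    p <- make_pair(cs[1], as.numeric(cs[2]), as.numeric(cs[3]))
    s <- sample_pair(p, 2e6)
    est <- mean(s$x < s$y)
    se <- sqrt(est * (1 - est) / 2e6)
    expect_lt(abs(est - prob_x_less_y(p)), 3 * se)
  }
})
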