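test_that("single-component EM equals the closed-form inverse-variance mean", {
  f <- fit_mixture(c(10, 20), c(1, 1), 1, seed = 1)
  expect_equal(f$means, 15, tolerance = 1e-10)
  expect_equal(f$weights, 1)
  f2 <- fit_mixture(c(10, 20), c(1, 2), 1, seed = 1)
  expect_equal(f2$means, 12, tolerance = 1e-10)  # (10/1 + 20/4)/(1 + 1/4)
  # random instances against the closed form
  set.seed(42)
  for (i in 1:10) {
    x <- runif(8, 0, 100); s <- runif(8, 0.5, 3)
    f <- fit_mixture(x, s, 1)
    expect_equal(f$means, sum(x / s^2) / sum(1 / s^2), tolerance = 1e-10)
  }
})

test_that("EM log-likelihood is monotone non-decreasing every iteration", {
  set.seed(7)
  x <- c(rnorm(20, 20, 1), rnorm(20, 60, 1))
  s <- runif(40, 0.5, 2)
  for (k in 1:4) {
    f <- fit_mixture(x, s, k, n_starts = 5, seed = k)
    expect_true(all(diff(f$loglik_trace) >= -1e-10))
  }
})

test_that("two well-separated loci are recovered with higher loglik than one", {
  set.seed(5)
  x <- c(rnorm(20, 20, 1), rnorm(20, 60, 1))
  s <- rep(1, 40)
  f2 <- fit_mixture(x, s, 2, seed = 9)
  f1 <- fit_mixture(x, s, 1, seed = 9)
  expect_lt(abs(f2$means[1] - 20), 0.5)
  expect_lt(abs(f2$means[2] - 60), 0.5)
  expect_gt(f2$loglik, f1$loglik)
})

test_that("K=2 EM reaches at least the grid-search likelihood on small instances", {
  set.seed(31)
  for (rep in 1:3) {
    x <- c(rnorm(5, 10, 1), rnorm(5, 30, 1))
    s <- runif(10, 0.8, 1.5)
    f <- fit_mixture(x, s, 2, seed = rep)
    expect_gte(f$loglik, oracle_grid_k2(x, s) - 1e-6)
  }
})

test_that("mixture fit rejects invalid inputs", {
  expect_error(fit_mixture(c(1, 2), c(1, 1), 3), "k must")
  expect_error(fit_mixture(c(1, NA), c(1, 1), 1), "non-finite")
  expect_error(fit_mixture(c(1, 2), c(1, 0), 1), "sds must")
})

test_that("information criteria reproduce hand arithmetic", {
  fake <- list(k = 2L, loglik = -10,
               responsibilities = matrix(c(1, 0, 0, 1), 2, 2))
  ic <- information_criteria(fake, n_obs = 20)
  expect_equal(ic$p_free, 3L)
  expect_equal(ic$aic, 26)
  expect_equal(ic$aicc, 27.5)
  expect_equal(ic$aic3, 29)
  expect_equal(ic$bic, 20 + 3 * log(20))
  # hard responsibilities: entropy term vanishes in AWE
  expect_equal(ic$awe, 20 + 2 * 3 * (1.5 + log(20)))
  # K = 1: responsibilities are 1, lnL_c = lnL
  one <- list(k = 1L, loglik = -10, responsibilities = matrix(1, 20, 1))
  ic1 <- information_criteria(one, n_obs = 20)
  expect_equal(ic1$awe, 20 + 2 * 1 * (1.5 + log(20)))
  expect_warning(
    icbad <- information_criteria(fake, n_obs = 4), "AICc")
  expect_equal(icbad$aicc, Inf)
})

test_that("model selection follows the three-of-five rule and tie-breaks", {
  mk <- function(aic, aicc, aic3, bic, awe) {
    ks <- seq_along(aic)
    data.frame(k = ks, aic = aic, aicc = aicc, aic3 = aic3, bic = bic,
               awe = awe)
  }
  # unanimity at K = 3
  rows <- mk(c(3, 2, 1), c(3, 2, 1), c(3, 2, 1), c(3, 2, 1), c(3, 2, 1))
  expect_equal(as.integer(select_model(rows)), 3L)
  # 3 of 5 minima at K = 2 beats 2 at K = 1
  rows <- mk(c(2, 1), c(2, 1), c(2, 1), c(1, 2), c(1, 2))
  expect_equal(as.integer(select_model(rows)), 2L)
  # counts {K2: 2, K3: 2, K1: 1} -> smallest K among the max holders
  rows <- mk(c(3, 1, 2), c(3, 1, 2), c(3, 2, 1), c(3, 2, 1), c(1, 2, 3))
  expect_equal(as.integer(select_model(rows)), 2L)
  expect_error(select_model(NULL), "empty")
  # a K strictly minimizing everything wins
  rows <- mk(c(5, 1, 9), c(5, 1, 9), c(5, 1, 9), c(5, 1, 9), c(5, 1, 9))
  expect_equal(as.integer(select_model(rows)), 2L)
})

test_that("membership needs >60% probability and the peak inside the MQTL CI", {
  f <- structure(list(k = 2L, means = c(10, 20), weights = c(0.5, 0.5),
                      loglik = 0,
                      responsibilities = matrix(c(0.61, 0.50, 0.39, 0.50),
                                                2, 2)),
                 class = "mixture_fit")
  asg <- assign_members(f, positions = c(10, 15), sds = c(1, 1),
                        qtl_ids = c("a", "b"))
  expect_equal(asg$assignments$qtl_id, "a")
  expect_equal(asg$unassigned, "b")  # 0.50 fails the strict threshold
  # K = 1: responsibility 1, always assigned
  f1 <- structure(list(k = 1L, means = 10, weights = 1, loglik = 0,
                       responsibilities = matrix(1, 1, 1)),
                  class = "mixture_fit")
  asg1 <- assign_members(f1, 10, 1, "solo")
  expect_equal(asg1$assignments$qtl_id, "solo")
  # peak outside the pooled CI is rejected even with high membership
  f2 <- structure(list(k = 1L, means = 10, weights = 1, loglik = 0,
                       responsibilities = matrix(1, 3, 1)),
                  class = "mixture_fit")
  asg2 <- assign_members(f2, positions = c(10, 10.1, 30),
                         sds = c(0.1, 0.1, 0.1),
                         qtl_ids = c("a", "b", "far"))
  expect_true("far" %in% asg2$unassigned)
  expect_setequal(asg2$assignments$qtl_id, c("a", "b"))
})

test_that("MQTL summaries pool members by inverse variance", {
  sm <- mqtl_summary(50, 2)
  expect_equal(sm$ci_low_cm, 50 - 3.92)
  expect_equal(sm$ci_high_cm, 50 + 3.92)
  sm2 <- mqtl_summary(c(10, 14), c(1, 1))
  expect_equal(sm2$peak_cm, 12)
  expect_equal(sm2$sd_cm, 1 / sqrt(2))
  # five members at sd 2: pooled CI width shrinks by sqrt(5)
  sm5 <- mqtl_summary(rep(8, 5), rep(2, 5))
  expect_equal(sm5$ci_high_cm - sm5$ci_low_cm, 2 * 1.96 * 2 / sqrt(5))
  expect_lt(sm5$ci_high_cm - sm5$ci_low_cm, 7.84)
})

test_that("chromosome runs pick the candidate K grid from the QTL count", {
  # n = 1: degenerate, K = 1, MQTL = that QTL
  pr1 <- data.frame(qtl_id = "q1", chr = 1L, position_cm = 30, sd_cm = 1.5)
  res1 <- suppressWarnings(run_chromosome(pr1, seed = 1))  # AICc undefined at n=1
  expect_equal(res1$k, 1L)
  expect_equal(res1$mqtls$n_members, 1L)
  expect_equal(res1$mqtls$peak_cm, 30)
  # n = 8: candidate Ks are 1..4
  set.seed(2)
  pr8 <- data.frame(qtl_id = sprintf("q%d", 1:8), chr = 1L,
                    position_cm = c(rnorm(4, 20, 1), rnorm(4, 70, 1)),
                    sd_cm = runif(8, 0.5, 1.5))
  res8 <- suppressWarnings(run_chromosome(pr8, seed = 3))
  expect_equal(sort(res8$criteria$k), 1:4)
  # n = 0: empty, no error
  res0 <- run_chromosome(pr1[0, ])
  expect_equal(res0$k, 0L)
  expect_equal(nrow(res0$mqtls), 0L)
})

test_that("planted loci are recovered and MQTL CIs shrink below member CIs", {
  fx <- make_projected_panel(seed = 19)
  res <- suppressWarnings(run_chromosome(fx$projected, seed = 19))
  expect_equal(res$k, 3L)
  expect_true(all(abs(sort(res$fit$means) - c(20, 60, 100)) < 1))
  mean_member_ci <- mean(fx$projected$ci_high_cm - fx$projected$ci_low_cm)
  mean_mqtl_ci <- mean(res$mqtls$ci_high_cm - res$mqtls$ci_low_cm)
  expect_lt(mean_mqtl_ci, mean_member_ci)
  # every assigned membership respects both rules
  expect_true(all(res$membership$membership > 0.60))
})

test_that("overview index bins hold per-QTL probability mass", {
  # near-point mass centred in one bin
  pr <- data.frame(qtl_id = "q", chr = 1L, position_cm = 5.25, sd_cm = 0.01,
                   ci_low_cm = 5.2, ci_high_cm = 5.3)
  oi <- overview_index(pr, span = c(0, 10), bin_width_cm = 0.5)
  expect_equal(sum(oi$index), 1, tolerance = 1e-6)
  expect_equal(max(oi$index), 1, tolerance = 1e-6)
  expect_equal(oi$start_cm[which.max(oi$index)], 5.0)
  # QTL centred exactly on a bin edge: two adjacent bins get ~0.5 each
  pr$position_cm <- 5.0; pr$sd_cm <- 0.05
  oi <- overview_index(pr, span = c(0, 10), bin_width_cm = 0.5)
  top2 <- sort(oi$index, decreasing = TRUE)[1:2]
  expect_equal(top2, c(0.5, 0.5), tolerance = 1e-3)
  # mixed sds agree with a quadrature oracle
  pr3 <- data.frame(qtl_id = c("a", "b", "c"), chr = 1L,
                    position_cm = c(3, 5.1, 7.7), sd_cm = c(0.4, 1.1, 0.2),
                    ci_low_cm = 0, ci_high_cm = 10)
  oi3 <- overview_index(pr3, span = c(0, 10), bin_width_cm = 0.5)
  for (b in seq_len(nrow(oi3))) {
    quad <- sum(vapply(1:3, function(i)
      stats::integrate(dnorm, oi3$start_cm[b], oi3$end_cm[b],
                       mean = pr3$position_cm[i],
                       sd = pr3$sd_cm[i])$value, numeric(1))) / 3
    expect_equal(oi3$index[b], quad, tolerance = 1e-6)
  }
  # per-QTL mass over all bins never exceeds 1
  expect_lte(sum(oi3$index), 1 + 1e-9)
})
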