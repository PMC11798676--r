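mini_scheme <- function(k) {
  # tiny ad-hoc scheme for hand-checkable likelihood cases
  structure(list(name = sprintf("MINI%d", k),
                 labels = paste0("ch", seq_len(k)), k = k),
            class = "channel_scheme")
}
mini_spectrum <- function(counts)
  spectrum(counts, mini_scheme(length(counts)), "mini")
mini_expected <- function(values)
  structure(list(values = values, pi = values / sum(values)),
            class = "expected_counts")

test_that("expected_counts is the matrix product H x A", {
  # single signature, activity 100 -> 100 * h
  ec <- expected_counts(cat6, c(TS01 = 100))
  expect_equal(unname(ec$values), unname(100 * cat6$matrix[, "TS01"]))
  expect_equal(sum(ec$pi), 1, tolerance = 1e-9)
  # empty attribution -> zeros
  ec0 <- expected_counts(cat6, attribution())
  expect_true(all(ec0$values == 0))
  # hand matrix product: h1 = (.5,.5), h2 = (1,0), a = (10,10) -> (15,5)
  sc <- mini_scheme(2)
  H <- matrix(c(0.5, 0.5, 1, 0), 2, 2,
              dimnames = list(sc$labels, c("s1", "s2")))
  cat2 <- signature_catalog(H, scheme = sc)
  expect_equal(unname(expected_counts(cat2, c(s1 = 10, s2 = 10))$values),
               c(15, 5))
  expect_error(expected_counts(cat6, c(NOPE = 1)), "unknown")
})

test_that("multinomial log-likelihood matches closed forms", {
  # d = (3,0), pi ~ (1,0): probability ~1 (up to the floor)
  expect_equal(multinomial_loglik(mini_spectrum(c(3, 0)),
                                  mini_expected(c(1, 0))),
               0, tolerance = 1e-6)
  # d = (1,1), pi = (1/2,1/2): pmf = 2 * 0.25 = 0.5
  expect_equal(multinomial_loglik(mini_spectrum(c(1, 1)),
                                  mini_expected(c(0.5, 0.5))),
               log(0.5), tolerance = 1e-12)
  # MLE property: pi = empirical proportions maximizes the log-likelihood
  set.seed(11)
  d <- rpois(8, 20) + 1
  sp <- mini_spectrum(d)
  best <- multinomial_loglik(sp, mini_expected(d / sum(d)))
  for (i in 1:25) {
    pi_alt <- rgamma(8, 1); pi_alt <- pi_alt / sum(pi_alt)
    expect_lte(multinomial_loglik(sp, mini_expected(pi_alt)), best + 1e-9)
  }
  # scale invariance: only proportions matter
  expect_equal(multinomial_loglik(sp, mini_expected(d * 37.5)),
               best, tolerance = 1e-9)
})

test_that("negative-binomial log-likelihood limits and maxima", {
  set.seed(12)
  d <- rpois(10, 15)
  sp <- mini_spectrum(d)
  cvals <- d + runif(10, -2, 2); cvals <- pmax(cvals, 0.1)
  # Poisson limit as size -> Inf
  nb <- negbinom_loglik(sp, mini_expected(cvals), dispersion = 1e8)
  pois <- sum(dpois(d, cvals, log = TRUE))
  expect_equal(nb, pois, tolerance = 1e-4)
  # per-channel term maximized at c_i = d_i (grid search oracle)
  di <- 7
  grid <- seq(0.5, 20, by = 0.1)
  terms <- dnbinom(di, size = 50, mu = grid, log = TRUE)
  expect_equal(grid[which.max(terms)], di, tolerance = 0.05)
  # all-zero spectrum with tiny means: log-likelihood near 0 from below
  sp0 <- mini_spectrum(rep(0, 5))
  ll0 <- negbinom_loglik(sp0, mini_expected(rep(1e-9, 5)), dispersion = 100)
  expect_lt(ll0, 0)
  expect_gt(ll0, -1e-6)
})

test_that("likelihood ratio test matches chi-square references", {
  r <- likelihood_ratio_test(-100, -100, df = 1)
  expect_equal(r$lambda, 0)
  expect_equal(r$p_value, 1.0)
  # lambda = 3.841, df = 1 -> p ~ 0.05 (chi-square quantile)
  expect_equal(likelihood_ratio_test(-101.9205, -100, df = 1)$p_value,
               0.05, tolerance = 1e-3)
  # df = 2 closed form: p = exp(-lambda/2)
  expect_equal(likelihood_ratio_test(-105, -100, df = 2)$p_value,
               exp(-5), tolerance = 1e-12)
  # clamping of negative lambda from optimizer noise
  expect_equal(likelihood_ratio_test(-99.9999, -100, df = 1)$lambda, 0)
  expect_error(likelihood_ratio_test(-1, 0, df = 0), "df")
  # p monotone decreasing in lambda for fixed df
  lams <- seq(0, 20, by = 0.5)
  ps <- vapply(lams, function(l)
    likelihood_ratio_test(-l / 2, 0, df = 1)$p_value, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("nested maximized models give non-negative lambda", {
  set.seed(13)
  for (i in 1:10) {
    truth <- c(TS01 = runif(1, 500, 3000), TS02 = runif(1, 500, 3000))
    sp <- sampled_spectrum(cat6, truth)
    sub <- mle_fit(sp, restrict_catalog(cat6, c("TS01", "TS02")),
                   "multinomial")
    full <- mle_fit(sp, restrict_catalog(cat6, c("TS01", "TS02", "TS03")),
                    "multinomial")
    expect_gte(full$objective, sub$objective - 1e-6)
  }
})
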