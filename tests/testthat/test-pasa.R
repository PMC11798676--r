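test_that("presence filter keeps needed signatures and is order-invariant", {
  set.seed(31)
  sp <- sampled_spectrum(cat4, c(TS01 = 1000))
  s1 <- presence_filter(sp, cat4)
  expect_true("TS01" %in% s1$survivors)
  report_ts01 <- s1$reports[[which(cat4$names == "TS01")]]
  expect_lt(report_ts01$lrt$p_value, 0.01)

  # permutation of catalog columns leaves the survivor set unchanged
  perm <- c("TS03", "TS01", "TS04", "TS02")
  s1p <- presence_filter(sp, restrict_catalog(cat4, perm))
  expect_setequal(s1p$survivors, s1$survivors)

  # single-signature catalog: retained without testing
  s1one <- presence_filter(sp, restrict_catalog(cat4, "TS02"))
  expect_equal(s1one$survivors, "TS02")
})

test_that("duplicate signatures are individually unnecessary and dropped", {
  m <- cbind(cat4$matrix, DUP1 = cat4$matrix[, "TS01"])
  colnames(m)[1] <- "TS01"
  catdup <- signature_catalog(m, scheme = sc96)
  set.seed(32)
  sp <- sampled_spectrum(cat4, c(TS01 = 3000, TS02 = 1000))
  s1 <- presence_filter(sp, catdup)
  expect_false("TS01" %in% s1$survivors)
  expect_false("DUP1" %in% s1$survivors)
  expect_true("TS02" %in% s1$survivors)
})

test_that("forward search selects the generating set", {
  # forced single survivor
  set.seed(33)
  sp1 <- sampled_spectrum(cat6, c(TS03 = 2000))
  fs1 <- forward_search(sp1, restrict_catalog(cat6, "TS03"))
  expect_equal(names(fs1$attribution$activities), "TS03")
  expect_equal(unname(fs1$attribution$activities), sp1$total,
               tolerance = 0.02 * sp1$total)

  # two near-orthogonal signatures among six survivors
  sp2 <- sampled_spectrum(cat6, c(TS01 = 5000, TS02 = 5000))
  fs2 <- forward_search(sp2, cat6)
  expect_setequal(names(fs2$attribution$activities), c("TS01", "TS02"))
  # every addition after the first is significant
  tr <- fs2$addition_trace
  expect_true(is.na(tr$p_value[1]))
  if (nrow(tr) > 1) expect_true(all(tr$p_value[-1] < 0.01))

  # exhaustive check: greedy set matches the best same-size subset
  best_ll <- -Inf; best_set <- NULL
  for (s in combn(cat6$names, 2, simplify = FALSE)) {
    ll <- mle_fit(sp2, restrict_catalog(cat6, s), "negbinom")$objective
    if (ll > best_ll) { best_ll <- ll; best_set <- s }
  }
  expect_setequal(names(fs2$attribution$activities), best_set)
})

test_that("attribute handles degenerate and exact inputs", {
  sp0 <- spectrum(setNames(rep(0, 96), sc96$labels), sc96, "empty")
  expect_warning(res0 <- attribute(sp0, cat6), "zero-count")
  expect_length(res0$attribution$activities, 0)

  spx <- exact_spectrum(cat6, c(TS04 = 20000))
  resx <- attribute(spx, cat6)
  expect_equal(names(resx$attribution$activities), "TS04")
  expect_gt(resx$reconstruction_cosine, 0.999)
})

test_that("standalone presence test agrees with the filter", {
  set.seed(34)
  sp <- sampled_spectrum(cat4, c(TS02 = 8000))
  s1 <- presence_filter(sp, cat4)
  for (sig in cat4$names) {
    rep_i <- signature_presence_test(sp, cat4, sig)
    filt_i <- s1$reports[[which(cat4$names == sig)]]
    expect_equal(rep_i$retained, filt_i$retained)
    expect_equal(rep_i$lrt$p_value, filt_i$lrt$p_value, tolerance = 1e-6)
  }
  # sole generating signature with 10^4 mutations: decisive
  expect_lt(signature_presence_test(sp, cat4, "TS02")$lrt$p_value, 1e-6)
  expect_error(signature_presence_test(sp, cat4, "NOPE"), "unknown")
})

test_that("attribution results are deterministic and sparse", {
  set.seed(35)
  sp <- sampled_spectrum(cat6, c(TS01 = 4000, TS05 = 1200))
  r1 <- attribute(sp, cat6)
  r2 <- attribute(sp, cat6)
  expect_identical(r1$attribution$activities, r2$attribution$activities)
  expect_identical(r1$addition_trace, r2$addition_trace)
  expect_lte(length(r1$attribution$activities), length(cat6$names))
  # reconstruction stored on the result matches expected_counts
  expect_equal(r1$reconstruction$values,
               expected_counts(cat6, r1$attribution)$values)
  # greedy improvement: cosine of the final set >= cosine of prefixes
  prefix <- r1$addition_trace$signature
  cosines <- vapply(seq_along(prefix), function(i) {
    f <- mle_fit(sp, restrict_catalog(cat6, prefix[seq_len(i)]), "negbinom")
    cosine_similarity(sp$counts,
                      expected_counts(cat6, f$attribution)$values)
  }, 0)
  expect_gte(r1$reconstruction_cosine, max(cosines) - 1e-6)
})

test_that("presence test p-value is usually large under the null", {
  set.seed(36)
  ps <- replicate(20, {
    sp <- sampled_spectrum(cat4, c(TS01 = 2000, TS02 = 1000))
    signature_presence_test(sp, cat4, "TS04")$lrt$p_value
  })
  expect_gt(mean(ps > 0.01), 0.8)
})
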