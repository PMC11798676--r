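test_that("fit_generator_params counts prevalence and recovers NB models", {
  tab <- rbind(TSA = c(0, 0, 5, 5), TSB = c(0, 0, 0, 0),
               TSC = c(10, 10, 10, 10))
  colnames(tab) <- paste0("s", 1:4)
  gp <- fit_generator_params(tab)
  sigs <- gp$signatures
  expect_equal(sigs$prevalence[sigs$signature == "TSA"], 0.5)
  expect_equal(sigs$prevalence[sigs$signature == "TSB"], 0)
  expect_true(is.na(sigs$activity_mu[sigs$signature == "TSB"]))
  # constant positive activities: mu = constant, size at the upper bound
  expect_equal(sigs$activity_mu[sigs$signature == "TSC"], 10)
  expect_gte(sigs$activity_size[sigs$signature == "TSC"], 1e5)

  # parameter recovery from NB(size = 2, mu = 500) draws
  set.seed(41)
  draws <- rnbinom(1e4, size = 2, mu = 500)
  tab2 <- matrix(draws, nrow = 1, dimnames = list("TSX", NULL))
  colnames(tab2) <- paste0("s", seq_len(ncol(tab2)))
  gp2 <- fit_generator_params(tab2)
  expect_equal(gp2$signatures$activity_mu, 500, tolerance = 0.15 * 500)
  expect_equal(gp2$signatures$activity_size, 2, tolerance = 0.15 * 2)
})

test_that("sample_ground_truth honors prevalence and positivity", {
  gp1 <- generator_params("t", data.frame(
    signature = "TS01", prevalence = 1.0,
    activity_size = 2, activity_mu = 1000))
  set.seed(42)
  for (i in 1:10) {
    tr <- sample_ground_truth(gp1)
    expect_equal(names(tr$activities), "TS01")
    expect_gt(tr$activities, 0)
  }
  # empirical presence fraction ~ prevalence (binomial 4 sigma)
  gp2 <- generator_params("t", data.frame(
    signature = c("TS01", "TS02"), prevalence = c(1.0, 0.3),
    activity_size = c(2, 2), activity_mu = c(1000, 400)))
  set.seed(43)
  n <- 1e4
  pres <- replicate(n, "TS02" %in%
                      names(sample_ground_truth(gp2)$activities))
  expect_equal(mean(pres), 0.3, tolerance = 0.02)
  # positive-conditioned mean: mu / (1 - P(0))
  set.seed(44)
  acts <- replicate(2000, {
    tr <- sample_ground_truth(gp2)
    unname(tr$activities["TS01"])
  })
  p0 <- dnbinom(0, size = 2, mu = 1000)
  expect_equal(mean(acts), 1000 / (1 - p0), tolerance = 0.05 * 1000)
  expect_error(sample_ground_truth(
    generator_params("t", data.frame(signature = "a", prevalence = 0,
                                     activity_size = NA_real_,
                                     activity_mu = NA_real_))), "prevalence")
})

test_that("sample_spectrum has the right expectation and LLN behavior", {
  truth <- attribution(c(TS01 = 2000, TS03 = 1000))
  set.seed(45)
  reps <- replicate(300, as.numeric(
    sample_spectrum(truth, cat6, channel_dispersion = 50)$counts))
  emp_mean <- rowMeans(reps)
  expected <- drop(cat6$matrix[, c("TS01", "TS03")] %*% c(2000, 1000))
  # per-channel Monte Carlo 3-sigma bound
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(emp_mean - expected) <= 3 * se + 1e-9))
  # conservation in expectation of the total
  expect_equal(mean(colSums(reps)), 3000, tolerance = 0.02 * 3000)

  # huge activity + huge size: proportions converge to the signature
  set.seed(46)
  sp <- sample_spectrum(attribution(c(TS02 = 1e6)), cat6, 1e6)
  expect_gt(cosine_similarity(sp$counts, cat6$matrix[, "TS02"]), 0.999)
})

test_that("generate_dataset is reproducible and seed-sensitive", {
  gp <- toy_generator_params("ToyType1")
  d1 <- generate_dataset(gp, cat6, n = 5, seed = 99)
  d2 <- generate_dataset(gp, cat6, n = 5, seed = 99)
  expect_identical(lapply(d1, function(s) s$spectrum$counts),
                   lapply(d2, function(s) s$spectrum$counts))
  expect_identical(lapply(d1, function(s) s$truth$activities),
                   lapply(d2, function(s) s$truth$activities))
  d3 <- generate_dataset(gp, cat6, n = 5, seed = 100)
  expect_false(identical(lapply(d1, function(s) s$spectrum$counts),
                         lapply(d3, function(s) s$spectrum$counts)))
  # n = 1 works; ground-truth cosine recorded
  d4 <- generate_dataset(gp, cat6, n = 1, seed = 7)
  expect_length(d4, 1)
  expect_true(d4[[1]]$truth_reconstruction_cosine > 0 &&
                d4[[1]]$truth_reconstruction_cosine <= 1)
})

test_that("reconstruction cosine increases with the size parameter", {
  gp <- toy_generator_params("ToyType2")
  med <- vapply(c(1, 10, 100, 1000), function(disp) {
    gp$channel_dispersion <- disp
    ds <- generate_dataset(gp, cat4, n = 120, seed = 17)
    median(vapply(ds, `[[`, 0, "truth_reconstruction_cosine"))
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("calibration hits its target in a closed loop", {
  gp <- toy_generator_params("ToyType2")
  cal <- calibrate_dispersion(gp, cat4, target = 0.95, seed = 19,
                              n_probe = 150, tol = 0.005)
  gp$channel_dispersion <- cal$dispersion
  ds <- generate_dataset(gp, cat4, n = 300, seed = 23)
  med <- median(vapply(ds, `[[`, 0, "truth_reconstruction_cosine"))
  expect_equal(med, 0.95, tolerance = 0.012)
  # unreachable target errors with the attainable range
  expect_error(calibrate_dispersion(gp, cat4, target = 0.99999, seed = 19,
                                    n_probe = 50), "attainable")
})

test_that("generator params survive a JSON round trip", {
  gp <- toy_generator_params("ToyType1", channel_dispersion = 72.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_params(gp, path)
  back <- read_generator_params(path)
  expect_equal(back$signatures, gp$signatures)
  expect_equal(back$channel_dispersion, 72.5)
  expect_equal(back$cancer_type, "ToyType1")
})
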