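# Synthetic tumor spectra with known ground truth.
#
# A cohort is generated in two stages. First, which signatures a tumor
# carries and how many mutations each contributes are drawn from
# per-signature presence probabilities (prevalence) and negative-binomial
# activity distributions fitted to an activity table of real attributions.
# Second, the per-channel counts due to each signature are drawn from
# negative binomials centered on activity x channel probability, with a
# dispersion (size) parameter that controls how faithfully spectra
# resemble their expected reconstruction.
#
# Negative-binomial parameterization throughout: (size, mu) with
# variance = mu + mu^2/size.

#' Generator parameters for one cancer type
#'
#' @param cancer_type Label for the cohort.
#' @param signatures data.frame with columns \code{signature},
#'   \code{prevalence} (fraction of tumors with activity > 0),
#'   \code{activity_size}, \code{activity_mu} (negative-binomial parameters
#'   of the positive activities).
#' @param channel_dispersion Size parameter for per-channel count sampling:
#'   a single shared value, or a named vector with one value per signature.
#' @return An object of class \code{generator_params}.
#' @export
generator_params <- function(cancer_type, signatures,
                             channel_dispersion = 50) {
  stopifnot(is.data.frame(signatures),
            all(c("signature", "prevalence", "activity_size",
                  "activity_mu") %in% names(signatures)))
  if (any(signatures$prevalence < 0 | signatures$prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  pos <- signatures$prevalence > 0
  if (any(pos & (is.na(signatures$activity_size) |
                 signatures$activity_size <= 0)) ||
      any(pos & (is.na(signatures$activity_mu) |
                 signatures$activity_mu <= 0)))
    stop("activity size/mu must be positive for signatures with prevalence > 0")
  if (any(channel_dispersion <= 0)) stop("channel_dispersion must be positive")
  structure(list(cancer_type = cancer_type, signatures = signatures,
                 channel_dispersion = channel_dispersion),
            class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf("<generator_params> %s: %d signatures, channel dispersion %s\n",
              x$cancer_type, nrow(x$signatures),
              paste(format(x$channel_dispersion, digits = 3),
                    collapse = "/")))
  invisible(x)
}

# Profile maximum likelihood for NB(size, mu) on positive counts.
# For fixed size the MLE of mu is the sample mean, so only size needs a
# 1-D search; method-of-moments supplies the starting bracket.
fit_nb_sizemu <- function(x, size_bounds = c(1e-3, 1e6)) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1, all(x >= 0))
  mu <- mean(x)
  if (length(x) == 1 || stats::var(x) <= 0) {
    # degenerate: zero variance looks Poisson-like (size at upper bound);
    # a single observation has no variance information (fallback size 1)
    size <- if (length(x) == 1) 1 else size_bounds[2]
    return(c(size = size, mu = mu))
  }
  nll <- function(log_size)
    -sum(stats::dnbinom(x, size = exp(log_size), mu = mu, log = TRUE))
  opt <- stats::optimize(nll, log(size_bounds))
  size <- exp(opt$minimum)
  # method-of-moments sanity: if the optimum sits at the bound because the
  # data are underdispersed, keep the bound (Poisson-like)
  c(size = size, mu = mu)
}

#' Fit generator parameters from an activity table
#'
#' Estimates, for each signature, the prevalence (fraction of samples with
#' activity > 0) and the negative-binomial (size, mu) of the positive
#' activities by profile maximum likelihood (the mean is the exact MLE of
#' mu for any size; size is found by 1-D optimization with
#' method-of-moments bracketing).
#'
#' @param activity_table Numeric matrix, signatures x samples, of
#'   non-negative activities (e.g. loaded with
#'   \code{load_matrix_tsv(..., role = "activities")}).
#' @param cancer_type Cohort label recorded in the result.
#' @param channel_dispersion Channel dispersion to record (not estimable
#'   from an activity table; see \code{\link{calibrate_dispersion}}).
#' @return A \code{\link{generator_params}} object. Signatures never active
#'   get prevalence 0 and NA activity parameters.
#' @export
fit_generator_params <- function(activity_table, cancer_type = "cohort",
                                 channel_dispersion = 50) {
  stopifnot(is.matrix(activity_table), ncol(activity_table) >= 2,
            all(activity_table >= 0))
  recs <- lapply(rownames(activity_table), function(sig) {
    a <- activity_table[sig, ]
    prev <- mean(a > 0)
    if (prev == 0)
      return(data.frame(signature = sig, prevalence = 0,
                        activity_size = NA_real_, activity_mu = NA_real_,
                        stringsAsFactors = FALSE))
    fit <- fit_nb_sizemu(a[a > 0])
    data.frame(signature = sig, prevalence = prev,
               activity_size = unname(fit["size"]),
               activity_mu = unname(fit["mu"]), stringsAsFactors = FALSE)
  })
  generator_params(cancer_type, do.call(rbind, recs), channel_dispersion)
}

#' Draw a ground-truth attribution
#'
#' Each signature is present independently with probability equal to its
#' prevalence; present signatures draw an activity from their negative
#' binomial conditioned on being positive (zero draws are redrawn). A draw
#' in which no signature at all is present is repeated (every tumor carries
#' at least one signature), up to 1000 attempts.
#'
#' @param params A \code{\link{generator_params}} with at least one
#'   signature of positive prevalence.
#' @param sample_id Identifier for the resulting attribution.
#' @return An \code{\link{attribution}} with strictly positive activities.
#'   Uses R's global RNG stream; seed with \code{set.seed}.
#' @export
sample_ground_truth <- function(params, sample_id = "synthetic") {
  sigs <- params$signatures
  active <- sigs[sigs$prevalence > 0, , drop = FALSE]
  if (nrow(active) == 0) stop("no signature has positive prevalence")
  for (attempt in seq_len(1000)) {
    present <- stats::runif(nrow(active)) < active$prevalence
    if (!any(present)) next
    acts <- vapply(which(present), function(i) {
      for (r in seq_len(1000)) {
        v <- stats::rnbinom(1, size = active$activity_size[i],
                            mu = active$activity_mu[i])
        if (v > 0) return(as.numeric(v))
      }
      # pathological parameters (P(0) ~ 1): fall back to 1 mutation
      1
    }, numeric(1))
    return(attribution(stats::setNames(acts, active$signature[present]),
                       sample_id))
  }
  stop("failed to draw a non-empty attribution in 1000 attempts")
}

#' Draw a spectrum given a ground-truth attribution
#'
#' For each present signature s and channel i, the count is drawn from a
#' negative binomial with mean activity_s * h_is and the signature's
#' channel dispersion; the spectrum is the channel-wise sum over
#' signatures.
#'
#' @param truth A non-empty \code{\link{attribution}}.
#' @param catalog A \code{\link{signature_catalog}} containing the truth's
#'   signatures.
#' @param channel_dispersion Shared positive size parameter, or a named
#'   vector with one entry per signature in \code{truth}.
#' @return A \code{\link{spectrum}}. Uses R's global RNG stream.
#' @export
sample_spectrum <- function(truth, catalog, channel_dispersion = 50) {
  acts <- truth$activities
  if (!length(acts)) stop("empty ground-truth attribution")
  disp <- rep(channel_dispersion, length.out = length(acts))
  if (!is.null(names(channel_dispersion)))
    disp <- channel_dispersion[names(acts)]
  if (any(is.na(disp) | disp <= 0)) stop("invalid channel dispersion")
  k <- catalog$scheme$k
  counts <- numeric(k)
  for (j in seq_along(acts)) {
    mu <- acts[j] * catalog$matrix[, names(acts)[j]]
    counts <- counts + stats::rnbinom(k, size = disp[j], mu = mu)
  }
  spectrum(stats::setNames(counts, catalog$scheme$labels), catalog$scheme,
           truth$sample_id)
}

#' Generate a cohort of synthetic samples with ground truth
#'
#' Draws \code{n} independent tumors. Each sample uses its own RNG
#' substream derived from \code{seed}, so the cohort is reproducible from
#' the single integer seed and individual samples can be regenerated.
#'
#' @param params A \code{\link{generator_params}}.
#' @param catalog A \code{\link{signature_catalog}} covering the
#'   signatures of \code{params}.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param prefix Sample-id prefix.
#' @return List of ground-truth samples, each a list with \code{spectrum},
#'   \code{truth} (attribution), \code{cancer_type}, \code{seed_path} and
#'   \code{truth_reconstruction_cosine} (cosine between the spectrum and
#'   the expected counts of the truth).
#' @export
generate_dataset <- function(params, catalog, n, seed, prefix = NULL) {
  stopifnot(n >= 1)
  if (is.null(prefix)) prefix <- params$cancer_type
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    set.seed(sub_seeds[i])
    id <- sprintf("%s::S%03d", prefix, i)
    truth <- sample_ground_truth(params, sample_id = id)
    sp <- sample_spectrum(truth, catalog, params$channel_dispersion)
    recon <- expected_counts(catalog, truth)
    list(spectrum = sp, truth = truth, cancer_type = params$cancer_type,
         seed_path = c(seed = seed, sub_seed = sub_seeds[i]),
         truth_reconstruction_cosine =
           if (sp$total > 0) cosine_similarity(sp$counts, recon$values)
           else NA_real_)
  })
}

#' Calibrate the channel dispersion to a target reconstruction accuracy
#'
#' The median cosine similarity between simulated spectra and their
#' ground-truth reconstructions increases monotonically with the
#' negative-binomial size parameter (less overdispersion = more faithful
#' spectra). This function bisects over a shared dispersion value until the
#' simulated median cosine is within \code{tol} of \code{target}, matching
#' the generator's noise level to the reconstruction accuracy observed in
#' real cohorts.
#'
#' @param params A \code{\link{generator_params}} (its recorded dispersion
#'   is ignored; the probed value is used).
#' @param catalog A \code{\link{signature_catalog}}.
#' @param target Target median cosine, in (0, 1).
#' @param seed Integer seed (common random numbers across probes keep the
#'   probe curve monotone).
#' @param n_probe Spectra per probe (>= 500 recommended).
#' @param tol Acceptable |median - target| (default 0.005).
#' @param bounds Dispersion search interval (default [1e-2, 1e6]).
#' @return List with \code{dispersion}, \code{median_cosine} and
#'   \code{n_iter}. Errors if the target lies outside the attainable range
#'   at the interval endpoints, reporting that range.
#' @export
calibrate_dispersion <- function(params, catalog, target, seed,
                                 n_probe = 500, tol = 0.005,
                                 bounds = c(1e-2, 1e6)) {
  stopifnot(target > 0, target < 1, n_probe >= 1)
  probe <- function(disp) {
    p <- params
    p$channel_dispersion <- disp
    ds <- generate_dataset(p, catalog, n_probe, seed, prefix = "cal")
    stats::median(vapply(ds, `[[`, 0, "truth_reconstruction_cosine"))
  }
  lo <- bounds[1]; hi <- bounds[2]
  m_lo <- probe(lo); m_hi <- probe(hi)
  if (target < m_lo || target > m_hi)
    stop(sprintf(
      "target median cosine %.4f outside attainable range [%.4f, %.4f]",
      target, m_lo, m_hi))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mid <- sqrt(lo * hi)               # bisect on the log scale
    m <- probe(mid)
    if (abs(m - target) <= tol || iter >= 40L)
      return(list(dispersion = mid, median_cosine = m, n_iter = iter))
    if (m < target) lo <- mid else hi <- mid
  }
}
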