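# Count-model likelihoods and the likelihood ratio test.
#
# Both steps of the attribution algorithm score an attribution A by the
# likelihood of the observed spectrum D given the reconstruction c = H A:
# step 1 under a multinomial model on the channel proportions, step 2 under
# independent negative binomials with means c_i and a shared dispersion.

# Floor applied to expected channel counts before forming multinomial
# probabilities or negative-binomial means. The model likelihoods are
# undefined at c_i = 0 with d_i > 0; a floor proportional to the total
# expected count preserves likelihood ordering while avoiding -Inf.
floor_expected <- function(values) {
  eps <- 1e-10 * max(1, sum(values))
  pmax(values, eps)
}

#' Expected channel counts of an attribution
#'
#' Computes the reconstruction \code{c = H A}: the expected mutation count
#' in each channel given the signatures and activities of an attribution,
#' together with the derived multinomial probability vector
#' \code{pi = c / sum(c)}.
#'
#' @param catalog A \code{\link{signature_catalog}} containing at least the
#'   signatures of \code{attrib}.
#' @param attrib An \code{\link{attribution}}, or a named numeric vector of
#'   activities.
#' @return An object of class \code{expected_counts}: list with
#'   \code{values} (length-k non-negative vector) and \code{pi} (multinomial
#'   parameters; all zero when the attribution is empty).
#' @export
expected_counts <- function(catalog, attrib) {
  act <- if (inherits(attrib, "attribution")) attrib$activities else attrib
  if (length(act) == 0) {
    v <- stats::setNames(numeric(catalog$scheme$k), catalog$scheme$labels)
    return(structure(list(values = v, pi = v), class = "expected_counts"))
  }
  missing <- setdiff(names(act), catalog$names)
  if (length(missing))
    stop("unknown signature(s): ", paste(missing, collapse = ", "))
  v <- drop(catalog$matrix[, names(act), drop = FALSE] %*% act)
  tot <- sum(v)
  pi <- if (tot > 0) v / tot else v
  structure(list(values = v, pi = pi), class = "expected_counts")
}

#' Multinomial log-likelihood of a spectrum
#'
#' Log probability of the observed counts under a multinomial distribution
#' whose parameters are the normalized expected counts, including the
#' multinomial coefficient. Computed via log-gamma. Expected counts are
#' floored (see Details) so the result is finite even when a channel with
#' observed mutations has zero expected count.
#'
#' @details Channels with expected count 0 are floored at
#'   \code{1e-10 * max(1, sum(expected))} before normalization; this keeps
#'   the likelihood finite and preserves the ordering of candidate
#'   attributions.
#'
#' @param spectrum A \code{\link{spectrum}}.
#' @param expected An \code{\link{expected_counts}} object (or a bare
#'   non-negative vector of expected counts).
#' @return The log-likelihood (a finite scalar).
#' @export
multinomial_loglik <- function(spectrum, expected) {
  d <- spectrum$counts
  c_ <- if (inherits(expected, "expected_counts")) expected$values else expected
  if (sum(c_) <= 0) stop("expected counts sum to zero")
  if (spectrum$total <= 0) stop("spectrum has no mutations")
  c_ <- floor_expected(c_)
  pi <- c_ / sum(c_)
  lgamma(sum(d) + 1) - sum(lgamma(d + 1)) + sum(d * log(pi))
}

#' Negative-binomial log-likelihood of a spectrum
#'
#' Sum over channels of the log negative-binomial probability of the
#' observed count, with mean equal to the (floored) expected count and a
#' shared size (dispersion) parameter: variance = mu + mu^2/size.
#'
#' @param spectrum A \code{\link{spectrum}}.
#' @param expected An \code{\link{expected_counts}} object or bare vector.
#' @param dispersion Positive size parameter shared across channels.
#' @return The log-likelihood (a finite scalar).
#' @export
negbinom_loglik <- function(spectrum, expected, dispersion) {
  stopifnot(dispersion > 0)
  d <- spectrum$counts
  c_ <- if (inherits(expected, "expected_counts")) expected$values else expected
  c_ <- floor_expected(c_)
  sum(stats::dnbinom(d, size = dispersion, mu = c_, log = TRUE))
}

#' Likelihood ratio test for nested attributions
#'
#' Tests whether a larger signature set fits significantly better than a
#' nested subset: \code{lambda = -2 (loglik_sub - loglik_full)}, referred
#' to a chi-square distribution with \code{df = |full| - |sub|} degrees of
#' freedom. Small negative lambdas arising from optimizer tolerance are
#' clamped to 0 (nested maximized likelihoods satisfy lambda >= 0 exactly).
#'
#' @param loglik_sub Maximized log-likelihood of the subset model.
#' @param loglik_full Maximized log-likelihood of the full model.
#' @param df Positive integer degrees of freedom (difference in the number
#'   of signatures).
#' @return An object of class \code{lrt_result}: list with \code{lambda},
#'   \code{df} and \code{p_value}.
#' @export
likelihood_ratio_test <- function(loglik_sub, loglik_full, df = 1L) {
  if (df < 1) stop("df must be a positive integer")
  lambda <- max(0, -2 * (loglik_sub - loglik_full))
  structure(list(lambda = lambda, df = as.integer(df),
                 p_value = stats::pchisq(lambda, df = df,
                                         lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt> lambda = %.4g, df = %d, p = %.4g\n",
              x$lambda, x$df, x$p_value))
  invisible(x)
}
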