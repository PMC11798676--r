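# Two-step sparse attribution: per-signature presence tests under a
# multinomial model (step 1) followed by a greedy forward search under a
# negative binomial model with a likelihood-ratio-test stopping rule
# (step 2).

#' Configuration for the attribution algorithm
#'
#' @param alpha Significance level for the likelihood ratio tests in both
#'   steps; default 0.01 favors sparse attributions.
#' @param dispersion Negative-binomial size parameter used by the step-2
#'   count model; default 100 (modest overdispersion relative to Poisson).
#' @param max_signatures Optional cap on the number of signatures in the
#'   returned attribution (\code{Inf} = no cap).
#' @return An object of class \code{pasa_config}.
#' @export
pasa_config <- function(alpha = 0.01, dispersion = 100,
                        max_signatures = Inf) {
  stopifnot(alpha > 0, alpha < 1, dispersion > 0, max_signatures >= 1)
  structure(list(alpha = alpha, dispersion = dispersion,
                 max_signatures = max_signatures),
            class = "pasa_config")
}

#' Step 1: signature presence filtering
#'
#' For each signature in the catalog, compares the best multinomial
#' maximum-likelihood fit using all signatures against the best fit with
#' that signature removed, via a likelihood ratio test with one degree of
#' freedom. A signature is retained iff its removal significantly worsens
#' the fit (p < alpha). Each signature is tested against all others, so the
#' result does not depend on testing order. A single-signature catalog is
#' retained without testing.
#'
#' @param spectrum A \code{\link{spectrum}} with at least one mutation.
#' @param catalog A \code{\link{signature_catalog}}.
#' @param config A \code{\link{pasa_config}}.
#' @return List with \code{survivors} (character vector, catalog order) and
#'   \code{reports} (list of per-signature presence-test reports with
#'   elements \code{signature}, \code{lrt}, \code{retained}).
#' @export
presence_filter <- function(spectrum, catalog, config = pasa_config()) {
  g <- length(catalog$names)
  stopifnot(g >= 1)
  if (spectrum$total <= 0) stop("spectrum has no mutations")
  if (g == 1) {
    return(list(survivors = catalog$names,
                reports = list(list(signature = catalog$names, lrt = NULL,
                                    retained = TRUE))))
  }
  full <- mle_fit(spectrum, catalog, model = "multinomial")
  reports <- lapply(catalog$names, function(sig) {
    sub_cat <- restrict_catalog(catalog, setdiff(catalog$names, sig))
    sub <- mle_fit(spectrum, sub_cat, model = "multinomial")
    lrt <- likelihood_ratio_test(sub$objective, full$objective, df = 1L)
    list(signature = sig, lrt = lrt, retained = lrt$p_value < config$alpha)
  })
  survivors <- catalog$names[vapply(reports, `[[`, TRUE, "retained")]
  list(survivors = survivors, reports = reports)
}

#' Presence test for one specific signature
#'
#' Standalone exposure of the step-1 likelihood ratio test: is
#' \code{target} statistically needed to explain the spectrum, given all
#' other signatures in the catalog?
#'
#' @inheritParams presence_filter
#' @param target Name of the signature to test.
#' @return A report list: \code{signature}, \code{lrt}
#'   (\code{lrt_result}), \code{retained}.
#' @export
signature_presence_test <- function(spectrum, catalog, target,
                                    config = pasa_config()) {
  if (!target %in% catalog$names)
    stop("unknown signature: ", target)
  if (length(catalog$names) == 1)
    return(list(signature = target, lrt = NULL, retained = TRUE))
  full <- mle_fit(spectrum, catalog, model = "multinomial")
  sub <- mle_fit(spectrum,
                 restrict_catalog(catalog, setdiff(catalog$names, target)),
                 model = "multinomial")
  lrt <- likelihood_ratio_test(sub$objective, full$objective, df = 1L)
  list(signature = target, lrt = lrt, retained = lrt$p_value < config$alpha)
}

#' Step 2: greedy forward search with LRT stopping
#'
#' Starting from the empty signature set, each iteration fits (negative
#' binomial maximum likelihood) the current set plus each remaining
#' candidate, picks the candidate with the highest fitted log-likelihood
#' (ties broken lexicographically by name), and adds it iff the one-degree-
#' of-freedom likelihood ratio test against the current set gives
#' p < alpha. The first signature is always added (the empty attribution
#' has no defined likelihood to serve as a baseline). The search stops at
#' the first non-significant best candidate or when candidates are
#' exhausted.
#'
#' @param spectrum A \code{\link{spectrum}} with at least one mutation.
#' @param survivors A \code{\link{signature_catalog}} restricted to the
#'   step-1 survivor set.
#' @param config A \code{\link{pasa_config}}.
#' @return An \code{attribution_result}: list with \code{attribution},
#'   \code{addition_trace} (data.frame signature/p_value/loglik in addition
#'   order), \code{reconstruction} (\code{expected_counts}),
#'   \code{reconstruction_cosine} and \code{final_loglik}.
#' @export
forward_search <- function(spectrum, survivors, config = pasa_config()) {
  stopifnot(length(survivors$names) >= 1)
  if (spectrum$total <= 0) stop("spectrum has no mutations")
  remaining <- survivors$names
  current <- character(0)
  current_loglik <- NA_real_
  current_fit <- NULL
  trace <- list()
  while (length(remaining) > 0 && length(current) < config$max_signatures) {
    fits <- lapply(remaining, function(sig)
      mle_fit(spectrum, restrict_catalog(survivors, c(current, sig)),
              model = "negbinom", dispersion = config$dispersion))
    lls <- vapply(fits, `[[`, 0, "objective")
    # best candidate by log-likelihood; near-ties resolved by name
    best_ll <- max(lls)
    cand <- which(lls >= best_ll - 1e-9)
    pick <- cand[order(remaining[cand])][1]
    if (length(current) == 0) {
      p <- NA_real_                    # first addition is unconditional
    } else {
      p <- likelihood_ratio_test(current_loglik, lls[pick], df = 1L)$p_value
      if (p >= config$alpha) break
    }
    current <- c(current, remaining[pick])
    current_loglik <- lls[pick]
    current_fit <- fits[[pick]]
    trace[[length(trace) + 1L]] <-
      data.frame(signature = remaining[pick], p_value = p,
                 loglik = current_loglik, stringsAsFactors = FALSE)
    remaining <- remaining[-pick]
  }
  finalize_attribution(spectrum, survivors, current_fit, trace,
                       step1_reports = NULL)
}

finalize_attribution <- function(spectrum, catalog, fit, trace,
                                 step1_reports) {
  if (is.null(fit)) {
    attrib <- attribution(numeric(0), spectrum$sample_id)
    recon <- expected_counts(catalog, attrib)
    cosine <- NA_real_
    loglik <- NA_real_
  } else {
    attrib <- fit$attribution
    recon <- expected_counts(catalog, attrib)
    cosine <- if (sum(recon$values) > 0 && spectrum$total > 0)
      cosine_similarity(spectrum$counts, recon$values) else NA_real_
    loglik <- fit$objective
  }
  structure(list(attribution = attrib,
                 step1_reports = step1_reports,
                 addition_trace = if (length(trace))
                   do.call(rbind, trace)
                 else data.frame(signature = character(0),
                                 p_value = numeric(0),
                                 loglik = numeric(0)),
                 reconstruction = recon,
                 reconstruction_cosine = cosine,
                 final_loglik = loglik),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  print(x$attribution)
  cat(sprintf("  reconstruction cosine: %.4f; log-likelihood: %.2f\n",
              x$reconstruction_cosine, x$final_loglik))
  invisible(x)
}

#' Full two-step signature attribution
#'
#' Runs \code{\link{presence_filter}} then \code{\link{forward_search}} on
#' the survivor set. If no signature survives step 1 (possible for flat or
#' tiny spectra), step 2 runs on the full catalog so a reconstruction is
#' still returned. A zero-count spectrum yields an empty attribution with a
#' warning.
#'
#' @param spectrum A \code{\link{spectrum}}.
#' @param catalog A \code{\link{signature_catalog}} (the signature universe
#'   for this sample, e.g. the signatures previously observed in its cancer
#'   type; restricting the universe is the caller's responsibility).
#' @param config A \code{\link{pasa_config}}.
#' @return An \code{attribution_result} (see \code{\link{forward_search}}),
#'   with \code{step1_reports} filled in.
#' @examples
#' cat6 <- toy_catalog()
#' sp <- spectrum(round(1000 * cat6$matrix[, 1]), cat6$scheme, "ex")
#' attribute(sp, cat6)
#' @export
attribute <- function(spectrum, catalog, config = pasa_config()) {
  if (spectrum$total <= 0) {
    warning("zero-count spectrum: returning empty attribution")
    return(finalize_attribution(spectrum, catalog, NULL, list(),
                                step1_reports = list()))
  }
  s1 <- presence_filter(spectrum, catalog, config)
  v <- if (length(s1$survivors)) s1$survivors else catalog$names
  res <- forward_search(spectrum, restrict_catalog(catalog, v), config)
  res$step1_reports <- s1$reports
  res
}
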