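# Exhaustive enumeration of alternative attributions.
#
# For small signature universes (2^g - 1 nonempty subsets), every subset is
# refit by NNLS and attributions are grouped by the set of signatures that
# end up with strictly positive activity. Counting how many distinct
# supports reconstruct a spectrum above a cosine-similarity threshold
# quantifies how ambiguous attribution is for that spectrum.

#' Enumeration configuration
#'
#' @param cosine_threshold Reconstruction cosine above which an attribution
#'   counts as a reasonable reconstruction; default 0.969 (the median
#'   reconstruction accuracy of real attributions).
#' @param min_activity_proportion Sparsity filter: attributions containing
#'   a signature responsible for less than this fraction of the sample's
#'   mutations are excluded from the filtered counts; default 0.03.
#' @param max_signatures_for_enumeration Refuse to enumerate universes
#'   larger than this (2^g subsets grow fast); default 22.
#' @return An object of class \code{enumeration_config}.
#' @export
enumeration_config <- function(cosine_threshold = 0.969,
                               min_activity_proportion = 0.03,
                               max_signatures_for_enumeration = 22L) {
  stopifnot(cosine_threshold > 0, cosine_threshold < 1,
            min_activity_proportion >= 0, min_activity_proportion < 1)
  structure(list(cosine_threshold = cosine_threshold,
                 min_activity_proportion = min_activity_proportion,
                 max_signatures_for_enumeration =
                   as.integer(max_signatures_for_enumeration)),
            class = "enumeration_config")
}

# All nonempty subsets of seq_len(g), by increasing size then
# lexicographic within size (deterministic iteration order).
nonempty_subsets <- function(g) {
  out <- vector("list", 2^g - 1)
  i <- 0L
  for (size in seq_len(g)) {
    cmb <- utils::combn(g, size, simplify = FALSE)
    for (s in cmb) { i <- i + 1L; out[[i]] <- s }
  }
  out
}

# Support of an NNLS activity vector: strictly positive up to solver
# tolerance, relative to the spectrum total.
fit_support <- function(activities, total) {
  names(activities)[activities > 1e-6 * total]
}

#' Enumerate all subset attributions of a spectrum
#'
#' NNLS-fits every nonempty signature subset, deduplicates attributions by
#' their fitted positive-activity support, and counts the distinct supports
#' whose reconstruction cosine exceeds the threshold, before and after the
#' minimum-activity-proportion sparsity filter.
#'
#' @param spectrum A \code{\link{spectrum}} with at least one mutation.
#' @param catalog A \code{\link{signature_catalog}} with at most
#'   \code{config$max_signatures_for_enumeration} signatures.
#' @param config An \code{\link{enumeration_config}}.
#' @return An \code{enumeration_result}: list with \code{sample_id},
#'   \code{n_subsets_tested}, \code{supports} (data.frame: support string,
#'   size, cosine, passing, filtered_passing), \code{activities} (list of
#'   named activity vectors parallel to \code{supports}),
#'   \code{n_passing_unfiltered}, \code{n_passing_filtered}, \code{best}
#'   (highest-cosine passing entry index or NA) and \code{best_filtered}.
#' @export
enumerate_attributions <- function(spectrum, catalog,
                                   config = enumeration_config()) {
  g <- length(catalog$names)
  if (g > config$max_signatures_for_enumeration)
    stop(sprintf(paste0("catalog has %d signatures; enumeration capped at ",
                        "%d (raise max_signatures_for_enumeration ",
                        "deliberately to override)"),
                 g, config$max_signatures_for_enumeration))
  if (spectrum$total <= 0) stop("zero-count spectrum")
  subsets <- nonempty_subsets(g)
  seen <- new.env(parent = emptyenv())
  rows <- list(); acts <- list()
  for (s in subsets) {
    sub <- restrict_catalog(catalog, catalog$names[s])
    fit <- nnls_fit(spectrum, sub)
    supp <- fit_support(fit$activities, spectrum$total)
    if (length(supp) == 0) next
    key <- paste(sort(supp), collapse = "+")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    a <- fit$activities[supp]
    recon <- drop(catalog$matrix[, supp, drop = FALSE] %*% a)
    cosine <- cosine_similarity(spectrum$counts, recon)
    passing <- cosine > config$cosine_threshold
    filtered <- passing &&
      all(a >= config$min_activity_proportion * spectrum$total)
    rows[[length(rows) + 1L]] <-
      data.frame(support = key, size = length(supp), cosine = cosine,
                 passing = passing, filtered_passing = filtered,
                 stringsAsFactors = FALSE)
    acts[[length(acts) + 1L]] <- a
  }
  supports <- do.call(rbind, rows)
  best <- if (any(supports$passing))
    which(supports$passing)[which.max(supports$cosine[supports$passing])]
  else NA_integer_
  best_f <- if (any(supports$filtered_passing))
    which(supports$filtered_passing)[
      which.max(supports$cosine[supports$filtered_passing])]
  else NA_integer_
  structure(list(sample_id = spectrum$sample_id,
                 n_subsets_tested = length(subsets),
                 supports = supports, activities = acts,
                 n_passing_unfiltered = sum(supports$passing),
                 n_passing_filtered = sum(supports$filtered_passing),
                 best = best, best_filtered = best_f),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat(sprintf(paste0("<enumeration> %s: %d subsets, %d distinct supports, ",
                     "%d passing (%d after activity filter)\n"),
              x$sample_id, x$n_subsets_tested, nrow(x$supports),
              x$n_passing_unfiltered, x$n_passing_filtered))
  invisible(x)
}

#' Compare best enumerated attributions against ground truth
#'
#' For each ground-truth sample: does any alternative support achieve a
#' higher reconstruction cosine than the best fit on the true support
#' (before the activity filter)? Does the best attribution after the
#' activity filter recover exactly the true support? How many true
#' signatures does that best attribution miss (false negatives) and how
#' many extra ones does it include (false positives)?
#'
#' @param samples List of ground-truth samples (as from
#'   \code{\link{generate_dataset}}).
#' @param catalog The shared \code{\link{signature_catalog}}.
#' @param config An \code{\link{enumeration_config}}.
#' @return List with \code{per_sample} (data.frame: sample_id, truth
#'   support, truth_cosine, best support and cosine, truth_beaten,
#'   best_correct, fn, fp) and \code{summary} (cohort means and the count
#'   of samples with a correct best attribution).
#' @export
best_vs_truth <- function(samples, catalog, config = enumeration_config()) {
  rows <- lapply(samples, function(gs) {
    sp <- gs$spectrum
    truth_supp <- sort(names(gs$truth$activities))
    enum <- enumerate_attributions(sp, catalog, config)
    truth_fit <- nnls_fit(sp, restrict_catalog(catalog, truth_supp))
    truth_recon <- drop(catalog$matrix[, truth_supp, drop = FALSE] %*%
                          truth_fit$activities)
    truth_cos <- cosine_similarity(sp$counts, truth_recon)
    others <- enum$supports$support != paste(truth_supp, collapse = "+")
    beaten <- any(others & enum$supports$cosine > truth_cos)
    if (!is.na(enum$best_filtered)) {
      best_supp <- strsplit(enum$supports$support[enum$best_filtered],
                            "+", fixed = TRUE)[[1]]
      best_cos <- enum$supports$cosine[enum$best_filtered]
    } else {
      best_supp <- character(0)
      best_cos <- NA_real_
    }
    data.frame(sample_id = sp$sample_id,
               truth_support = paste(truth_supp, collapse = "+"),
               truth_cosine = truth_cos,
               best_support = paste(best_supp, collapse = "+"),
               best_cosine = best_cos,
               truth_beaten = beaten,
               best_correct = identical(sort(best_supp), truth_supp),
               fn = length(setdiff(truth_supp, best_supp)),
               fp = length(setdiff(best_supp, truth_supp)),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  list(per_sample = per_sample,
       summary = data.frame(
         n = nrow(per_sample),
         n_truth_beaten = sum(per_sample$truth_beaten),
         n_best_correct = sum(per_sample$best_correct),
         mean_fn = mean(per_sample$fn),
         mean_fp = mean(per_sample$fp)))
}
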