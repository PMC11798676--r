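# Evaluation measures for comparing an inferred attribution against ground
# truth over a fixed signature universe (the signatures known to occur in
# the cancer type).

#' Metrics configuration
#'
#' @param epsilon Smoothing constant added to estimated proportions in the
#'   denominator of the KL divergence; default 0.001.
#' @return An object of class \code{metrics_config}.
#' @export
metrics_config <- function(epsilon = 0.001) {
  stopifnot(epsilon > 0)
  structure(list(epsilon = epsilon), class = "metrics_config")
}

activity_vector <- function(attrib, universe) {
  act <- if (inherits(attrib, "attribution")) attrib$activities else attrib
  out <- stats::setNames(numeric(length(universe)), universe)
  if (length(act)) {
    outside <- setdiff(names(act), universe)
    if (length(outside))
      stop("signature(s) outside universe: ",
           paste(outside, collapse = ", "))
    out[names(act)] <- act
  }
  out
}

#' Presence/absence confusion counts
#'
#' Presence on either side is defined as activity > 0. TP counts
#' signatures present in both truth and inference; FP present only in the
#' inference; FN only in truth; TN in neither.
#'
#' @param truth,inferred \code{\link{attribution}} objects (or named
#'   activity vectors).
#' @param universe Character vector of all signature names offered.
#' @return List with \code{tp}, \code{fp}, \code{tn}, \code{fn}, \code{p}
#'   (ground-truth positives) and \code{universe_size}.
#' @export
confusion_counts <- function(truth, inferred, universe) {
  x <- activity_vector(truth, universe) > 0
  y <- activity_vector(inferred, universe) > 0
  list(tp = sum(x & y), fp = sum(!x & y), tn = sum(!x & !y),
       fn = sum(x & !y), p = sum(x), universe_size = length(universe))
}

#' Evaluate one inferred attribution against ground truth
#'
#' Computes precision, recall (sensitivity), specificity, F1, the scaled
#' Manhattan and scaled L2 distances between the activity vectors over the
#' universe (each divided by the sample's total mutation count M), the
#' base-2 KL divergence of activity proportions (truth relative to
#' inference, denominator smoothed by epsilon), and the Combined Score
#' (1 - scaled Manhattan) + precision + recall, whose maximum 3 is reached
#' exactly at perfect set recovery with exact activities.
#'
#' An empty inferred attribution has precision 1 (no false positives to
#' penalize) and recall 0.
#'
#' @param truth,inferred \code{\link{attribution}} objects or named
#'   activity vectors.
#' @param universe Character vector of all signatures offered.
#' @param spectrum_total Total mutation count M of the sample (> 0).
#' @param config A \code{\link{metrics_config}}.
#' @return A one-row data.frame with columns \code{precision},
#'   \code{recall}, \code{specificity}, \code{f1}, \code{scaled_manhattan},
#'   \code{scaled_l2}, \code{kl_divergence}, \code{combined_score}.
#' @export
evaluate_sample <- function(truth, inferred, universe, spectrum_total,
                            config = metrics_config()) {
  stopifnot(spectrum_total > 0)
  x <- activity_vector(truth, universe)
  y <- activity_vector(inferred, universe)
  cc <- confusion_counts(x, y, universe)
  precision <- if (cc$tp + cc$fp == 0) 1 else cc$tp / (cc$tp + cc$fp)
  recall <- if (cc$p == 0) 1 else cc$tp / cc$p
  specificity <- if (cc$tn + cc$fp == 0) 1 else cc$tn / (cc$tn + cc$fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  sm <- sum(abs(x - y)) / spectrum_total
  sl2 <- sqrt(sum((x - y)^2)) / spectrum_total
  # KL over activity proportions, base 2, eps-smoothed denominator;
  # terms with X_i = 0 contribute 0 (0 log 0 convention)
  xp <- if (sum(x) > 0) x / sum(x) else x
  yp <- if (sum(y) > 0) y / sum(y) else y
  sup <- xp > 0
  kl <- sum(xp[sup] * log2(xp[sup] / (yp[sup] + config$epsilon)))
  data.frame(precision = precision, recall = recall,
             specificity = specificity, f1 = f1,
             scaled_manhattan = sm, scaled_l2 = sl2,
             kl_divergence = kl,
             combined_score = (1 - sm) + precision + recall)
}

#' Summarize evaluations across samples, approaches and cancer types
#'
#' @param evaluations data.frame of per-sample measures (as returned by
#'   \code{\link{evaluate_sample}}, row-bound) with additional label
#'   columns \code{approach} and \code{cancer_type}.
#' @return List with \code{by_group} (mean/median/SD of each measure per
#'   approach x cancer type), \code{overall} (per approach, across cancer
#'   types) and dense ranks by descending mean Combined Score in
#'   \code{overall$rank} (ties share a rank).
#' @export
summarize_evaluations <- function(evaluations) {
  stopifnot(nrow(evaluations) >= 1,
            all(c("approach", "cancer_type") %in% names(evaluations)))
  measures <- c("precision", "recall", "specificity", "f1",
                "scaled_manhattan", "scaled_l2", "kl_divergence",
                "combined_score")
  agg <- function(df) {
    stats_row <- lapply(measures, function(m)
      c(mean = mean(df[[m]]), median = stats::median(df[[m]]),
        sd = stats::sd(df[[m]])))
    out <- as.data.frame(t(unlist(stats_row)))
    names(out) <- as.vector(outer(c("mean", "median", "sd"), measures,
                                  function(s, m) paste(m, s, sep = "_")))
    out
  }
  grp <- split(evaluations,
               interaction(evaluations$approach, evaluations$cancer_type,
                           drop = TRUE, sep = "||"))
  by_group <- do.call(rbind, lapply(names(grp), function(g) {
    parts <- strsplit(g, "||", fixed = TRUE)[[1]]
    cbind(data.frame(approach = parts[1], cancer_type = parts[2],
                     n = nrow(grp[[g]]), stringsAsFactors = FALSE),
          agg(grp[[g]]))
  }))
  ov <- split(evaluations, evaluations$approach)
  overall <- do.call(rbind, lapply(names(ov), function(a)
    cbind(data.frame(approach = a, n = nrow(ov[[a]]),
                     stringsAsFactors = FALSE), agg(ov[[a]]))))
  # dense rank by descending mean combined score; exact ties share a rank
  ms <- overall$combined_score_mean
  overall$rank <- match(-ms, sort(unique(-ms)))
  rownames(by_group) <- rownames(overall) <- NULL
  list(by_group = by_group, overall = overall)
}
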