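# Activity optimizers for a fixed signature subset: non-negative least
# squares (Lawson-Hanson active set) and maximum likelihood under the
# multinomial or negative binomial count models.

# Lawson-Hanson NNLS: minimize ||A x - b||_2 subject to x >= 0.
# Active-set method; exact for this small, dense, convex problem.
lawson_hanson_nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))           # gradient of -0.5*RSS at x = 0
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- tryCatch(
        drop(solve(crossprod(A[, P, drop = FALSE]),
                   crossprod(A[, P, drop = FALSE], b))),
        error = function(e) {
          drop(qr.coef(qr(A[, P, drop = FALSE]), b))
        })
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Non-negative least squares activity fit
#'
#' Finds activities minimizing the Euclidean norm of \code{D - H A}
#' subject to \code{A >= 0} (the convex problem solved by quadratic
#' programming in NNLS-based attribution tools). The solution is the global
#' optimum.
#'
#' @param spectrum A \code{\link{spectrum}}.
#' @param catalog A \code{\link{signature_catalog}} restricted to the
#'   signature subset to fit.
#' @return An object of class \code{fit_result}: list with
#'   \code{attribution} (signatures with positive activity only),
#'   \code{activities} (full named vector incl. zeros), \code{objective}
#'   (residual Euclidean norm), \code{converged}, \code{n_evals}.
#' @export
nnls_fit <- function(spectrum, catalog) {
  if (length(catalog$names) == 0) stop("empty signature subset")
  H <- catalog$matrix
  d <- as.numeric(spectrum$counts)
  x <- lawson_hanson_nnls(H, d)
  names(x) <- catalog$names
  resid <- sqrt(sum((d - drop(H %*% x))^2))
  structure(list(attribution = attribution(x, spectrum$sample_id),
                 activities = x, objective = resid,
                 converged = TRUE, n_evals = NA_integer_),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective = %.6g, converged = %s\n",
              x$objective, x$converged))
  print(x$attribution)
  invisible(x)
}

# Objective and gradient on the log-activity scale (guarantees a > 0;
# activities below exp(LOWER) are treated as absent on return).
mle_objective <- function(model, H, d, dispersion) {
  M <- sum(d)
  colsum <- colSums(H)
  lg_const <- lgamma(M + 1) - sum(lgamma(d + 1))
  if (model == "multinomial") {
    fn <- function(t) {
      a <- exp(t)
      c_ <- floor_expected(drop(H %*% a))
      -(lg_const + sum(d * log(c_ / sum(c_))))
    }
    gr <- function(t) {
      a <- exp(t)
      c_ <- floor_expected(drop(H %*% a))
      g_a <- drop(crossprod(H, d / c_)) - M * colsum / sum(c_)
      -g_a * a
    }
  } else {
    r <- dispersion
    fn <- function(t) {
      a <- exp(t)
      c_ <- floor_expected(drop(H %*% a))
      -sum(stats::dnbinom(d, size = r, mu = c_, log = TRUE))
    }
    gr <- function(t) {
      a <- exp(t)
      c_ <- floor_expected(drop(H %*% a))
      g_c <- d / c_ - (d + r) / (c_ + r)
      -drop(crossprod(H, g_c)) * a
    }
  }
  list(fn = fn, gr = gr)
}

#' Maximum-likelihood activity fit
#'
#' Maximizes the multinomial or negative-binomial log-likelihood of the
#' spectrum over non-negative activities for a fixed signature subset.
#' Optimization is bounded quasi-Newton (L-BFGS-B) over log-activities,
#' initialized at the NNLS solution (zeros replaced by a small positive
#' value), which makes the fit deterministic. Under the multinomial model
#' only activity proportions are identifiable; the returned activities are
#' rescaled to sum to the spectrum total.
#'
#' @param spectrum A \code{\link{spectrum}} with at least one mutation.
#' @param catalog A restricted \code{\link{signature_catalog}}.
#' @param model \code{"multinomial"} or \code{"negbinom"}.
#' @param dispersion Negative-binomial size parameter (ignored for the
#'   multinomial model).
#' @return A \code{fit_result}; \code{objective} is the achieved
#'   log-likelihood.
#' @export
mle_fit <- function(spectrum, catalog,
                    model = c("multinomial", "negbinom"),
                    dispersion = 100) {
  model <- match.arg(model)
  if (length(catalog$names) == 0) stop("empty signature subset")
  if (spectrum$total <= 0) stop("spectrum has no mutations")
  H <- catalog$matrix
  d <- as.numeric(spectrum$counts)
  obj <- mle_objective(model, H, d, dispersion)

  init <- nnls_fit(spectrum, catalog)$activities
  init[init < 1e-4 * spectrum$total] <- 1e-4 * spectrum$total
  lower <- log(1e-6 * spectrum$total)
  upper <- log(10 * max(spectrum$total, 1))
  t0 <- pmin(pmax(log(init), lower), upper)

  run <- function(t_start) {
    stats::optim(t_start, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 2000, factr = 1e4))
  }
  res <- run(t0)
  converged <- res$convergence == 0
  if (!converged) {                     # one perturbed restart
    res2 <- run(pmin(pmax(t0 + 0.5, lower), upper))
    if (res2$value < res$value) res <- res2
    converged <- res$convergence == 0 || res2$convergence == 0
  }
  a <- exp(res$par)
  names(a) <- catalog$names
  eval_ll <- function(act) {
    ec <- expected_counts(catalog, act)
    if (model == "multinomial") multinomial_loglik(spectrum, ec)
    else negbinom_loglik(spectrum, ec, dispersion)
  }
  # activities pinned near the lower bound are numerically absent; zeroing
  # them also restores exact nested-model monotonicity (a superset model
  # can always mimic a subset by dropping the extra signature entirely,
  # which the log-scale bound alone cannot represent)
  a_thr <- a
  a_thr[a_thr <= 2e-6 * spectrum$total] <- 0
  if (any(a_thr > 0) && eval_ll(a_thr) >= eval_ll(a)) a <- a_thr
  loglik <- eval_ll(a)
  if (model == "multinomial") a <- a * spectrum$total / sum(a)
  structure(list(attribution = attribution(a, spectrum$sample_id),
                 activities = a, objective = loglik,
                 converged = converged,
                 n_evals = sum(res$counts, na.rm = TRUE)),
            class = "fit_result")
}
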