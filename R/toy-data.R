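# Deterministic toy signatures and generator parameters. These keep all
# tests and examples self-contained: the toy signatures are near-orthogonal
# (each concentrates most of its mass on its own block of channels), which
# is the easy regime where attribution is expected to work, while still
# exercising every code path of the real COSMIC-scale workflow.

#' Toy signature catalog
#'
#' Builds \code{n_sig} deterministic, near-orthogonal signatures over the
#' SBS96 scheme. Signature j places \code{1 - background} of its mass on
#' the j-th block of \code{96 / n_sig} channels (with a per-signature
#' within-block shape so no two signatures are scalar multiples) and
#' spreads the remaining \code{background} mass uniformly over all
#' channels.
#'
#' @param n_sig Number of signatures (a divisor of 96; default 6).
#' @param background Off-block uniform mass per signature (default 0.10).
#' @return A \code{\link{signature_catalog}} with signatures
#'   \code{TS01 ... TS<n>}.
#' @export
toy_catalog <- function(n_sig = 6, background = 0.10) {
  stopifnot(n_sig >= 2, 96 %% n_sig == 0, background >= 0, background < 1)
  sc <- channel_scheme("SBS96")
  block <- 96 / n_sig
  mat <- matrix(background / 96, nrow = 96, ncol = n_sig,
                dimnames = list(sc$labels, sprintf("TS%02d", seq_len(n_sig))))
  for (j in seq_len(n_sig)) {
    idx <- ((j - 1) * block + 1):(j * block)
    shape <- 1 + (seq_len(block) + j) %% 5       # varies by signature
    mat[idx, j] <- mat[idx, j] + (1 - background) * shape / sum(shape)
  }
  signature_catalog(mat, scheme = sc, tol = 1e-9)
}

#' Toy generator parameters
#'
#' Two pseudo cancer-type parameter sets over the signatures of
#' \code{\link{toy_catalog}}, emulating the shape of real per-cancer-type
#' activity models: a few near-ubiquitous signatures with large, highly
#' dispersed activities plus rarer signatures with smaller activities.
#' Activity means span roughly 500 to 8000 mutations with negative-binomial
#' sizes of 1 to 3 (strongly overdispersed, as in real attribution tables);
#' the default channel dispersion of 50 yields reconstruction accuracies in
#' the range seen in real data.
#'
#' @param cancer_type One of \code{"ToyType1"} (6 signatures, mixed
#'   prevalences) or \code{"ToyType2"} (4 signatures, sparser tumors).
#' @param channel_dispersion Channel-count size parameter (default 50).
#' @return A \code{\link{generator_params}} object.
#' @export
toy_generator_params <- function(cancer_type = c("ToyType1", "ToyType2"),
                                 channel_dispersion = 50) {
  cancer_type <- match.arg(cancer_type)
  sigs <- if (cancer_type == "ToyType1") {
    data.frame(
      signature = sprintf("TS%02d", 1:6),
      prevalence = c(0.95, 0.80, 0.60, 0.40, 0.30, 0.20),
      activity_size = c(2, 2, 1.5, 1, 1, 3),
      activity_mu = c(8000, 4000, 2000, 1000, 500, 1500),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      signature = sprintf("TS%02d", 1:4),
      prevalence = c(1.00, 0.50, 0.35, 0.25),
      activity_size = c(3, 1.5, 1, 2),
      activity_mu = c(5000, 1500, 800, 2500),
      stringsAsFactors = FALSE)
  }
  generator_params(cancer_type, sigs, channel_dispersion)
}

#' Read or write generator parameters as JSON
#'
#' @param params A \code{\link{generator_params}} object.
#' @param path File path.
#' @return \code{write_generator_params}: \code{path}, invisibly;
#'   \code{read_generator_params}: a \code{generator_params} object.
#' @export
write_generator_params <- function(params, path) {
  jsonlite::write_json(
    list(cancer_type = params$cancer_type,
         channel_dispersion = params$channel_dispersion,
         signatures = params$signatures),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_params
#' @export
read_generator_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  disp <- x$channel_dispersion
  if (!is.null(names(disp)) && length(names(disp)) == 0) names(disp) <- NULL
  generator_params(x$cancer_type, as.data.frame(x$signatures), disp)
}
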