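# Containers for spectra, signature catalogs and attributions, plus
# COSMIC-style tab-separated matrix I/O.

#' Mutational spectrum of one sample
#'
#' @param counts Named or unnamed numeric vector of non-negative integer
#'   mutation counts, one per channel of \code{scheme}. Values within 1e-6
#'   of an integer are rounded; other non-integers are rejected.
#' @param scheme A \code{\link{channel_scheme}}, or \code{NULL} to infer it
#'   from the names of \code{counts}.
#' @param sample_id Sample identifier.
#' @return An object of class \code{spectrum}: list with \code{sample_id},
#'   \code{scheme}, \code{counts} (named, canonical channel order) and
#'   \code{total}.
#' @export
spectrum <- function(counts, scheme = NULL, sample_id = "sample") {
  if (is.null(scheme)) {
    if (is.null(names(counts)))
      stop("counts must be named when no scheme is given")
    scheme <- infer_scheme(names(counts))
    if (is.null(scheme))
      stop("could not infer channel scheme from count names")
  }
  counts <- canonicalize_counts(counts, scheme, "spectrum")
  counts <- validate_counts(counts, "spectrum")
  structure(list(sample_id = sample_id, scheme = scheme,
                 counts = counts, total = sum(counts)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %s, %d mutations over %d channels\n",
              x$sample_id, x$scheme$name, x$total, x$scheme$k))
  invisible(x)
}

#' Catalog of mutational signatures
#'
#' Each column of \code{mat} is one signature: a multinomial probability
#' vector over the channels of \code{scheme} (non-negative, summing to 1
#' within \code{tol}).
#'
#' @param mat Numeric matrix, channels x signatures, with row names giving
#'   channel labels and column names giving signature names.
#' @param scheme A \code{\link{channel_scheme}} or \code{NULL} to infer.
#' @param tol Allowed deviation of each column sum from 1 (default 1e-3,
#'   matching the tolerance applied to files written by other tools);
#'   columns are renormalized to sum to exactly 1 after validation.
#' @return An object of class \code{signature_catalog} with elements
#'   \code{scheme}, \code{names} and \code{matrix} (k x g, canonical row
#'   order, columns renormalized).
#' @export
signature_catalog <- function(mat, scheme = NULL, tol = 1e-3) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("signature matrix must have row names")
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("Sig", seq_len(ncol(mat)))
  if (is.null(scheme)) {
    scheme <- infer_scheme(rownames(mat))
    if (is.null(scheme))
      stop("could not infer channel scheme from signature row labels")
  }
  mat <- canonicalize_rows(mat, scheme, "signature catalog")
  if (any(mat < 0))
    stop("signature catalog contains negative values")
  cs <- colSums(mat)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad))
    stop(sprintf("signature column(s) do not sum to 1 (tolerance %g): %s",
                 tol,
                 paste(sprintf("%s (sum %.6f)", colnames(mat)[bad], cs[bad]),
                       collapse = ", ")))
  mat <- sweep(mat, 2, cs, "/")
  structure(list(scheme = scheme, names = colnames(mat), matrix = mat),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("<signature_catalog> %s: %d signatures (%s)\n",
              x$scheme$name, length(x$names),
              paste(utils::head(x$names, 6), collapse = ", ")))
  invisible(x)
}

#' Restrict a catalog to a subset of signatures
#'
#' @param catalog A \code{\link{signature_catalog}}.
#' @param names Character vector of signature names to keep (order kept).
#' @return A \code{signature_catalog} with only the requested columns.
#' @export
restrict_catalog <- function(catalog, names) {
  missing <- setdiff(names, catalog$names)
  if (length(missing))
    stop("unknown signature(s): ", paste(missing, collapse = ", "))
  m <- catalog$matrix[, names, drop = FALSE]
  structure(list(scheme = catalog$scheme, names = names, matrix = m),
            class = "signature_catalog")
}

#' Signature attribution for one sample
#'
#' An attribution maps signature names to strictly positive activities
#' (numbers of mutations ascribed to each signature). Zero or negative
#' activities are dropped, so absence from the mapping means activity 0.
#'
#' @param activities Named numeric vector of activities.
#' @param sample_id Sample identifier.
#' @return An object of class \code{attribution}.
#' @export
attribution <- function(activities = numeric(0), sample_id = "sample") {
  if (length(activities) && is.null(names(activities)))
    stop("activities must be named by signature")
  activities <- activities[activities > 0]
  if (anyDuplicated(names(activities)))
    stop("duplicated signature names in activities")
  if (length(activities))
    activities <- activities[order(names(activities))]
  else
    activities <- stats::setNames(numeric(0), character(0))
  structure(list(sample_id = sample_id, activities = activities),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  if (!length(x$activities)) {
    cat(sprintf("<attribution> %s: empty\n", x$sample_id))
  } else {
    cat(sprintf("<attribution> %s: %s\n", x$sample_id,
                paste(sprintf("%s=%.1f", names(x$activities), x$activities),
                      collapse = ", ")))
  }
  invisible(x)
}

# ---- TSV I/O ---------------------------------------------------------------

ROW_LABEL_HEADERS <- c("MutationType", "Mutation Type", "Type", "MutationsType",
                       "Mutation_Type", "Signature", "")

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least two tab-separated columns in ", path)
  first <- names(df)[1]
  if (!(first %in% ROW_LABEL_HEADERS || grepl("^X(\\.[0-9]+)?$", first) ||
        first %in% c("V1")))
    # tolerate any unrecognized first header: it is the row-label column by
    # position, but warn so silently mislabeled files are noticed
    warning("treating first column '", first, "' as row labels")
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric entries in matrix file ", path)
  rownames(mat) <- labels
  mat
}

#' Load a COSMIC-style tab-separated matrix
#'
#' Reads a tab-separated file whose first column holds mutation-type labels
#' (header \code{MutationType}, \code{Mutation Type}, \code{Type} or
#' unnamed) and whose remaining columns are samples (\code{role =
#' "spectra"}), signatures (\code{role = "signatures"}) or samples of an
#' activity table (\code{role = "activities"}, rows = signatures). Rows are
#' reordered into the canonical channel order of the scheme regardless of
#' input order.
#'
#' @param path Path to a TSV file (UTF-8; Unix or Windows line endings).
#' @param role One of \code{"spectra"}, \code{"signatures"},
#'   \code{"activities"}.
#' @param scheme A \code{\link{channel_scheme}} or \code{NULL} to infer
#'   (ignored for \code{role = "activities"}).
#' @return For \code{"spectra"}: a list of \code{\link{spectrum}} objects,
#'   one per column. For \code{"signatures"}: a
#'   \code{\link{signature_catalog}}. For \code{"activities"}: a numeric
#'   matrix signatures x samples.
#' @export
load_matrix_tsv <- function(path, role = c("spectra", "signatures",
                                           "activities"),
                            scheme = NULL) {
  role <- match.arg(role)
  mat <- read_tsv_matrix(path)
  if (role == "activities") {
    if (any(mat < 0)) stop("negative values in activity table ", path)
    return(mat)
  }
  if (is.null(scheme)) {
    scheme <- infer_scheme(rownames(mat))
    if (is.null(scheme)) {
      known <- unique(unlist(lapply(c("SBS96", "DBS78", "ID83"),
                                    function(n) channel_scheme(n)$labels)))
      bad <- setdiff(rownames(mat), known)
      stop("unknown mutation-type labels in ", path, ": ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  if (role == "signatures") {
    signature_catalog(mat, scheme = scheme)
  } else {
    lapply(colnames(mat), function(s)
      spectrum(stats::setNames(mat[, s], rownames(mat)), scheme = scheme,
               sample_id = s))
  }
}

#' Write a matrix, spectra or catalog as a COSMIC-style TSV
#'
#' @param x A \code{signature_catalog}, a list of \code{spectrum} objects,
#'   or a numeric matrix with row names.
#' @param path Output file path (written with Unix line endings).
#' @param label_header Header for the row-label column.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(x, path, label_header = "MutationType") {
  if (inherits(x, "signature_catalog")) {
    mat <- x$matrix
  } else if (is.list(x) && length(x) && inherits(x[[1]], "spectrum")) {
    mat <- sapply(x, function(s) s$counts)
    colnames(mat) <- vapply(x, function(s) s$sample_id, character(1))
    rownames(mat) <- x[[1]]$scheme$labels
  } else {
    mat <- as.matrix(x)
  }
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

# Reorder matrix rows into canonical scheme order, validating labels.
canonicalize_rows <- function(mat, scheme, what) {
  labs <- rownames(mat)
  unknown <- setdiff(labs, scheme$labels)
  if (length(unknown))
    stop(sprintf("%s has labels not in scheme %s: %s", what, scheme$name,
                 paste(utils::head(unknown, 10), collapse = ", ")))
  missing <- setdiff(scheme$labels, labs)
  if (length(missing))
    stop(sprintf("%s is missing labels of scheme %s: %s", what, scheme$name,
                 paste(utils::head(missing, 10), collapse = ", ")))
  if (anyDuplicated(labs)) stop(what, " has duplicated row labels")
  mat[scheme$labels, , drop = FALSE]
}

canonicalize_counts <- function(counts, scheme, what) {
  if (!is.null(names(counts))) {
    m <- canonicalize_rows(matrix(counts, ncol = 1,
                                  dimnames = list(names(counts), NULL)),
                           scheme, what)
    counts <- stats::setNames(m[, 1], rownames(m))
  } else {
    if (length(counts) != scheme$k)
      stop(sprintf("%s has %d channels; scheme %s expects %d", what,
                   length(counts), scheme$name, scheme$k))
    names(counts) <- scheme$labels
  }
  counts
}

validate_counts <- function(counts, what) {
  if (any(counts < 0)) stop(what, " contains negative counts")
  r <- round(counts)
  if (any(abs(counts - r) > 1e-6))
    stop(what, " contains non-integer counts")
  r
}

# ---- Cosine similarity -----------------------------------------------------

#' Cosine similarity between two non-negative vectors
#'
#' @param u,v Numeric non-negative vectors of equal length, each with at
#'   least one positive entry.
#' @return \code{sum(u*v) / (||u|| ||v||)}, in \code{[0, 1]} for
#'   non-negative inputs.
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0)) # 1/sqrt(2)
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}
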