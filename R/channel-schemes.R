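# Canonical mutation-type channel schemes (COSMIC conventions).
#
# All matrices loaded by the package are re-sorted into these orders, so
# inputs written by different tools (which disagree on row order) compare
# equal after loading.

#' Channel scheme for a class of mutation types
#'
#' A channel scheme fixes the ordered set of mutation-type labels that index
#' the rows of spectra and signature catalogs. Three schemes are supported:
#' \code{SBS96} (single-base substitutions in trinucleotide context),
#' \code{DBS78} (doublet-base substitutions) and \code{ID83} (small
#' insertions and deletions). Label sets and their canonical order follow
#' the COSMIC mutational-signature site conventions.
#'
#' @param name One of \code{"SBS96"}, \code{"DBS78"}, \code{"ID83"}.
#' @return An object of class \code{channel_scheme} with elements
#'   \code{name}, \code{labels} (ordered character vector) and \code{k}
#'   (number of channels: 96, 78 or 83).
#' @examples
#' channel_scheme("SBS96")$k # 96
#' head(channel_scheme("DBS78")$labels)
#' @export
channel_scheme <- function(name = c("SBS96", "DBS78", "ID83")) {
  name <- match.arg(name)
  labels <- switch(name,
    SBS96 = sbs96_labels(),
    DBS78 = dbs78_labels(),
    ID83  = id83_labels()
  )
  stopifnot(!anyDuplicated(labels))
  structure(list(name = name, labels = labels, k = length(labels)),
            class = "channel_scheme")
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat(sprintf("<channel_scheme> %s: %d channels (%s ... %s)\n",
              x$name, x$k, x$labels[1], x$labels[x$k]))
  invisible(x)
}

# 6 pyrimidine-centric substitution classes x 16 flanking contexts.
# COSMIC file order: substitution-major, then 5' base, then 3' base.
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    unlist(lapply(bases, function(b5)
      paste0(b5, "[", s, "]", bases)))
  }), use.names = FALSE)
}

# 78 doublet-base substitutions: 10 reference doublets, each with the
# alternate doublets that are not reverse-complement-equivalent duplicates.
dbs78_labels <- function() {
  alts <- list(
    AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
    AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
    CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
    CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
    CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
    GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
    TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
    TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
    TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
    TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG")
  )
  unlist(lapply(names(alts), function(ref)
    paste0(ref, ">", alts[[ref]])), use.names = FALSE)
}

# 83 indel channels: 1-bp deletions/insertions split by C/T and homopolymer
# length, longer deletions/insertions by repeat count, and deletions with
# flanking microhomology.
id83_labels <- function() {
  lab <- function(size, type, subtype, len)
    paste(size, type, subtype, len, sep = ":")
  c(
    lab(1, "Del", "C", 0:5), lab(1, "Del", "T", 0:5),
    lab(1, "Ins", "C", 0:5), lab(1, "Ins", "T", 0:5),
    lab(2, "Del", "R", 0:5), lab(3, "Del", "R", 0:5),
    lab(4, "Del", "R", 0:5), lab(5, "Del", "R", 0:5),
    lab(2, "Ins", "R", 0:5), lab(3, "Ins", "R", 0:5),
    lab(4, "Ins", "R", 0:5), lab(5, "Ins", "R", 0:5),
    lab(2, "Del", "M", 1), lab(3, "Del", "M", 1:2),
    lab(4, "Del", "M", 1:3), lab(5, "Del", "M", 1:5)
  )
}

# Guess the scheme from a set of row labels; NULL if no scheme matches.
infer_scheme <- function(labels) {
  for (nm in c("SBS96", "DBS78", "ID83")) {
    sc <- channel_scheme(nm)
    if (all(labels %in% sc$labels)) return(sc)
  }
  NULL
}
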