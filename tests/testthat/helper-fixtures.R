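# Shared fixtures, all built in code.

cat6 <- toy_catalog(6)
cat4 <- toy_catalog(4)
sc96 <- channel_scheme("SBS96")

# exact (noise-free) spectrum from integer activities
exact_spectrum <- function(catalog, activities, id = "exact") {
  ec <- expected_counts(catalog, activities)
  spectrum(round(ec$values), catalog$scheme, id)
}

# spectrum with multinomial sampling noise from given activities
sampled_spectrum <- function(catalog, activities, id = "sampled") {
  ec <- expected_counts(catalog, activities)
  counts <- stats::rmultinom(1, size = round(sum(activities)),
                             prob = ec$pi)[, 1]
  spectrum(stats::setNames(counts, catalog$scheme$labels), catalog$scheme,
           id)
}
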