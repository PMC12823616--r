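## shared, lazily built objects (cascade tables are the only mildly
## expensive constructions; build each at most once per test run)
.cache <- new.env(parent = emptyenv())

cached_basis <- function(order = 4, T = 1, J = 5, augment = 0,
                         mode = "scaling_only") {
  key <- paste(order, T, J, augment, mode, sep = "|")
  if (is.null(.cache[[key]]))
    .cache[[key]] <- wavelet_basis(order = order, T = T, J = J,
                                   mode = mode, augment = augment)
  .cache[[key]]
}

## closed-form db2 filter (independent of the spectral factorization code)
db2_exact <- c((1 + sqrt(3)) / (4 * sqrt(2)),
               (3 + sqrt(3)) / (4 * sqrt(2)),
               (3 - sqrt(3)) / (4 * sqrt(2)),
               (1 - sqrt(3)) / (4 * sqrt(2)))

sup_rel_err <- function(got, ref, floor = 1) {
  max(abs(got - ref) / pmax(abs(ref), floor))
}
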