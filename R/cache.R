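# Per-raster memoization of derived products (components, boundaries,
# distance maps, validation). The cache is keyed on the label matrix of
# the most recent mask, so the repeated lookups inside one
# extractFeatureRow() (and across the spur/TPI/PB/ALCB stages) are
# computed once. Purely an evaluation cache: results are identical to the
# uncached computation.
.ubmCacheEnv <- new.env(parent = emptyenv())

.maskMemo <- function(mask, name, fn) {
  lab <- mask@labels
  if (is.null(.ubmCacheEnv$key) || !identical(.ubmCacheEnv$key, lab)) {
    .ubmCacheEnv$key <- lab
    .ubmCacheEnv$store <- new.env(parent = emptyenv())
  }
  st <- .ubmCacheEnv$store
  if (!exists(name, envir = st, inherits = FALSE))
    assign(name, fn(), envir = st)
  get(name, envir = st, inherits = FALSE)
}
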