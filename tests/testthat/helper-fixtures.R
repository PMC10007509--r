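# Shared fixtures: small phantom datasets and quickly trained models.

tiny_dataset <- function(n_train = 20, n_val = 5, n_test = 5, size = 32,
                         seed = 1, ...) {
  area <- if (size >= 32) c(20, 60) else c(6, 12)
  generate_dataset(n_train, n_val, n_test, height = size, width = size,
                   lesion_area = area, seed = seed, ...)
}

# a quickly trained model for inference-level tests (cached per kind)
.fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function(kind = "ae", epochs = 3, seed = 1) {
  key <- paste(kind, epochs, seed)
  if (is.null(.fit_cache[[key]])) {
    ds <- tiny_dataset()
    .fit_cache[[key]] <- anomaly_autoencoder(
      ds, kind, epochs = epochs, seed = seed, augment_gamma = FALSE)
  }
  .fit_cache[[key]]
}

random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}
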