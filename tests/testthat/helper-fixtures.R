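# Shared fixtures, built once per test file and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_config <- function() memo("config", phantom_config())

default_training <- function() {
  memo("training", generate_training_set(default_config(), seed = 0L))
}

default_basis <- function() memo("basis", fit_spectral_pca(default_training()))

default_eos_spectra <- function() {
  memo("eos", generate_training_set(
    default_config(),
    seed = 1L, n_per_class = 300L, classes = "eosinophil"
  ))
}

default_pair <- function() {
  memo("pair", select_band_pair(
    mean_class_error(default_basis(), default_eos_spectra()),
    default_config()$band_edges
  ))
}

small_phantom <- function(seed = 0L) {
  generate_phantom(phantom_config(width = 64L, height = 64L), seed = seed)
}

random_cube <- function(h = 4L, w = 4L, nb = 3L, kind = "transmittance") {
  spectral_cube(array(runif(h * w * nb), c(h, w, nb)),
    cbind(450 + 20 * (seq_len(nb) - 1), 465 + 20 * (seq_len(nb) - 1)),
    kind = kind
  )
}
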