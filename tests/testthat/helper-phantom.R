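# small, fast phantom used by unit tests (full-size phantoms are exercised
# in the acceptance tests)
small_spec <- function(..., vessels = list()) {
  phantom_spec(height = 96, width = 128,
               base_rows = c(24, 32, 42, 50, 57, 70, 77, 84),
               tilt = 2, bow = 2, vessels = vessels, ...)
}

no_crop <- function() oct_config(crop_fraction = 0)
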