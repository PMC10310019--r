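# internal helpers shared across modules

gbm_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "gutbrainmst_error"))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    gbm_abort(sprintf("`%s` must be a single finite number.", name),
              "gbm_invalid_config")
  }
  if (positive && x <= 0) {
    gbm_abort(sprintf("`%s` must be positive.", name), "gbm_invalid_config")
  }
  invisible(x)
}

# draw from a generator with the RNG state isolated and restored
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
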