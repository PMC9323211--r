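fixture_formulations <- function() {
  read_formulation_table(
    system.file("extdata", "ctab_preemulsions.csv", package = "ocurel"))
}

# model parameter sets used for synthetic fitting studies
study_model_params <- function() {
  list(
    "kink" = default_kink_params(),
    "korsmeyer-peppas" = list(k = 0.03, n = 0.45),
    "higuchi" = list(kH = 0.05),
    "hixson-crowell" = list(M0 = 0.9, kHC = 1 / 500),
    "weibull" = list(Minf = 0.9, lambda = 150, b = 1.4)
  )
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
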