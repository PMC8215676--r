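# shared fixtures, all generated in code

ref_surface <- reference_surface()

# Region-1 cell means from the default design at a given noise level
region1_cells <- function(seed, a = 0.02, b = 0) {
  dat <- generate_growth(noise = noise_model(a, b), seed = seed)
  cells <- aggregate_cells(dat)
  cells[!(cells$t >= 14 & cells$I > 400), , drop = FALSE]
}

# deterministic 2D logistic sample on the canonical sampling days
logistic2d_data <- function(seed, A = 400, k2 = 0.5, tc = 13,
                            rel_sd = 0.02,
                            days = c(0, 5, 8, 10, 14, 16)) {
  truth <- params_2d("logistic", A = A, k2 = k2, tc = tc)
  mu <- eval_2d(truth, days)
  set.seed(seed)
  data.frame(t = days, dw = mu * (1 + rnorm(length(days), 0, rel_sd)))
}
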