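# Feature tables with planted structure, used across the factor-analysis and
# discriminant tests.

# 22 observed parameters generated from 6 orthogonal latent factors in
# disjoint blocks (sizes 4,4,4,4,3,3) plus iid noise.
planted_factor_table <- function(n = 500, noise_sd = 0.2, seed = 1) {
  blocks <- rep(1:6, times = c(4, 4, 4, 4, 3, 3))
  gibbonsong:::with_seed(seed, {
    latent <- matrix(rnorm(n * 6), n)
    x <- latent[, blocks] + matrix(rnorm(n * 22, 0, noise_sd), n)
    colnames(x) <- call_parameter_names()
    list(table = as.data.frame(x), latent = latent, blocks = blocks)
  })
}

# small element-measure table shaped like measure_element() output
toy_elements <- function(onsets, durations, f0 = 800) {
  data.frame(
    start_f0 = f0, end_f0 = f0, max_f0 = f0, mean_f0 = f0,
    duration = durations, rel_loc_max_f0 = 0,
    onset = onsets, offset = onsets + durations
  )
}
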