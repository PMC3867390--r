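test_that("spectrogram geometry matches the analysis setup", {
  p <- spectrogram_params()
  res <- spectrogram_resolution(p)
  expect_equal(res$hop_s, 0.016)
  expect_equal(res$bin_hz, 31.25)

  # pure tone lands in the right bin
  t <- (0:15999) / 8000
  spec <- compute_spectrogram(sin(2 * pi * 1000 * t), p)
  peak <- spec$freq[which.max(spec$mag[, 50])]
  expect_lt(abs(peak - 1000), 31.25 / 2 + 1e-9)

  # resampling from 44.1 kHz preserves the tone
  t44 <- (0:44099) / 44100
  spec44 <- compute_spectrogram(sin(2 * pi * 700 * t44), p, input_rate = 44100)
  peak44 <- spec44$freq[which.max(spec44$mag[, 30])]
  expect_lt(abs(peak44 - 700), 31.25)

  expect_error(compute_spectrogram(numeric(0)), "empty")
  expect_error(spectrogram_params(fft_length = 300), "power of two")
  expect_error(spectrogram_params(threshold_db = 3), "negative")
})

test_that("element detection is silent on silence and monotone in threshold", {
  spec0 <- compute_spectrogram(numeric(8000))
  expect_length(extract_elements(spec0), 0)

  cfg <- simulation_config(seed = 8, snr_db = 40)
  prof <- data.frame(male_id = "M01", baseline_f0 = 700, age_class = "adult")
  wave <- synthesize_song(prof, 3, seed = 21, cfg)$wave
  frames_at <- function(th) {
    spec <- compute_spectrogram(wave, spectrogram_params(threshold_db = th))
    sum(vapply(extract_elements(spec, min_frames = 1), nrow, integer(1)))
  }
  counts <- vapply(seq(-5, -20, by = -2.5), frames_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("measured elements on near-noiseless audio match ground truth", {
  cfg <- simulation_config(seed = 5, snr_db = 60)
  pop <- simulate_population(cfg)
  syn <- synthesize_song(pop$males[2, ], 5, seed = 77, cfg)
  feats <- extract_call_features(syn$wave)
  truth <- syn$elements

  expect_equal(nrow(feats$elements), nrow(truth))         # every element found
  expect_equal(max(feats$elements$call_index), max(truth$call_index))

  hop <- 0.016; bin <- 31.25
  expect_lt(mean(abs(feats$elements$duration - (truth$offset - truth$onset))),
            2 * hop)
  for (v in c("start_f0", "end_f0", "max_f0")) {
    expect_lt(max(abs(feats$elements[[v]] - truth[[v]])), bin)
  }
  expect_lt(mean(abs(feats$elements$mean_f0 - truth$mean_f0)), bin / 2)

  # element intervals partition the call up to hop quantization
  for (ci in unique(feats$elements$call_index)) {
    el <- feats$elements[feats$elements$call_index == ci, ]
    gaps <- if (nrow(el) > 1) sum(el$onset[-1] - el$offset[-nrow(el)]) else 0
    call_dur <- el$offset[nrow(el)] - el$onset[1]
    expect_lt(abs(sum(el$duration) + gaps - call_dur), hop)
  }
})

test_that("contour measurement follows the stated conventions", {
  m <- measure_element(data.frame(time = c(0, 0.1, 0.2), f0 = c(700, 900, 950)))
  expect_equal(m$start_f0, 700)
  expect_equal(m$end_f0, 950)
  expect_equal(m$max_f0, 950)
  expect_equal(m$mean_f0, 850)
  expect_equal(m$rel_loc_max_f0, 1)
  expect_equal(m$duration, 0.2)

  flat <- measure_element(data.frame(time = c(0, 0.1, 0.2), f0 = c(800, 800, 800)))
  expect_equal(flat$start_f0, 800)
  expect_equal(flat$max_f0, 800)
  expect_equal(flat$rel_loc_max_f0, 0)       # first attainment of the maximum

  expect_error(measure_element(data.frame(time = 0, f0 = 700)), "2-frame")
})

test_that("call segmentation splits on the gap threshold", {
  # gaps between elements: 0.5, 0.5, 8.0, 0.5 s
  on <- c(0, 0.7, 1.4, 9.6, 10.3)
  el <- toy_elements(on, rep(0.2, 5))
  seg <- segment_calls(el, max_gap = 5)
  expect_equal(unname(table(seg$call_index)), array(c(3L, 2L)))

  single <- segment_calls(toy_elements(0, 0.3), max_gap = 5)
  expect_equal(single$call_index, 1L)
  expect_equal(single$offset - single$onset, 0.3)
})

test_that("call aggregation yields exactly the 22 parameters with block rules", {
  expect_length(call_parameter_names(), 22)

  el <- toy_elements(c(0, 0.5, 1.2), c(0.2, 0.4, 0.6))
  agg <- aggregate_call(el)
  acoustic <- agg[, call_parameter_names()]
  expect_equal(ncol(acoustic), 22)
  expect_equal(agg$mean_element_duration, 0.4)
  expect_equal(agg$maximum_element_duration, 0.6)
  expect_equal(agg$variation_element_duration, 0.2)
  # n-1 intervals: 0.3 and 0.3
  expect_equal(agg$mean_interval_duration, 0.3)
  expect_equal(agg$variation_interval_duration, 0)
  expect_equal(agg$call_duration, 1.8)
  # maximum >= mean for every measure with data
  for (nm in gibbonsong:::element_measures) {
    expect_gte(agg[[paste0("maximum_", nm)]], agg[[paste0("mean_", nm)]])
  }
  # identical elements: all variation entries zero
  same <- toy_elements(c(0, 0.5, 1.0), rep(0.3, 3))
  agg_same <- aggregate_call(same)
  expect_true(all(abs(agg_same[, grep("^variation_", names(agg_same))]) < 1e-12))

  # single-element call: interval and variation blocks missing, flagged
  one <- aggregate_call(toy_elements(0, 0.3))
  expect_true(one$flag_single_element)
  expect_true(is.na(one$mean_interval_duration))
  expect_true(all(is.na(one[, grep("^variation_", names(one))])))
  expect_equal(one$call_duration, 0.3)

  # coefficient-of-variation convention
  cv <- aggregate_call(el, variation = "cv")
  expect_equal(cv$variation_element_duration, 0.2 / 0.4)
})
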