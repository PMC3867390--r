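test_that("population structure covers the study's social organization", {
  cfg <- simulation_config(n_males = 14, seed = 1)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$males), 14)
  expect_true(any(pop$groups$type == "multimale"))
  expect_true(any(pop$groups$type == "pair"))
  expect_gte(length(unique(pop$males$age_class)), 2)
  expect_true(all(pop$males$baseline_f0 >= 400 & pop$males$baseline_f0 <= 1600))
  expect_true(all(pop$males$androgen_mean > 0))
  # statuses consistent with group composition
  multi <- pop$groups$group_id[pop$groups$type == "multimale"]
  expect_true(all(pop$males$status[pop$males$group_id %in% multi] %in%
                    c("multi_primary", "secondary")))
  expect_true(all(pop$males$status[!pop$males$group_id %in% multi] == "pair_primary"))

  pop2 <- simulate_population(cfg)
  expect_identical(pop, pop2)
  expect_error(simulate_population(simulation_config(n_males = 1)), "n_males")
})

test_that("the injected androgen-pitch effect is recoverable by OLS on profiles", {
  cfg <- simulation_config(n_males = 200, effect_androgen_pitch = 0.5, seed = 7)
  m <- simulate_population(cfg)$males
  z_a <- (log(m$androgen_mean) - log(cfg$androgen_location)) / cfg$androgen_between_sd
  pitch_sd_units <- (m$baseline_f0 - cfg$f0_center) / cfg$f0_sd
  slope <- coef(lm(pitch_sd_units ~ z_a))[["z_a"]]
  expect_lt(abs(slope - 0.5), 0.1)
})

test_that("synthesized songs have the expected call/element structure", {
  cfg <- simulation_config(seed = 2)
  prof <- data.frame(male_id = "M01", baseline_f0 = 700, age_class = "adult")
  syn <- synthesize_song(prof, 4, seed = 10, cfg)
  el <- syn$elements
  expect_equal(length(unique(el$call_index)), 4)
  counts <- table(el$call_index)
  expect_true(all(counts >= 3 & counts <= 50))
  # start F0 near the 700 Hz baseline
  expect_true(all(abs(el$start_f0 - 700) < 700 * 0.2))
  # truth invariants: ordered non-overlapping intervals, contour band
  expect_true(all(el$offset > el$onset))
  expect_true(all(diff(el$onset) > 0))
  expect_true(all(el$onset[-1] >= el$offset[-nrow(el)]))
  expect_true(all(el$max_f0 >= el$start_f0 & el$max_f0 >= el$end_f0))
  expect_true(all(el$max_f0 >= el$mean_f0))
  expect_true(all(el$rel_loc_max_f0 >= 0 & el$rel_loc_max_f0 <= 1))
  expect_true(all(el$max_f0 <= 2000))

  # determinism, and truth independent of audio rendering
  syn2 <- synthesize_song(prof, 4, seed = 10, cfg)
  expect_identical(syn$wave, syn2$wave)
  expect_identical(syn$elements, syn2$elements)
  syn3 <- synthesize_song(prof, 4, seed = 10, cfg, audio = FALSE)
  expect_null(syn3$wave)
  expect_identical(syn$elements, syn3$elements)

  # senior call durations scale by the age factor (same seed, same structure)
  prof_s <- data.frame(male_id = "M01", baseline_f0 = 700, age_class = "senior")
  syn_s <- synthesize_song(prof_s, 4, seed = 10, cfg, audio = FALSE)
  dur_a <- tapply(syn$elements$offset, syn$elements$call_index, max) -
    tapply(syn$elements$onset, syn$elements$call_index, min)
  dur_s <- tapply(syn_s$elements$offset, syn_s$elements$call_index, max) -
    tapply(syn_s$elements$onset, syn_s$elements$call_index, min)
  expect_equal(as.numeric(dur_s / dur_a), rep(cfg$effect_age_callduration, 4),
               tolerance = 1e-10)
})

test_that("androgen series cover recording days and match declared moments", {
  cfg <- simulation_config(seed = 3)
  prof <- list(male_id = "M01", androgen_mean = 150, androgen_sd = 37.5)
  days <- seq(10, 148, by = 6)           # 24 recording days
  fec <- simulate_androgen_series(prof, days, seed = 4, cfg)
  in_window <- vapply(days, function(d) {
    any(fec$collection_day - d >= 0 & fec$collection_day - d <= 7)
  }, logical(1))
  expect_gte(sum(in_window), 22)
  expect_true(all(fec$androgen > 0))

  prof0 <- list(male_id = "M02", androgen_mean = 150, androgen_sd = 0)
  fec0 <- simulate_androgen_series(prof0, days, seed = 4, cfg)
  expect_true(all(fec0$androgen == 150))

  # law of large numbers against the generator-declared mean
  big <- simulate_androgen_series(prof, seq_len(1000), seed = 9,
                                  simulation_config(seed = 3, study_span = 1100,
                                                    n_samples_per_male = 29))
  expect_lt(abs(mean(big$androgen) - 150) / 150, 0.02)
})

test_that("datasets round-trip through disk byte-identically", {
  cfg <- simulation_config(n_males = 3, seed = 6, calls_per_song_mean = 5)
  truth <- simulate_truth(cfg)
  dir <- withr::local_tempdir()
  write_dataset(truth, dir)
  expect_equal(length(list.files(dir, pattern = "\\.wav$")), nrow(truth$songs))

  back <- read_dataset(dir)
  expect_equal(back$males, truth$males, tolerance = 1e-12)
  expect_equal(back$fecal_samples$androgen, truth$fecal_samples$androgen,
               tolerance = 1e-12)
  expect_s3_class(back$fecal_samples$collection_date, "Date")
  # ISO-8601 dates on disk
  raw <- read.csv(file.path(dir, "fecal_samples.csv"), colClasses = "character")
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", raw$collection_date)))

  # re-rendered audio equals the lazily regenerated waveform (PCM quantization)
  sg <- truth$songs[1, ]
  wav <- read_wav(file.path(dir, paste0(sg$song_id, ".wav")))
  direct <- synthesize_song(truth$males[truth$males$male_id == sg$male_id, ],
                            sg$n_calls, sg$song_seed, cfg,
                            pitch_offset = sg$pitch_offset)$wave
  expect_equal(wav$sample_rate, 8000)
  expect_lt(max(abs(wav$wave - direct)), 1 / 32767)

  # byte-identical CSVs on re-simulation under the same seed
  truth2 <- simulate_truth(cfg)
  dir2 <- withr::local_tempdir()
  write_dataset(truth2, dir2)
  for (f in c("males.csv", "songs.csv", "elements_truth.csv", "fecal_samples.csv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("feature-level and model-level simulators expose their knobs", {
  d <- simulate_call_features(n_males = 4, calls_per_male = 10, days_per_male = 2,
                              separation = 5, seed = 2)
  expect_equal(nrow(d), 40)
  expect_equal(sum(grepl("^f\\d\\d$", names(d))), 22)
  expect_equal(length(unique(d$recording_day)), 8)
  # separation honored: minimum pairwise centroid distance >= 5 within-SDs
  cent <- aggregate(d[, -(1:2)], list(d$male_id), mean)[, -1]
  expect_gte(min(dist(cent)), 0.8 * 5)   # sample means jitter around truth

  m <- simulate_model_table(n_males = 6, days_per_male = 3, calls_per_song = 4,
                            seed = 5)
  expect_equal(nrow(m), 6 * 3 * 4)
  expect_true(all(abs(tapply(m$androgen_within, m$male_id, mean)) < 1e-10))
  expect_identical(m, simulate_model_table(n_males = 6, days_per_male = 3,
                                           calls_per_song = 4, seed = 5))
})
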