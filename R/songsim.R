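# Synthetic gibbon solo-song generator.
#
# Produces audio with ground-truth element annotations plus matched fecal
# androgen series, with the statistical structure the downstream analysis
# assumes: individually distinct frequency-modulated elements grouped into
# calls and songs, a between-male androgen -> pitch effect, an age -> call
# duration effect, and day-level temporal autocorrelation in the acoustic
# residuals.

#' Configuration for the song/hormone simulation
#'
#' Encodes the study conditions emulated by the generator: population size
#' and social structure, the injected effect sizes, noise levels, and the
#' temporal extent of the study.
#'
#' @param n_males number of males in the population (>= 2).
#' @param effect_androgen_pitch between-male androgen effect on baseline
#'   pitch, in SDs of pitch per SD of (log) mean androgen level.
#' @param effect_androgen_pitch_within within-male day-level androgen effect
#'   on pitch, same units; 0 by default (the between-subjects effect is the
#'   one the study design expects to carry signal).
#' @param effect_age_callduration multiplicative factor applied to element
#'   and interval durations of senior males, so senior calls are shorter by
#'   this factor.
#' @param ac_sigma_true bandwidth (days) of the injected day-level residual
#'   autocorrelation in pitch.
#' @param ac_amplitude SD of the autocorrelated pitch residual, in pitch SDs.
#' @param snr_db signal-to-noise ratio of the synthesized audio, dB.
#' @param seed master seed; fully determines all output.
#' @param study_span study duration in days.
#' @param f0_center population-central baseline fundamental frequency, Hz.
#' @param f0_sd between-male SD of baseline pitch, Hz.
#' @param androgen_location population-central mean fecal androgen level,
#'   ng/g epiandrosterone equivalents.
#' @param androgen_between_sd SD of log mean androgen across males.
#' @param androgen_cv within-male coefficient of variation of androgen.
#' @param n_samples_per_male target number of fecal samples per male
#'   (individual counts drawn in \[5, 29\]).
#' @param calls_per_song_mean mean number of calls per song.
#' @return an object of class `sim_config` (a named list).
#' @export
simulation_config <- function(n_males = 14,
                              effect_androgen_pitch = 0.5,
                              effect_androgen_pitch_within = 0,
                              effect_age_callduration = 0.75,
                              ac_sigma_true = 2,
                              ac_amplitude = 0.3,
                              snr_db = 40,
                              seed = 1,
                              study_span = 180,
                              f0_center = 700,
                              f0_sd = 60,
                              androgen_location = 150,
                              androgen_between_sd = 0.4,
                              androgen_cv = 0.25,
                              n_samples_per_male = 15,
                              calls_per_song_mean = 16) {
  if (n_males < 2) stop_input("n_males must be >= 2 (got %s)", n_males)
  stopifnot(is.finite(effect_androgen_pitch), is.finite(effect_age_callduration),
            ac_sigma_true > 0, study_span >= 14, androgen_location > 0)
  structure(list(
    n_males = as.integer(n_males),
    effect_androgen_pitch = effect_androgen_pitch,
    effect_androgen_pitch_within = effect_androgen_pitch_within,
    effect_age_callduration = effect_age_callduration,
    ac_sigma_true = ac_sigma_true,
    ac_amplitude = ac_amplitude,
    snr_db = snr_db,
    seed = as.integer(seed),
    study_span = as.integer(study_span),
    f0_center = f0_center,
    f0_sd = f0_sd,
    androgen_location = androgen_location,
    androgen_between_sd = androgen_between_sd,
    androgen_cv = androgen_cv,
    n_samples_per_male = as.integer(n_samples_per_male),
    calls_per_song_mean = calls_per_song_mean,
    study_start = as.Date("2008-10-01")
  ), class = "sim_config")
}

#' Simulate the male population and its group structure
#'
#' Males are allocated to pair-living groups (one adult male each) and
#' unifemale/multimale units (two or more males); social status follows the
#' allocation (the lone pair male, the primary male of a multimale unit, or a
#' secondary male). Age classes cover adults and seniors, with occasional
#' subadults that are carried descriptively but excluded from modeling.
#' Baseline pitch is tied to mean androgen level through
#' `effect_androgen_pitch`.
#'
#' @param config a [simulation_config()].
#' @return list with `males` (one row per male: `male_id`, `group_id`,
#'   `status`, `age_class`, `baseline_f0`, `androgen_mean`, `androgen_sd`,
#'   `n_recording_days`) and `groups` (group-level composition table).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_males
  with_seed(derive_seed(config$seed, 11L), {
    # group structure: ~2 multimale units with 2 males each at the reference
    # scale of 14 males (10 pair-living + 4 multimale males), >= 1 always
    n_multi <- max(1L, round(n / 7))
    multi_sizes <- rep(2L, n_multi)
    extra <- n - 0L
    # assign first 2*n_multi males to multimale units, rest pair-living
    male_id <- sprintf("M%02d", seq_len(n))
    group_id <- character(n)
    status <- character(n)
    k <- 1L
    for (g in seq_len(n_multi)) {
      for (j in seq_len(multi_sizes[g])) {
        if (k > n) break
        group_id[k] <- sprintf("G%02d", g)
        status[k] <- if (j == 1L) "multi_primary" else "secondary"
        k <- k + 1L
      }
    }
    g <- n_multi
    while (k <= n) {
      g <- g + 1L
      group_id[k] <- sprintf("G%02d", g)
      status[k] <- "pair_primary"
      k <- k + 1L
    }
    age_class <- sample(c("adult", "senior", "subadult"), n, replace = TRUE,
                        prob = c(0.60, 0.28, 0.12))
    # guarantee both modeled age classes are present
    if (!any(age_class == "adult")) age_class[1] <- "adult"
    if (!any(age_class == "senior")) age_class[which(age_class != "adult")[1] %||% n] <- "senior"
    if (!any(age_class == "senior")) age_class[n] <- "senior"

    z_a <- rnorm(n)                                   # standardized log androgen level
    androgen_mean <- config$androgen_location * exp(config$androgen_between_sd * z_a)
    androgen_sd <- androgen_mean * config$androgen_cv
    baseline_f0 <- config$f0_center +
      config$f0_sd * (config$effect_androgen_pitch * z_a + rnorm(n, 0, 0.75))
    baseline_f0 <- pmax(400, pmin(1600, baseline_f0))
    n_recording_days <- sample(2:4, n, replace = TRUE)

    males <- data.frame(
      male_id = male_id, group_id = group_id, status = status,
      age_class = age_class, baseline_f0 = baseline_f0,
      androgen_mean = androgen_mean, androgen_sd = androgen_sd,
      n_recording_days = n_recording_days,
      stringsAsFactors = FALSE
    )
    groups <- aggregate(list(n_males = males$male_id), by = list(group_id = males$group_id),
                        FUN = length)
    groups$type <- ifelse(groups$n_males > 1, "multimale", "pair")
    list(males = males, groups = groups)
  })
}

# Draw element structure for one call: element count, durations, intervals,
# and F0 contour anchors. pitch_hz is the day-level pitch driving this call.
draw_call_structure <- function(pitch_hz, dur_factor) {
  n_elem <- min(50L, 3L + rnbinom(1, size = 5, mu = 6))
  dur <- pmin(1.5, pmax(0.08, rlnorm(n_elem, log(0.27), 0.45))) * dur_factor
  gap <- if (n_elem > 1) {
    pmin(4.0, pmax(0.20, rlnorm(n_elem - 1, log(0.54), 0.45))) * dur_factor
  } else numeric(0)
  start_f0 <- pitch_hz * exp(rnorm(n_elem, 0, 0.04))
  max_f0 <- start_f0 * runif(n_elem, 1.30, 1.45)
  end_f0 <- max_f0 * runif(n_elem, 0.96, 1.00)
  rel_loc <- runif(n_elem, 0.67, 0.95)
  # keep contours inside the synthesis band
  scl <- pmin(1, 1950 / max_f0)
  list(n_elem = n_elem, dur = dur, gap = gap,
       start_f0 = start_f0 * scl, max_f0 = max_f0 * scl,
       end_f0 = end_f0 * scl, rel_loc = rel_loc)
}

# Instantaneous F0 of one element at times tau in [0, 1]: half-cosine rise
# from start to the maximum at rel_loc, then a shallow half-cosine decay to
# the end value (start F0 < end F0 ~ max F0).
element_f0_at <- function(tau, start_f0, max_f0, end_f0, rel_loc) {
  f <- numeric(length(tau))
  up <- tau <= rel_loc
  f[up] <- start_f0 + (max_f0 - start_f0) * (1 - cos(pi * tau[up] / rel_loc)) / 2
  f[!up] <- max_f0 - (max_f0 - end_f0) *
    (1 - cos(pi * (tau[!up] - rel_loc) / (1 - rel_loc))) / 2
  f
}

#' Synthesize one solo song with ground-truth annotations
#'
#' Renders a song as a sequence of calls, each a train of frequency-modulated
#' tonal elements (rising sweep to a late maximum), separated by silences of
#' at least 6 s between calls and short intervals within calls, over additive
#' broadband noise at `snr_db`. Element timing and contour anchors are drawn
#' from ranges emulating field measurements of adult white-handed gibbons;
#' senior males have element and interval durations scaled by
#' `effect_age_callduration`.
#'
#' @param profile one row of the `males` table from [simulate_population()]
#'   (or any list with `baseline_f0` and `age_class`).
#' @param n_calls number of calls (>= 1).
#' @param seed integer; structure and noise are each drawn from seeds derived
#'   from it, so truth tables can be regenerated without rendering audio.
#' @param config a [simulation_config()]; supplies the age factor and SNR.
#' @param pitch_offset additive day-level pitch offset in Hz (androgen
#'   within-day and autocorrelated components, supplied by
#'   [simulate_truth()]); default 0.
#' @param audio if `FALSE`, skip waveform rendering and return truth only.
#' @param sample_rate output rate, Hz.
#' @return list with `wave` (numeric, or `NULL` if `audio = FALSE`),
#'   `sample_rate`, and `elements`: one row per element with `onset`,
#'   `offset` (s, song-relative), `call_index`, `element_index`, and true
#'   `start_f0`, `end_f0`, `max_f0`, `mean_f0`, `rel_loc_max_f0`.
#' @export
synthesize_song <- function(profile, n_calls, seed, config = simulation_config(),
                            pitch_offset = 0, audio = TRUE, sample_rate = 8000) {
  if (n_calls < 1) stop_input("n_calls must be >= 1")
  dur_factor <- if (identical(profile$age_class, "senior")) config$effect_age_callduration else 1
  pitch_hz <- profile$baseline_f0 + pitch_offset

  structure_draws <- with_seed(derive_seed(seed, 1L), {
    calls <- lapply(seq_len(n_calls), function(i) draw_call_structure(pitch_hz, dur_factor))
    call_gaps <- runif(n_calls - 1, 6.5, 9.0)
    list(calls = calls, call_gaps = call_gaps)
  })
  calls <- structure_draws$calls
  call_gaps <- structure_draws$call_gaps

  # lay out elements on the song timeline
  rows <- vector("list", n_calls)
  t0 <- 1.0                                  # lead-in silence
  for (ci in seq_len(n_calls)) {
    cl <- calls[[ci]]
    onset <- numeric(cl$n_elem)
    t <- t0
    for (e in seq_len(cl$n_elem)) {
      onset[e] <- t
      t <- t + cl$dur[e] + if (e < cl$n_elem) cl$gap[e] else 0
    }
    # true mean F0 over a dense contour grid
    mean_f0 <- vapply(seq_len(cl$n_elem), function(e) {
      tau <- seq(0, 1, length.out = max(16L, ceiling(cl$dur[e] * 500)))
      mean(element_f0_at(tau, cl$start_f0[e], cl$max_f0[e], cl$end_f0[e], cl$rel_loc[e]))
    }, numeric(1))
    rows[[ci]] <- data.frame(
      call_index = ci, element_index = seq_len(cl$n_elem),
      onset = onset, offset = onset + cl$dur,
      start_f0 = cl$start_f0, end_f0 = cl$end_f0, max_f0 = cl$max_f0,
      mean_f0 = mean_f0, rel_loc_max_f0 = cl$rel_loc
    )
    t0 <- t + if (ci < n_calls) call_gaps[ci] else 0
  }
  elements <- do.call(rbind, rows)
  total_dur <- max(elements$offset) + 1.0

  wave <- NULL
  if (audio) {
    n_samp <- ceiling(total_dur * sample_rate)
    wave <- numeric(n_samp)
    for (i in seq_len(nrow(elements))) {
      el <- elements[i, ]
      idx0 <- floor(el$onset * sample_rate)
      n_el <- max(2L, round((el$offset - el$onset) * sample_rate))
      tau <- seq(0, 1, length.out = n_el)
      f <- element_f0_at(tau, el$start_f0, el$max_f0, el$end_f0, el$rel_loc_max_f0)
      phase <- 2 * pi * cumsum(f) / sample_rate
      ramp_n <- min(round(0.008 * sample_rate), floor(n_el / 4))
      env <- rep(1, n_el)
      if (ramp_n > 0) {
        env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
        env[n_el - seq_len(ramp_n) + 1L] <- seq(0, 1, length.out = ramp_n)
      }
      seg <- idx0 + seq_len(n_el)
      seg <- seg[seg <= n_samp]
      wave[seg] <- wave[seg] + 0.8 * env[seq_along(seg)] * sin(phase[seq_along(seg)])
    }
    sig_rms <- sqrt(mean(wave[wave != 0]^2))
    noise_sd <- sig_rms * 10^(-config$snr_db / 20)
    wave <- wave + with_seed(derive_seed(seed, 2L), rnorm(n_samp, 0, noise_sd))
    peak <- max(abs(wave))
    if (peak > 0.99) wave <- wave * (0.99 / peak)
  }
  list(wave = wave, sample_rate = sample_rate, elements = elements)
}

#' Simulate a male's fecal androgen sample series
#'
#' Samples are constructed around the 3-day excretion lag: for each recording
#' day, the androgen level that drove that day's song pitch appears as a
#' fecal sample collected three days later, so every recording day has an
#' in-window (0-7 day) sample by construction. Additional background samples
#' are scattered over the study span to reach the male's target sample count.
#'
#' @param profile one row of the `males` table (needs `male_id`,
#'   `androgen_mean`, `androgen_sd`).
#' @param recording_days integer days since study start (or `Date` vector).
#' @param seed integer seed.
#' @param config a [simulation_config()].
#' @param day_levels optional androgen levels (ng/g) driving each recording
#'   day's pitch; drawn from the male's distribution if missing.
#' @return data.frame with `male_id`, `collection_day` (integer),
#'   `collection_date`, `androgen` (ng/g), `is_lag3` (whether the sample is
#'   the constructed day-3 excretion of a recording day).
#' @export
simulate_androgen_series <- function(profile, recording_days, seed,
                                     config = simulation_config(),
                                     day_levels = NULL) {
  if (length(recording_days) == 0) stop_input("recording_days must be non-empty")
  if (inherits(recording_days, "Date")) {
    recording_days <- as.integer(recording_days - config$study_start)
  }
  with_seed(derive_seed(seed, 3L), {
    if (is.null(day_levels)) {
      day_levels <- draw_androgen(length(recording_days), profile$androgen_mean,
                                  profile$androgen_sd)
    }
    lag3_days <- recording_days + 3L
    n_target <- max(5L, min(29L, config$n_samples_per_male +
                              sample(-3:3, 1)))
    n_extra <- max(0L, n_target - length(lag3_days))
    extra_days <- sample(seq_len(config$study_span), n_extra, replace = TRUE)
    extra_vals <- draw_androgen(n_extra, profile$androgen_mean, profile$androgen_sd)
    out <- data.frame(
      male_id = profile$male_id,
      collection_day = c(lag3_days, extra_days),
      androgen = c(day_levels, extra_vals),
      is_lag3 = c(rep(TRUE, length(lag3_days)), rep(FALSE, n_extra)),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$collection_day), , drop = FALSE]
    out$collection_date <- config$study_start + out$collection_day
    rownames(out) <- NULL
    out[, c("male_id", "collection_day", "collection_date", "androgen", "is_lag3")]
  })
}

# Log-normal androgen draws parameterized by natural-scale mean and SD;
# sd = 0 degenerates to the mean exactly.
draw_androgen <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

# Gaussian-process day-level residual: squared-exponential kernel with
# length-scale sigma (days), marginal SD `amplitude`.
gp_residual <- function(times, sigma, amplitude) {
  n <- length(times)
  if (n == 0) return(numeric(0))
  if (amplitude <= 0) return(numeric(n))
  K <- amplitude^2 * exp(-outer(times, times, "-")^2 / (2 * sigma^2))
  diag(K) <- diag(K) + 1e-8
  as.numeric(t(chol(K)) %*% rnorm(n))
}

#' Simulate the complete ground-truth study
#'
#' Orchestrates the population, recording schedule, day-level androgen and
#' pitch processes, song structure, and fecal sampling into one coherent
#' truth object. Songs are annotated with the seed and pitch offset needed to
#' re-render their audio deterministically (see [synthesize_song()] and
#' [write_dataset()]).
#'
#' @param config a [simulation_config()].
#' @param audio if `TRUE`, render and keep waveforms in memory (list column
#'   `waves`); default `FALSE` (truth tables only).
#' @return list with `config`, `males`, `groups`, `songs`, `elements`
#'   (element truth across all songs, with absolute call times), and
#'   `fecal_samples`; when `audio = TRUE` also `waves` (list named by
#'   song_id).
#' @export
simulate_truth <- function(config = simulation_config(), audio = FALSE) {
  pop <- simulate_population(config)
  males <- pop$males
  with_seed(derive_seed(config$seed, 21L), {
    schedule <- lapply(seq_len(nrow(males)), function(i) {
      m <- males[i, ]
      days <- sort(sample(seq(3, config$study_span - 8), m$n_recording_days))
      hours <- runif(length(days), 6, 9)       # dawn chorus
      data.frame(male_id = m$male_id, day = days, hour = hours,
                 stringsAsFactors = FALSE)
    })
    schedule <- do.call(rbind, schedule)

    # day-level androgen and pitch processes per male
    songs <- NULL
    fecal <- NULL
    song_counter <- 0L
    for (i in seq_len(nrow(males))) {
      m <- males[i, ]
      sch <- schedule[schedule$male_id == m$male_id, ]
      a_levels <- draw_androgen(nrow(sch), m$androgen_mean, m$androgen_sd)
      s2 <- log(1 + config$androgen_cv^2)
      z_within <- if (s2 > 0) {
        zl <- (log(a_levels) - (log(m$androgen_mean) - s2 / 2)) / sqrt(s2)
        zl - mean(zl)
      } else rep(0, nrow(sch))
      ac <- gp_residual(sch$day + sch$hour / 24, config$ac_sigma_true,
                        config$ac_amplitude)
      pitch_offset <- config$f0_sd *
        (config$effect_androgen_pitch_within * z_within + ac)
      n_songs_day <- 1L + (runif(nrow(sch)) < 0.15)
      for (d in seq_len(nrow(sch))) {
        for (s in seq_len(n_songs_day[d])) {
          song_counter <- song_counter + 1L
          songs <- rbind(songs, data.frame(
            song_id = sprintf("S%03d", song_counter),
            male_id = m$male_id, group_id = m$group_id,
            day = sch$day[d],
            date = format(config$study_start + sch$day[d]),
            time_days = sch$day[d] + sch$hour[d] / 24 + (s - 1L) * 0.02,
            n_calls = max(4L, rpois(1, config$calls_per_song_mean)),
            androgen_level = a_levels[d],
            pitch_offset = pitch_offset[d],
            song_seed = derive_seed(config$seed, 1000L + song_counter),
            stringsAsFactors = FALSE
          ))
        }
      }
      fec <- simulate_androgen_series(
        m, sch$day, derive_seed(config$seed, 500L + i), config,
        day_levels = a_levels)
      fecal <- rbind(fecal, fec)
    }
    rownames(songs) <- NULL

    elements <- vector("list", nrow(songs))
    waves <- if (audio) vector("list", nrow(songs)) else NULL
    for (j in seq_len(nrow(songs))) {
      sg <- songs[j, ]
      syn <- synthesize_song(males[males$male_id == sg$male_id, ],
                             sg$n_calls, sg$song_seed, config,
                             pitch_offset = sg$pitch_offset, audio = audio)
      el <- syn$elements
      el$song_id <- sg$song_id
      el$male_id <- sg$male_id
      el$call_time_days <- sg$time_days + el$onset / 86400
      elements[[j]] <- el
      if (audio) waves[[j]] <- syn$wave
    }
    elements <- do.call(rbind, elements)
    out <- list(config = config, males = males, groups = pop$groups,
                songs = songs, elements = elements, fecal_samples = fecal)
    if (audio) {
      names(waves) <- songs$song_id
      out$waves <- waves
    }
    out
  })
}

#' Write a simulated dataset to disk
#'
#' Writes one WAV file per song plus CSV tables `males.csv`, `songs.csv`,
#' `elements_truth.csv` and `fecal_samples.csv` (ISO-8601 dates). Audio is
#' re-rendered from each song's stored seed, so a truth object simulated with
#' `audio = FALSE` writes identical waveforms.
#'
#' @param truth result of [simulate_truth()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory %s", out_dir)
  config <- truth$config
  utils::write.csv(truth$males, file.path(out_dir, "males.csv"), row.names = FALSE)
  utils::write.csv(truth$songs, file.path(out_dir, "songs.csv"), row.names = FALSE)
  utils::write.csv(truth$elements, file.path(out_dir, "elements_truth.csv"),
                   row.names = FALSE)
  fec <- truth$fecal_samples
  fec$collection_date <- format(fec$collection_date)
  utils::write.csv(fec, file.path(out_dir, "fecal_samples.csv"), row.names = FALSE)
  for (j in seq_len(nrow(truth$songs))) {
    sg <- truth$songs[j, ]
    wave <- if (!is.null(truth$waves)) truth$waves[[sg$song_id]] else {
      synthesize_song(truth$males[truth$males$male_id == sg$male_id, ],
                      sg$n_calls, sg$song_seed, config,
                      pitch_offset = sg$pitch_offset)$wave
    }
    write_wav(wave, file.path(out_dir, paste0(sg$song_id, ".wav")))
  }
  invisible(out_dir)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `males`, `songs`, `elements`, `fecal_samples` tables.
#' @export
read_dataset <- function(dir) {
  fec <- utils::read.csv(file.path(dir, "fecal_samples.csv"),
                         stringsAsFactors = FALSE)
  fec$collection_date <- as.Date(fec$collection_date)
  list(
    males = utils::read.csv(file.path(dir, "males.csv"), stringsAsFactors = FALSE),
    songs = utils::read.csv(file.path(dir, "songs.csv"), stringsAsFactors = FALSE),
    elements = utils::read.csv(file.path(dir, "elements_truth.csv"),
                               stringsAsFactors = FALSE),
    fecal_samples = fec
  )
}

#' Simulate call-level feature vectors directly (no audio)
#'
#' Fast generator of synthetic call feature tables for the discriminant
#' analysis: each male has a feature-space centroid, calls are spread over
#' recording days, and day-level random effects induce the within-day
#' correlation that motivates the day-wise restricted permutation test.
#'
#' @param n_males number of males.
#' @param calls_per_male calls per male.
#' @param days_per_male recording days per male; calls are split evenly.
#' @param separation minimum pairwise distance between male centroids, in
#'   units of the total within-male SD; 0 gives an exchangeable null.
#' @param day_sd SD of the day-level random effect (per feature), in units of
#'   the call-level residual SD (1).
#' @param n_features feature dimensionality (22 to mirror the call
#'   parameters).
#' @param seed integer seed.
#' @return data.frame with `male_id`, `recording_day` and feature columns
#'   `f01`..`fNN`.
#' @export
simulate_call_features <- function(n_males = 10, calls_per_male = 30,
                                   days_per_male = 4, separation = 5,
                                   day_sd = 0, n_features = 22, seed = 1) {
  stopifnot(n_males >= 2, calls_per_male >= days_per_male)
  with_seed(seed, {
    centroids <- matrix(rnorm(n_males * n_features), n_males)
    if (separation > 0) {
      dmin <- min(dist(centroids))
      centroids <- centroids * (separation * sqrt(1 + day_sd^2) / dmin)
    } else {
      centroids[] <- 0
    }
    rows <- vector("list", n_males)
    for (m in seq_len(n_males)) {
      day <- sort(rep_len(seq_len(days_per_male), calls_per_male))
      day_eff <- matrix(rnorm(days_per_male * n_features, 0, day_sd),
                        days_per_male)
      x <- centroids[rep(m, calls_per_male), , drop = FALSE] +
        day_eff[day, , drop = FALSE] +
        matrix(rnorm(calls_per_male * n_features), calls_per_male)
      rows[[m]] <- data.frame(
        male_id = sprintf("M%02d", m),
        recording_day = sprintf("M%02d_D%02d", m, day),
        x, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    names(out)[-(1:2)] <- sprintf("f%02d", seq_len(n_features))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a ready-to-model factor-score dataset (no audio)
#'
#' Generates the merged modeling table the mixed-model stage consumes:
#' per-call response with known fixed effects (between/within androgen, age,
#' status), crossed/nested random effects (group, male, date within male,
#' song), and a day-scale autocorrelated residual process drawn from a
#' Gaussian-kernel (squared-exponential) covariance with bandwidth
#' `ac_sigma_true` — the parameter the autocorrelation-term fit is asked to
#' recover.
#'
#' @param n_males number of males (adult/senior only).
#' @param days_per_male recording days per male.
#' @param songs_per_day songs per recording day.
#' @param calls_per_song calls per song.
#' @param beta named fixed-effect coefficients: `intercept`,
#'   `androgen_between`, `androgen_within`, `age_senior`,
#'   `status_multi_primary`, `status_secondary`.
#' @param sd_group,sd_male,sd_date,sd_song random-intercept SDs.
#' @param sd_slope SD of the within-androgen random slope across males.
#' @param sigma_ac marginal SD of the autocorrelated residual.
#' @param ac_sigma_true bandwidth (days) of the autocorrelated residual.
#' @param sigma_e iid residual SD.
#' @param seed integer seed.
#' @return data.frame with identifiers, predictors (`androgen_between`,
#'   `androgen_within`, `age`, `status`), `time_days`, and `response`.
#' @export
simulate_model_table <- function(n_males = 13, days_per_male = 3,
                                 songs_per_day = 1, calls_per_song = 12,
                                 beta = c(intercept = 0, androgen_between = 0.5,
                                          androgen_within = 0, age_senior = -0.5,
                                          status_multi_primary = 0, status_secondary = 0),
                                 sd_group = 0.08, sd_male = 0.08, sd_date = 0.12,
                                 sd_song = 0.1, sd_slope = 0, sigma_ac = 0.15,
                                 ac_sigma_true = 2, sigma_e = 0.3, seed = 1) {
  with_seed(seed, {
    n_multi <- max(1L, round(n_males / 7))
    status <- character(n_males); group <- character(n_males)
    k <- 1L
    for (g in seq_len(n_multi)) {
      for (j in 1:2) {
        if (k > n_males) break
        group[k] <- sprintf("G%02d", g)
        status[k] <- if (j == 1) "multi_primary" else "secondary"
        k <- k + 1L
      }
    }
    g <- n_multi
    while (k <= n_males) {
      g <- g + 1L
      group[k] <- sprintf("G%02d", g); status[k] <- "pair_primary"; k <- k + 1L
    }
    age <- sample(c("adult", "senior"), n_males, TRUE, prob = c(0.7, 0.3))
    age[1] <- "adult"; if (!any(age == "senior")) age[n_males] <- "senior"
    # the male panel is a fixed study condition: standardize the between-male
    # androgen scores to mean 0, SD 1 so every simulated study has the
    # nominal between-male spread
    z_between <- as.numeric(scale(rnorm(n_males)))
    slope_m <- rnorm(n_males, 0, sd_slope)
    u_group <- rnorm(length(unique(group)), 0, sd_group)
    names(u_group) <- unique(group)
    u_male <- rnorm(n_males, 0, sd_male)

    rows <- vector("list", n_males)
    song_counter <- 0L
    for (m in seq_len(n_males)) {
      # recording bouts: teams follow a group on consecutive or near-consecutive
      # days, so within-male day spacings are 1-3 days
      days <- sample(5:120, 1) + cumsum(c(0, sample(1:3, days_per_male - 1, TRUE)))
      w_day <- rnorm(days_per_male); w_day <- w_day - mean(w_day)
      u_date <- rnorm(days_per_male, 0, sd_date)
      per_day <- vector("list", days_per_male)
      for (d in seq_len(days_per_male)) {
        songs <- lapply(seq_len(songs_per_day), function(s) {
          song_counter <<- song_counter + 1L
          t0 <- days[d] + runif(1, 6, 9) / 24
          data.frame(
            song_id = sprintf("S%04d", song_counter),
            time_days = t0 + seq_len(calls_per_song) * 15 / 86400,
            u_song = rnorm(1, 0, sd_song), day_index = d
          )
        })
        per_day[[d]] <- do.call(rbind, songs)
      }
      tab <- do.call(rbind, per_day)
      eps_ac <- gp_residual(tab$time_days, ac_sigma_true, sigma_ac)
      d <- tab$day_index
      mu <- beta[["intercept"]] +
        beta[["androgen_between"]] * z_between[m] +
        (beta[["androgen_within"]] + slope_m[m]) * w_day[d] +
        beta[["age_senior"]] * (age[m] == "senior") +
        beta[["status_multi_primary"]] * (status[m] == "multi_primary") +
        beta[["status_secondary"]] * (status[m] == "secondary") +
        u_group[group[m]] + u_male[m] + u_date[d] + tab$u_song
      rows[[m]] <- data.frame(
        male_id = sprintf("M%02d", m), group_id = group[m],
        status = status[m], age = age[m],
        date = sprintf("M%02d_D%02d", m, d), song_id = tab$song_id,
        time_days = tab$time_days,
        androgen_between = z_between[m], androgen_within = w_day[d],
        response = mu + eps_ac + rnorm(nrow(tab), 0, sigma_e),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
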