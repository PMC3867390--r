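# End-to-end orchestration: simulate -> extract -> factor analysis -> pDFA ->
# hormone matching -> mixed models, with the paper-shaped summary tables.

#' Configuration for a full analysis run
#'
#' Collects every stage's parameters under one seed. Inclusion rules follow
#' the study design: only solo songs are simulated; subadult males appear in
#' the descriptive tables but are excluded from the factor-score models.
#'
#' @param seed master seed.
#' @param sim a [simulation_config()] (its seed is overridden by `seed`).
#' @param spectrogram a [spectrogram_params()].
#' @param max_gap call-segmentation gap, s.
#' @param n_select,n_selections,n_permutations,perm_selections pDFA settings.
#' @param sigma_grid bandwidth grid size for the mixed models.
#' @param p_method "lrt" or "bootstrap" for the fixed-effect p-values.
#' @param n_boot bootstrap simulations when `p_method = "bootstrap"`.
#' @param run_loso run leave-one-subject-out stability (slow; default FALSE).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = NULL,
                       spectrogram = spectrogram_params(),
                       max_gap = 5, n_select = 23, n_selections = 100,
                       n_permutations = 1000, perm_selections = n_selections,
                       sigma_grid = 10, p_method = "lrt", n_boot = 1000,
                       run_loso = FALSE) {
  sim <- sim %||% simulation_config(seed = seed)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, spectrogram = spectrogram,
                 max_gap = max_gap, n_select = n_select,
                 n_selections = n_selections, n_permutations = n_permutations,
                 perm_selections = perm_selections, sigma_grid = sigma_grid,
                 p_method = p_method, n_boot = n_boot, run_loso = run_loso),
            class = "run_config")
}

#' Run the full analysis chain on simulated songs
#'
#' Simulates the population and songs, measures every song's audio into call
#' features, fits the factor model on transformed parameters, runs the pDFA
#' on the transformed features of males with enough calls, matches androgen
#' samples by the excretion-lag rule, and fits the six factor-score mixed
#' models with the autocorrelation term. A manifest logs per-stage row counts
#' and exclusions.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, stage artifacts are written
#'   (`factor_model.json`, `factor_scores.csv`, `pdfa_result.json`,
#'   `glmm_report.csv`, `descriptives.csv`, `manifest.json`).
#' @return list with `calls`, `elements`, `transform_spec`, `factor_model`,
#'   `scores`, `pdfa`, `matched`, `model_data`, `fits`, `effects`,
#'   `descriptives`, `manifest` (and `loso` when enabled).
#' @export
run_full_analysis <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- simulate_truth(config$sim, audio = FALSE)
  males <- truth$males
  songs <- truth$songs

  # --- acoustics ------------------------------------------------------------
  call_rows <- list(); elem_rows <- list()
  for (j in seq_len(nrow(songs))) {
    sg <- songs[j, ]
    wave <- synthesize_song(males[males$male_id == sg$male_id, ], sg$n_calls,
                            sg$song_seed, config$sim,
                            pitch_offset = sg$pitch_offset)$wave
    feats <- extract_call_features(wave, config$spectrogram,
                                   max_gap = config$max_gap)
    if (is.null(feats$calls)) next
    cf <- feats$calls
    cf$song_id <- sg$song_id
    cf$male_id <- sg$male_id
    cf$recording_day <- paste(sg$male_id, sg$day, sep = "_")
    cf$date <- sg$date
    cf$time_days <- sg$time_days
    call_rows[[j]] <- cf
    ef <- feats$elements
    ef$song_id <- sg$song_id
    ef$male_id <- sg$male_id
    elem_rows[[j]] <- ef
  }
  calls <- do.call(rbind, call_rows)
  elements <- do.call(rbind, elem_rows)
  calls <- merge(calls, males[, c("male_id", "age_class", "status", "group_id")],
                 by = "male_id")

  # --- factor analysis (solo songs of adult + senior males) -----------------
  modeled <- calls[calls$age_class %in% c("adult", "senior"), , drop = FALSE]
  # calls with a degenerate (zero) value in a log-transformed parameter
  # cannot enter the factor analysis; they are excluded and counted
  log_cols <- names(which(default_transforms() == "log"))
  degenerate <- rep(FALSE, nrow(modeled))
  for (nm in log_cols) {
    degenerate <- degenerate | (!is.na(modeled[[nm]]) & modeled[[nm]] <= 0)
  }
  n_degenerate <- sum(degenerate)
  modeled <- modeled[!degenerate, , drop = FALSE]
  tspec <- transform_spec(modeled)
  trans <- apply_transforms(modeled, tspec)
  fm <- fit_factor_model(trans, tspec)
  scores <- factor_scores(trans, fm)
  scored <- cbind(trans[, c("male_id", "song_id", "call_id", "recording_day",
                            "date", "time_days", "age_class", "status", "group_id")],
                  scores)

  # --- pDFA on transformed parameters ---------------------------------------
  pdfa_data <- trans[, c("male_id", "recording_day", names(tspec$transforms))]
  pdfa_data <- pdfa_data[stats::complete.cases(pdfa_data), , drop = FALSE]
  pdfa_res <- run_pdfa(pdfa_data, n_select = config$n_select,
                       n_selections = config$n_selections,
                       n_permutations = config$n_permutations,
                       perm_selections = config$perm_selections,
                       seed = derive_seed(config$seed, 7L))

  # --- hormone matching and centering ---------------------------------------
  ma <- match_androgens(songs[, c("song_id", "male_id", "day", "date")],
                        truth$fecal_samples)
  matched <- ma$matched
  cen <- center_androgens(matched$androgen, matched$male_id)
  matched <- cbind(matched, cen)

  # --- mixed models ---------------------------------------------------------
  model_data <- merge(scored, matched[, c("song_id", "androgen_between",
                                          "androgen_within")], by = "song_id")
  model_data$age <- model_data$age_class
  model_data$date <- model_data$recording_day
  fits <- list()
  for (k in seq_len(fm$n_factors)) {
    resp <- paste0("factor", k)
    spec_k <- glmm_spec(resp)
    fits[[resp]] <- fit_with_ac(model_data, spec_k, sigma_grid = config$sigma_grid)
  }
  effects <- test_fixed_effects(fits, method = config$p_method,
                                n_boot = config$n_boot,
                                seed = derive_seed(config$seed, 9L))

  descriptives <- descriptive_by_age(elements, calls)

  manifest <- list(
    seed = config$seed,
    n_males = nrow(males), n_songs = nrow(songs),
    n_calls_measured = nrow(calls),
    n_calls_modeled = nrow(model_data),
    n_calls_excluded_age = sum(!calls$age_class %in% c("adult", "senior")),
    n_calls_excluded_degenerate = n_degenerate,
    n_calls_dropped_fa = fm$n_dropped,
    n_songs_unmatched_androgen = ma$n_unmatched,
    pdfa_excluded_males = pdfa_res$excluded,
    n_factors = fm$n_factors
  )

  out <- list(calls = calls, elements = elements, transform_spec = tspec,
              factor_model = fm, scores = scored, pdfa = pdfa_res,
              matched = matched, model_data = model_data, fits = fits,
              effects = effects, descriptives = descriptives,
              manifest = manifest)
  if (isTRUE(config$run_loso)) {
    out$loso <- loso_stability(model_data, glmm_spec("factor1"),
                               sigma_grid = config$sigma_grid)
  }
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_factor_model(run$factor_model, file.path(out_dir, "factor_model.json"),
                     run$transform_spec)
  utils::write.csv(run$scores, file.path(out_dir, "factor_scores.csv"),
                   row.names = FALSE)
  p <- run$pdfa
  jsonlite::write_json(
    list(observed_rate = p$observed_rate, chance_level = p$chance_level,
         p_value = p$p_value, n_selections = p$n_selections,
         n_permutations = p$n_permutations, n_males = p$n_males,
         n_calls = p$n_calls, seed = p$seed),
    file.path(out_dir, "pdfa_result.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$effects, file.path(out_dir, "glmm_report.csv"),
                   row.names = FALSE)
  utils::write.csv(run$descriptives, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Descriptive element/call statistics by age class
#'
#' Median, quartiles (linear-interpolation convention), minimum and maximum
#' of the descriptive acoustic parameters, per age class, plus element and
#' call counts. Covers all age classes including subadults, which only enter
#' here.
#'
#' @param elements element-level table with `duration`, F0 columns and
#'   `male_id`; intervals and call durations are taken from `calls`.
#' @param calls call-level table with `call_duration`,
#'   `mean_interval_duration` and `age_class`.
#' @return data.frame: one row per (parameter, age class) with `median`,
#'   `q1`, `q3`, `min`, `max`, `n`; plus count rows for elements and calls.
#' @export
descriptive_by_age <- function(elements, calls) {
  if (nrow(calls) == 0) stop_input("empty call table")
  if (!"age_class" %in% names(elements)) {
    elements <- merge(elements,
                      unique(calls[, c("male_id", "age_class")]), by = "male_id")
  }
  key <- paste(elements$male_id, elements$song_id, elements$call_index)
  n_by_call <- tapply(elements$duration, key, length)
  age_by_call <- tapply(elements$age_class, key, function(a) a[1])

  params <- list(
    list(name = "call duration [s]", values = calls$call_duration,
         age = calls$age_class),
    list(name = "number of elements", values = as.numeric(n_by_call),
         age = as.character(age_by_call)),
    list(name = "element duration [s]", values = elements$duration,
         age = elements$age_class),
    list(name = "interval duration [s]", values = calls$mean_interval_duration,
         age = calls$age_class),
    list(name = "start F0 [Hz]", values = elements$start_f0,
         age = elements$age_class),
    list(name = "end F0 [Hz]", values = elements$end_f0,
         age = elements$age_class),
    list(name = "max F0 [Hz]", values = elements$max_f0,
         age = elements$age_class),
    list(name = "location of max F0", values = elements$rel_loc_max_f0,
         age = elements$age_class)
  )
  classes <- c("subadult", "adult", "senior")
  rows <- list()
  for (p in params) {
    for (cl in classes) {
      v <- p$values[p$age == cl & !is.na(p$values)]
      rows[[length(rows) + 1L]] <- if (length(v) == 0) {
        data.frame(parameter = p$name, age_class = cl, median = NA, q1 = NA,
                   q3 = NA, min = NA, max = NA, n = 0L)
      } else {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)   # linear interpolation
        data.frame(parameter = p$name, age_class = cl, median = q[[2]],
                   q1 = q[[1]], q3 = q[[3]], min = min(v), max = max(v),
                   n = length(v))
      }
    }
  }
  counts <- lapply(classes, function(cl) {
    data.frame(parameter = "counts", age_class = cl,
               median = NA, q1 = NA, q3 = NA, min = NA, max = NA,
               n = sum(elements$age_class == cl))
  })
  call_counts <- lapply(classes, function(cl) {
    data.frame(parameter = "call counts", age_class = cl,
               median = NA, q1 = NA, q3 = NA, min = NA, max = NA,
               n = sum(calls$age_class == cl))
  })
  out <- do.call(rbind, c(rows, counts, call_counts))
  rownames(out) <- NULL
  out
}
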