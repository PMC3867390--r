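# Matching fecal androgen measurements to song recordings via the excretion
# lag, and decomposing the matched values into between- and within-subject
# components.
#
# Fecal androgen metabolites reflect circulating levels with a delay: day 3
# after a recording is taken as the day whose fecal sample best reflects the
# androgen status on the recording day. Only samples collected between the
# recording day and 7 days later are eligible; among those, the sample(s)
# closest to the optimal day are used, averaging when several are equally
# close. Distances are in calendar days (samples are collected in the
# morning hours, recordings at dawn; sub-day precision is not available).

#' Match a male's fecal samples to one recording date
#'
#' @param recording_date `Date` (or integer day) of the recording.
#' @param samples data.frame of the male's samples with `collection_date`
#'   (or `collection_day`) and `androgen`.
#' @param lag_optimal optimal excretion lag in days (default 3).
#' @param lag_window inclusive eligible lag range (default `c(0, 7)`).
#' @return one-row data.frame `androgen`, `lag_days`, `n_samples_averaged`,
#'   or `NULL` when no sample falls in the window (the observation is then
#'   excluded downstream, not imputed).
#' @export
match_samples <- function(recording_date, samples, lag_optimal = 3,
                          lag_window = c(0, 7)) {
  day_col <- if ("collection_day" %in% names(samples) &&
                 !inherits(recording_date, "Date")) {
    samples$collection_day
  } else samples$collection_date
  lag <- as.numeric(day_col) - as.numeric(recording_date)
  in_win <- which(lag >= lag_window[1] & lag <= lag_window[2])
  if (length(in_win) == 0) return(NULL)
  d <- abs(lag[in_win] - lag_optimal)
  best <- in_win[d == min(d)]
  data.frame(androgen = mean(samples$androgen[best]),
             lag_days = mean(lag[best]),
             n_samples_averaged = length(best))
}

#' Match androgen samples to a whole song table
#'
#' Applies [match_samples()] per song using that male's samples, and reports
#' the lag distribution of the matches.
#'
#' @param songs data.frame with `song_id`, `male_id` and `date` (or `day`).
#' @param fecal_samples data.frame with `male_id`, `collection_date` (or
#'   `collection_day`) and `androgen`.
#' @inheritParams match_samples
#' @return list: `matched` (songs joined with `androgen`, `lag_days`,
#'   `n_samples_averaged`; unmatched songs are dropped), `n_unmatched`,
#'   `lag_counts` (table of matched lags).
#' @export
match_androgens <- function(songs, fecal_samples, lag_optimal = 3,
                            lag_window = c(0, 7)) {
  use_day <- "day" %in% names(songs) && "collection_day" %in% names(fecal_samples)
  rows <- vector("list", nrow(songs))
  for (i in seq_len(nrow(songs))) {
    s <- songs[i, ]
    fs <- fecal_samples[fecal_samples$male_id == s$male_id, , drop = FALSE]
    rec <- if (use_day) s$day else as.Date(s$date)
    m <- if (nrow(fs)) {
      if (use_day) {
        match_samples(rec, fs[, c("collection_day", "androgen")], lag_optimal, lag_window)
      } else {
        match_samples(rec, fs, lag_optimal, lag_window)
      }
    } else NULL
    if (!is.null(m)) rows[[i]] <- cbind(s, m)
  }
  got <- !vapply(rows, is.null, logical(1))
  matched <- if (any(got)) do.call(rbind, rows[got]) else NULL
  list(matched = matched, n_unmatched = sum(!got),
       lag_counts = if (any(got)) table(round(matched$lag_days)) else table(numeric(0)))
}

#' Z-transform and within-subject centering of matched androgen values
#'
#' Values are first z-transformed over all observations (mean 0, SD 1); the
#' between-subject term is each male's mean z-value and the within-subject
#' term the observation's deviation from it, so `between + within` recovers
#' the z-value exactly and the within term has mean zero per male.
#'
#' @param values numeric androgen values (one per observation).
#' @param male_id subject label per observation.
#' @return data.frame `androgen_z`, `androgen_between`, `androgen_within`.
#' @export
center_androgens <- function(values, male_id) {
  if (length(unique(values)) < 2) stop_input("androgen values have zero variance")
  z <- as.numeric(scale(values))
  between <- stats::ave(z, male_id)
  data.frame(androgen_z = z, androgen_between = between,
             androgen_within = z - between)
}
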