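# Accelerometer preprocessing: epoch consolidation, non-wear detection,
# cut-point intensity classification, day validity, mean daily MVPA.

#' Consolidate 15-second epochs into 60-second periods
#'
#' Each minute's count is the sum of its four consecutive 15-s epochs within
#' a day; trailing epochs that do not complete a minute are dropped rather
#' than zero-padded. A series already at 60 s is passed through unchanged
#' with a notice.
#'
#' @param series A [count_series()].
#' @return A `count_series` at 60-s epochs; `epoch` becomes the minute index
#'   within the day.
#' @export
aggregate_epochs <- function(series) {
  stopifnot(inherits(series, "count_series"))
  if (attr(series, "epoch_seconds") == 60) {
    message("series already at 60-s epochs; returning unchanged")
    return(series)
  }
  if (!nrow(series)) return(count_series(as.data.frame(series), 60))
  key <- interaction(series$participant_id, series$day, drop = TRUE)
  parts <- split(seq_len(nrow(series)), key)
  out <- lapply(parts, function(idx) {
    idx <- idx[order(series$epoch[idx])]
    n_min <- length(idx) %/% 4L
    if (n_min == 0L) return(NULL)
    keep <- idx[seq_len(4L * n_min)]
    mins <- colSums(matrix(series$counts[keep], nrow = 4L))
    data.frame(participant_id = series$participant_id[idx[1]],
               day = series$day[idx[1]],
               day_type = series$day_type[idx[1]],
               epoch = seq_len(n_min), counts = mins,
               stringsAsFactors = FALSE)
  })
  count_series(do.call(rbind, out), 60)
}

#' Flag non-wear minutes
#'
#' Every maximal run of consecutive zero-count minutes of at least
#' `min_zero_run` minutes is flagged non-wear in its entirety; all remaining
#' minutes are wear. Runs are evaluated on the concatenated minute stream of
#' each participant's recording (a run is not broken by a day boundary).
#'
#' @param series A 60-s [count_series()].
#' @param min_zero_run Minimum zero-run length, default 20 minutes.
#' @return A `wear_annotation` data.frame: the series columns plus `wear`
#'   (logical) and `class` (initialized to `"nonwear"` / `NA`, filled by
#'   [classify_intensity()]).
#' @export
detect_nonwear <- function(series, min_zero_run = 20L) {
  stopifnot(inherits(series, "count_series"))
  if (attr(series, "epoch_seconds") != 60) {
    stopf("non-wear detection operates on 60-s epochs; run aggregate_epochs()")
  }
  df <- as.data.frame(series)
  df$wear <- TRUE
  if (nrow(df)) {
    for (pid in unique(df$participant_id)) {
      idx <- which(df$participant_id == pid)
      idx <- idx[order(df$day[idx], df$epoch[idx])]
      r <- rle(df$counts[idx] == 0)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      long0 <- which(r$values & r$lengths >= min_zero_run)
      for (j in long0) df$wear[idx[starts[j]:ends[j]]] <- FALSE
    }
  }
  df$class <- ifelse(df$wear, NA_character_, "nonwear")
  structure(df, class = c("wear_annotation", "data.frame"),
            min_zero_run = min_zero_run)
}

#' Classify minute intensity by cut-points
#'
#' Wear minutes are classified from counts/min: sedentary (<= `cuts[1]`),
#' light (`cuts[1]` < counts <= `cuts[2]`), MVPA (> `cuts[2]`). Minutes
#' flagged non-wear keep class `"nonwear"` regardless of counts.
#'
#' @param annotation A `wear_annotation` from [detect_nonwear()].
#' @param cuts Numeric cut-points `c(sedentary = 100, light = 2295)`.
#' @return The annotation with `class` filled in.
#' @export
classify_intensity <- function(annotation, cuts = c(sedentary = 100,
                                                    light = 2295)) {
  stopifnot(inherits(annotation, "wear_annotation"), length(cuts) == 2,
            cuts[1] < cuts[2])
  cl <- annotation$class
  w <- annotation$wear
  cl[w & annotation$counts <= cuts[1]] <- "sedentary"
  cl[w & annotation$counts > cuts[1] & annotation$counts <= cuts[2]] <- "light"
  cl[w & annotation$counts > cuts[2]] <- "mvpa"
  annotation$class <- cl
  annotation
}

#' Summarize wear and intensity minutes per day
#'
#' @param annotation A classified `wear_annotation`.
#' @param min_wear_minutes Minutes of (non-contiguous) wear needed for a
#'   valid day; default 480 (8 h), inclusive.
#' @return Data.frame with one row per participant-day: `participant_id`,
#'   `day`, `day_type`, `wear_minutes`, `sedentary`, `light`, `mvpa`,
#'   `valid_day`.
#' @export
summarize_days <- function(annotation, min_wear_minutes = 480L) {
  stopifnot(inherits(annotation, "wear_annotation"))
  if (anyNA(annotation$class)) {
    stopf("annotation has unclassified minutes; run classify_intensity()")
  }
  key <- interaction(annotation$participant_id, annotation$day, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(annotation)), key), function(idx) {
    cl <- annotation$class[idx]
    data.frame(participant_id = annotation$participant_id[idx[1]],
               day = annotation$day[idx[1]],
               day_type = annotation$day_type[idx[1]],
               wear_minutes = sum(cl != "nonwear"),
               sedentary = sum(cl == "sedentary"),
               light = sum(cl == "light"),
               mvpa = sum(cl == "mvpa"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$day), , drop = FALSE]
  out$valid_day <- out$wear_minutes >= min_wear_minutes
  rownames(out) <- NULL
  out
}

#' Does a recording satisfy the wear-time inclusion criterion?
#'
#' @param summaries Day summaries from [summarize_days()] for one
#'   participant.
#' @param min_weekdays Minimum valid weekdays (default 3).
#' @param min_weekend Minimum valid weekend days (default 1).
#' @return `TRUE` iff the participant has at least the required valid
#'   weekday and weekend days.
#' @export
participant_valid <- function(summaries, min_weekdays = 3L, min_weekend = 1L) {
  ok <- summaries$valid_day
  sum(ok & summaries$day_type == "weekday") >= min_weekdays &&
    sum(ok & summaries$day_type == "weekend") >= min_weekend
}

#' Mean daily MVPA over valid days
#'
#' @param summaries Day summaries for one participant.
#' @inheritParams participant_valid
#' @return Mean MVPA minutes/day across valid days only.
#' @export
mean_daily_mvpa <- function(summaries, min_weekdays = 3L, min_weekend = 1L) {
  if (!participant_valid(summaries, min_weekdays, min_weekend)) {
    stopf("participant does not meet the %d weekday + %d weekend valid-day %s",
          min_weekdays, min_weekend, "criterion and is excluded")
  }
  mean(summaries$mvpa[summaries$valid_day])
}

#' End-to-end accelerometer preprocessing
#'
#' Runs consolidation (if needed), non-wear detection, intensity
#' classification and day summaries, and returns per-participant validity and
#' mean daily MVPA.
#'
#' @param series A [count_series()] (15-s or 60-s epochs), possibly covering
#'   several participants.
#' @param cuts Intensity cut-points, see [classify_intensity()].
#' @param min_zero_run,min_wear_minutes,min_weekdays,min_weekend Rule
#'   parameters, see the stage functions.
#' @return List with `annotation`, `days` (all day summaries) and
#'   `participants` (data.frame: `participant_id`, `valid`,
#'   `mean_daily_mvpa` — `NA` for excluded participants).
#' @export
process_counts <- function(series, cuts = c(sedentary = 100, light = 2295),
                           min_zero_run = 20L, min_wear_minutes = 480L,
                           min_weekdays = 3L, min_weekend = 1L) {
  if (attr(series, "epoch_seconds") == 15) {
    series <- aggregate_epochs(series)
  }
  ann <- classify_intensity(detect_nonwear(series, min_zero_run), cuts)
  days <- summarize_days(ann, min_wear_minutes)
  parts <- lapply(split(days, days$participant_id), function(d) {
    ok <- participant_valid(d, min_weekdays, min_weekend)
    data.frame(participant_id = d$participant_id[1], valid = ok,
               mean_daily_mvpa = if (ok) {
                 mean_daily_mvpa(d, min_weekdays, min_weekend)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  participants <- do.call(rbind, parts)
  rownames(participants) <- NULL
  list(annotation = ann, days = days, participants = participants)
}
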