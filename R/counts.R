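# Accelerometer count-series container and trace simulator.

# Counts-per-minute bands implied by the cut-points: sedentary <= 100,
# light (100, 2295], MVPA > 2295.
.intensity_band <- function(intensity) {
  switch(intensity,
         sedentary = c(0, 100),
         light     = c(101, 2295),
         mvpa      = c(2296, 12000),
         stopf("unknown intensity class '%s'", intensity))
}

#' Build a count series from epoch-level data
#'
#' @param df Data.frame with columns `participant_id`, `day` (integer day
#'   index), `day_type` (`"weekday"` or `"weekend"`), `epoch` (1-based index
#'   within day) and `counts` (non-negative).
#' @param epoch_seconds Epoch length, 15 or 60 seconds.
#' @return A `count_series` (data.frame subclass with an `epoch_seconds`
#'   attribute).
#' @export
count_series <- function(df, epoch_seconds = 60) {
  if (!epoch_seconds %in% c(15, 60)) {
    stopf("epoch_seconds must be 15 or 60, got %s", epoch_seconds)
  }
  need <- c("participant_id", "day", "day_type", "epoch", "counts")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("count series lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (any(df$counts < 0)) stopf("counts must be non-negative")
  if (!all(df$day_type %in% c("weekday", "weekend"))) {
    stopf("day_type must be 'weekday' or 'weekend'")
  }
  df <- df[order(df$participant_id, df$day, df$epoch), , drop = FALSE]
  ord_ok <- tapply(df$epoch, interaction(df$participant_id, df$day,
                                         drop = TRUE),
                   function(e) !any(duplicated(e)))
  if (length(ord_ok) && !all(unlist(ord_ok))) {
    stopf("duplicated epoch indices within a day")
  }
  rownames(df) <- NULL
  structure(df, epoch_seconds = epoch_seconds,
            class = c("count_series", "data.frame"))
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d epochs of %d s, %d participant(s), %d day(s)\n",
              nrow(x), attr(x, "epoch_seconds"),
              length(unique(x$participant_id)),
              nrow(unique(x[c("participant_id", "day")]))))
  NextMethod()
}

#' Specify one simulated day of accelerometer wear
#'
#' @param day_type `"weekday"` or `"weekend"`.
#' @param minutes Total recorded minutes in the day (default 840 = 14 h).
#' @param bouts Data.frame with columns `start` (1-based minute), `duration`
#'   (minutes), `intensity` (`"sedentary"`, `"light"`, `"mvpa"`) and
#'   `mean_cpm` (target counts/min, must lie in the intensity band). Bouts
#'   may not overlap. Minutes not covered by a bout are background sedentary.
#' @param nonwear Data.frame with columns `start`, `duration`: blocks forced
#'   to zero counts (they override any bout).
#' @return A `trace_day` list.
#' @export
trace_day <- function(day_type = "weekday", minutes = 840,
                      bouts = NULL, nonwear = NULL) {
  stopifnot(day_type %in% c("weekday", "weekend"), minutes >= 1)
  if (!is.null(bouts) && nrow(bouts)) {
    if (any(bouts$start < 1 | bouts$start + bouts$duration - 1 > minutes)) {
      stopf("bout outside the recorded day")
    }
    cover <- unlist(mapply(function(s, d) seq(s, length.out = d),
                           bouts$start, bouts$duration, SIMPLIFY = FALSE))
    if (anyDuplicated(cover)) stopf("overlapping bouts in day spec")
    for (i in seq_len(nrow(bouts))) {
      band <- .intensity_band(bouts$intensity[i])
      if (bouts$mean_cpm[i] < band[1] || bouts$mean_cpm[i] > band[2]) {
        stopf("bout %d: mean_cpm %g outside the %s band [%g, %g]",
              i, bouts$mean_cpm[i], bouts$intensity[i], band[1], band[2])
      }
    }
  }
  if (!is.null(nonwear) && nrow(nonwear)) {
    if (any(nonwear$duration < 0)) stopf("negative non-wear length")
    if (any(nonwear$start < 1 |
            nonwear$start + pmax(nonwear$duration - 1, 0) > minutes)) {
      stopf("non-wear block outside the recorded day")
    }
  }
  structure(list(day_type = day_type, minutes = minutes,
                 bouts = bouts, nonwear = nonwear),
            class = "trace_day")
}

#' Simulate an accelerometer count trace
#'
#' Builds a per-epoch count series for one participant from a day-by-day
#' schedule of intensity bouts and forced non-wear blocks. Background minutes
#' draw 1-80 counts/min (sedentary, never zero, so scheduled non-wear blocks
#' are the only qualifying zero runs); bout minutes draw counts/min uniformly
#' within +/-15% of the bout's target, clamped to the intensity band, so each
#' realized minute classifies into the declared class; non-wear minutes are
#' exactly zero. At 15-s resolution each minute's count is split over its
#' four epochs by a multinomial draw.
#'
#' @param days List of [trace_day()] objects (empty list gives an empty
#'   series).
#' @param epoch_seconds 15 or 60.
#' @param participant_id Identifier stored in the series.
#' @param seed Integer seed; fixed seed gives an identical trace.
#' @return A [count_series()].
#' @export
generate_count_trace <- function(days, epoch_seconds = 60,
                                 participant_id = "P0001", seed = 1L) {
  if (!epoch_seconds %in% c(15, 60)) stopf("epoch_seconds must be 15 or 60")
  if (!length(days)) {
    empty <- data.frame(participant_id = character(), day = integer(),
                        day_type = character(), epoch = integer(),
                        counts = numeric(), stringsAsFactors = FALSE)
    return(count_series(empty, epoch_seconds))
  }
  if (!all(vapply(days, inherits, TRUE, "trace_day"))) {
    stopf("days must be a list of trace_day objects")
  }
  with_seed(seed, {
    per_day <- lapply(seq_along(days), function(d) {
      sp <- days[[d]]
      cpm <- 1 + floor(runif(sp$minutes) * 80)  # background sedentary
      if (!is.null(sp$bouts) && nrow(sp$bouts)) {
        for (i in seq_len(nrow(sp$bouts))) {
          band <- .intensity_band(sp$bouts$intensity[i])
          idx <- seq(sp$bouts$start[i], length.out = sp$bouts$duration[i])
          target <- sp$bouts$mean_cpm[i]
          lo <- max(band[1], floor(target * 0.85))
          hi <- min(band[2], ceiling(target * 1.15))
          cpm[idx] <- round(runif(length(idx), lo, hi))
        }
      }
      if (!is.null(sp$nonwear) && nrow(sp$nonwear)) {
        for (i in seq_len(nrow(sp$nonwear))) {
          if (sp$nonwear$duration[i] == 0) next
          idx <- seq(sp$nonwear$start[i], length.out = sp$nonwear$duration[i])
          cpm[idx] <- 0
        }
      }
      if (epoch_seconds == 60) {
        data.frame(participant_id = participant_id, day = d,
                   day_type = sp$day_type, epoch = seq_len(sp$minutes),
                   counts = cpm, stringsAsFactors = FALSE)
      } else {
        quarters <- vapply(cpm, function(cnt) {
          if (cnt == 0) return(c(0, 0, 0, 0))
          as.numeric(rmultinom(1, cnt, rep(0.25, 4)))
        }, numeric(4))
        data.frame(participant_id = participant_id, day = d,
                   day_type = sp$day_type,
                   epoch = seq_len(4 * sp$minutes),
                   counts = as.numeric(quarters), stringsAsFactors = FALSE)
      }
    })
    count_series(do.call(rbind, per_day), epoch_seconds)
  })
}
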