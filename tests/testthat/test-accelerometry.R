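# Accelerometer preprocessing rules.

test_that("15-s epochs consolidate into minute sums, dropping partial tails", {
  mk15 <- function(counts) {
    count_series(data.frame(participant_id = "P1", day = 1,
                            day_type = "weekday",
                            epoch = seq_along(counts), counts = counts), 15)
  }
  expect_equal(aggregate_epochs(mk15(c(10, 20, 30, 40)))$counts, 100)
  expect_equal(aggregate_epochs(mk15(rep(0, 8)))$counts, c(0, 0))
  # 9 epochs: two complete minutes, last epoch dropped (manual windowing)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  expect_equal(aggregate_epochs(mk15(x))$counts, c(sum(x[1:4]), sum(x[5:8])))
  # a 60-s series passes through unchanged with a notice
  s60 <- series_from_counts(c(5, 10))
  expect_message(out <- aggregate_epochs(s60), "60-s")
  expect_identical(out, s60)
})

test_that("zero runs of 20+ minutes are non-wear, shorter runs are wear", {
  flank <- c(500, 600)
  s25 <- series_from_counts(c(flank, rep(0, 25), flank))
  ann <- detect_nonwear(s25)
  expect_equal(sum(!ann$wear), 25)
  expect_true(all(!ann$wear[3:27]))
  s19 <- series_from_counts(c(flank, rep(0, 19), flank))
  expect_true(all(detect_nonwear(s19)$wear))
  alternating <- series_from_counts(rep(c(0, 500), 30))
  expect_true(all(detect_nonwear(alternating)$wear))
})

test_that("non-wear runs span day boundaries within a recording", {
  d1 <- data.frame(participant_id = "P1", day = 1, day_type = "weekday",
                   epoch = 1:30, counts = c(rep(300, 18), rep(0, 12)))
  d2 <- data.frame(participant_id = "P1", day = 2, day_type = "weekday",
                   epoch = 1:30, counts = c(rep(0, 10), rep(300, 20)))
  ann <- detect_nonwear(count_series(rbind(d1, d2), 60))
  # 12 + 10 = 22 consecutive zero minutes across the boundary
  expect_equal(sum(!ann$wear), 22)
})

test_that("intensity cut-points are applied literally at the boundaries", {
  s <- series_from_counts(c(100, 101, 2295, 2296, 0))
  ann <- classify_intensity(detect_nonwear(s))
  expect_equal(ann$class, c("sedentary", "light", "light", "mvpa", "sedentary"))
  # non-wear wins over counts
  s2 <- series_from_counts(c(rep(0, 25), 3000))
  ann2 <- classify_intensity(detect_nonwear(s2))
  expect_equal(ann2$class[1:25], rep("nonwear", 25))
  expect_equal(ann2$class[26], "mvpa")
})

test_that("every minute gets exactly one class and classes partition time", {
  set.seed(14)
  for (r in 1:10) {
    counts <- sample(c(0, 0, 0, 50, 500, 3000), 200, replace = TRUE)
    ann <- classify_intensity(detect_nonwear(series_from_counts(counts)))
    expect_false(anyNA(ann$class))
    d <- summarize_days(ann)
    expect_equal(d$wear_minutes, d$sedentary + d$light + d$mvpa)
    expect_equal(d$wear_minutes + sum(ann$class == "nonwear"), 200)
  }
})

test_that("non-wear detection is idempotent", {
  counts <- c(rep(100, 30), rep(0, 25), rep(50, 10), rep(0, 19), 100)
  s <- series_from_counts(counts)
  a1 <- detect_nonwear(s)
  # re-detect on the same series: identical flags
  a2 <- detect_nonwear(s)
  expect_identical(a1$wear, a2$wear)
})

test_that("raising the MVPA cut-point never increases MVPA minutes", {
  set.seed(3)
  counts <- round(runif(300, 0, 5000))
  ann0 <- detect_nonwear(series_from_counts(counts))
  mvpa_min <- vapply(c(1500, 2295, 3000, 4000), function(cut) {
    a <- classify_intensity(ann0, cuts = c(sedentary = 100, light = cut))
    sum(a$class == "mvpa")
  }, 0)
  expect_true(all(diff(mvpa_min) <= 0))
})

test_that("day validity uses the inclusive 480-minute wear bound", {
  mk_day <- function(wear) {
    counts <- c(rep(200, wear), rep(0, 700 - wear))
    ann <- classify_intensity(detect_nonwear(series_from_counts(counts)))
    summarize_days(ann)
  }
  expect_true(mk_day(500)$valid_day)
  expect_true(mk_day(480)$valid_day)
  expect_false(mk_day(479)$valid_day)
})

test_that("participant validity needs 3 valid weekdays and 1 weekend day", {
  mk <- function(wd_valid, we_valid, wd_total = 5, we_total = 2) {
    data.frame(
      participant_id = "P1",
      day = seq_len(wd_total + we_total),
      day_type = c(rep("weekday", wd_total), rep("weekend", we_total)),
      wear_minutes = 500, sedentary = 400, light = 50, mvpa = 50,
      valid_day = c(rep(TRUE, wd_valid), rep(FALSE, wd_total - wd_valid),
                    rep(TRUE, we_valid), rep(FALSE, we_total - we_valid)))
  }
  expect_true(participant_valid(mk(3, 1)))
  expect_false(participant_valid(mk(4, 0)))
  expect_false(participant_valid(mk(2, 2)))
})

test_that("mean daily MVPA averages valid days only and errors when excluded", {
  summ <- data.frame(
    participant_id = "P1", day = 1:5,
    day_type = c("weekday", "weekday", "weekday", "weekend", "weekday"),
    wear_minutes = c(500, 500, 500, 500, 100),
    sedentary = 0, light = 0,
    mvpa = c(60, 70, 80, 70, 200),
    valid_day = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # the invalid day's 200 MVPA minutes are excluded: hand-filtered mean = 70
  expect_equal(mean_daily_mvpa(summ), 70)
  summ0 <- summ; summ0$mvpa <- 0
  expect_equal(mean_daily_mvpa(summ0), 0)
  bad <- summ; bad$valid_day <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_error(mean_daily_mvpa(bad), "excluded")
})

test_that("scheduled MVPA is recovered exactly end-to-end", {
  mvpa_bout <- function(dur) data.frame(start = 60, duration = dur,
                                        intensity = "mvpa", mean_cpm = 3000)
  days <- c(lapply(c(40, 50, 60), function(d) {
    trace_day("weekday", minutes = 600, bouts = mvpa_bout(d))
  }), list(trace_day("weekend", minutes = 600, bouts = mvpa_bout(30))))
  tr <- generate_count_trace(days, seed = 21)
  res <- process_counts(tr)
  expect_true(res$participants$valid)
  expect_equal(res$participants$mean_daily_mvpa, (40 + 50 + 60 + 30) / 4)
})
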