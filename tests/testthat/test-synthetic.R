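# Synthetic cohort and count-trace generation.

test_that("cohort size, labels and gender come from the profile specs", {
  specs <- reference_profiles()
  coh <- generate_cohort(specs, seed = 11)
  expect_equal(nrow(coh), 194)
  expect_equal(as.integer(table(coh$true_profile)[
    c("Excellers", "Notables", "Resilients", "Moderates", "Strugglers",
      "Socializers")]),
    c(29L, 43L, 29L, 35L, 38L, 20L))
  expect_false(anyNA(cohort_matrix(coh)))
  iv <- input_variables()
  for (i in seq_len(nrow(iv))) {
    v <- coh[[iv$variable[i]]]
    expect_true(all(v >= iv$lower[i] & v <= iv$upper[i]), label = iv$variable[i])
  }
})

test_that("zero spread collapses every draw to the median", {
  sp <- profile_spec("flat", 10,
                     location = c(daily_mvpa = 45, bmi_percentile = 50,
                                  school_enjoyment = 3),
                     spread = c(daily_mvpa = 0, bmi_percentile = 0,
                                school_enjoyment = 0))
  coh <- generate_cohort(list(sp), seed = 2)
  expect_equal(coh$daily_mvpa, rep(45, 10))
  expect_equal(coh$bmi_percentile, rep(50, 10))
  expect_equal(coh$school_enjoyment, rep(3, 10))
})

test_that("a location outside its bounds is rejected naming the variable", {
  expect_error(
    profile_spec("bad", 5,
                 location = c(bmi_percentile = 120),
                 spread = c(bmi_percentile = 10)),
    "bmi_percentile")
})

test_that("per-profile sample medians track the spec medians", {
  # Monte-Carlo check against the generator's own parameters: the mean of
  # the per-seed sample medians must sit within half an IQR of the target
  specs <- reference_profiles()
  vars <- input_variables()$variable
  seeds <- c(101, 202, 303, 404, 505)
  cohorts <- lapply(seeds, function(s) generate_cohort(specs, seed = s))
  for (sp in specs) {
    for (v in vars) {
      meds <- vapply(cohorts, function(coh) {
        median(coh[[v]][coh$true_profile == sp$name])
      }, 0)
      tol <- max(0.5 * sp$spread[[v]], 1e-9)
      expect_lt(abs(mean(meds) - sp$location[[v]]), tol + 1e-9,
                label = sprintf("%s %s", sp$name, v))
    }
  }
})

test_that("generated medians converge to the spec medians at large n", {
  iv <- input_variables()
  specs <- reference_profiles(sizes = rep(2000L, 6))
  coh <- generate_cohort(specs, seed = 31)
  for (sp in specs) {
    sub <- coh[coh$true_profile == sp$name, ]
    for (v in iv$variable) {
      rng <- iv$upper[iv$variable == v] - iv$lower[iv$variable == v]
      expect_lt(abs(median(sub[[v]]) - sp$location[[v]]), 0.02 * rng,
                label = sprintf("%s %s", sp$name, v))
    }
  }
})

test_that("cohort generation is deterministic and CSV round-trips", {
  specs <- tiny_specs()
  a <- generate_cohort(specs, seed = 5)
  b <- generate_cohort(specs, seed = 5)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_cohort_csv(f1)
  expect_equal(back$daily_mvpa, a$daily_mvpa)
  expect_equal(as.character(back$gender), as.character(a$gender))
  unlink(c(f1, f2))
})

test_that("outcomes are drawn per profile with integer rounding", {
  coh <- generate_cohort(reference_profiles(), seed = 4)
  coh <- generate_outcomes(coh, seed = 4)
  expect_true(all(outcome_variables()$variable %in% names(coh)))
  expect_true(all(coh$math_fluency == round(coh$math_fluency)))
  expect_true(all(coh$stroop_dot_time > 0))
  # Exceller math fluency centers on its spec median (26, IQR 6)
  ex <- coh$math_fluency[coh$true_profile == "Excellers"]
  expect_lt(abs(median(ex) - 26), 3)
  # determinism
  coh2 <- generate_outcomes(generate_cohort(reference_profiles(), seed = 4),
                            seed = 4)
  expect_identical(coh, coh2)
})

test_that("zero-IQR outcomes equal their medians and unknown profiles error", {
  coh <- generate_cohort(tiny_specs(), seed = 9)
  os <- list(
    A = data.frame(variable = "math_fluency", location = 25, spread = 0),
    B = data.frame(variable = "math_fluency", location = 20, spread = 0)
  )
  out <- generate_outcomes(coh, os, seed = 1)
  expect_equal(out$math_fluency, ifelse(coh$true_profile == "A", 25, 20))
  coh$true_profile <- "C"
  expect_error(generate_outcomes(coh, os, seed = 1), "C")
  expect_error(generate_outcomes(coh[, setdiff(names(coh), "true_profile")],
                                 os), "true_profile")
})

test_that("count traces honor bout schedules and non-wear blocks", {
  day <- trace_day("weekday", minutes = 600,
                   bouts = data.frame(start = 100, duration = 30,
                                      intensity = "mvpa", mean_cpm = 3000),
                   nonwear = data.frame(start = 300, duration = 25))
  tr <- generate_count_trace(list(day), seed = 3)
  expect_s3_class(tr, "count_series")
  expect_equal(nrow(tr), 600)
  # forced zeros exactly where scheduled
  expect_true(all(tr$counts[300:324] == 0))
  expect_true(all(tr$counts[setdiff(1:600, 300:324)] > 0))
  # bout minutes land in the MVPA band, background in the sedentary band
  expect_true(all(tr$counts[100:129] > 2295))
  expect_true(all(tr$counts[setdiff(1:600, c(100:129, 300:324))] <= 100))
  # determinism and degenerate input
  expect_identical(generate_count_trace(list(day), seed = 3), tr)
  expect_equal(nrow(generate_count_trace(list(), seed = 1)), 0)
})

test_that("overlapping bouts and out-of-band bout targets are rejected", {
  expect_error(trace_day(bouts = data.frame(
    start = c(10, 20), duration = c(15, 10),
    intensity = c("mvpa", "light"), mean_cpm = c(3000, 1000))),
    "overlap")
  expect_error(trace_day(bouts = data.frame(
    start = 10, duration = 5, intensity = "light", mean_cpm = 5000)),
    "band")
})

test_that("15-s traces split each minute into four epochs summing to it", {
  day <- trace_day("weekend", minutes = 20)
  tr60 <- generate_count_trace(list(day), epoch_seconds = 60, seed = 8)
  tr15 <- generate_count_trace(list(day), epoch_seconds = 15, seed = 8)
  expect_equal(nrow(tr15), 80)
  sums <- colSums(matrix(tr15$counts, nrow = 4))
  # same seed, same per-minute counts before splitting
  expect_equal(sums, tr60$counts)
})
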