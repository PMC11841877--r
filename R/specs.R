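#' Canonical input variables of the profiling analysis
#'
#' The fifteen participant-level input variables the self-organizing map is
#' trained on, with their admissible ranges on the native scale and, for
#' questionnaire scores, the instrument step used when Likert snapping is
#' requested. Physical measures: daily MVPA (min/day), cardiorespiratory
#' fitness (PACER laps), actual motor competence (CAMSA score), BMI
#' percentile, self-reported physical activity (PAQ-C, 1-5). Psychological:
#' perceived motor competence (1-4), perceived physical literacy (1-4),
#' intrinsic and identified motivation (1-5), basic-psychological-need (BPN)
#' competence (1-5), physical self-concept (1-4). Social: BPN relatedness,
#' school enjoyment, social identity, task-involving climate (all 1-5).
#'
#' @return A data.frame with columns `variable`, `lower`, `upper`, `step`
#'   (NA for continuous measures) and `domain`.
#' @export
input_variables <- function() {
  data.frame(
    variable = c(
      "daily_mvpa", "cardiorespiratory_fitness", "actual_motor_competence",
      "bmi_percentile", "self_reported_pa",
      "perceived_motor_competence", "perceived_physical_literacy",
      "intrinsic_motivation", "identified_motivation", "bpn_competence",
      "physical_self_concept",
      "bpn_relatedness", "school_enjoyment", "social_identity",
      "task_involving_climate"
    ),
    lower = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    upper = c(300, 150, 28, 100, 5, 4, 4, 5, 5, 5, 4, 5, 5, 5, 5),
    step = c(NA, NA, NA, NA, NA, 0.05, 0.01,
             1 / 3, 1 / 3, 0.2, 1 / 3, 0.2, 0.2, 1 / 9, 0.2),
    domain = c(rep("physical", 5), rep("psychological", 6), rep("social", 4)),
    stringsAsFactors = FALSE
  )
}

#' Construct a generative profile specification
#'
#' A profile specification holds, for one latent participant profile, the
#' per-variable median (`location`) and interquartile range (`spread`) on the
#' native scale, the closed admissible interval per variable, the profile
#' size, and the proportion of girls. [generate_cohort()] draws each variable
#' from a median-matched truncated normal parameterized by these values.
#'
#' @param name Profile label.
#' @param size Number of participants (non-negative integer).
#' @param location Named numeric vector of medians (one per variable).
#' @param spread Named numeric vector of interquartile ranges, same names as
#'   `location`; all values must be >= 0.
#' @param bounds Data.frame with columns `variable`, `lower`, `upper`.
#'   Defaults to the ranges in [input_variables()] for the variables present.
#' @param girl_fraction Proportion of girls in `[0, 1]`.
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(name, size, location, spread,
                         bounds = NULL, girl_fraction = 0.5) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(size) != 1 || size < 0 || size != round(size)) {
    stopf("profile '%s': size must be a non-negative integer", name)
  }
  if (is.null(names(location)) || is.null(names(spread))) {
    stopf("profile '%s': location and spread must be named", name)
  }
  if (!setequal(names(location), names(spread))) {
    stopf("profile '%s': location and spread name mismatch", name)
  }
  spread <- spread[names(location)]
  if (any(spread < 0)) {
    stopf("profile '%s': negative spread for %s", name,
          paste(names(spread)[spread < 0], collapse = ", "))
  }
  if (girl_fraction < 0 || girl_fraction > 1) {
    stopf("profile '%s': girl_fraction must be in [0, 1]", name)
  }
  if (is.null(bounds)) {
    iv <- input_variables()
    bounds <- iv[match(names(location), iv$variable),
                 c("variable", "lower", "upper")]
    # variables unknown to the canonical table get unbounded support
    miss <- is.na(bounds$variable)
    bounds$variable[miss] <- names(location)[miss]
    bounds$lower[miss] <- -Inf
    bounds$upper[miss] <- Inf
  }
  bounds <- bounds[match(names(location), bounds$variable), ]
  out_of_bounds <- names(location)[location < bounds$lower |
                                     location > bounds$upper]
  if (length(out_of_bounds)) {
    stopf("profile '%s': location outside bounds for %s", name,
          paste(out_of_bounds, collapse = ", "))
  }
  structure(
    list(name = name, size = as.integer(size),
         location = location, spread = spread,
         bounds = bounds, girl_fraction = girl_fraction),
    class = "profile_spec"
  )
}

#' @export
print.profile_spec <- function(x, ...) {
  cat(sprintf("<profile_spec> %s: n = %d, %.0f%% girls, %d variables\n",
              x$name, x$size, 100 * x$girl_fraction, length(x$location)))
  invisible(x)
}

# Per-profile medians and IQRs of the fifteen input variables for the six
# published child profiles, plus per-profile girl fractions. Rows follow
# input_variables() order; columns are the profiles.
.profile_medians <- function() {
  m <- cbind(
    Excellers   = c(70.43, 56, 22, 37, 3.48, 3.55, 3.63, 5, 5, 4.8, 3.5,
                    4.2, 3.8, 4.56, 4.6),
    Notables    = c(34.86, 26, 21, 81.5, 3.42, 3.35, 3.43, 5, 5, 4.4, 3.33,
                    4.6, 4, 4.56, 4.6),
    Resilients  = c(34, 22, 20, 79.5, 2.99, 3.15, 3.17, 4.67, 4.33, 4.2, 3,
                    3, 3.6, 3.67, 3.6),
    Moderates   = c(40.57, 28, 19, 28.1, 3.02, 2.7, 2.97, 4.67, 4.33, 4, 2.67,
                    4, 3.4, 4, 4),
    Strugglers  = c(33.57, 19, 19, 79.35, 2.30, 2.58, 2.6, 3.67, 3.67, 3.2,
                    2.25, 3, 2.8, 3.22, 3.4),
    Socializers = c(33.88, 11, 14.5, 90.6, 2.89, 2.53, 2.75, 4.33, 4.33, 3.8,
                    2.67, 4.1, 3.8, 3.89, 4.4)
  )
  rownames(m) <- input_variables()$variable
  m
}

.profile_iqrs <- function() {
  m <- cbind(
    Excellers   = c(32, 20, 4, 32.4, 0.49, 0.3, 0.23, 0, 0.33, 0.4, 0.5,
                    0.8, 1, 1.22, 0.8),
    Notables    = c(22.2, 15.5, 5, 22.5, 0.91, 0.45, 0.28, 0.33, 0.67, 1, 0.5,
                    0.8, 0.8, 0.72, 0.8),
    Resilients  = c(21.1, 15, 3, 20.9, 0.66, 0.4, 0.37, 0.67, 0.67, 0.6, 0.33,
                    1, 1, 0.89, 0.8),
    Moderates   = c(22.3, 15, 3.5, 25.7, 0.57, 0.63, 0.33, 0.33, 0.67, 0.8,
                    0.5, 0.6, 0.9, 0.72, 0.4),
    Strugglers  = c(21.4, 11.8, 4, 27.2, 0.89, 0.44, 0.52, 1, 0.33, 0.8, 0.63,
                    1, 1, 0.64, 0.6),
    Socializers = c(20.5, 6.5, 3.25, 8.6, 0.51, 0.63, 0.48, 0.75, 0.67, 0.65,
                    0.54, 1.1, 1.2, 0.61, 0.61)
  )
  rownames(m) <- input_variables()$variable
  m
}

#' The six reference child profiles
#'
#' Generative specifications for the six activity-cognition profiles the
#' package is designed around (Excellers, Notables, Resilients, Moderates,
#' Strugglers, Socializers; sizes 29/43/29/35/38/20, total 194). Locations
#' and spreads are the published per-cluster medians and interquartile ranges
#' of the fifteen input variables. Girl fractions: Resilients 0.31,
#' Moderates 0.657, Strugglers 0.605, Socializers 0.65 as reported; Notables
#' 0.50 (described as balanced); Excellers 0.19, chosen so the cohort total
#' matches the reported 48.96% girls.
#'
#' @param iqr_scale Multiplier applied to every spread; values below 1
#'   sharpen the separation between profiles (e.g. `0.5` for recovery
#'   simulations).
#' @param sizes Integer vector of six profile sizes.
#' @return A list of six [profile_spec()] objects.
#' @export
reference_profiles <- function(iqr_scale = 1,
                               sizes = c(29L, 43L, 29L, 35L, 38L, 20L)) {
  stopifnot(length(sizes) == 6, iqr_scale >= 0)
  med <- .profile_medians()
  iqr <- .profile_iqrs()
  girls <- c(Excellers = 0.19, Notables = 0.50, Resilients = 0.31,
             Moderates = 0.657, Strugglers = 0.605, Socializers = 0.65)
  lapply(seq_len(6), function(i) {
    nm <- colnames(med)[i]
    profile_spec(nm, sizes[i],
                 location = med[, i], spread = iqr[, i] * iqr_scale,
                 girl_fraction = girls[[nm]])
  })
}

#' Outcome variables of the cognitive battery
#'
#' Names, admissible ranges and integer flags for the cognitive outcome
#' variables: academic achievement (school grades 0-5), perceived math and
#' language performance (Likert 1-5), math fluency (correct operations out of
#' 160), Digit Span total recall, Stroop completion times (seconds) and total
#' responses per round.
#'
#' @return Data.frame with columns `variable`, `lower`, `upper`, `integer`.
#' @export
outcome_variables <- function() {
  data.frame(
    variable = c("academic_achievement", "perceived_math_performance",
                 "perceived_language_performance", "math_fluency",
                 "digit_span_total", "stroop_dot_time", "stroop_word_time",
                 "stroop_color_time", "stroop_dot_responses",
                 "stroop_word_responses", "stroop_color_responses"),
    lower = c(0, 1, 1, 0, 0, 1, 1, 1, 0, 0, 0),
    upper = c(5, 5, 5, 160, 30, 600, 600, 600, 60, 60, 60),
    integer = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Reference per-profile outcome distributions
#'
#' Per-profile medians and interquartile ranges for the cognitive outcomes.
#' Math fluency, Digit Span and the Stroop times/responses use the published
#' per-cluster values; academic achievement and the perceived-performance
#' scores are synthetic choices consistent with the reported direction of
#' between-cluster differences (they are not printed per cluster).
#'
#' @return Named list (one element per profile) of data.frames with columns
#'   `variable`, `location`, `spread`.
#' @export
reference_outcome_specs <- function() {
  ov <- outcome_variables()$variable
  med <- cbind(
    Excellers   = c(4.2, 4, 4, 26, 5, 63.9, 51.7, 64.3, 24, 24, 25),
    Notables    = c(4.0, 4, 4, 29, 5, 64.5, 52.1, 59.5, 25, 25, 25),
    Resilients  = c(4.0, 4, 4, 28, 5, 51.6, 41.5, 49.3, 25, 25, 26),
    Moderates   = c(4.1, 4, 4, 23, 5, 64.3, 53.5, 65.8, 25, 25, 26),
    Strugglers  = c(3.5, 3, 3, 21, 4, 64.5, 48.5, 58.7, 24, 25, 25),
    Socializers = c(3.4, 3, 3, 21.5, 5, 76.1, 62.9, 74.4, 25.5, 25, 26.5)
  )
  iqr <- cbind(
    Excellers   = c(1, 1, 1, 6, 1, 25, 19.8, 19.6, 1, 1, 3),
    Notables    = c(1, 1, 1, 8.5, 1, 32.1, 21.1, 28.2, 2, 2, 3),
    Resilients  = c(1, 1, 1, 7, 1, 36.3, 13.5, 26.2, 3, 4, 4),
    Moderates   = c(1, 1, 1, 9.5, 1, 25.7, 30.3, 31.2, 3, 2.5, 4),
    Strugglers  = c(1, 1, 1, 11, 1, 30.9, 27, 33.1, 2, 2, 3),
    Socializers = c(1, 1, 1, 8, 1, 31.2, 30.2, 42.8, 1.25, 2, 1.25)
  )
  rownames(med) <- rownames(iqr) <- ov
  out <- lapply(colnames(med), function(nm) {
    data.frame(variable = ov, location = med[, nm], spread = iqr[, nm],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- colnames(med)
  out
}

#' Published Kruskal-Wallis statistics for the reference analysis
#'
#' The reported Kruskal-Wallis chi-square statistics and epsilon-squared
#' effect sizes for the fifteen input variables and the cognitive outcomes of
#' the 194-child reference analysis (df = 5 throughout). Used to check the
#' internal identity `eps^2 = H / (n - 1)` against an independent source.
#'
#' @param which `"input"` or `"outcome"`.
#' @return Data.frame with `variable`, `H`, `eps2` and `n`.
#' @export
reference_effect_sizes <- function(which = c("input", "outcome")) {
  which <- match.arg(which)
  if (which == "input") {
    data.frame(
      variable = input_variables()$variable,
      H = c(42.3, 82.6, 62.1, 97.5, 67.8, 115.0, 105.4, 95.2, 87.4, 77.1,
            107.4, 84.0, 41.2, 75.3, 70.0),
      eps2 = c(0.22, 0.43, 0.32, 0.51, 0.35, 0.60, 0.55, 0.49, 0.45, 0.40,
               0.56, 0.44, 0.21, 0.39, 0.36),
      n = 194L, stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      variable = c("math_fluency", "digit_span_total", "stroop_dot_time",
                   "stroop_word_time", "stroop_color_time",
                   "stroop_dot_responses", "stroop_word_responses",
                   "stroop_color_responses", "dot_time_efficacy",
                   "word_time_efficacy", "dot_responses_efficacy",
                   "word_responses_efficacy"),
      H = c(28.54, 4.43, 8.49, 17.67, 13.68, 16.54, 4.98, 7.69, 5.6, 1.41,
            2.86, 4.12),
      eps2 = c(0.1479, 0.02293, 0.04398, 0.09154, 0.07086, 0.08571, 0.02583,
               0.03983, 0.02904, 0.00732, 0.01481, 0.02136),
      n = 194L, stringsAsFactors = FALSE
    )
  }
}
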