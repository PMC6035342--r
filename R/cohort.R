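# Synthetic matched case-control cohort simulator. Emulates the structure
# the analysis assumes -- 20 controls per case matched on sex and week of
# birth (+/- 1 year), an index contact date (CLD) per case with a terminal
# contact block of at most one month, and class-specific per-factor event
# prevalences in each look-back frame.

#' Illustrative planted prevalence table
#'
#' Probability that a person has at least one event of each factor in each
#' time frame, by class. The table is an illustrative configuration for the
#' simulator -- cases enriched for psychotropic prescriptions, depression and
#' anxiety, and self-harm, with weaker enrichment for hospital admission and
#' substance misuse, and near-universal GP contact in both classes. It is not
#' calibrated to any registry.
#'
#' @return Data frame with columns `factor`, `frame`, `control`, `case`
#'   (60 rows, probabilities in `[0, 1]`).
#' @seealso [null_prevalence()], [single_factor_prevalence()]
#' @export
default_prevalence <- function() {
  ctrl <- list(
    depression_anxiety    = c(0.020, 0.050, 0.060, 0.150),
    other_common_mental   = c(0.010, 0.020, 0.030, 0.080),
    other_mental_health   = c(0.005, 0.010, 0.015, 0.040),
    injury_poisoning      = c(0.020, 0.050, 0.060, 0.150),
    self_harm             = c(0.002, 0.005, 0.008, 0.020),
    alcohol_misuse        = c(0.010, 0.020, 0.030, 0.080),
    drugs_misuse          = c(0.005, 0.010, 0.015, 0.040),
    possible_maltreatment = c(0.001, 0.002, 0.003, 0.010),
    physical_sleep        = c(0.005, 0.010, 0.015, 0.050),
    nonphysical_sleep     = c(0.005, 0.015, 0.020, 0.060),
    others                = c(0.300, 0.500, 0.550, 0.800),
    opiates_rx            = c(0.020, 0.050, 0.060, 0.150),
    psychotropics_rx      = c(0.030, 0.060, 0.080, 0.180),
    gp_contact            = c(0.600, 0.850, 0.900, 0.970),
    hospital_admission    = c(0.030, 0.080, 0.100, 0.300)
  )
  case <- list(
    depression_anxiety    = c(0.200, 0.300, 0.280, 0.450),
    other_common_mental   = c(0.050, 0.080, 0.080, 0.150),
    other_mental_health   = c(0.040, 0.060, 0.060, 0.120),
    injury_poisoning      = c(0.050, 0.100, 0.100, 0.220),
    self_harm             = c(0.080, 0.120, 0.120, 0.250),
    alcohol_misuse        = c(0.060, 0.100, 0.100, 0.200),
    drugs_misuse          = c(0.050, 0.080, 0.080, 0.150),
    possible_maltreatment = c(0.004, 0.008, 0.010, 0.030),
    physical_sleep        = c(0.010, 0.020, 0.030, 0.080),
    nonphysical_sleep     = c(0.020, 0.040, 0.050, 0.120),
    others                = c(0.350, 0.550, 0.600, 0.850),
    opiates_rx            = c(0.060, 0.120, 0.120, 0.250),
    psychotropics_rx      = c(0.250, 0.350, 0.330, 0.480),
    gp_contact            = c(0.550, 0.800, 0.850, 0.950),
    hospital_admission    = c(0.120, 0.250, 0.250, 0.500)
  )
  stopifnot(identical(names(ctrl), risk_factors()),
            identical(names(case), risk_factors()))
  data.frame(
    factor = rep(risk_factors(), each = length(TIME_FRAMES)),
    frame = rep(TIME_FRAMES, times = length(risk_factors())),
    control = unlist(ctrl, use.names = FALSE),
    case = unlist(case, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Null prevalence table (no class difference)
#'
#' The [default_prevalence()] table with the case column replaced by the
#' control column, so case and control event rates are identical. Cohorts
#' generated from it carry no class signal: a competent classifier should
#' score at chance on them.
#'
#' @return Data frame in the same format as [default_prevalence()].
#' @export
null_prevalence <- function() {
  prev <- default_prevalence()
  prev$case <- prev$control
  prev
}

#' Prevalence table with a single planted class difference
#'
#' All factors in all frames share a common background probability in both
#' classes, except one (factor, frame) cell which gets class-specific
#' probabilities. Used for parameter-recovery experiments: the planted cell
#' is the only source of case-control signal.
#'
#' @param factor Factor label to enrich (one of [risk_factors()]).
#' @param frame Time frame of the enrichment (one of [time_frames()]).
#' @param case_prob,control_prob Probabilities for the enriched cell.
#' @param background Probability used everywhere else, both classes.
#' @return Data frame in the same format as [default_prevalence()].
#' @export
single_factor_prevalence <- function(factor, frame, case_prob = 0.95,
                                     control_prob = 0.02, background = 0.1) {
  stopifnot(factor %in% risk_factors(), frame %in% TIME_FRAMES,
            case_prob >= 0, case_prob <= 1,
            control_prob >= 0, control_prob <= 1,
            background >= 0, background <= 1)
  prev <- default_prevalence()
  prev$control <- background
  prev$case <- background
  hit <- prev$factor == factor & prev$frame == frame
  prev$control[hit] <- control_prob
  prev$case[hit] <- case_prob
  prev
}

validate_prevalence <- function(prev) {
  need <- c("factor", "frame", "control", "case")
  if (!is.data.frame(prev) || !all(need %in% names(prev))) {
    stop("prevalence must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!prev$factor %in% risk_factors())) {
    stop("unknown factor label(s) in prevalence table: ",
         paste(setdiff(prev$factor, risk_factors()), collapse = ", "),
         call. = FALSE)
  }
  if (any(!prev$frame %in% TIME_FRAMES)) {
    stop("unknown time frame(s) in prevalence table", call. = FALSE)
  }
  pr <- c(prev$control, prev$case)
  if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1)) {
    stop("prevalence probabilities must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(prev$factor, prev$frame)
  if (anyDuplicated(key)) stop("duplicate (factor, frame) rows", call. = FALSE)
  full <- paste(rep(risk_factors(), each = 4), rep(TIME_FRAMES, 15))
  if (!setequal(key, full)) {
    stop("prevalence table must cover all 15 factors x 4 frames",
         call. = FALSE)
  }
  invisible(prev)
}

#' Cohort simulation configuration
#'
#' Bundles and validates everything [generate_cohort()] needs. Defaults
#' mirror the study population the analysis targets: 20 matched controls per
#' case, 77.3% male cases, age at index contact centred near 48 years, study
#' window 2001--2015.
#'
#' @param n_cases Number of cases (positive integer).
#' @param controls_per_case Matched controls per case (default 20).
#' @param male_fraction Probability a case is male (default 0.773).
#' @param age_mean,age_sd Mean and SD of age at the index contact, in years
#'   (defaults 48 and 14); draws are truncated at 10 years.
#' @param prevalence Planted prevalence table, see [default_prevalence()].
#' @param events_per_active_factor Mean number of events per active
#'   (factor, frame) cell; counts are drawn as `1 + Poisson(mean - 1)`.
#' @param study_start,study_end Calendar bounds on all event dates.
#' @param seed Integer seed making the cohort reproducible.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases,
                          controls_per_case = 20,
                          male_fraction = 0.773,
                          age_mean = 48,
                          age_sd = 14,
                          prevalence = default_prevalence(),
                          events_per_active_factor = 1.5,
                          study_start = as.Date("2001-01-01"),
                          study_end = as.Date("2015-12-31"),
                          seed = 1L) {
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1 ||
      n_cases != round(n_cases)) {
    stop("n_cases must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(controls_per_case) || controls_per_case < 1 ||
      controls_per_case != round(controls_per_case)) {
    stop("controls_per_case must be a positive integer", call. = FALSE)
  }
  if (male_fraction < 0 || male_fraction > 1) {
    stop("male_fraction must be a probability", call. = FALSE)
  }
  if (age_mean < 10) stop("age_mean must be at least 10 years", call. = FALSE)
  if (events_per_active_factor < 1) {
    stop("events_per_active_factor must be >= 1", call. = FALSE)
  }
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (as.numeric(study_end - study_start) < 5 * DAYS_PER_YEAR + 1) {
    stop("study window must span more than five years so that every index ",
         "date has a full look-back period", call. = FALSE)
  }
  validate_prevalence(prevalence)
  structure(list(
    n_cases = as.integer(n_cases),
    controls_per_case = as.integer(controls_per_case),
    male_fraction = male_fraction,
    age_mean = age_mean, age_sd = age_sd,
    prevalence = prevalence,
    events_per_active_factor = events_per_active_factor,
    study_start = study_start, study_end = study_end,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Select matched controls for one case
#'
#' Draws `k` distinct controls from a candidate pool, requiring identical
#' sex and birth date within one year (365.25 days) of the case. Sampling
#' uses the current RNG state and is without replacement within the pool.
#'
#' @param case One-row data frame describing the case (needs `sex`,
#'   `birth_date`, `person_id`).
#' @param pool Data frame of candidate persons (needs `person_id`, `sex`,
#'   `birth_date`).
#' @param k Number of controls to draw; `k = 0` returns an empty pool slice.
#' @return `k` rows of `pool`.
#' @export
match_controls <- function(case, pool, k) {
  stopifnot(is.data.frame(case), nrow(case) == 1, is.data.frame(pool),
            k >= 0, k == round(k))
  if (k == 0) return(pool[0, , drop = FALSE])
  eligible <- pool$sex == case$sex &
    abs(as.numeric(pool$birth_date - case$birth_date)) <= DAYS_PER_YEAR
  n_ok <- sum(eligible)
  if (n_ok < k) {
    stop(sprintf(
      "matching exhausted for case %s: %d controls requested, %d eligible",
      case$person_id, k, n_ok), call. = FALSE)
  }
  idx <- which(eligible)
  take <- if (length(idx) == 1) idx else sample(idx, k)
  pool[take[seq_len(k)], , drop = FALSE]
}

# Integer day-offset range (days before CLD) guaranteed to fall inside each
# frame under the fractional-day bounds.
frame_day_range <- function(frame) {
  lo <- if (frame == "1M") 0L else floor(FRAME_LOWER[[frame]]) + 1L
  hi <- floor(FRAME_UPPER[[frame]])
  c(lo, hi)
}

factor_source <- function(factor) {
  ifelse(factor == "hospital_admission", "hospital", "GP")
}

# Vectorised event planting over many persons; the exported per-person
# wrapper is plant_factor_events().
plant_events_for <- function(persons, config) {
  prev <- config$prevalence
  n <- nrow(persons)
  cell <- prev[rep(seq_len(nrow(prev)), times = n), ]
  cell$person_id <- rep(persons$person_id, each = nrow(prev))
  cell$label <- rep(persons$label, each = nrow(prev))
  cell$cld <- rep(persons$cld_date, each = nrow(prev))
  p <- ifelse(cell$label == "case", cell$case, cell$control)
  active <- cell[stats::runif(nrow(cell)) < p, , drop = FALSE]
  if (nrow(active) == 0) return(empty_events())
  n_ev <- 1L + stats::rpois(nrow(active), config$events_per_active_factor - 1)
  ev <- active[rep(seq_len(nrow(active)), times = n_ev), , drop = FALSE]
  rng <- vapply(TIME_FRAMES, frame_day_range, numeric(2))
  lo <- rng[1, ev$frame]
  hi <- rng[2, ev$frame]
  offset <- lo + floor(stats::runif(nrow(ev)) * (hi - lo + 1))
  offset <- pmin(offset, hi)
  data.frame(
    person_id = ev$person_id,
    source = factor_source(ev$factor),
    event_date = as.Date(ev$cld, origin = "1970-01-01") - offset,
    category = ev$factor,
    code = paste0("SYN:", ev$factor),
    in_cld_block = FALSE,
    stringsAsFactors = FALSE
  )
}

empty_events <- function() {
  data.frame(person_id = character(), source = character(),
             event_date = as.Date(character()), category = character(),
             code = character(), in_cld_block = logical(),
             stringsAsFactors = FALSE)
}

#' Plant factor events for one person
#'
#' For each (factor, time frame) cell, a Bernoulli draw at the class-specific
#' prevalence decides whether the person has that factor in that frame; if
#' so, one or more events (count `1 + Poisson(mean - 1)`) are dated uniformly
#' within the frame relative to the person's index contact date. Prescription
#' and diagnosis events carry source `"GP"` (hospital data has no
#' prescriptions); hospital admissions carry source `"hospital"`.
#'
#' @param person One-row data frame with `person_id`, `label`, `cld_date`.
#' @param config A [cohort_config()].
#' @return Data frame of events (possibly zero rows).
#' @export
plant_factor_events <- function(person, config) {
  stopifnot(is.data.frame(person), nrow(person) == 1)
  if (is.na(person$cld_date)) {
    stop("person has no index contact (cld_date)", call. = FALSE)
  }
  plant_events_for(person, config)
}

# Terminal contact block: 1-3 contacts within at most one month before a
# case's CLD, flagged so the feature builder can exclude them.
plant_cld_blocks <- function(cases) {
  n_ev <- 1L + stats::rpois(nrow(cases), 0.8)
  idx <- rep(seq_len(nrow(cases)), times = n_ev)
  span <- sample(0:30, nrow(cases), replace = TRUE)
  offset <- floor(stats::runif(length(idx)) * (span[idx] + 1))
  hosp <- stats::runif(length(idx)) < 0.3
  data.frame(
    person_id = cases$person_id[idx],
    source = ifelse(hosp, "hospital", "GP"),
    event_date = cases$cld_date[idx] - offset,
    category = ifelse(hosp, "hospital_admission", "gp_contact"),
    code = "SYN:cld_contact",
    in_cld_block = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic matched case-control cohort
#'
#' Produces `n_cases` cases, each with `controls_per_case` controls matched
#' on sex and birth date within one year, plus an event stream drawn from the
#' planted prevalence table. Each case receives an index contact date (CLD)
#' uniform in the study window (leaving a full five-year look-back), a
#' terminal contact block of at most one month flagged `in_cld_block`, and
#' controls inherit their matched case's CLD as index date so features are
#' computed over the same calendar window.
#'
#' @param config A [cohort_config()].
#' @return List of class `cohort` with elements `persons` (one row per
#'   person) and `events` (one row per event).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_cases = 5, seed = 42))
#' nrow(coh$persons)  # 5 cases + 100 controls
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cases
  k <- config$controls_per_case

  # Cases: sex, age at CLD (truncated normal, >= 10y), CLD uniform in the
  # window that leaves a full five-year look-back inside the study period.
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(age < 10)) {
    bad <- age < 10
    age[bad] <- stats::rnorm(sum(bad), config$age_mean, config$age_sd)
  }
  first_cld <- config$study_start + ceiling(5 * DAYS_PER_YEAR)
  span <- as.numeric(config$study_end - first_cld)
  cld <- first_cld + floor(stats::runif(n) * (span + 1))
  birth <- cld - round(age * DAYS_PER_YEAR)
  cases <- data.frame(
    person_id = sprintf("case_%05d", seq_len(n)),
    label = "case",
    sex = sex,
    birth_date = birth,
    cld_date = cld,
    matched_case_id = sprintf("case_%05d", seq_len(n)),
    stringsAsFactors = FALSE
  )

  # Controls: per case, a candidate pool of same-sex persons born within a
  # year, thinned through match_controls() so the matching rule is the one
  # actually enforced.
  control_list <- vector("list", n)
  for (i in seq_len(n)) {
    m <- k + 5L
    pool <- data.frame(
      person_id = sprintf("ctrl_%05d_%03d", i, seq_len(m)),
      sex = cases$sex[i],
      birth_date = cases$birth_date[i] +
        sample.int(2L * 365L + 1L, m, replace = TRUE) - 366L,
      stringsAsFactors = FALSE
    )
    picked <- match_controls(cases[i, ], pool, k)
    picked$label <- "control"
    picked$cld_date <- cases$cld_date[i]
    picked$matched_case_id <- cases$person_id[i]
    control_list[[i]] <- picked
  }
  controls <- do.call(rbind, control_list)
  controls <- controls[, c("person_id", "label", "sex", "birth_date",
                           "cld_date", "matched_case_id")]
  persons <- rbind(cases, controls)
  persons$age_at_cld <-
    as.numeric(persons$cld_date - persons$birth_date) / DAYS_PER_YEAR
  rownames(persons) <- NULL

  events <- plant_events_for(persons, config)
  blocks <- plant_cld_blocks(cases)
  events <- rbind(events, blocks)
  events <- events[order(events$person_id, events$event_date), ]
  rownames(events) <- NULL

  structure(list(persons = persons, events = events, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_case <- sum(x$persons$label == "case")
  cat(sprintf("Synthetic case-control cohort: %d cases, %d controls, %d events\n",
              n_case, nrow(x$persons) - n_case, nrow(x$events)))
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' Writes `persons.csv` and `events.csv` (comma-delimited, header row,
#' ISO-8601 dates) into `dir`.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "persons.csv")
  ep <- file.path(dir, "events.csv")
  utils::write.csv(cohort$persons, pp, row.names = FALSE)
  utils::write.csv(cohort$events, ep, row.names = FALSE)
  invisible(c(persons = pp, events = ep))
}

#' Read person and event tables written by [write_cohort()]
#'
#' @param persons_path,events_path Paths to the delimited files.
#' @return List with elements `persons` and `events`, dates parsed.
#' @export
read_cohort <- function(persons_path, events_path) {
  persons <- utils::read.csv(persons_path, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  persons$birth_date <- as.Date(persons$birth_date)
  persons$cld_date <- as.Date(persons$cld_date)
  events$event_date <- as.Date(events$event_date)
  if (!is.logical(events$in_cld_block)) {
    events$in_cld_block <- as.logical(events$in_cld_block)
  }
  list(persons = persons, events = events)
}
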