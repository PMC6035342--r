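# Controlled vocabulary shared by the simulator, the feature builder and the
# behaviour analyses. Factor labels name what the category records, not any
# particular coding system.

DIAGNOSIS_FACTORS <- c(
  "depression_anxiety", "other_common_mental", "other_mental_health",
  "injury_poisoning", "self_harm", "alcohol_misuse", "drugs_misuse",
  "possible_maltreatment", "physical_sleep", "nonphysical_sleep", "others"
)
PRESCRIPTION_FACTORS <- c("opiates_rx", "psychotropics_rx")
CONTACT_FACTORS <- c("gp_contact", "hospital_admission")

TIME_FRAMES <- c("1M", "6M", "1Y", "5Y")

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

# Look-back frame bounds in days before the index contact date (CLD).
# 1M is closed at both ends; the others are (lower, upper] on the
# days-before axis, i.e. closed at their early calendar edge.
FRAME_LOWER <- c(`1M` = 0, `6M` = DAYS_PER_MONTH, `1Y` = 6 * DAYS_PER_MONTH,
                 `5Y` = DAYS_PER_YEAR)
FRAME_UPPER <- c(`1M` = DAYS_PER_MONTH, `6M` = 6 * DAYS_PER_MONTH,
                 `1Y` = DAYS_PER_YEAR, `5Y` = 5 * DAYS_PER_YEAR)

RISK_LEVELS <- c("VLR", "LR", "MLR", "MHR", "HR", "VHR")
RISK_BREAKS <- c(0, 0.17, 0.33, 0.5, 0.67, 0.83, 1)

#' Risk factor labels
#'
#' The 15 binary health-event factors used throughout the package: 11
#' diagnosis categories (including the catch-all `"others"`), 2 prescription
#' categories (GP data only), plus the two contact-derived factors
#' (`"gp_contact"` fires on any GP-source event, `"hospital_admission"` on
#' any hospital-source event, regardless of category).
#'
#' @return Character vector of the 15 factor labels.
#' @export
#' @examples
#' risk_factors()
risk_factors <- function() {
  c(DIAGNOSIS_FACTORS, PRESCRIPTION_FACTORS, CONTACT_FACTORS)
}

#' Look-back time frames
#'
#' The four disjoint windows before the index contact date (CLD):
#' `1M` = \[CLD - 1 month, CLD\], `6M` = \[CLD - 6 months, CLD - 1 month),
#' `1Y` = \[CLD - 1 year, CLD - 6 months), `5Y` = \[CLD - 5 years,
#' CLD - 1 year). One month is 30.4375 days, one year 365.25 days.
#'
#' @return Character vector `c("1M", "6M", "1Y", "5Y")`.
#' @export
time_frames <- function() TIME_FRAMES

#' Names of the 62 model input features
#'
#' Age at CLD (raw years), sex (male = 1, female = 0), then one presence bit
#' per (factor, time frame) combination, factor-major:
#' `depression_anxiety_1M`, `depression_anxiety_6M`, ...
#'
#' @return Character vector of length 62.
#' @export
feature_names <- function() {
  bits <- as.vector(t(outer(risk_factors(), TIME_FRAMES, paste, sep = "_")))
  c("age", "sex", bits)
}
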