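# Feature builder: categorize coded events and test factor presence in the
# four look-back frames anchored at each person's index contact date,
# producing the 62-dimensional model input
# (age, sex, 15 factors x 4 frames).

CODE_MAPPED_CATEGORIES <- c(DIAGNOSIS_FACTORS, PRESCRIPTION_FACTORS)
CODING_SYSTEMS <- c("Read", "ICD10")

#' Load a code-to-category map
#'
#' Reads a delimited file with columns `coding_system` (`Read` for GP data,
#' `ICD10` for hospital data), `code`, and `category` (one of the 11
#' diagnosis or 2 prescription categories). The map is user-pluggable: any
#' clinical code list can be supplied. Duplicate (system, code) rows with
#' conflicting categories are rejected.
#'
#' @param path Path to a CSV file.
#' @return Data frame of class `code_map`.
#' @export
load_code_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("coding_system", "code", "category")
  if (!all(need %in% names(map))) {
    stop("code map needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  as_code_map(map[need])
}

#' Build a code map from a data frame
#'
#' @param map Data frame with columns `coding_system`, `code`, `category`.
#' @return Validated data frame of class `code_map`.
#' @export
as_code_map <- function(map) {
  bad_sys <- setdiff(unique(map$coding_system), CODING_SYSTEMS)
  if (length(bad_sys)) {
    stop("unknown coding system(s): ", paste(bad_sys, collapse = ", "),
         "; valid: ", paste(CODING_SYSTEMS, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(map$category), CODE_MAPPED_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown category label(s): ", paste(bad_cat, collapse = ", "),
         "; valid categories: ",
         paste(CODE_MAPPED_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  key <- paste(map$coding_system, map$code, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conflict <- tapply(map$category[dup], key[dup],
                       function(x) length(unique(x)) > 1)
    if (any(conflict)) {
      stop("conflicting categories for code(s): ",
           paste(gsub("\r", "/", names(conflict)[conflict]), collapse = ", "),
           call. = FALSE)
    }
    map <- map[!duplicated(key), , drop = FALSE]
  }
  rownames(map) <- NULL
  structure(map, class = c("code_map", "data.frame"))
}

#' Look up codes in a code map
#'
#' @param map A `code_map`.
#' @param coding_system,code Character vectors (recycled to equal length).
#' @return Character vector of categories, `NA` where unmapped.
#' @export
code_map_lookup <- function(map, coding_system, code) {
  stopifnot(inherits(map, "code_map"))
  key <- paste(coding_system, code, sep = "\r")
  map_key <- paste(map$coding_system, map$code, sep = "\r")
  map$category[match(key, map_key)]
}

#' Assign an event to its look-back time frame
#'
#' Computes which of the four disjoint frames contains an event relative to
#' the index contact date. On the days-before axis (`cld - event`):
#' `1M` covers `[0, 1 month]` (closed at both ends), `6M` `(1, 6]` months,
#' `1Y` `(6, 12]` months, `5Y` `(1, 5]` years, with 1 month = 30.4375 days
#' and 1 year = 365.25 days. So an event exactly one month before the index
#' date is `1M`, exactly six months before is `6M`, and so on.
#'
#' @param event_date,cld_date `Date` vectors, or numeric day counts.
#' @return Character vector of frame tags, `NA` for events after `cld_date`
#'   or more than five years before it.
#' @export
#' @examples
#' cld <- as.Date("2010-06-01")
#' window_of(cld - 10, cld)    # "1M"
#' window_of(cld - 400, cld)   # "5Y"
window_of <- function(event_date, cld_date) {
  d <- as.numeric(cld_date) - as.numeric(event_date)
  out <- rep(NA_character_, length(d))
  out[d >= 0 & d <= FRAME_UPPER[["1M"]]] <- "1M"
  out[d > FRAME_LOWER[["6M"]] & d <= FRAME_UPPER[["6M"]]] <- "6M"
  out[d > FRAME_LOWER[["1Y"]] & d <= FRAME_UPPER[["1Y"]]] <- "1Y"
  out[d > FRAME_LOWER[["5Y"]] & d <= FRAME_UPPER[["5Y"]]] <- "5Y"
  out
}

# Resolve each event's category: keep a valid supplied category, otherwise
# map the raw code (Read for GP events, ICD10 for hospital events), and fall
# back to the "others" diagnosis group so GP-contact semantics stay intact.
resolve_categories <- function(events, code_map = NULL) {
  cat <- if ("category" %in% names(events)) events$category
         else rep(NA_character_, nrow(events))
  known <- cat %in% c(CODE_MAPPED_CATEGORIES, CONTACT_FACTORS)
  if (!all(known) && !is.null(code_map)) {
    sys <- ifelse(events$source == "GP", "Read", "ICD10")
    mapped <- code_map_lookup(code_map, sys[!known], events$code[!known])
    cat[!known] <- mapped
    known <- !is.na(cat) & cat %in% c(CODE_MAPPED_CATEGORIES, CONTACT_FACTORS)
  }
  cat[!known] <- "others"
  cat
}

# Presence bits for a block of persons: n x 60 matrix in feature_names()
# order (factor-major). Excludes CLD-block events and events after the
# index date.
presence_matrix <- function(persons, events, code_map = NULL) {
  n <- nrow(persons)
  bit_names <- feature_names()[-(1:2)]
  P <- matrix(0, n, length(bit_names),
              dimnames = list(persons$person_id, bit_names))
  if (nrow(events) == 0) return(P)

  pid <- match(events$person_id, persons$person_id)
  orphans <- is.na(pid)
  if (any(orphans)) {
    warning(sum(orphans), " event(s) reference unknown person ids; ignored")
    events <- events[!orphans, , drop = FALSE]
    pid <- pid[!orphans]
  }
  if (nrow(events) == 0) return(P)

  keep <- !events$in_cld_block
  events <- events[keep, , drop = FALSE]
  pid <- pid[keep]
  if (nrow(events) == 0) return(P)

  late <- as.numeric(events$event_date) >
    as.numeric(persons$cld_date[pid])
  if (any(late)) {
    warning(sum(late), " event(s) dated after the index contact; ignored")
    events <- events[!late, , drop = FALSE]
    pid <- pid[!late]
  }
  frame <- window_of(events$event_date, persons$cld_date[pid])
  in_frame <- !is.na(frame)
  events <- events[in_frame, , drop = FALSE]
  pid <- pid[in_frame]
  frame <- frame[in_frame]
  if (nrow(events) == 0) return(P)

  category <- resolve_categories(events, code_map)
  set_bits <- function(rows, fct) {
    if (!length(rows)) return()
    cols <- match(paste(fct, frame[rows], sep = "_"), bit_names)
    P[cbind(pid[rows], cols)] <<- 1
  }
  # Category-driven factors (diagnoses + prescriptions).
  coded <- which(category %in% CODE_MAPPED_CATEGORIES)
  if (length(coded)) {
    cols <- match(paste(category[coded], frame[coded], sep = "_"), bit_names)
    P[cbind(pid[coded], cols)] <- 1
  }
  # Contact-derived factors fire on source alone, regardless of category.
  set_bits(which(events$source == "GP"), "gp_contact")
  set_bits(which(events$source == "hospital"), "hospital_admission")
  P
}

#' Build the 62-dimensional feature vector for one person
#'
#' Encodes age at the index contact (raw years), sex (male = 1), and one
#' presence bit per (factor, time frame): the bit is 1 iff the person has at
#' least one qualifying event of that factor dated in that frame. Events
#' flagged as part of the terminal contact block (`in_cld_block`) never
#' contribute, so no information directly tied to the death enters the
#' features. The `gp_contact` factor fires on any GP-source event and
#' `hospital_admission` on any hospital-source event, whatever the category.
#'
#' @param person One-row data frame with `person_id`, `sex`, `age_at_cld`,
#'   `cld_date`.
#' @param events Events for this person (rows for other ids are ignored).
#' @param code_map Optional [as_code_map()] used for events without a valid
#'   category; unmapped codes fall to the `"others"` group.
#' @return Named numeric vector of length 62.
#' @export
build_feature_vector <- function(person, events, code_map = NULL) {
  stopifnot(is.data.frame(person), nrow(person) == 1)
  if (is.null(person$cld_date) || is.na(person$cld_date)) {
    stop("person has no index contact date (cld_date)", call. = FALSE)
  }
  events <- events[events$person_id == person$person_id, , drop = FALSE]
  P <- presence_matrix(person, events, code_map)
  x <- c(age = unname(person$age_at_cld),
         sex = as.numeric(person$sex == "male"),
         P[1, ])
  names(x) <- feature_names()
  x
}

#' Build the design matrix and label vector for a cohort
#'
#' Stacks [build_feature_vector()] over all persons (row order follows
#' `persons`) and encodes the label as 1 for cases, 0 for controls. Events
#' referencing unknown person ids raise a warning with a count.
#'
#' @param persons Person table (needs `person_id`, `label`, `sex`,
#'   `age_at_cld`, `cld_date`).
#' @param events Event table for the whole cohort.
#' @param code_map Optional [as_code_map()].
#' @return List with `x` (numeric matrix, persons x 62, rownames =
#'   person ids) and `y` (0/1 numeric labels).
#' @export
build_design_matrix <- function(persons, events, code_map = NULL) {
  stopifnot(is.data.frame(persons), nrow(persons) > 0)
  if (anyNA(persons$cld_date)) {
    stop("some persons have no index contact date (cld_date)", call. = FALSE)
  }
  P <- presence_matrix(persons, events, code_map)
  x <- cbind(age = persons$age_at_cld,
             sex = as.numeric(persons$sex == "male"),
             P)
  rownames(x) <- persons$person_id
  colnames(x) <- feature_names()
  list(x = x, y = as.numeric(persons$label == "case"))
}
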