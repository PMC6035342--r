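# End-to-end orchestration: simulate -> featurize -> evaluate (optionally
# with a label-shuffle null arm) -> fit final model -> behaviour analyses,
# all driven by one seeded configuration, plus input-file validation.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param train A [training_config()].
#' @param architectures Architecture tags to evaluate.
#' @param n_repeats,n_folds Cross-validation plan dimensions.
#' @param test_train_ratio Overlap correction for the t-test (default 1/8).
#' @param shuffle_null Also run the label-shuffle null arm?
#' @param behavior Run the behaviour analyses on the best architecture?
#' @param master_seed Single seed from which every stage seed derives.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort,
                       train = training_config(),
                       architectures = "nn0",
                       n_repeats = 2L,
                       n_folds = 5L,
                       test_train_ratio = 1 / 8,
                       shuffle_null = FALSE,
                       behavior = TRUE,
                       master_seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(train, "training_config"),
            all(architectures %in% names(ARCHITECTURES)))
  structure(list(cohort = cohort, train = train,
                 architectures = architectures,
                 n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 test_train_ratio = test_train_ratio,
                 shuffle_null = isTRUE(shuffle_null),
                 behavior = isTRUE(behavior),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

stage_seeds <- function(master_seed) {
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("cohort", "folds", "cv", "shuffle", "final")
  s
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, builds features, cross-validates every requested
#' architecture, optionally repeats the evaluation after shuffling the case
#' labels within matched groups (the null arm), fits a final model with the
#' best (lowest mean error) architecture on the full cohort, and summarizes
#' its behaviour. Identical configuration and master seed give an identical
#' report.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; if given, the report is written there
#'   as `report.json` together with `cv_results.csv` and the cohort tables.
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$master_seed)

  ccfg <- config$cohort
  ccfg$seed <- unname(seeds["cohort"])
  message("stage simulate: ", ccfg$n_cases, " cases x ",
          ccfg$controls_per_case + 1L)
  cohort <- generate_cohort(ccfg)

  message("stage featurize: ", nrow(cohort$persons), " persons, ",
          nrow(cohort$events), " events")
  design <- build_design_matrix(cohort$persons, cohort$events)

  plan <- make_folds(cohort$persons, config$n_repeats, config$n_folds,
                     seed = unname(seeds["folds"]))
  results <- list()
  for (arch in config$architectures) {
    message("stage evaluate: ", arch, " (", config$n_repeats, "x",
            config$n_folds, "-fold)")
    results[[arch]] <- run_cv(design$x, design$y, cohort$persons, plan,
                              arch, config$train,
                              seed = unname(seeds["cv"]))
  }
  summaries <- lapply(results, summarize_cv)
  comparisons <- if (length(results) >= 2) {
    compare_architectures(results, "error", config$test_train_ratio)
  }

  null_block <- NULL
  if (config$shuffle_null) {
    message("stage evaluate (shuffle null)")
    shuffled <- shuffle_labels(cohort$persons,
                               seed = unname(seeds["shuffle"]))
    y_null <- as.numeric(shuffled$label == "case")
    null_results <- lapply(config$architectures, function(arch) {
      run_cv(design$x, y_null, shuffled, plan, arch, config$train,
             seed = unname(seeds["cv"]))
    })
    names(null_results) <- config$architectures
    null_block <- list(results = null_results,
                       summaries = lapply(null_results, summarize_cv))
  }

  mean_err <- vapply(summaries,
                     function(s) s$mean[s$metric == "error"], numeric(1))
  best_arch <- names(which.min(mean_err))

  behavior_block <- NULL
  final_model <- NULL
  if (config$behavior) {
    message("stage behave: fitting final ", best_arch)
    final_model <- fit_risk_model(design$x, design$y,
                                  cohort$persons$matched_case_id,
                                  best_arch, config$train,
                                  seed = unname(seeds["final"]))
    scores <- nn_predict(final_model, design$x)
    behavior_block <- list(
      score_histogram = score_histogram(scores, design$y),
      toggle_summary = toggle_all_factors(final_model, design$x),
      risk_profile = profile_factors(design$x, scores, design$y),
      bin_summary = summarize_bins(scores, cohort$persons$sex,
                                   cohort$persons$age_at_cld, design$y)
    )
  }

  report <- structure(list(
    config = list(n_cases = ccfg$n_cases,
                  controls_per_case = ccfg$controls_per_case,
                  architectures = config$architectures,
                  n_repeats = config$n_repeats, n_folds = config$n_folds,
                  test_train_ratio = config$test_train_ratio,
                  master_seed = config$master_seed),
    cohort = cohort, design = design, plan = plan,
    cv = list(results = results, summaries = summaries,
              comparisons = comparisons),
    null = null_block,
    best_arch = best_arch,
    model = final_model,
    behavior = behavior_block
  ), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("cldrisk pipeline report\n")
  cat(sprintf("  cohort: %d cases x %d (1 case + %d controls)\n",
              x$config$n_cases, x$config$controls_per_case + 1L,
              x$config$controls_per_case))
  for (arch in names(x$cv$summaries)) {
    s <- x$cv$summaries[[arch]]
    cat(sprintf(
      "  %-10s error %5.2f%% (SD %4.2f)  sens %5.2f%%  spec %5.2f%%  AUC %.3f\n",
      arch, s$mean[s$metric == "error"], s$sd[s$metric == "error"],
      s$mean[s$metric == "sensitivity"], s$mean[s$metric == "specificity"],
      s$mean[s$metric == "auc"]))
  }
  if (!is.null(x$null)) {
    for (arch in names(x$null$summaries)) {
      s <- x$null$summaries[[arch]]
      cat(sprintf("  shuffle-null %-10s error %5.2f%%  AUC %.3f\n", arch,
                  s$mean[s$metric == "error"], s$mean[s$metric == "auc"]))
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (configuration, per-architecture summaries,
#' comparisons, behaviour summaries), `cv_results.csv`, and the cohort
#' tables into `dir`.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the report path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(report$cohort, dir)
  cv_rows <- do.call(rbind, lapply(names(report$cv$results), function(a) {
    cbind(arch = a, as.data.frame(report$cv$results[[a]]))
  }))
  utils::write.csv(cv_rows, file.path(dir, "cv_results.csv"),
                   row.names = FALSE)
  payload <- list(
    config = report$config,
    summaries = report$cv$summaries,
    comparisons = report$cv$comparisons,
    null_summaries = if (!is.null(report$null)) report$null$summaries,
    best_arch = report$best_arch,
    behavior = if (!is.null(report$behavior)) list(
      toggle_summary = report$behavior$toggle_summary,
      bin_summary = report$behavior$bin_summary)
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Validate person, event and code-map files
#'
#' Schema and consistency checks on delimited inputs: required columns,
#' parseable ISO-8601 dates (violations listed with line numbers), valid
#' labels and sources, every control matched to an existing case of the same
#' sex born within one year, index dates present, and no events referencing
#' unknown persons.
#'
#' @param persons_path,events_path Paths to the delimited tables.
#' @param codemap_path Optional code map path.
#' @return List of class `validation_report` with a `violations` data frame
#'   (`severity`, `message`, `line`) and logical `ok` (no hard violations).
#' @export
validate_inputs <- function(persons_path, events_path,
                            codemap_path = NULL) {
  v <- list()
  add <- function(severity, message, line = NA_integer_) {
    v[[length(v) + 1L]] <<- data.frame(severity = severity,
                                       message = message, line = line)
  }
  persons <- utils::read.csv(persons_path, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)

  need_p <- c("person_id", "label", "sex", "birth_date", "cld_date",
              "matched_case_id")
  miss <- setdiff(need_p, names(persons))
  if (length(miss)) {
    add("hard", paste("persons file missing column(s):",
                      paste(miss, collapse = ", ")))
    out <- do.call(rbind, v)
    return(structure(list(violations = out, ok = FALSE),
                     class = "validation_report"))
  }
  need_e <- c("person_id", "source", "event_date", "category", "code",
              "in_cld_block")
  miss <- setdiff(need_e, names(events))
  if (length(miss)) {
    add("hard", paste("events file missing column(s):",
                      paste(miss, collapse = ", ")))
  }

  parse_dates <- function(x, what, offset_header = 1L) {
    d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
    bad <- which(is.na(d) & !is.na(x) & x != "")
    for (i in bad) {
      add("hard", sprintf("unparseable %s '%s'", what, x[i]),
          i + offset_header)
    }
    d
  }
  birth <- parse_dates(persons$birth_date, "birth_date")
  cld <- parse_dates(persons$cld_date, "cld_date")
  bad_label <- which(!persons$label %in% c("case", "control"))
  for (i in bad_label) {
    add("hard", sprintf("invalid label '%s'", persons$label[i]), i + 1L)
  }
  if (anyNA(cld)) add("hard", "missing index contact date(s)")

  is_ctrl <- persons$label == "control"
  case_ix <- match(persons$matched_case_id, persons$person_id)
  no_case <- is_ctrl & (is.na(case_ix) |
                          persons$label[case_ix] != "case")
  for (i in which(no_case)) {
    add("hard", sprintf("control %s lacks a matched case",
                        persons$person_id[i]), i + 1L)
  }
  ok_ctrl <- is_ctrl & !no_case
  if (any(ok_ctrl)) {
    sex_mismatch <- ok_ctrl & persons$sex != persons$sex[case_ix]
    for (i in which(sex_mismatch)) {
      add("hard", sprintf("control %s sex differs from matched case",
                          persons$person_id[i]), i + 1L)
    }
    db <- abs(as.numeric(birth - birth[case_ix]))
    far <- ok_ctrl & !is.na(db) & db > DAYS_PER_YEAR
    for (i in which(far)) {
      add("hard", sprintf("control %s born more than a year from case",
                          persons$person_id[i]), i + 1L)
    }
  }

  if ("event_date" %in% names(events)) {
    parse_dates(events$event_date, "event_date")
  }
  if ("person_id" %in% names(events)) {
    orphan <- which(!events$person_id %in% persons$person_id)
    if (length(orphan)) {
      add("soft", sprintf("%d event(s) reference unknown person ids",
                          length(orphan)), orphan[1] + 1L)
    }
  }
  if ("source" %in% names(events)) {
    bad_src <- which(!events$source %in% c("GP", "hospital"))
    for (i in utils::head(bad_src, 20)) {
      add("hard", sprintf("invalid source '%s'", events$source[i]), i + 1L)
    }
  }
  if (!is.null(codemap_path)) {
    tryCatch(load_code_map(codemap_path),
             error = function(e) add("hard", conditionMessage(e)))
  }

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(severity = character(), message = character(),
               line = integer())
  structure(list(violations = violations,
                 ok = !any(violations$severity == "hard")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x$violations) == 0) {
    cat("validation: clean\n")
  } else {
    cat("validation:", sum(x$violations$severity == "hard"), "hard,",
        sum(x$violations$severity == "soft"), "soft violation(s)\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}
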