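# Feature builder: code maps, time-frame windows, 62-dimensional encoding.

test_that("window_of places events in the documented frames", {
  cld <- as.Date("2010-06-01")
  expect_equal(window_of(cld - 0, cld), "1M")
  expect_equal(window_of(cld - 10, cld), "1M")
  expect_equal(window_of(cld - 31, cld), "6M")
  expect_equal(window_of(cld - 200, cld), "1Y")
  expect_equal(window_of(cld - 400, cld), "5Y")
  expect_equal(window_of(cld - 2200, cld), NA_character_)
  expect_equal(window_of(cld + 1, cld), NA_character_)

  # fractional-day boundaries resolve into the earlier-named frame
  expect_equal(window_of(0, 30.4375), "1M")       # exactly one month
  expect_equal(window_of(0, 6 * 30.4375), "6M")   # exactly six months
  expect_equal(window_of(0, 365.25), "1Y")        # exactly one year
  expect_equal(window_of(0, 5 * 365.25), "5Y")    # exactly five years
  expect_equal(window_of(0, 30.4375 + 1e-6), "6M")
})

test_that("frames partition the five-year look-back with no overlap", {
  d <- c(seq(0, 1830, by = 0.25), 30.4375, 182.625, 365.25, 1826.25)
  tags <- window_of(0, d)  # d days before an index date at day d
  in_range <- d <= 5 * 365.25
  expect_true(all(!is.na(tags[in_range])))
  expect_true(all(is.na(tags[!in_range])))
  # each frame claims a contiguous, disjoint span
  lo <- tapply(d[in_range], tags[in_range], min)
  hi <- tapply(d[in_range], tags[in_range], max)
  ord <- c("1M", "6M", "1Y", "5Y")
  expect_true(all(hi[ord][-4] < lo[ord][-1]))
})

test_that("code maps validate, reject conflicts and round-trip lookups", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.csv")
  write.csv(data.frame(coding_system = c("ICD10", "Read"),
                       code = c("X60", "E2B.."),
                       category = c("self_harm", "depression_anxiety")),
            path, row.names = FALSE)
  map <- load_code_map(path)
  expect_equal(code_map_lookup(map, "ICD10", "X60"), "self_harm")
  expect_equal(code_map_lookup(map, "Read", "E2B.."), "depression_anxiety")
  expect_true(is.na(code_map_lookup(map, "ICD10", "Z99")))

  expect_error(as_code_map(data.frame(coding_system = "ICD10", code = "X60",
                                      category = "not_a_category")),
               "valid categories")
  expect_error(as_code_map(data.frame(coding_system = c("ICD10", "ICD10"),
                                      code = c("X60", "X60"),
                                      category = c("self_harm", "others"))),
               "conflicting")
  # duplicate consistent rows collapse silently
  ok <- as_code_map(data.frame(coding_system = c("ICD10", "ICD10"),
                               code = c("X60", "X60"),
                               category = c("self_harm", "self_harm")))
  expect_equal(nrow(ok), 1)
})

test_that("feature vectors have the documented shape and semantics", {
  person <- data.frame(person_id = "p1", label = "case", sex = "male",
                       age_at_cld = 48.2, cld_date = as.Date("2010-06-01"))
  no_events <- data.frame(person_id = character(), source = character(),
                          event_date = as.Date(character()),
                          category = character(), code = character(),
                          in_cld_block = logical())
  x <- build_feature_vector(person, no_events)
  expect_length(x, 62)
  expect_equal(length(risk_factors()), 15)
  expect_equal(names(x), feature_names())
  expect_equal(unname(x[1]), 48.2)
  expect_equal(unname(x[2]), 1)  # male = 1
  expect_true(all(x[-(1:2)] == 0))

  ev <- data.frame(person_id = "p1", source = "GP",
                   event_date = as.Date("2010-05-20"),
                   category = "self_harm", code = "SYN", in_cld_block = FALSE)
  x <- build_feature_vector(person, ev)
  expect_equal(unname(x["self_harm_1M"]), 1)
  expect_equal(unname(x["gp_contact_1M"]), 1)  # any GP event fires it
  expect_equal(sum(x[-(1:2)]), 2)

  # the same event inside the terminal contact block never contributes
  ev$in_cld_block <- TRUE
  x <- build_feature_vector(person, ev)
  expect_true(all(x[-(1:2)] == 0))

  # hospital source fires the admission factor regardless of category
  ev2 <- data.frame(person_id = "p1", source = "hospital",
                    event_date = as.Date("2009-01-10"),
                    category = "depression_anxiety", code = "SYN",
                    in_cld_block = FALSE)
  x <- build_feature_vector(person, ev2)
  expect_equal(unname(x["hospital_admission_5Y"]), 1)
  expect_equal(unname(x["depression_anxiety_5Y"]), 1)
  expect_equal(unname(x["gp_contact_5Y"]), 0)
})

test_that("duplicate events are idempotent and additions are monotone", {
  coh <- small_cohort(n_cases = 4, seed = 8)
  d1 <- build_design_matrix(coh$persons, coh$events)
  d2 <- build_design_matrix(coh$persons, rbind(coh$events, coh$events))
  expect_identical(d1$x, d2$x)

  extra <- data.frame(person_id = coh$persons$person_id[1], source = "GP",
                      event_date = coh$persons$cld_date[1] - 3,
                      category = "drugs_misuse", code = "SYN",
                      in_cld_block = FALSE)
  d3 <- build_design_matrix(coh$persons, rbind(coh$events, extra))
  expect_true(all(d3$x[, -(1:2)] >= d1$x[, -(1:2)]))
})

test_that("design matrix matches an independent per-person recount", {
  coh <- small_cohort(n_cases = 6, seed = 21)
  d <- build_design_matrix(coh$persons, coh$events)
  expect_equal(dim(d$x), c(126, 62))
  expect_equal(sum(d$y), 6)

  # brute-force oracle: scan each person's events one by one
  for (col in c("psychotropics_rx_1M", "self_harm_5Y", "gp_contact_6M",
                "hospital_admission_1Y")) {
    parts <- strsplit(col, "_(?=[^_]+$)", perl = TRUE)[[1]]
    fct <- parts[1]; frm <- parts[2]
    oracle <- vapply(seq_len(nrow(coh$persons)), function(i) {
      p <- coh$persons[i, ]
      hit <- 0
      for (j in seq_len(nrow(coh$events))) {
        e <- coh$events[j, ]
        if (e$person_id != p$person_id || e$in_cld_block) next
        dd <- as.numeric(p$cld_date - e$event_date)
        w <- if (dd < 0) NA_character_
             else if (dd <= 30.4375) "1M"
             else if (dd <= 6 * 30.4375) "6M"
             else if (dd <= 365.25) "1Y"
             else if (dd <= 5 * 365.25) "5Y"
             else NA_character_
        if (is.na(w) || w != frm) next
        fires <- if (fct == "gp_contact") e$source == "GP"
                 else if (fct == "hospital_admission") e$source == "hospital"
                 else e$category == fct
        if (fires) hit <- 1
      }
      hit
    }, numeric(1))
    expect_equal(unname(d$x[, col]), oracle, label = col)
  }
})

test_that("row order is equivariant and orphans warn", {
  coh <- small_cohort(n_cases = 4, seed = 13)
  d1 <- build_design_matrix(coh$persons, coh$events)
  perm <- rev(seq_len(nrow(coh$persons)))
  d2 <- build_design_matrix(coh$persons[perm, ], coh$events)
  expect_identical(d1$x[perm, ], d2$x)
  expect_identical(d1$y[perm], d2$y)

  orphan <- data.frame(person_id = "ghost", source = "GP",
                       event_date = as.Date("2010-01-01"),
                       category = "others", code = "X", in_cld_block = FALSE)
  expect_warning(build_design_matrix(coh$persons,
                                     rbind(coh$events, orphan)),
                 "1 event")
})
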