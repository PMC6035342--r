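# Behaviour of a trained risk model: score distributions by class,
# single-factor toggle deltas, factor distribution and incidence across risk
# levels, and per-bin demographics.

#' Histogram of risk scores by class
#'
#' Counts scores per class in fixed-width bins covering (0, 1].
#'
#' @param scores Numeric scores in (0, 1).
#' @param labels 0/1 or `"case"`/`"control"`.
#' @param bin_width Bin width; must divide 1 evenly (default 0.05).
#' @return Data frame with `bin_lo`, `bin_hi`, `n_case`, `n_control`.
#' @export
score_histogram <- function(scores, labels, bin_width = 0.05) {
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-9) {
    stop("bin_width must divide 1 evenly", call. = FALSE)
  }
  is_case <- as_case_indicator(labels)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scores, breaks, include.lowest = TRUE, right = TRUE)
  data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    n_case = as.vector(table(bin[is_case])),
    n_control = as.vector(table(bin[!is_case]))
  )
}

#' Risk-score change from toggling one factor bit
#'
#' For every sample, the (factor, time frame) input bit is forced to 1 and
#' to 0 with all other inputs untouched, and the difference in output score
#' `delta = r_on - r_off` is recorded. Age and sex are not binary factors
#' and cannot be toggled.
#'
#' @param net Trained `cldrisk_net`.
#' @param x Raw design matrix (as given to [fit_risk_model()]).
#' @param factor One of [risk_factors()].
#' @param frame One of [time_frames()].
#' @return Object of class `delta_risk`: list with `factor`, `frame` and the
#'   per-sample `delta` vector.
#' @export
toggle_factor <- function(net, x, factor, frame) {
  if (factor %in% c("age", "sex") || !factor %in% risk_factors()) {
    stop("only the 15 binary factors can be toggled, not '", factor, "'",
         call. = FALSE)
  }
  stopifnot(frame %in% TIME_FRAMES)
  col <- paste(factor, frame, sep = "_")
  if (!col %in% colnames(x)) {
    stop("column ", col, " not found in the design matrix", call. = FALSE)
  }
  x_on <- x
  x_on[, col] <- 1
  x_off <- x
  x_off[, col] <- 0
  delta <- nn_predict(net, x_on) - nn_predict(net, x_off)
  structure(list(factor = factor, frame = frame, delta = delta),
            class = "delta_risk")
}

#' @export
print.delta_risk <- function(x, ...) {
  cat(sprintf("Toggle %s [%s]: mean delta = %+.4f (sd %.4f, n = %d)\n",
              x$factor, x$frame, mean(x$delta), stats::sd(x$delta),
              length(x$delta)))
  invisible(x)
}

#' Toggle every factor bit and summarize
#'
#' Runs [toggle_factor()] for all 60 (factor, frame) bits.
#'
#' @inheritParams toggle_factor
#' @param combined If `TRUE`, additionally toggle each factor across all
#'   four frames simultaneously (15 extra rows with `frame = "all"`).
#' @return Data frame with `factor`, `frame`, `mean_delta`, `sd_delta`, `n`.
#' @export
toggle_all_factors <- function(net, x, combined = FALSE) {
  grid <- expand.grid(factor = risk_factors(), frame = TIME_FRAMES,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- toggle_factor(net, x, grid$factor[i], grid$frame[i])
    data.frame(factor = d$factor, frame = d$frame,
               mean_delta = mean(d$delta), sd_delta = stats::sd(d$delta),
               n = length(d$delta))
  })
  out <- do.call(rbind, rows)
  if (combined) {
    comb <- lapply(risk_factors(), function(f) {
      cols <- paste(f, TIME_FRAMES, sep = "_")
      x_on <- x; x_on[, cols] <- 1
      x_off <- x; x_off[, cols] <- 0
      d <- nn_predict(net, x_on) - nn_predict(net, x_off)
      data.frame(factor = f, frame = "all", mean_delta = mean(d),
                 sd_delta = stats::sd(d), n = length(d))
    })
    out <- rbind(out, do.call(rbind, comb))
  }
  rownames(out) <- NULL
  out
}

#' Factor distribution and incidence across risk levels
#'
#' For every (factor, frame) bit: how many individuals present it, what
#' share of them the model classifies as cases (`r > 0.5`), how they
#' distribute over the six risk levels, and the factor's incidence within
#' each level and within actual cases and controls.
#'
#' @param x Raw design matrix.
#' @param scores Model scores aligned with the rows of `x`.
#' @param labels 0/1 or `"case"`/`"control"`.
#' @return Data frame, one row per (factor, frame), with columns
#'   `n_presenting`, `pct_classified_case`, `n_VLR` ... `n_VHR`,
#'   `inc_VLR` ... `inc_VHR`, `inc_case`, `inc_control`.
#' @export
profile_factors <- function(x, scores, labels) {
  stopifnot(nrow(x) == length(scores))
  is_case <- as_case_indicator(labels)
  lev <- risk_level(scores)
  bin_sizes <- table(lev)
  grid <- expand.grid(factor = risk_factors(), frame = TIME_FRAMES,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    col <- paste(grid$factor[i], grid$frame[i], sep = "_")
    present <- x[, col] == 1
    n <- sum(present)
    counts <- table(lev[present])
    inc_bin <- ifelse(bin_sizes > 0, counts / bin_sizes, 0)
    out <- data.frame(factor = grid$factor[i], frame = grid$frame[i],
                      n_presenting = n,
                      pct_classified_case =
                        if (n > 0) 100 * mean(scores[present] > 0.5) else 0)
    for (l in RISK_LEVELS) out[[paste0("n_", l)]] <- as.integer(counts[[l]])
    for (l in RISK_LEVELS) out[[paste0("inc_", l)]] <- as.numeric(inc_bin[[l]])
    out$inc_case <- if (any(is_case)) mean(present[is_case]) else 0
    out$inc_control <- if (any(!is_case)) mean(present[!is_case]) else 0
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Demographics per risk level
#'
#' One row per risk level plus one each for actual controls and cases:
#' number of individuals, number and percentage of males with a 95%
#' normal-approximation binomial confidence interval, and mean age. Empty
#' levels keep their row with a zero count and blank statistics.
#'
#' @param scores Model scores.
#' @param sex `"male"`/`"female"` per person (or 1/0).
#' @param age Age in years per person.
#' @param labels 0/1 or `"case"`/`"control"`.
#' @return Data frame with columns `group`, `n`, `n_male`, `male_pct`,
#'   `male_ci_lo`, `male_ci_hi`, `mean_age`.
#' @export
summarize_bins <- function(scores, sex, age, labels) {
  stopifnot(length(scores) == length(sex), length(sex) == length(age))
  is_male <- if (is.character(sex) || is.factor(sex)) {
    as.character(sex) == "male"
  } else sex == 1
  is_case <- as_case_indicator(labels)
  lev <- risk_level(scores)
  one_row <- function(name, members) {
    n <- sum(members)
    if (n == 0) {
      return(data.frame(group = name, n = 0L, n_male = NA_integer_,
                        male_pct = NA_real_, male_ci_lo = NA_real_,
                        male_ci_hi = NA_real_, mean_age = NA_real_))
    }
    nm <- sum(is_male[members])
    p <- nm / n
    half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
    data.frame(group = name, n = n, n_male = nm, male_pct = 100 * p,
               male_ci_lo = 100 * max(0, p - half),
               male_ci_hi = 100 * min(1, p + half),
               mean_age = mean(age[members]))
  }
  rows <- c(list(one_row("controls", !is_case), one_row("cases", is_case)),
            lapply(RISK_LEVELS, function(l) one_row(l, lev == l)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
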