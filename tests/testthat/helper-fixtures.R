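# Shared fixtures: small cohorts and a fast training configuration used
# throughout the suite.

fast_cfg <- function(...) {
  training_config(max_epochs_per_stage = 30L, ...)
}

small_cohort <- function(n_cases = 10, seed = 1, ...) {
  generate_cohort(cohort_config(n_cases = n_cases, seed = seed, ...))
}

# Finite-difference gradient of nn_cost over every parameter (or a subset
# of weight coordinates), the independent oracle for backpropagation.
numeric_gradient <- function(net, x, y, weights, l2_scale, h = 1e-4,
                             max_coords = Inf) {
  gW <- lapply(net$W, function(w) array(NA_real_, dim = dim(w)))
  gb <- lapply(net$b, function(b) rep(NA_real_, length(b)))
  for (l in seq_along(net$W)) {
    coords <- seq_along(net$W[[l]])
    if (length(coords) > max_coords) {
      coords <- sort(sample(coords, max_coords))
    }
    for (i in coords) {
      up <- net; up$W[[l]][i] <- up$W[[l]][i] + h
      dn <- net; dn$W[[l]][i] <- dn$W[[l]][i] - h
      gW[[l]][i] <- (nn_cost(up, x, y, weights, l2_scale) -
                       nn_cost(dn, x, y, weights, l2_scale)) / (2 * h)
    }
    for (i in seq_along(net$b[[l]])) {
      up <- net; up$b[[l]][i] <- up$b[[l]][i] + h
      dn <- net; dn$b[[l]][i] <- dn$b[[l]][i] - h
      gb[[l]][i] <- (nn_cost(up, x, y, weights, l2_scale) -
                       nn_cost(dn, x, y, weights, l2_scale)) / (2 * h)
    }
  }
  list(W = gW, b = gb)
}

# Relative disagreement between analytic and numeric gradients, ignoring
# coordinates the numeric oracle skipped.
gradient_rel_error <- function(analytic, numeric) {
  rel <- function(a, n) {
    ok <- !is.na(n)
    if (!any(ok)) return(0)
    max(abs(a[ok] - n[ok]) / pmax(abs(a[ok]) + abs(n[ok]), 1e-3))
  }
  max(
    max(mapply(function(a, n) rel(a, n), analytic$W, numeric$W)),
    max(mapply(function(a, n) rel(a, n), analytic$b, numeric$b))
  )
}

# Brute-force AUC: probability a random case outscores a random control,
# ties counting one half.
pairwise_auc <- function(scores, labels) {
  case_s <- scores[labels == 1]
  ctrl_s <- scores[labels == 0]
  total <- 0
  for (cs in case_s) {
    total <- total + sum(cs > ctrl_s) + 0.5 * sum(cs == ctrl_s)
  }
  total / (length(case_s) * length(ctrl_s))
}

# Direct step-up Benjamini-Hochberg computation.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
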