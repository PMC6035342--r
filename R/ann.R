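# Shallow feed-forward networks built from first principles: tanh hidden
# layers, sigmoid output, imbalance-weighted squared-error cost with l2
# weight regularization, analytic backpropagation, and staged-batch gradient
# descent with exponential learning-rate decay and validation-based early
# stopping.

ARCHITECTURES <- list(
  nn0 = integer(0), nn10 = 10L, nn50 = 50L, nn100 = 100L,
  `nn10-10` = c(10L, 10L), `nn50-50` = c(50L, 50L),
  `nn100-100` = c(100L, 100L)
)

#' Network architecture by tag
#'
#' Seven configurations are supported: `nn0` (no hidden layer; the model is
#' then exactly logistic regression), one hidden layer of size 10, 50 or 100
#' (`nn10`, `nn50`, `nn100`), and two equal hidden layers (`nn10-10`,
#' `nn50-50`, `nn100-100`).
#'
#' @param tag One of the seven architecture tags.
#' @return List with `tag` and integer vector `hidden_sizes`.
#' @export
nn_architecture <- function(tag) {
  if (!tag %in% names(ARCHITECTURES)) {
    stop("unknown architecture '", tag, "'; valid: ",
         paste(names(ARCHITECTURES), collapse = ", "), call. = FALSE)
  }
  list(tag = tag, hidden_sizes = ARCHITECTURES[[tag]])
}

#' Initialize a network
#'
#' Weights are drawn uniformly in `+/- sqrt(6 / (fan_in + fan_out))` (a
#' fan-balanced scheme that keeps tanh units out of saturation at the start);
#' biases start at zero.
#'
#' @param arch Architecture tag or the result of [nn_architecture()].
#' @param seed Optional integer seed; same seed gives identical weights.
#' @param input_dim Input width (default 62).
#' @return Object of class `cldrisk_net` with per-layer weight matrices `W`
#'   (rows = units, columns = inputs) and bias vectors `b`.
#' @export
init_network <- function(arch, seed = NULL, input_dim = 62L) {
  if (is.character(arch)) arch <- nn_architecture(arch)
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(input_dim, arch$hidden_sizes, 1L)
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                     nrow = fan_out, ncol = fan_in)
    b[[l]] <- rep(0, fan_out)
  }
  structure(list(tag = arch$tag, sizes = sizes, W = W, b = b,
                 age_center = NULL, age_scale = NULL),
            class = "cldrisk_net")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass keeping per-layer activations (A[[1]] is the input).
nn_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("non-finite values in network input",
                               call. = FALSE)
  n_layers <- length(net$W)
  A <- vector("list", n_layers + 1L)
  A[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- A[[l]] %*% t(net$W[[l]])
    z <- sweep(z, 2, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < n_layers) tanh(z) else sigmoid(z)
  }
  A
}

#' Score samples with a network
#'
#' Runs the forward pass and returns the output score `r` in (0, 1),
#' interpreted as the estimated risk of being a case. If the network stores
#' age-standardization constants (set during training), the first column of
#' `x` is standardized before the pass; presence bits and sex are fed raw.
#'
#' @param net A `cldrisk_net`.
#' @param x Numeric matrix (samples x inputs) or a single feature vector.
#' @param standardize Apply stored age standardization (default `TRUE`).
#' @return Numeric vector of scores, one per row of `x`.
#' @export
nn_predict <- function(net, x, standardize = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (standardize && !is.null(net$age_center)) {
    x[, 1] <- (x[, 1] - net$age_center) / net$age_scale
  }
  A <- nn_forward(net, x)
  as.vector(A[[length(A)]])
}

#' Per-sample misclassification weights
#'
#' Cases carry weight 1 and controls `1/controls_per_case` (1/20 by
#' default), so in a complete 1:20 cohort both classes contribute the same
#' total weight to the cost.
#'
#' @param y 0/1 labels (1 = case).
#' @param case_weight,control_weight Class weights.
#' @return Numeric weight vector.
#' @export
cost_weights <- function(y, case_weight = 1, control_weight = 1 / 20) {
  ifelse(y == 1, case_weight, control_weight)
}

#' Network cost: weighted mean squared error plus l2 penalty
#'
#' `cost = sum(v_i (r_i - t_i)^2) / sum(v_i) + l2_scale * sum(W^2)`, where
#' `v_i` are the class weights from [cost_weights()] and the penalty runs
#' over connection weights only (biases are not penalized).
#'
#' @param net A `cldrisk_net`.
#' @param x Input matrix.
#' @param y 0/1 targets.
#' @param weights Per-sample weights; defaults to [cost_weights()].
#' @param l2_scale Regularization scale (default 0.01).
#' @return Scalar cost.
#' @export
nn_cost <- function(net, x, y, weights = cost_weights(y), l2_scale = 0.01) {
  r <- nn_predict(net, x, standardize = FALSE)
  data_term <- sum(weights * (r - y)^2) / sum(weights)
  penalty <- l2_scale * sum(vapply(net$W, function(w) sum(w^2), numeric(1)))
  data_term + penalty
}

#' Analytic cost gradient via backpropagation
#'
#' Exact gradients of [nn_cost()] with respect to every weight matrix and
#' bias vector. The l2 term contributes `2 * l2_scale * W` to each weight
#' gradient and nothing to bias gradients.
#'
#' @inheritParams nn_cost
#' @return List with `W` and `b`, mirroring the network's shapes.
#' @export
nn_gradient <- function(net, x, y, weights = cost_weights(y),
                        l2_scale = 0.01) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_layers <- length(net$W)
  A <- nn_forward(net, x)
  r <- as.vector(A[[n_layers + 1L]])
  V <- sum(weights)
  # d(data)/dr, then through the sigmoid: dr/dz = r (1 - r)
  delta <- matrix(2 * weights * (r - y) / V * r * (1 - r), ncol = 1)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- t(delta) %*% A[[l]] + 2 * l2_scale * net$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      # tanh'(z) = 1 - tanh(z)^2, and A[[l]] holds tanh(z)
      delta <- (delta %*% net$W[[l]]) * (1 - A[[l]]^2)
    }
  }
  list(W = gW, b = gb)
}

#' Training configuration
#'
#' Training proceeds in three sequential stages of growing batch size,
#' expressed in cases per batch; each case is always accompanied by its
#' matched controls, so with 20 controls per case the default stages use
#' total batches of 525, 2100 and the full training set. The learning rate
#' restarts at `initial_learning_rate` with every stage and decays
#' exponentially per epoch. A stage ends when `max_epochs_per_stage` is
#' reached, when the relative change of the validation cost falls below
#' `val_change_threshold`, or when the validation cost moves in the wrong
#' direction (parameters then revert to the best epoch).
#'
#' @param stage_batch_cases Cases per batch for each stage; `Inf` means all.
#' @param initial_learning_rate Starting learning rate (default 1).
#' @param decay_rate Per-epoch exponential decay factor (default 0.95).
#' @param max_epochs_per_stage Epoch cap per stage (default 200).
#' @param val_change_threshold Relative validation-cost change below which a
#'   stage stops (default 1e-4).
#' @param l2_scale l2 regularization scale (default 0.01).
#' @param case_weight,control_weight Class weights for the cost (1 and 1/20).
#' @param seed Optional seed for batch shuffling.
#' @return Object of class `training_config`.
#' @export
training_config <- function(stage_batch_cases = c(25, 100, Inf),
                            initial_learning_rate = 1,
                            decay_rate = 0.95,
                            max_epochs_per_stage = 200L,
                            val_change_threshold = 1e-4,
                            l2_scale = 0.01,
                            case_weight = 1,
                            control_weight = 1 / 20,
                            seed = NULL) {
  stopifnot(l2_scale >= 0, case_weight > 0, control_weight > 0,
            initial_learning_rate > 0, decay_rate > 0, decay_rate <= 1,
            max_epochs_per_stage >= 0, val_change_threshold >= 0,
            all(diff(stage_batch_cases) >= 0))
  structure(list(stage_batch_cases = stage_batch_cases,
                 initial_learning_rate = initial_learning_rate,
                 decay_rate = decay_rate,
                 max_epochs_per_stage = as.integer(max_epochs_per_stage),
                 val_change_threshold = val_change_threshold,
                 l2_scale = l2_scale,
                 case_weight = case_weight,
                 control_weight = control_weight,
                 seed = seed),
            class = "training_config")
}

get_params <- function(net) list(W = net$W, b = net$b)
set_params <- function(net, p) { net$W <- p$W; net$b <- p$b; net }

# Validation cost is the data term only: early stopping tracks fit, not the
# penalty.
val_cost <- function(net, x, y, cfg) {
  v <- cost_weights(y, cfg$case_weight, cfg$control_weight)
  r <- nn_predict(net, x, standardize = FALSE)
  sum(v * (r - y)^2) / sum(v)
}

#' Train a network with staged-batch gradient descent
#'
#' Batches are composed of whole case groups -- a case and its matched
#' controls are never split across batches, mirroring the pair-preserving
#' partitioning used everywhere else. Inputs are used as given; standardize
#' age beforehand (see [fit_risk_model()] which handles this).
#'
#' @param net A `cldrisk_net` (typically fresh from [init_network()]).
#' @param x_train,y_train Training inputs and 0/1 targets.
#' @param groups_train Case-group id per training row (e.g.
#'   `matched_case_id`); rows sharing an id travel together.
#' @param x_val,y_val Validation fold driving early stopping.
#' @param cfg A [training_config()].
#' @return List with the trained `net` and a `history` data frame
#'   (stage, epoch, learning rate, training cost, validation cost).
#' @export
nn_train <- function(net, x_train, y_train, groups_train, x_val, y_val,
                     cfg = training_config()) {
  stopifnot(inherits(cfg, "training_config"))
  if (length(y_val) == 0) {
    stop("empty validation set: early stopping needs one", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  group_ids <- unique(groups_train)
  row_by_group <- split(seq_along(groups_train), groups_train)
  v_all <- cost_weights(y_train, cfg$case_weight, cfg$control_weight)
  history <- list()

  for (stage in seq_along(cfg$stage_batch_cases)) {
    per_batch <- cfg$stage_batch_cases[stage]
    n_batches <- if (is.finite(per_batch)) {
      max(1L, ceiling(length(group_ids) / per_batch))
    } else 1L
    best <- get_params(net)
    best_val <- val_cost(net, x_val, y_val, cfg)
    prev_val <- best_val
    epoch <- 0L
    while (epoch < cfg$max_epochs_per_stage) {
      lr <- cfg$initial_learning_rate * cfg$decay_rate^epoch
      shuffled <- sample(group_ids)
      split_ix <- rep(seq_len(n_batches),
                      each = ceiling(length(shuffled) / n_batches),
                      length.out = length(shuffled))
      for (bi in seq_len(n_batches)) {
        rows <- unlist(row_by_group[shuffled[split_ix == bi]],
                       use.names = FALSE)
        g <- nn_gradient(net, x_train[rows, , drop = FALSE], y_train[rows],
                         v_all[rows], cfg$l2_scale)
        for (l in seq_along(net$W)) {
          net$W[[l]] <- net$W[[l]] - lr * g$W[[l]]
          net$b[[l]] <- net$b[[l]] - lr * g$b[[l]]
        }
      }
      epoch <- epoch + 1L
      vc <- val_cost(net, x_val, y_val, cfg)
      tc <- nn_cost(net, x_train, y_train, v_all, cfg$l2_scale)
      history[[length(history) + 1L]] <-
        data.frame(stage = stage, epoch = epoch, lr = lr,
                   train_cost = tc, val_cost = vc)
      if (!is.finite(vc) || !is.finite(tc)) {
        stop("training diverged: non-finite cost", call. = FALSE)
      }
      if (vc < best_val) best <- get_params(net)
      if (vc > prev_val) {            # not improving: stop, keep best
        net <- set_params(net, best)
        break
      }
      if (abs(prev_val - vc) / max(abs(prev_val), 1e-12) <
          cfg$val_change_threshold) break
      prev_val <- vc
      best_val <- min(best_val, vc)
    }
    net <- set_params(net, best)
  }
  list(net = net,
       history = if (length(history)) do.call(rbind, history)
                 else data.frame(stage = integer(), epoch = integer(),
                                 lr = numeric(), train_cost = numeric(),
                                 val_cost = numeric()))
}

#' Fit a risk model on a cohort's feature matrix
#'
#' Convenience wrapper: standardizes age with training statistics (stored in
#' the network and re-applied by [nn_predict()]), holds out a
#' group-preserving validation slice for early stopping, and trains.
#'
#' @param x Raw design matrix from [build_design_matrix()].
#' @param y 0/1 labels.
#' @param groups Case-group id per row.
#' @param arch Architecture tag (default `"nn0"`).
#' @param cfg A [training_config()].
#' @param val_fraction Fraction of case groups held out for validation.
#' @param seed Seed for initialization, the validation split and batching.
#' @return Trained `cldrisk_net` (with `history` attribute).
#' @export
fit_risk_model <- function(x, y, groups, arch = "nn0",
                           cfg = training_config(), val_fraction = 0.1,
                           seed = 1L) {
  set.seed(seed)
  ids <- unique(groups)
  n_val <- max(1L, round(val_fraction * length(ids)))
  val_ids <- sample(ids, n_val)
  is_val <- groups %in% val_ids
  net <- init_network(arch, input_dim = ncol(x))
  mu <- mean(x[!is_val, 1])
  sd_ <- stats::sd(x[!is_val, 1])
  if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
  xs <- x
  xs[, 1] <- (xs[, 1] - mu) / sd_
  cfg$seed <- NULL  # RNG already seeded; keep one stream
  fit <- nn_train(net, xs[!is_val, , drop = FALSE], y[!is_val],
                  groups[!is_val], xs[is_val, , drop = FALSE], y[is_val],
                  cfg)
  net <- fit$net
  net$age_center <- mu
  net$age_scale <- sd_
  attr(net, "history") <- fit$history
  net
}

#' Classify a risk score
#'
#' The decision threshold is 0.5: scores strictly above it are classified as
#' cases, everything else as controls.
#'
#' @param r Numeric score vector in (0, 1).
#' @return Character vector, `"case"` or `"control"`.
#' @export
classify <- function(r) ifelse(r > 0.5, "case", "control")

#' Risk level of a score
#'
#' Six right-closed bins of the estimated risk score: very low (`VLR`,
#' `r <= 0.17`), low (`LR`, `0.17 < r <= 0.33`), moderate-low (`MLR`,
#' `<= 0.5`), moderate-high (`MHR`, `<= 0.67`), high (`HR`, `<= 0.83`) and
#' very high (`VHR`, `r > 0.83`).
#'
#' @param r Numeric score vector in (0, 1).
#' @return Factor with levels `VLR`, `LR`, `MLR`, `MHR`, `HR`, `VHR`.
#' @export
risk_level <- function(r) {
  cut(r, breaks = RISK_BREAKS, labels = RISK_LEVELS, right = TRUE,
      include.lowest = TRUE)
}

#' Save a trained network as JSON
#'
#' @param net A `cldrisk_net`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(net, path) {
  payload <- list(
    tag = net$tag, sizes = net$sizes,
    W = lapply(net$W, function(w) list(dim = dim(w), values = as.vector(w))),
    b = net$b, age_center = net$age_center, age_scale = net$age_scale
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network saved by [save_model()]
#'
#' @param path JSON path.
#' @return A `cldrisk_net`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(seq_along(p$W$dim), function(l) {
    matrix(p$W$values[[l]], nrow = p$W$dim[[l]][1], ncol = p$W$dim[[l]][2])
  })
  b <- if (is.list(p$b)) p$b else list(p$b)
  structure(list(tag = p$tag, sizes = p$sizes, W = W,
                 b = lapply(b, as.numeric),
                 age_center = p$age_center, age_scale = p$age_scale),
            class = "cldrisk_net")
}
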