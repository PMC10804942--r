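# Gradient-boosted tree models over sensor profiles: multiclass ecosystem
# and condition classifiers, and regressors for physical parameters.
# The boosting backend is xgboost, driven single-threaded with a fixed
# seed so fits are reproducible.

#' Train/test/validation split of a sensor profile
#'
#' Disjoint, exhaustive split of the rows, 70/20/10 by default. With
#' `stratified = TRUE` each label class is split at those proportions
#' (largest-remainder rounding, so per-class counts are within one sample
#' of exact proportionality); every class must then have at least 3
#' samples. Deterministic given `seed`.
#'
#' @param m A `sensor_profile`, or a character vector of labels named by
#'   row id.
#' @param label_field Metadata column used for stratification when `m` is
#'   a profile.
#' @param fractions Named fractions `c(train, test, validation)`, summing
#'   to 1, all positive.
#' @param stratified Stratify by label class?
#' @param seed Integer seed.
#' @return A list with character-vector elements `train`, `test`,
#'   `validation` of metagenome ids.
#' @export
split_profile <- function(m, label_field = "ecosystem",
                          fractions = c(train = 0.7, test = 0.2,
                                        validation = 0.1),
                          stratified = TRUE, seed = 1) {
  if (inherits(m, "sensor_profile")) {
    assert_columns(m$meta, label_field, "profile metadata")
    labels <- setNames(as.character(m$meta[[label_field]]),
                       m$meta$metagenome_id)
  } else {
    labels <- m
    if (is.null(names(labels))) abort("labels must be named by row id")
  }
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three positive values summing to 1")
  }
  names(fractions) <- c("train", "test", "validation")

  alloc <- function(ids) {
    n <- length(ids)
    base <- floor(n * fractions)
    rem <- n - sum(base)
    if (rem > 0) {
      frac_part <- n * fractions - base
      extra <- stable_order(-frac_part, seq_along(fractions))[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    shuffled <- sample(ids)
    grp <- factor(rep(names(fractions), times = base),
                  levels = names(fractions))
    split(shuffled, grp)
  }

  set.seed(as.integer(seed))
  if (stratified) {
    sizes <- table(labels)
    small <- names(sizes)[sizes < 3]
    if (length(small) > 0) {
      abort(sprintf(
        "class(es) too small to stratify (need >= 3 samples): %s",
        paste(small, collapse = ", ")
      ))
    }
    parts <- list(train = character(0), test = character(0),
                  validation = character(0))
    for (cl in sort(unique(labels))) {
      ids <- names(labels)[labels == cl]
      a <- alloc(ids)
      for (p in names(parts)) parts[[p]] <- c(parts[[p]], a[[p]] %||% character(0))
    }
  } else {
    a <- alloc(names(labels))
    parts <- list(train = a$train %||% character(0),
                  test = a$test %||% character(0),
                  validation = a$validation %||% character(0))
  }
  parts
}

#' Boosted-model configuration
#'
#' Hyperparameters for the gradient-boosted tree backend. Each of
#' `learning_rate`, `tree_depth` and `l2_leaf_reg` may be a vector; the
#' Cartesian product defines the grid searched by [grid_search()]. The
#' classification task optimizes a multiclass softmax loss and is selected
#' on accuracy; regression minimizes squared error and is selected on R².
#'
#' @param task `"multiclass"` or `"regression"`.
#' @param learning_rate Shrinkage per boosting step.
#' @param tree_depth Maximum tree depth.
#' @param l2_leaf_reg L2 regularization on leaf weights.
#' @param nrounds Number of boosting rounds.
#' @param seed Integer seed passed to the backend.
#' @return A `model_config` object.
#' @export
model_config <- function(task = c("multiclass", "regression"),
                         learning_rate = 0.1, tree_depth = 6,
                         l2_leaf_reg = 1, nrounds = 150, seed = 1) {
  task <- match.arg(task)
  if (length(learning_rate) < 1 || length(tree_depth) < 1 ||
      length(l2_leaf_reg) < 1) {
    abort("each grid axis must be nonempty")
  }
  structure(
    list(
      task = task, learning_rate = learning_rate, tree_depth = tree_depth,
      l2_leaf_reg = l2_leaf_reg, nrounds = nrounds, seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' @rdname model_config
#' @param cfg A `model_config`.
#' @return `config_grid()`: tibble of grid points in first-in-grid order.
#' @export
config_grid <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  as_tibble(expand.grid(
    l2_leaf_reg = cfg$l2_leaf_reg,
    tree_depth = cfg$tree_depth,
    learning_rate = cfg$learning_rate,
    KEEP.OUT.ATTRS = FALSE
  ))[, c("learning_rate", "tree_depth", "l2_leaf_reg")]
}

profile_rows <- function(m, ids) {
  x <- if (inherits(m, "sensor_profile")) m$values else m
  if (is.null(ids)) x else x[ids, , drop = FALSE]
}

fit_booster <- function(x, y, cfg, point, n_class = NULL) {
  params <- list(
    max_depth = point$tree_depth,
    eta = point$learning_rate,
    lambda = point$l2_leaf_reg,
    nthread = 1,
    seed = cfg$seed
  )
  if (cfg$task == "multiclass") {
    params$objective <- "multi:softprob"
    params$num_class <- n_class
  } else {
    params$objective <- "reg:squarederror"
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = cfg$nrounds,
                     verbose = 0)
}

new_sensor_model <- function(booster, task, classes, features, params, cfg) {
  structure(
    list(booster = booster, task = task, classes = classes,
         features = features, params = params, cfg = cfg),
    class = "sensor_model"
  )
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf(
    "<sensor_model: %s, %d features%s>\n", x$task, length(x$features),
    if (x$task == "multiclass") sprintf(", %d classes", length(x$classes)) else ""
  ))
  invisible(x)
}

#' Train a multiclass sensor-profile classifier
#'
#' Gradient-boosted decision trees with a multiclass softmax loss; given a
#' fixed seed the fit is reproducible. Training labels must contain at
#' least two classes.
#'
#' @param x Numeric matrix of profiles (rows = samples), or a
#'   `sensor_profile`.
#' @param labels Class labels, one per row of `x`.
#' @param cfg A [model_config()] (its first grid point is used; run
#'   [grid_search()] to tune).
#' @return A `sensor_model`.
#' @export
train_classifier <- function(x, labels, cfg = model_config("multiclass")) {
  stopifnot(inherits(cfg, "model_config"))
  x <- profile_rows(x, NULL)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) abort("one label per row required")
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("training labels contain a single class")
  point <- config_grid(cfg)[1, ]
  booster <- fit_booster(x, match(labels, classes) - 1L, cfg, point,
                         n_class = length(classes))
  new_sensor_model(booster, "multiclass", classes, colnames(x), point, cfg)
}

#' Train a sensor-profile regressor
#'
#' @param x Numeric matrix of profiles or a `sensor_profile`.
#' @param targets Numeric target values, one per row; must not be constant.
#' @param cfg A [model_config()] with `task = "regression"`.
#' @return A `sensor_model`.
#' @export
train_regressor <- function(x, targets, cfg = model_config("regression")) {
  stopifnot(inherits(cfg, "model_config"))
  x <- profile_rows(x, NULL)
  if (length(targets) != nrow(x)) abort("one target per row required")
  if (!is.numeric(targets) || anyNA(targets)) abort("targets must be numeric")
  if (isTRUE(all.equal(min(targets), max(targets)))) {
    abort("target is constant; nothing to regress")
  }
  point <- config_grid(cfg)[1, ]
  booster <- fit_booster(x, targets, cfg, point)
  new_sensor_model(booster, "regression", NULL, colnames(x), point, cfg)
}

#' Predict from a fitted sensor model
#'
#' @param object A `sensor_model`.
#' @param newdata Matrix or `sensor_profile`.
#' @param type `"class"` (labels), `"prob"` (per-class probabilities),
#'   `"margin"` (raw scores) or `"response"` (regression prediction).
#' @param ... Unused.
#' @return Labels, a matrix of scores, or a numeric vector.
#' @export
predict.sensor_model <- function(object, newdata,
                                 type = c("class", "prob", "margin",
                                          "response"), ...) {
  type <- match.arg(type)
  x <- profile_rows(newdata, NULL)
  x <- x[, object$features, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(x)
  if (object$task == "regression") {
    return(predict(object$booster, dm))
  }
  if (type == "margin") {
    out <- predict(object$booster, dm, outputmargin = TRUE)
    colnames(out) <- object$classes
    return(out)
  }
  prob <- predict(object$booster, dm)
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  object$classes[max.col(prob, ties.method = "first")]
}

#' Exhaustive grid search on a validation set
#'
#' Evaluates every point of the configuration grid (Cartesian product of
#' learning rate, tree depth and L2 leaf regularization, in first-in-grid
#' order) on the validation split — accuracy for classification, R² for
#' regression — and refits the best point on the training split. Metric
#' ties are broken by grid order, so the search is deterministic.
#'
#' @param x_train,y_train Training rows and labels/targets.
#' @param x_val,y_val Validation rows and labels/targets.
#' @param cfg A [model_config()] whose vectors span the grid.
#' @return List with `model` (refit best), `best_params` (one-row tibble)
#'   and `log` (tibble of every grid point and its validation metric).
#' @export
grid_search <- function(x_train, y_train, x_val, y_val, cfg) {
  stopifnot(inherits(cfg, "model_config"))
  grid <- config_grid(cfg)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- cfg
    cfg_i$learning_rate <- grid$learning_rate[i]
    cfg_i$tree_depth <- grid$tree_depth[i]
    cfg_i$l2_leaf_reg <- grid$l2_leaf_reg[i]
    if (cfg$task == "multiclass") {
      fit <- train_classifier(x_train, y_train, cfg_i)
      scores[i] <- mean(predict(fit, x_val, type = "class") ==
                          as.character(y_val))
    } else {
      fit <- train_regressor(x_train, y_train, cfg_i)
      scores[i] <- r_squared(y_val, predict(fit, x_val))
    }
  }
  best <- which.max(scores)  # first maximum wins ties
  cfg_best <- cfg
  cfg_best$learning_rate <- grid$learning_rate[best]
  cfg_best$tree_depth <- grid$tree_depth[best]
  cfg_best$l2_leaf_reg <- grid$l2_leaf_reg[best]
  model <- if (cfg$task == "multiclass") {
    train_classifier(x_train, y_train, cfg_best)
  } else {
    train_regressor(x_train, y_train, cfg_best)
  }
  list(
    model = model,
    best_params = mutate(grid[best, ], metric = scores[best]),
    log = mutate(grid, metric = scores)
  )
}

r_squared <- function(observed, predicted) {
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

#' Evaluate a classifier on held-out rows
#'
#' Accuracy, per-class F1 and the complete confusion matrix over the union
#' of model classes and observed labels (zero rows included). Labels never
#' seen in training are kept as their own confusion rows and flagged.
#'
#' @param model A multiclass `sensor_model`.
#' @param x Held-out rows.
#' @param labels True labels for `x` (nonempty).
#' @return A `model_eval` object; see [glance.model_eval()].
#' @export
evaluate <- function(model, x, labels) {
  stopifnot(inherits(model, "sensor_model"))
  if (model$task != "multiclass") abort("use evaluate_r2() for regressors")
  labels <- as.character(labels)
  if (length(labels) == 0) abort("test set is empty")
  pred <- predict(model, x, type = "class")
  unseen <- setdiff(unique(labels), model$classes)
  if (length(unseen) > 0) {
    warn(sprintf("label(s) unseen in training: %s",
                 paste(unseen, collapse = ", ")))
  }
  all_classes <- sort(union(model$classes, labels))
  confusion <- table(
    true = factor(labels, levels = all_classes),
    predicted = factor(pred, levels = all_classes)
  )
  f1 <- tibble(
    class = all_classes,
    f1 = map_dbl(all_classes, function(cl) {
      tp <- sum(pred == cl & labels == cl)
      fp <- sum(pred == cl & labels != cl)
      fn <- sum(pred != cl & labels == cl)
      if (2 * tp + fp + fn == 0) return(NA_real_)
      2 * tp / (2 * tp + fp + fn)
    })
  )
  structure(
    list(
      accuracy = mean(pred == labels),
      f1 = f1,
      confusion = confusion,
      n = length(labels),
      unseen_labels = unseen,
      best_params = model$params
    ),
    class = "model_eval"
  )
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval: accuracy %.3f on %d samples>\n", x$accuracy, x$n))
  invisible(x)
}

#' Tidy / summarise an evaluation report
#'
#' `tidy()` returns the confusion matrix in long form (`true`,
#' `predicted`, `n`); `glance()` returns a one-row summary with accuracy
#' and macro-F1.
#'
#' @param x A `model_eval`.
#' @param ... Unused.
#' @export
tidy.model_eval <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion)) |>
    rename(n = "Freq") |>
    mutate(true = as.character(.data$true),
           predicted = as.character(.data$predicted))
}

#' @rdname tidy.model_eval
#' @export
glance.model_eval <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    macro_f1 = mean(x$f1$f1, na.rm = TRUE),
    n = x$n,
    n_classes = nrow(x$f1)
  )
}

#' Held-out R² for a regressor
#'
#' `1 - SS_res / SS_tot` on the held-out rows; predicting the held-out
#' mean scores exactly 0.
#'
#' @param model A regression `sensor_model`.
#' @param x Held-out rows.
#' @param targets True values.
#' @return A single number.
#' @export
evaluate_r2 <- function(model, x, targets) {
  stopifnot(inherits(model, "sensor_model"))
  if (model$task != "regression") abort("use evaluate() for classifiers")
  r_squared(targets, predict(model, x))
}

#' Majority Pfam accession per cluster
#'
#' Maps every cluster to the most frequent Pfam accession among its member
#' domains (ties broken lexicographically), the coarse feature space used
#' by [feature_set_comparison()].
#'
#' @param assignment A `cluster_assignment` covering `domains`.
#' @param domains Sensor-domain tibble.
#' @return Tibble with `cluster_id` and `pfam_acc`.
#' @export
cluster_pfam_map <- function(assignment, domains) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  domains |>
    mutate(cluster_id = assignment$cluster_of[.data$seq_id]) |>
    count(.data$cluster_id, .data$pfam_acc) |>
    group_by(.data$cluster_id) |>
    arrange(desc(.data$n), .data$pfam_acc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("cluster_id", "pfam_acc")
}

#' Compare cluster-level and Pfam-level feature spaces
#'
#' Trains two classifiers under identical split, seed and hyperparameters:
#' one on the cluster-resolution profile matrix, one on the Pfam-level
#' matrix obtained by summing cluster columns within each Pfam accession.
#' Because several sensor families can share one Pfam, the Pfam matrix can
#' only lose resolution; the paired reports quantify what that costs.
#'
#' @param m A `sensor_profile` (cluster columns).
#' @param cluster_pfam Tibble mapping `cluster_id` to `pfam_acc` (from
#'   [cluster_pfam_map()]).
#' @param label_field Metadata column holding the class label.
#' @param cfg A [model_config()].
#' @param split A [split_profile()] result; computed at `cfg$seed` when
#'   omitted.
#' @return List with `model_eval`s `cluster` and `pfam`, and a two-row
#'   `comparison` tibble.
#' @export
feature_set_comparison <- function(m, cluster_pfam, label_field = "ecosystem",
                                   cfg = model_config("multiclass"),
                                   split = NULL) {
  stopifnot(inherits(m, "sensor_profile"))
  missing_map <- setdiff(colnames(m$values), cluster_pfam$cluster_id)
  if (length(missing_map) > 0) {
    abort(sprintf("cluster(s) without Pfam mapping: %s",
                  paste(head(missing_map, 5), collapse = ", ")))
  }
  pfam_of <- setNames(cluster_pfam$pfam_acc, cluster_pfam$cluster_id)
  groups <- pfam_of[colnames(m$values)]
  pfam_values <- t(rowsum(t(m$values), group = groups))
  if (!identical(rownames(pfam_values), rownames(m$values))) {
    abort("row mismatch between cluster and Pfam matrices")
  }

  labels <- setNames(as.character(m$meta[[label_field]]),
                     m$meta$metagenome_id)
  if (is.null(split)) {
    split <- split_profile(m, label_field, seed = cfg$seed)
  }
  eval_on <- function(values) {
    fit <- train_classifier(values[split$train, , drop = FALSE],
                            labels[split$train], cfg)
    evaluate(fit, values[split$test, , drop = FALSE], labels[split$test])
  }
  cluster_eval <- eval_on(m$values)
  pfam_eval <- eval_on(pfam_values)
  list(
    cluster = cluster_eval,
    pfam = pfam_eval,
    comparison = tibble(
      features = c("cluster", "pfam"),
      n_features = c(ncol(m$values), ncol(pfam_values)),
      accuracy = c(cluster_eval$accuracy, pfam_eval$accuracy)
    )
  )
}
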