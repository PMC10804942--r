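# Additive feature attributions and the unsupervised views used for
# interpretation: hierarchical heatmap ordering and 2-D embeddings.

#' Additive per-feature attributions
#'
#' Decomposes the model's raw score for every (sample, class) pair into
#' per-feature contributions plus a base value (TreeSHAP, computed inside
#' the tree backend). The decomposition satisfies local accuracy: for each
#' sample and class, the attributions plus the base value reproduce the
#' model's raw score. Positive values push the model toward the class,
#' negative values away from it.
#'
#' @param model A `sensor_model`.
#' @param x Rows to attribute (matrix or `sensor_profile`).
#' @return An `attribution_table`: long tibble with `sample`, `class`,
#'   `feature`, `value`, carrying a `base` tibble (`sample`, `class`,
#'   `base_value`, `raw_score`) as attribute. For regressors the single
#'   pseudo-class is `"(response)"`.
#' @export
attribute <- function(model, x) {
  stopifnot(inherits(model, "sensor_model"))
  x <- profile_rows(x, NULL)
  x <- x[, model$features, drop = FALSE]
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%04d", seq_len(nrow(x)))
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- predict(model$booster, dm, predcontrib = TRUE)
  raw <- predict(model$booster, dm, outputmargin = TRUE)

  if (model$task == "multiclass") {
    classes <- model$classes
  } else {
    classes <- "(response)"
    contrib <- array(contrib, dim = c(nrow(x), 1L, ncol(x) + 1L))
    raw <- matrix(raw, ncol = 1L)
  }
  n <- nrow(x); k <- length(classes); p <- length(model$features)

  long <- tibble(
    sample = rep(rownames(x), times = k * p),
    class = rep(rep(classes, each = n), times = p),
    feature = rep(model$features, each = n * k),
    value = as.vector(contrib[, , seq_len(p), drop = FALSE])
  )
  base <- tibble(
    sample = rep(rownames(x), times = k),
    class = rep(classes, each = n),
    base_value = as.vector(contrib[, , p + 1L]),
    raw_score = as.vector(raw)
  )
  structure(long, base = base, class = c("attribution_table", class(long)))
}

#' Base values and raw scores of an attribution table
#'
#' @param t An `attribution_table`.
#' @return Tibble with `sample`, `class`, `base_value`, `raw_score`.
#' @export
attribution_base <- function(t) {
  stopifnot(inherits(t, "attribution_table"))
  attr(t, "base")
}

#' Rank features by attribution mass
#'
#' Orders features by the sum over samples (and over classes, for global
#' scope) of their attribution values — absolute values by default,
#' signed sums optionally. Descending, with ties broken by feature id so
#' the ranking is stable and independent of sample order.
#'
#' @param t An `attribution_table`.
#' @param scope `"global"` (one ranking) or `"class"` (one per class).
#' @param signed Sum signed values instead of absolute values?
#' @return Tibble with `feature`, `total`, `rank` (and `class` for class
#'   scope).
#' @export
rank_features <- function(t, scope = c("global", "class"), signed = FALSE) {
  stopifnot(inherits(t, "attribution_table"))
  if (nrow(t) == 0) abort("attribution table is empty")
  scope <- match.arg(scope)
  agg <- if (signed) identity else abs
  grouping <- if (scope == "global") "feature" else c("class", "feature")
  t |>
    group_by(across(all_of(grouping))) |>
    summarise(total = sum(agg(.data$value)), .groups = "drop_last") |>
    arrange(desc(.data$total), .data$feature, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Hierarchical ordering for heatmaps
#'
#' Row and column dendrograms on log2-transformed abundances
#' (`log2(value + pseudocount)`, pseudocount defaulting to half the
#' smallest nonzero value), average linkage on Euclidean distances.
#'
#' @param m A `sensor_profile` or numeric matrix.
#' @param linkage Linkage method for [stats::hclust()].
#' @param pseudocount Added before the log2 transform; `NULL` for the
#'   default.
#' @return List with `row_order`, `col_order` (permutations of row/column
#'   indices), the two `hclust` trees, and the transformed matrix.
#' @export
hierarchical_order <- function(m, linkage = "average", pseudocount = NULL) {
  x <- if (inherits(m, "sensor_profile")) m$values else m
  if (length(x) == 0) abort("matrix is empty")
  if (is.null(pseudocount)) {
    nz <- x[x > 0]
    pseudocount <- if (length(nz)) min(nz) / 2 else 1e-6
  }
  lx <- log2(x + pseudocount)
  order_of <- function(mat) {
    if (nrow(mat) < 2) {
      return(list(order = seq_len(nrow(mat)), tree = NULL))
    }
    tree <- hclust(dist(mat), method = linkage)
    list(order = tree$order, tree = tree)
  }
  rows <- order_of(lx)
  cols <- order_of(t(lx))
  list(
    row_order = rows$order, col_order = cols$order,
    row_tree = rows$tree, col_tree = cols$tree,
    log2_values = lx
  )
}

#' 2-D embedding of sensor profiles
#'
#' t-SNE on the profile rows. Perplexity defaults to 30 and is clipped to
#' `(n - 1) / 3` for small inputs; the embedding is deterministic given
#' `seed`. Up to 500 rows the exact gradient is used (duplicated profiles
#' then embed essentially coincident); above that the Barnes-Hut
#' approximation keeps the cost near-linear.
#'
#' @param m A `sensor_profile` or numeric matrix with at least 3 rows.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity before clipping.
#' @param max_iter Gradient iterations.
#' @return Tibble with `metagenome_id`, `dim1`, `dim2`, joined with the
#'   profile metadata when available.
#' @export
embed_profile <- function(m, seed = 1, perplexity = 30, max_iter = 1000) {
  x <- if (inherits(m, "sensor_profile")) m$values else m
  if (nrow(x) < 3) abort("need at least 3 rows to embed")
  perplexity <- min(perplexity, (nrow(x) - 1) / 3)
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(x, perplexity = perplexity, check_duplicates = FALSE,
                      pca = nrow(x) > 50, num_threads = 1,
                      theta = if (nrow(x) <= 500) 0 else 0.5,
                      max_iter = max_iter)
  out <- tibble(
    metagenome_id = rownames(x) %||% sprintf("row%04d", seq_len(nrow(x))),
    dim1 = fit$Y[, 1], dim2 = fit$Y[, 2]
  )
  if (inherits(m, "sensor_profile")) {
    out <- left_join(out, m$meta, by = "metagenome_id")
  }
  out
}

#' Features most rank-correlated with an anchor feature
#'
#' Spearman correlation of every other column's abundance vector with the
#' anchor's, returning the top `k` by absolute correlation (anchor
#' excluded). A constant anchor has no ranks to correlate and is an error.
#'
#' @param m A `sensor_profile` or numeric matrix.
#' @param anchor_feature Column name of the anchor cluster.
#' @param k Number of features to return (0 allowed).
#' @return Tibble with `feature` and `rho`, by descending `|rho|`.
#' @export
correlated_feature_group <- function(m, anchor_feature, k = 12) {
  x <- if (inherits(m, "sensor_profile")) m$values else m
  if (!anchor_feature %in% colnames(x)) {
    abort(sprintf("anchor feature '%s' not present", anchor_feature))
  }
  anchor <- x[, anchor_feature]
  if (min(anchor) == max(anchor)) {
    abort("anchor feature is constant; rank correlation undefined")
  }
  if (k == 0) return(tibble(feature = character(), rho = numeric()))
  others <- setdiff(colnames(x), anchor_feature)
  rho <- suppressWarnings(
    cor(anchor, x[, others, drop = FALSE], method = "spearman")[1, ]
  )
  tibble(feature = others, rho = unname(rho)) |>
    filter(!is.na(.data$rho)) |>
    arrange(desc(abs(.data$rho)), .data$feature) |>
    head(k)
}
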