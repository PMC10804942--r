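# Ecosystem-level diversity statistics over the sensor profile matrix.
#
# These are computed on the UNFILTERED matrix: the prevalence filter used
# before model training would bias richness downward, so the full cluster
# set gives the accurate picture of the sensor landscape.

presence_by_class <- function(m, by) {
  assert_columns(m$meta, by, "profile metadata")
  labels <- m$meta[[by]]
  pres <- m$values > 0
  classes <- sort(unique(labels))
  out <- matrix(FALSE, length(classes), ncol(pres),
                dimnames = list(classes, colnames(pres)))
  for (cl in classes) {
    rows <- which(labels == cl)
    out[cl, ] <- colSums(pres[rows, , drop = FALSE]) > 0
  }
  out
}

#' Relative Ecosystem Richness (RER)
#'
#' The number of distinct clusters observed in an ecosystem divided by the
#' number of distinct clusters observed anywhere: how much each ecosystem
#' contributes to global sensor diversity.
#'
#' @param m A `sensor_profile` (use the unfiltered matrix).
#' @param by Metadata column defining the grouping (default `"ecosystem"`).
#' @return Tibble with the grouping column, `rer`, `n_clusters` and
#'   `n_samples`.
#' @export
rer <- function(m, by = "ecosystem") {
  stopifnot(inherits(m, "sensor_profile"))
  pres <- presence_by_class(m, by)
  denom <- sum(colSums(pres) > 0)
  if (denom == 0) abort("no cluster is present anywhere")
  tibble(
    !!by := rownames(pres),
    rer = unname(rowSums(pres)) / denom,
    n_clusters = unname(rowSums(pres)),
    n_samples = as.vector(table(m$meta[[by]])[rownames(pres)])
  )
}

#' Ecosystem Typical Sample Richness (ETSR)
#'
#' The mean per-sample count of distinct clusters in an ecosystem divided
#' by the ecosystem's total distinct cluster count: how representative a
#' typical sample is of its ecosystem's sensor repertoire. An ecosystem
#' with a single sample scores exactly 1; an ecosystem with no clusters at
#' all gets `NA` rather than 0/0.
#'
#' @inheritParams rer
#' @return Tibble with the grouping column, `etsr` and `n_samples`.
#' @export
etsr <- function(m, by = "ecosystem") {
  stopifnot(inherits(m, "sensor_profile"))
  assert_columns(m$meta, by, "profile metadata")
  labels <- m$meta[[by]]
  per_sample <- rowSums(m$values > 0)
  pres <- presence_by_class(m, by)
  classes <- rownames(pres)
  tibble(
    !!by := classes,
    etsr = map_dbl(classes, function(cl) {
      total <- sum(pres[cl, ])
      if (total == 0) return(NA_real_)
      mean(per_sample[labels == cl]) / total
    }),
    n_samples = as.vector(table(labels)[classes])
  )
}

#' Combined per-ecosystem metrics table
#'
#' RER, ETSR, mean sensor fraction and sample count in one tibble.
#'
#' @inheritParams rer
#' @return Tibble with one row per class.
#' @export
ecosystem_metrics <- function(m, by = "ecosystem") {
  r <- rer(m, by)
  e <- etsr(m, by) |> select(-"n_samples")
  sf <- sensor_fraction(m) |>
    mutate(!!by := m$meta[[by]][match(.data$metagenome_id,
                                      m$meta$metagenome_id)]) |>
    group_by(.data[[by]]) |>
    summarise(mean_sensor_fraction = mean(.data$sensor_fraction),
              .groups = "drop")
  r |>
    left_join(e, by = by) |>
    left_join(sf, by = by) |>
    select(all_of(by), "rer", "etsr", "mean_sensor_fraction",
           "n_clusters", "n_samples")
}

#' Between-class correlation of mean sensor profiles
#'
#' Spearman rank correlation between the per-class mean abundance vectors
#' over the matrix's cluster set. Pairs involving a constant vector are
#' reported as `NA`.
#'
#' @inheritParams rer
#' @param method Correlation method (default `"spearman"`).
#' @return Symmetric class-by-class correlation matrix with unit diagonal.
#' @export
ecosystem_correlation <- function(m, by = "ecosystem", method = "spearman") {
  stopifnot(inherits(m, "sensor_profile"))
  assert_columns(m$meta, by, "profile metadata")
  labels <- m$meta[[by]]
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("need at least 2 classes")
  means <- t(vapply(classes, function(cl) {
    colMeans(m$values[labels == cl, , drop = FALSE])
  }, numeric(ncol(m$values))))
  rownames(means) <- classes
  cc <- suppressWarnings(cor(t(means), method = method))
  diag(cc) <- 1
  cc
}

#' Count clusters rare across ecosystems
#'
#' For each ecosystem, the number of its clusters found in at most
#' `rarity_max_ecosystems` ecosystems overall. With the default threshold
#' of 1 this counts ecosystem-unique clusters.
#'
#' @inheritParams rer
#' @param rarity_max_ecosystems Rarity threshold (>= 1).
#' @return Tibble with the grouping column and `n_rare_clusters`.
#' @export
rare_cluster_enrichment <- function(m, by = "ecosystem",
                                    rarity_max_ecosystems = 1) {
  stopifnot(inherits(m, "sensor_profile"))
  if (rarity_max_ecosystems < 1) abort("`rarity_max_ecosystems` must be >= 1")
  pres <- presence_by_class(m, by)
  eco_count <- colSums(pres)
  rare <- eco_count >= 1 & eco_count <= rarity_max_ecosystems
  tibble(
    !!by := rownames(pres),
    n_rare_clusters = as.integer(pres[, rare, drop = FALSE] %*%
                                   rep(1L, sum(rare)))
  )
}
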