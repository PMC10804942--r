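# The sensor profile matrix: metagenomes x sensor clusters, values are
# copy-number fractions of each sample's total gene copies.

new_sensor_profile <- function(values, meta, totals) {
  structure(
    list(values = values, meta = meta, totals = totals),
    class = "sensor_profile"
  )
}

#' @export
print.sensor_profile <- function(x, ...) {
  cat(sprintf(
    "<sensor_profile: %d metagenomes x %d clusters, %.1f%% nonzero>\n",
    nrow(x$values), ncol(x$values),
    if (length(x$values)) 100 * mean(x$values > 0) else 0
  ))
  invisible(x)
}

#' @export
dim.sensor_profile <- function(x) dim(x$values)

#' @export
as.matrix.sensor_profile <- function(x, ...) x$values

#' Tidy a sensor profile matrix
#'
#' @param x A `sensor_profile`.
#' @param ... Unused.
#' @return Long tibble with `metagenome_id`, `cluster_id`, `value`
#'   (zeros included).
#' @export
tidy.sensor_profile <- function(x, ...) {
  as_tibble(x$values, rownames = "metagenome_id") |>
    tidyr::pivot_longer(-"metagenome_id", names_to = "cluster_id",
                        values_to = "value")
}

#' Summarise a sensor profile matrix
#'
#' @param x A `sensor_profile`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, sparsity, mean row sum.
#' @export
glance.sensor_profile <- function(x, ...) {
  tibble(
    n_metagenomes = nrow(x$values),
    n_clusters = ncol(x$values),
    prop_nonzero = if (length(x$values)) mean(x$values > 0) else NA_real_,
    mean_row_sum = if (nrow(x$values)) mean(rowSums(x$values)) else NA_real_
  )
}

#' Build the sensor profile matrix
#'
#' The value for (metagenome m, cluster c) is the summed copy number of
#' the genes of m contributing at least one sensor domain to c, divided by
#' m's total gene copy number. A gene with domains in k distinct clusters
#' contributes its full copy number to each of the k clusters (but only
#' once per cluster, however many of its domains land there). Metagenomes
#' present in `gene_totals` but without sensors keep an all-zero row.
#'
#' @param domains Sensor-domain tibble (`seq_id`, `gene_id`,
#'   `metagenome_id`, `copy_number`).
#' @param assignment A `cluster_assignment` covering every `seq_id`.
#' @param gene_totals Tibble with `metagenome_id`, `total_copy` (from
#'   [gene_copy_totals()]); totals must be positive.
#' @param meta Metadata tibble (`metagenome_id`, `ecosystem`, optional
#'   `condition` and physical-parameter columns).
#' @return A `sensor_profile` object.
#' @export
build_matrix <- function(domains, assignment, gene_totals, meta = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  assert_columns(domains, c("seq_id", "gene_id", "metagenome_id", "copy_number"),
                 "sensor domain table")
  assert_columns(gene_totals, c("metagenome_id", "total_copy"), "gene totals")
  if (any(gene_totals$total_copy <= 0)) {
    abort("every metagenome must have a positive total gene copy number")
  }
  unassigned <- setdiff(domains$seq_id, names(assignment$cluster_of))
  if (length(unassigned) > 0) {
    abort(sprintf(
      "domain(s) without cluster assignment: %s",
      paste(head(unassigned, 5), collapse = ", ")
    ))
  }
  missing_total <- setdiff(unique(domains$metagenome_id),
                           gene_totals$metagenome_id)
  if (length(missing_total) > 0) {
    abort(sprintf(
      "no gene total for metagenome(s): %s",
      paste(head(missing_total, 5), collapse = ", ")
    ))
  }

  rows <- sort(unique(gene_totals$metagenome_id))
  totals <- setNames(gene_totals$total_copy, gene_totals$metagenome_id)[rows]

  contrib <- domains |>
    mutate(cluster_id = assignment$cluster_of[.data$seq_id]) |>
    distinct(.data$metagenome_id, .data$gene_id, .data$cluster_id,
             .data$copy_number) |>
    group_by(.data$metagenome_id, .data$cluster_id) |>
    summarise(copy = sum(.data$copy_number), .groups = "drop")

  cols <- sort(unique(contrib$cluster_id))
  values <- matrix(0, nrow = length(rows), ncol = length(cols),
                   dimnames = list(rows, cols))
  if (nrow(contrib) > 0) {
    values[cbind(
      match(contrib$metagenome_id, rows),
      match(contrib$cluster_id, cols)
    )] <- contrib$copy / totals[contrib$metagenome_id]
  }

  if (!is.null(meta)) {
    assert_columns(meta, c("metagenome_id"), "metadata table")
    meta <- meta |> filter(.data$metagenome_id %in% rows)
    meta <- meta[match(rows, meta$metagenome_id), , drop = FALSE]
  } else {
    meta <- tibble(metagenome_id = rows)
  }
  new_sensor_profile(values, as_tibble(meta), totals)
}

#' Drop rare sensor clusters
#'
#' Keeps clusters present (value > 0) in at least `min_prevalence`
#' metagenomes; row values are not renormalized. This is the sparsity
#' filter applied before model training.
#'
#' @param m A `sensor_profile`.
#' @param min_prevalence Minimum number of metagenomes a cluster must
#'   appear in (default 100).
#' @return The filtered `sensor_profile`.
#' @export
filter_clusters <- function(m, min_prevalence = 100) {
  stopifnot(inherits(m, "sensor_profile"))
  if (min_prevalence < 1) abort("`min_prevalence` must be >= 1")
  keep <- colSums(m$values > 0) >= min_prevalence
  if (!any(keep)) {
    warn("no cluster meets the prevalence threshold; result has 0 columns")
  }
  m$values <- m$values[, keep, drop = FALSE]
  m
}

#' Drop samples from small or ambiguous label classes
#'
#' Removes rows whose label is in `drop_labels` (matched against the full
#' label and against each ":"-separated level of it), then removes rows
#' whose label class has `min_per_class` or fewer members — strictly
#' greater-than semantics, so the default 30 keeps classes of 31 and up.
#'
#' @param m A `sensor_profile` with the label column in its metadata.
#' @param min_per_class Strict lower bound on class size (default 30).
#' @param drop_labels Labels removed outright (default `"Unclassified"`).
#' @param label_field Metadata column holding the label (default
#'   `"ecosystem"`; `"condition"` for disease-state work).
#' @return The filtered `sensor_profile`.
#' @export
filter_samples <- function(m, min_per_class = 30,
                           drop_labels = "Unclassified",
                           label_field = "ecosystem") {
  stopifnot(inherits(m, "sensor_profile"))
  assert_columns(m$meta, label_field, "profile metadata")
  labels <- m$meta[[label_field]]
  if (anyNA(labels)) {
    abort(sprintf("label field '%s' has missing values", label_field))
  }
  in_drop <- function(lab) {
    lab %in% drop_labels |
      map_lgl_any_level(lab, drop_labels)
  }
  keep <- !in_drop(labels)
  sizes <- table(labels[keep])
  keep <- keep & (as.vector(sizes[labels]) > min_per_class)
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    abort("sample filtering removed every row")
  }
  m$values <- m$values[keep, , drop = FALSE]
  m$meta <- m$meta[keep, , drop = FALSE]
  m$totals <- m$totals[keep]
  m
}

map_lgl_any_level <- function(labels, drop_labels) {
  if (length(drop_labels) == 0) return(rep(FALSE, length(labels)))
  map_lgl(strsplit(labels, ":", fixed = TRUE), function(levels) {
    any(levels %in% drop_labels)
  })
}

#' Per-metagenome sensor fraction
#'
#' The share of a metagenome's gene copies carried by sensor-contributing
#' genes: the row sum of the unfiltered profile matrix. Compute it on the
#' matrix before any cluster filtering, since dropped columns take their
#' abundance with them.
#'
#' @param m A `sensor_profile`.
#' @return Tibble with `metagenome_id` and `sensor_fraction`.
#' @export
sensor_fraction <- function(m) {
  stopifnot(inherits(m, "sensor_profile"))
  tibble(
    metagenome_id = rownames(m$values),
    sensor_fraction = unname(rowSums(m$values))
  )
}
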