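# Deduplication and identity/coverage clustering of sensor sequences.
#
# The built-in clusterer is greedy incremental centroid clustering in the
# CD-HIT/linclust tradition: sequences are visited longest-first and each
# joins the first existing centroid it matches at the identity and coverage
# thresholds, otherwise it founds a new cluster. Identity comes from a
# global Needleman-Wunsch alignment scored match +1 / mismatch 0 / gap -1,
# counted as matches over alignment columns; coverage is aligned residue
# pairs over sequence length.

#' Clustering parameters
#'
#' @param min_identity Minimum identity fraction in (0, 1] for a sequence
#'   to join a cluster.
#' @param coverage_mode How coverage is evaluated: `"bidirectional"`
#'   (both sequences must be covered; the minimum of the two coverages is
#'   used), `"target"` (centroid coverage) or `"query"` (member coverage).
#' @param coverage_fraction Minimum coverage fraction in (0, 1].
#' @return A `cluster_params` object.
#' @export
cluster_params <- function(min_identity = 0.5,
                           coverage_mode = c("bidirectional", "target", "query"),
                           coverage_fraction = 0.8) {
  coverage_mode <- match.arg(coverage_mode)
  if (min_identity <= 0 || min_identity > 1) {
    abort("`min_identity` must lie in (0, 1]")
  }
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    abort("`coverage_fraction` must lie in (0, 1]")
  }
  structure(
    list(
      min_identity = min_identity,
      coverage_mode = coverage_mode,
      coverage_fraction = coverage_fraction
    ),
    class = "cluster_params"
  )
}

#' Deduplicate sensor sequences
#'
#' Exact string equality defines duplicates. Each unique sequence is
#' represented by its first member (in input order).
#'
#' @param domains Sensor-domain tibble with `seq_id` and `sequence`.
#' @return Tibble of unique sequences: `uid` (representative `seq_id`),
#'   `sequence`, `multiplicity`, and `members` (list column of member
#'   `seq_id`s). Multiplicities sum to the input size.
#' @export
dedup <- function(domains) {
  assert_columns(domains, c("seq_id", "sequence"), "sensor domain table")
  if (any(!nzchar(domains$sequence) | is.na(domains$sequence))) {
    abort("empty sequence encountered during deduplication")
  }
  domains |>
    group_by(.data$sequence) |>
    summarise(
      uid = first(.data$seq_id),
      multiplicity = n(),
      members = list(.data$seq_id),
      .groups = "drop"
    ) |>
    arrange(match(.data$uid, domains$seq_id)) |>
    select("uid", "sequence", "multiplicity", "members")
}

#' Pairwise identity and coverage between two sequences
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch 0, gap -1;
#' identity is matches over alignment columns, coverage is aligned residue
#' pairs over sequence length, combined according to `mode` (bidirectional
#' takes the minimum of the two coverages and is symmetric in its
#' arguments; `query` covers `a`, `target` covers `b`).
#'
#' @param a,b Nonempty amino-acid strings.
#' @param mode Coverage mode, as in [cluster_params()].
#' @return Named numeric vector with `identity` and `coverage`.
#' @export
pairwise_identity <- function(a, b, mode = "bidirectional") {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be nonempty")
  stats <- .nw_align_stats(a, b)
  cov_a <- stats$pairs / nchar(a)
  cov_b <- stats$pairs / nchar(b)
  coverage <- switch(mode,
    bidirectional = min(cov_a, cov_b),
    query = cov_a,
    target = cov_b,
    abort("unknown coverage mode")
  )
  c(identity = stats$matches / stats$columns, coverage = coverage)
}

new_cluster_assignment <- function(cluster_of, centroid_of, multiplicity = NULL) {
  structure(
    list(
      cluster_of = cluster_of,
      centroid_of = centroid_of,
      multiplicity = multiplicity
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment: %d sequences in %d clusters>\n",
    length(x$cluster_of), length(x$centroid_of)
  ))
  invisible(x)
}

#' Tidy a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Tibble with `seq_id`, `cluster_id`, `is_centroid`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(
    seq_id = names(x$cluster_of),
    cluster_id = unname(x$cluster_of)
  ) |>
    mutate(is_centroid = .data$seq_id %in% unname(x$centroid_of))
}

#' Greedy incremental centroid clustering
#'
#' Sequences are sorted longest-first (ties broken lexicographically by
#' sequence id, radix order) and visited once: a sequence joins the first
#' existing centroid whose identity and coverage meet the thresholds, else
#' it founds a new cluster with itself as centroid. Because centroids are
#' at least as long as later members, query coverage is member coverage
#' and target coverage is centroid coverage. The result is fully
#' deterministic from the ordering rule.
#'
#' @param seqs Named character vector of sequences (names are sequence
#'   ids), or a [dedup()] tibble.
#' @param params A [cluster_params()].
#' @param seed Accepted for interface compatibility and ignored: the
#'   algorithm has no random choices.
#' @return A `cluster_assignment`: `cluster_of` maps sequence id to
#'   cluster id, `centroid_of` maps cluster id to its representative
#'   sequence id (always a member of its own cluster).
#' @export
cluster_greedy <- function(seqs, params = cluster_params(), seed = NULL) {
  stopifnot(inherits(params, "cluster_params"))
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$uid)
  if (length(seqs) == 0) abort("input must be nonempty")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("sequences must carry unique names")
  }

  ord <- stable_order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ids <- names(seqs)

  centroid_seq <- character(0)
  centroid_id <- character(0)
  cluster_of <- setNames(character(length(seqs)), ids)

  for (i in seq_along(seqs)) {
    assigned <- NA_integer_
    if (length(centroid_seq) > 0) {
      stats <- .nw_align_batch(seqs[[i]], centroid_seq)
      coverage <- switch(params$coverage_mode,
        bidirectional = pmin(stats[, "cov_query"], stats[, "cov_target"]),
        query = stats[, "cov_query"],
        target = stats[, "cov_target"]
      )
      hit <- which(stats[, "identity"] >= params$min_identity &
                     coverage >= params$coverage_fraction)
      if (length(hit) > 0) assigned <- hit[1]
    }
    if (is.na(assigned)) {
      centroid_seq <- c(centroid_seq, seqs[[i]])
      centroid_id <- c(centroid_id, ids[i])
      assigned <- length(centroid_seq)
    }
    cluster_of[[ids[i]]] <- centroid_id[assigned]
  }

  # cluster ids: stable, derived from centroid discovery order
  cluster_ids <- setNames(sprintf("cluster%05d", seq_along(centroid_id)),
                          centroid_id)
  new_cluster_assignment(
    cluster_of = setNames(unname(cluster_ids[cluster_of]), names(cluster_of)),
    centroid_of = setNames(centroid_id, unname(cluster_ids))
  )
}

#' Cluster sensor domains end to end
#'
#' Convenience wrapper: deduplicates, clusters unique sequences with
#' [cluster_greedy()], then propagates each unique sequence's cluster to
#' all of its duplicate members so the assignment covers every input
#' domain.
#'
#' @param domains Sensor-domain tibble.
#' @param params A [cluster_params()].
#' @return A `cluster_assignment` over all `seq_id`s, with the
#'   `multiplicity` field mapping unique ids to member ids.
#' @export
cluster_sensors <- function(domains, params = cluster_params()) {
  uniq <- dedup(domains)
  asg <- cluster_greedy(uniq, params)
  cluster_of <- unlist(map2(
    uniq$members, asg$cluster_of[uniq$uid],
    function(members, cl) setNames(rep(cl, length(members)), members)
  ))
  new_cluster_assignment(
    cluster_of = cluster_of,
    centroid_of = asg$centroid_of,
    multiplicity = setNames(uniq$members, uniq$uid)
  )
}

#' Cluster with an external tool (MMseqs2-compatible)
#'
#' Shells out to an external clustering binary in the many-against-many
#' style and parses its native two-column cluster TSV
#' (representative, member) into the same assignment structure as
#' [cluster_greedy()]. The binary being absent is an explicit error,
#' never a silent fallback to the built-in clusterer.
#'
#' @param fasta_path FASTA of sequences to cluster.
#' @param params A [cluster_params()].
#' @param tool_path Path or name of the binary (default `"mmseqs"`).
#' @param workdir Scratch directory for the tool's databases.
#' @return A `cluster_assignment`.
#' @export
cluster_external <- function(fasta_path, params = cluster_params(),
                             tool_path = "mmseqs",
                             workdir = tempfile("clust")) {
  stopifnot(inherits(params, "cluster_params"))
  resolved <- Sys.which(tool_path)
  if (!nzchar(resolved)) {
    abort(sprintf("external clustering tool unavailable: '%s' not found on PATH",
                  tool_path))
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  cov_mode <- switch(params$coverage_mode,
    bidirectional = 0L, target = 1L, query = 2L
  )
  out_prefix <- file.path(workdir, "clu")
  status <- system2(resolved, c(
    "easy-cluster", shQuote(fasta_path), shQuote(out_prefix),
    shQuote(file.path(workdir, "tmp")),
    "--min-seq-id", format(params$min_identity),
    "--cov-mode", cov_mode, "-c", format(params$coverage_fraction)
  ), stdout = FALSE, stderr = FALSE)
  if (status != 0) {
    abort(sprintf("external clustering tool exited with status %d", status))
  }
  read_cluster_tsv(paste0(out_prefix, "_cluster.tsv"))
}

#' Parse a two-column cluster TSV (representative, member)
#'
#' @param path TSV path, no header, two columns.
#' @return A `cluster_assignment`.
#' @export
read_cluster_tsv <- function(path) {
  df <- readr::read_tsv(path, col_names = c("representative", "member"),
                        col_types = "cc", progress = FALSE)
  if (nrow(df) == 0 || anyNA(df$representative) || anyNA(df$member)) {
    abort(sprintf("malformed cluster TSV: %s", path))
  }
  if (anyDuplicated(df$member)) {
    abort("malformed cluster TSV: a member appears in more than one cluster")
  }
  reps <- unique(df$representative)
  missing_reps <- setdiff(reps, df$member)
  if (length(missing_reps) > 0) {
    abort("malformed cluster TSV: representative missing from its own cluster")
  }
  cluster_ids <- setNames(sprintf("cluster%05d", seq_along(reps)), reps)
  new_cluster_assignment(
    cluster_of = setNames(unname(cluster_ids[df$representative]), df$member),
    centroid_of = setNames(reps, unname(cluster_ids))
  )
}
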