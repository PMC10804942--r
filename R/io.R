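# Readers and writers for the pipeline's plain-text interchange formats:
# annotation TSV, metadata TSV, amino-acid FASTA, cluster TSV, matrix TSV.

ANNOTATION_COLS <- c(
  "metagenome_id", "gene_id", "pfam_acc", "ali_start", "ali_end",
  "gene_copy_number", "protein_length"
)

#' Read a gene/domain annotation table
#'
#' One row per domain hit: IMG-style export with 1-based, inclusive
#' alignment coordinates and a read-mapping gene copy-number estimate.
#' Genes without domain hits may appear with a placeholder accession so
#' that per-metagenome gene totals can be recovered from the table.
#'
#' @param path Path to a tab-separated annotation file with columns
#'   `metagenome_id`, `gene_id`, `pfam_acc`, `ali_start`, `ali_end`,
#'   `gene_copy_number`, `protein_length`.
#' @return A tibble with those columns, types enforced.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, ANNOTATION_COLS, "annotation table")
  df |>
    mutate(
      ali_start = as.integer(.data$ali_start),
      ali_end = as.integer(.data$ali_end),
      protein_length = as.integer(.data$protein_length),
      gene_copy_number = as.numeric(.data$gene_copy_number)
    )
}

#' @rdname read_annotations
#' @param annotations Annotation tibble to write.
#' @export
write_annotations <- function(annotations, path) {
  assert_columns(annotations, ANNOTATION_COLS, "annotation table")
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Metadata rows link a metagenome to its three-level ecosystem path
#' (`Level1:Level2:Level3`, GOLD style), an optional condition label and
#' optional physical parameters (numeric columns).
#'
#' @param path Path to a tab-separated metadata file; must contain
#'   `metagenome_id` and `ecosystem` columns.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("metagenome_id", "ecosystem"), "metadata table")
  df
}

#' @rdname read_metadata
#' @param meta Metadata tibble to write.
#' @export
write_metadata <- function(meta, path) {
  assert_columns(meta, c("metagenome_id", "ecosystem"), "metadata table")
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read and write sensor-domain FASTA
#'
#' Headers follow the `gene_id|domain_index|pfam_acc` convention so a
#' sequence's provenance survives a round trip through flat files.
#'
#' @param path FASTA file path.
#' @return `read_sensor_fasta()` returns a tibble with columns `seq_id`
#'   (the full header), `gene_id`, `domain_index`, `pfam_acc`, `sequence`.
#' @export
read_sensor_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- names(seqs)
  parts <- stringr::str_split_fixed(ids, stringr::fixed("|"), 3)
  tibble(
    seq_id = ids,
    gene_id = parts[, 1],
    domain_index = suppressWarnings(as.integer(parts[, 2])),
    pfam_acc = parts[, 3],
    sequence = as.character(seqs)
  )
}

#' @rdname read_sensor_fasta
#' @param domains Tibble with at least `seq_id` and `sequence` columns
#'   (as produced by [excise_sensors()]).
#' @export
write_sensor_fasta <- function(domains, path) {
  assert_columns(domains, c("seq_id", "sequence"), "sensor domain table")
  set <- Biostrings::AAStringSet(setNames(domains$sequence, domains$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a sensor profile matrix to disk
#'
#' Two dialects: `dense` (row ids in the first column, one column per
#' cluster) and `sparse` triplets (`metagenome_id`, `cluster_id`, `value`;
#' zeros omitted).
#'
#' @param m A [sensor_profile] object.
#' @param path Output TSV path.
#' @param format `"dense"` or `"sparse"`.
#' @export
write_profile_matrix <- function(m, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "sensor_profile"))
  if (format == "dense") {
    df <- as_tibble(m$values, rownames = "metagenome_id")
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    long <- tidy(m) |> filter(.data$value > 0)
    readr::write_tsv(long, path, progress = FALSE)
  }
  invisible(path)
}
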