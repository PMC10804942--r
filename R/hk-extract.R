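# Histidine-kinase identification and sensory-domain excision.
#
# HK proteins are recognized by the co-occurrence of their two conserved
# domains (HATPase PF02518 and HisKA PF00512); everything between/around
# them that matches a curated sensor accession list is a sensory domain.
# Coordinates are 1-based and inclusive on both ends throughout (the
# Pfam/HMMER alignment-coordinate convention).

#' Configuration for HK identification and excision
#'
#' @param conserved_accs Pfam accessions whose joint presence defines an HK
#'   protein. Defaults to HATPase (PF02518) and HisKA (PF00512).
#' @param sensor_accs Pfam accessions recognized as sensory domains (a
#'   curated list for real data; the generator's accession set for synthetic
#'   corpora). Must be disjoint from `conserved_accs`. Hits matching neither
#'   set are ignored.
#' @return An `hk_config` object.
#' @export
hk_config <- function(conserved_accs = HK_CONSERVED_ACCS, sensor_accs) {
  if (length(conserved_accs) < 1) abort("`conserved_accs` must be nonempty")
  if (missing(sensor_accs) || length(sensor_accs) < 1) {
    abort("`sensor_accs` must be a nonempty accession vector")
  }
  overlap <- intersect(conserved_accs, sensor_accs)
  if (length(overlap) > 0) {
    abort(sprintf(
      "conserved and sensor accession sets must be disjoint (shared: %s)",
      paste(overlap, collapse = ", ")
    ))
  }
  structure(
    list(
      conserved_accs = unique(conserved_accs),
      sensor_accs = unique(sensor_accs)
    ),
    class = "hk_config"
  )
}

validate_gene_records <- function(genes) {
  assert_columns(genes, ANNOTATION_COLS, "annotation table")
  bad <- genes |>
    filter(
      .data$ali_start < 1 | .data$ali_end < .data$ali_start |
        .data$ali_end > .data$protein_length |
        .data$gene_copy_number < 0
    )
  if (nrow(bad) > 0) {
    abort(sprintf(
      "malformed domain coordinates or copy number for gene(s): %s",
      paste(unique(head(bad$gene_id, 5)), collapse = ", ")
    ))
  }
  invisible(genes)
}

#' Identify histidine-kinase proteins
#'
#' Keeps exactly those genes whose hit set contains at least one hit for
#' each conserved accession. Output row order follows input order
#' (order-stable), one row per retained domain hit.
#'
#' @param genes Annotation tibble (one row per domain hit).
#' @param cfg An [hk_config()].
#' @return The subset of `genes` belonging to HK proteins.
#' @export
identify_hk <- function(genes, cfg) {
  stopifnot(inherits(cfg, "hk_config"))
  if (nrow(genes) == 0) return(genes)
  validate_gene_records(genes)
  hk_genes <- genes |>
    filter(.data$pfam_acc %in% cfg$conserved_accs) |>
    distinct(.data$metagenome_id, .data$gene_id, .data$pfam_acc) |>
    count(.data$metagenome_id, .data$gene_id) |>
    filter(.data$n == length(cfg$conserved_accs)) |>
    select("metagenome_id", "gene_id")
  semi_join(genes, hk_genes, by = c("metagenome_id", "gene_id"))
}

#' Excise sensory domains from HK proteins
#'
#' For every hit whose accession is in the sensor set, the corresponding
#' substring of the protein sequence is cut out. Conserved-domain hits are
#' never excised and unknown accessions are ignored. Overlapping sensor
#' hits within one gene are resolved by dropping the shorter hit entirely
#' (ties: the later-starting hit), with a warning, so excised residues
#' within a gene never overlap. Domains are returned in coordinate order
#' and indexed along the protein.
#'
#' @param hk_genes Annotation tibble of HK genes (from [identify_hk()]).
#' @param proteins Named character vector (or tibble with `gene_id`,
#'   `sequence`) of full-length protein sequences. Optional: when `NULL`,
#'   sequences are taken from a `sequence` column of `hk_genes` if present,
#'   otherwise an error is raised.
#' @param cfg An [hk_config()].
#' @return Tibble of sensor domains: `seq_id` (`gene_id|index|pfam_acc`),
#'   `gene_id`, `metagenome_id`, `domain_index`, `pfam_acc`, `ali_start`,
#'   `ali_end`, `sequence`, `copy_number`.
#' @export
excise_sensors <- function(hk_genes, proteins, cfg) {
  stopifnot(inherits(cfg, "hk_config"))
  empty <- tibble(
    seq_id = character(), gene_id = character(), metagenome_id = character(),
    domain_index = integer(), pfam_acc = character(),
    ali_start = integer(), ali_end = integer(),
    sequence = character(), copy_number = numeric()
  )
  if (nrow(hk_genes) == 0) return(empty)
  validate_gene_records(hk_genes)
  if (is.data.frame(proteins)) {
    proteins <- setNames(proteins$sequence, proteins$gene_id)
  }

  hits <- hk_genes |>
    filter(.data$pfam_acc %in% cfg$sensor_accs) |>
    arrange(.data$gene_id, .data$ali_start, .data$ali_end, .data$pfam_acc)
  if (nrow(hits) == 0) return(empty)

  missing_seq <- setdiff(unique(hits$gene_id), names(proteins))
  if (length(missing_seq) > 0) {
    abort(sprintf(
      "no protein sequence for gene(s): %s",
      paste(head(missing_seq, 5), collapse = ", ")
    ))
  }
  too_long <- hits |>
    filter(.data$ali_end > nchar(proteins[.data$gene_id]))
  if (nrow(too_long) > 0) {
    abort(sprintf(
      "domain coordinates exceed sequence length for gene(s): %s",
      paste(unique(head(too_long$gene_id, 5)), collapse = ", ")
    ))
  }

  # Resolve overlaps per gene: repeatedly drop the shorter of an
  # overlapping pair (later-starting on ties).
  resolve <- function(df, gene) {
    repeat {
      if (nrow(df) < 2) return(df)
      ov <- which(df$ali_start[-1] <= df$ali_end[-nrow(df)])
      if (length(ov) == 0) return(df)
      i <- ov[1]; j <- i + 1L
      len_i <- df$ali_end[i] - df$ali_start[i]
      len_j <- df$ali_end[j] - df$ali_start[j]
      drop <- if (len_j <= len_i) j else i
      warn(sprintf(
        "dropping overlapping sensor hit %s:%d-%d in gene %s",
        df$pfam_acc[drop], df$ali_start[drop], df$ali_end[drop], gene
      ))
      df <- df[-drop, , drop = FALSE]
    }
  }
  hits <- hits |>
    group_by(.data$gene_id) |>
    group_modify(~ resolve(.x, .y$gene_id)) |>
    ungroup()

  hits |>
    arrange(match(.data$gene_id, unique(hk_genes$gene_id)), .data$ali_start) |>
    group_by(.data$gene_id) |>
    mutate(domain_index = row_number()) |>
    ungroup() |>
    mutate(
      sequence = unname(substr(proteins[.data$gene_id], .data$ali_start,
                               .data$ali_end)),
      seq_id = sprintf("%s|%d|%s", .data$gene_id, .data$domain_index,
                       .data$pfam_acc),
      copy_number = .data$gene_copy_number
    ) |>
    select(
      "seq_id", "gene_id", "metagenome_id", "domain_index", "pfam_acc",
      "ali_start", "ali_end", "sequence", "copy_number"
    )
}

#' Histogram of sensor-domain counts per HK protein
#'
#' Counts, for each number of sensory domains, how many HK proteins carry
#' exactly that many. HK genes with no sensor hit contribute to the zero
#' bin, so the histogram total equals the number of HK proteins.
#'
#' @param hk_genes Annotation tibble of HK genes (from [identify_hk()]).
#' @param cfg An [hk_config()].
#' @return Tibble with `n_sensor_domains` and `n_proteins`, ascending.
#' @export
count_sensor_domains <- function(hk_genes, cfg) {
  stopifnot(inherits(cfg, "hk_config"))
  if (nrow(hk_genes) == 0) {
    return(tibble(n_sensor_domains = integer(), n_proteins = integer()))
  }
  hk_genes |>
    group_by(.data$metagenome_id, .data$gene_id) |>
    summarise(
      n_sensor_domains = sum(.data$pfam_acc %in% cfg$sensor_accs),
      .groups = "drop"
    ) |>
    count(.data$n_sensor_domains, name = "n_proteins") |>
    arrange(.data$n_sensor_domains)
}

#' Cross-tabulate Pfam accessions against sequence clusters
#'
#' For each sensor Pfam accession, counts the number of distinct clusters
#' that contain at least one domain annotated with it. A cluster holding
#' two accessions increments both counts.
#'
#' @param assignment A [cluster_assignment] covering `domains`.
#' @param domains Sensor-domain tibble (with `seq_id` and `pfam_acc`).
#' @return Tibble with `pfam_acc` and `n_clusters`, descending by count.
#' @export
pfam_cluster_crosstab <- function(assignment, domains) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cluster_of <- assignment$cluster_of
  unassigned <- setdiff(domains$seq_id, names(cluster_of))
  if (length(unassigned) > 0) {
    abort(sprintf(
      "domain(s) without cluster assignment: %s",
      paste(head(unassigned, 5), collapse = ", ")
    ))
  }
  domains |>
    mutate(cluster_id = cluster_of[.data$seq_id]) |>
    distinct(.data$pfam_acc, .data$cluster_id) |>
    count(.data$pfam_acc, name = "n_clusters") |>
    arrange(desc(.data$n_clusters), .data$pfam_acc)
}
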