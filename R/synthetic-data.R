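# Synthetic corpus generator: domain-annotated metagenomes with planted
# sensor-family structure, so extraction, clustering, profiling and the
# models can all be tested against a known ground truth.

MAX_PROTEIN_LEN <- 5000L
BACKGROUND_ACC <- "PF99999"
HISKA_LEN <- 100L
HATPASE_LEN <- 111L
DOMAIN_LINKER <- 5L

#' Describe one synthetic ecosystem
#'
#' An ecosystem is a three-level GOLD-style path (e.g.
#' `"Host-associated:Human:Large Intestine"`) plus the generative knobs for
#' its samples: how many metagenomes, the expected abundance weights over the
#' shared pool of planted sensor families, the mean fraction of genes that
#' are histidine-kinase sensors, and the expected number of non-sensor
#' background genes per sample.
#'
#' @param name Ecosystem path, three ":"-separated levels.
#' @param n_metagenomes Number of samples to generate (may be 0).
#' @param cluster_weights Nonnegative weights over the family pool; per-sample
#'   family mixtures are Dirichlet-distributed around these (normalized)
#'   weights. Families with weight 0 never occur in the ecosystem.
#' @param sensor_fraction_mean Mean fraction of a sample's genes that are HK
#'   sensor genes, in (0, 1).
#' @param background_genes_mean Expected count of non-HK genes per sample.
#' @param physical_params Optional named list of `c(mean, sd)` pairs; each
#'   becomes a numeric metadata column drawn per sample.
#' @param condition Optional condition/disease label attached to every sample.
#' @return An `ecosystem_spec` object.
#' @export
ecosystem_spec <- function(name, n_metagenomes, cluster_weights,
                           sensor_fraction_mean = 0.05,
                           background_genes_mean = 400,
                           physical_params = NULL,
                           condition = NA_character_) {
  if (!is.character(name) || length(name) != 1) {
    abort("`name` must be a single ecosystem path string")
  }
  if (n_metagenomes < 0) abort("`n_metagenomes` must be >= 0")
  if (any(cluster_weights < 0) || sum(cluster_weights) <= 0) {
    abort("`cluster_weights` must be nonnegative with positive sum")
  }
  if (sensor_fraction_mean <= 0 || sensor_fraction_mean >= 1) {
    abort("`sensor_fraction_mean` must lie in (0, 1)")
  }
  if (background_genes_mean <= 0) abort("`background_genes_mean` must be positive")
  structure(
    list(
      name = name,
      n_metagenomes = as.integer(n_metagenomes),
      cluster_weights = cluster_weights / sum(cluster_weights),
      sensor_fraction_mean = sensor_fraction_mean,
      background_genes_mean = background_genes_mean,
      physical_params = physical_params,
      condition = condition
    ),
    class = "ecosystem_spec"
  )
}

#' Generate a pool of planted sensor families
#'
#' Draws `n_families` centroid sequences over the standard 20-letter
#' amino-acid alphabet, rejection-sampled so that every centroid pair is
#' less than 50% identical under global alignment — planted families are
#' therefore separable at any clustering identity threshold of 0.5 or more.
#' Family members are later drawn as centroid variants with at most
#' `mutation_rate` of their positions substituted, so within-family identity
#' never drops below `1 - mutation_rate`.
#'
#' @param n_families Number of families (>= 1).
#' @param seq_len_range Length range `c(min, max)` for centroids, residues.
#' @param mutation_rate Maximum substituted fraction for family variants,
#'   in `[0, 0.5)`.
#' @param seed Integer seed; the pool is deterministic given it.
#' @param pfam_accs Optional character vector of Pfam-style accessions, one
#'   per family (recycled assignments allowed: two families may share an
#'   accession, which is how Pfam-vs-cluster resolution experiments are
#'   built). Defaults to one synthetic accession per family.
#' @param max_attempts Rejection-sampling attempts per centroid before the
#'   pool is declared unattainable (error).
#' @return A `family_pool` object: a list with a `families` tibble
#'   (`family_id`, `pfam_acc`, `centroid`, `length`) and the `mutation_rate`.
#' @export
make_family_pool <- function(n_families, seq_len_range = c(60L, 120L),
                             mutation_rate = 0.05, seed = 1,
                             pfam_accs = NULL, max_attempts = 200L) {
  if (n_families < 1) abort("`n_families` must be >= 1")
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    abort("`mutation_rate` must lie in [0, 0.5)")
  }
  if (length(seq_len_range) != 2 || seq_len_range[1] < 1 ||
      seq_len_range[2] < seq_len_range[1]) {
    abort("`seq_len_range` must be c(min, max) with min >= 1")
  }
  if (is.null(pfam_accs)) {
    pfam_accs <- sprintf("PF9%04d", seq_len(n_families))
  }
  if (length(pfam_accs) != n_families) {
    abort("`pfam_accs` must have one entry per family")
  }

  set.seed(as.integer(seed))
  centroids <- character(0)
  for (k in seq_len(n_families)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      len <- sample(seq_len_range[1]:seq_len_range[2], 1L)
      cand <- random_aa_string(len)
      if (length(centroids) == 0) {
        ok <- TRUE
      } else {
        stats <- .nw_align_batch(cand, centroids)
        ok <- all(stats[, "identity"] < 0.5)
      }
      if (ok) {
        centroids <- c(centroids, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "could not draw %d mutually separable centroids at lengths %d-%d",
        n_families, seq_len_range[1], seq_len_range[2]
      ))
    }
  }

  structure(
    list(
      families = tibble(
        family_id = sprintf("fam%04d", seq_len(n_families)),
        pfam_acc = pfam_accs,
        centroid = centroids,
        length = nchar(centroids)
      ),
      mutation_rate = mutation_rate
    ),
    class = "family_pool"
  )
}

# Lay out one HK gene: sensor domains first (with linkers), then the two
# conserved domains. Returns hit rows and the protein length.
# Full-length protein string consistent with a layout: random residues
# with the sensor-domain sequences spliced in at their coordinates.
build_protein <- function(lay, sensor_seqs) {
  s <- random_aa_string(lay$protein_length)
  for (j in seq_along(sensor_seqs)) {
    substr(s, lay$sensors[[j]][["start"]], lay$sensors[[j]][["end"]]) <-
      sensor_seqs[[j]]
  }
  s
}

hk_gene_layout <- function(sensor_lens) {
  pos <- 10L
  rows <- vector("list", length(sensor_lens))
  i <- 0L
  for (len in sensor_lens) {
    i <- i + 1L
    start <- pos + 1L
    end <- start + len - 1L
    rows[[i]] <- c(start = start, end = end)
    pos <- end + DOMAIN_LINKER
  }
  hiska <- c(start = pos + 1L, end = pos + HISKA_LEN)
  pos <- hiska[["end"]] + DOMAIN_LINKER
  hatpase <- c(start = pos + 1L, end = pos + HATPASE_LEN)
  list(
    sensors = rows,
    hiska = hiska,
    hatpase = hatpase,
    protein_length = hatpase[["end"]] + 10L
  )
}

#' Generate a synthetic metagenome corpus
#'
#' Produces the three flat inputs the pipeline consumes — a gene/domain
#' annotation table, sensor-domain sequences, and sample metadata — plus the
#' generating ground truth. Every HK gene carries both conserved domains
#' (PF02518, PF00512) and, by default, one sensor domain drawn from the
#' ecosystem's family mixture; per-gene copy numbers are geometric with
#' mean 2. The result is deterministic given `seed`.
#'
#' @param specs List of [ecosystem_spec()] objects with distinct names.
#' @param pool A [make_family_pool()] pool; each ecosystem's
#'   `cluster_weights` must have one entry per pool family.
#' @param seed Integer seed.
#' @param dirichlet_concentration Concentration of the per-sample Dirichlet
#'   around each ecosystem's weights; larger means samples hew closer to the
#'   ecosystem mean.
#' @param zero_sensor_prob Probability that an HK gene carries no sensor
#'   domain (conserved domains only).
#' @return A `sensor_corpus`: list with tibbles `annotations`, `sensors`,
#'   `proteins` (full-length HK protein sequences consistent with the
#'   annotated coordinates), `metadata`, the `truth` list (`family_of_sequence`,
#'   `ecosystem_of_sample`, `planted_fractions`, `sensor_fraction`), and the
#'   `pool`.
#' @export
generate_corpus <- function(specs, pool, seed = 1,
                            dirichlet_concentration = 50,
                            zero_sensor_prob = 0) {
  if (inherits(specs, "ecosystem_spec")) specs <- list(specs)
  if (length(specs) == 0) abort("`specs` must be nonempty")
  stopifnot(inherits(pool, "family_pool"))
  nm <- map_chr(specs, "name")
  if (anyDuplicated(nm)) abort("ecosystem names must be distinct")
  n_fam <- nrow(pool$families)
  for (s in specs) {
    if (length(s$cluster_weights) != n_fam) {
      abort("each spec's `cluster_weights` must have one entry per pool family")
    }
  }

  set.seed(as.integer(seed))
  ann <- list(); sens <- list(); meta <- list()
  planted <- list(); sensor_frac <- list(); prot <- list()
  fam_of_seq <- character(0)
  mg_counter <- 0L

  for (s in specs) {
    for (i in seq_len(s$n_metagenomes)) {
      mg_counter <- mg_counter + 1L
      mg <- sprintf("MG%05d", mg_counter)
      f <- s$sensor_fraction_mean
      n_total <- max(1L, rpois(1L, s$background_genes_mean / (1 - f)))
      n_hk <- rbinom(1L, n_total, f)
      n_bg <- n_total - n_hk

      # per-sample family mixture
      alpha <- dirichlet_concentration * s$cluster_weights
      g <- rgamma(n_fam, shape = alpha, rate = 1)
      p_fam <- if (sum(g) > 0) g / sum(g) else s$cluster_weights

      gene_rows <- list(); sens_rows <- list(); prot_rows <- list()
      hk_fam <- character(0); hk_copy <- numeric(0); hk_has_sensor <- logical(0)

      for (gidx in seq_len(n_hk)) {
        gene_id <- sprintf("%s_g%05d", mg, gidx)
        fam_idx <- sample.int(n_fam, 1L, prob = p_fam)
        fam <- pool$families$family_id[fam_idx]
        copy <- 1 + rgeom(1L, 0.5)
        has_sensor <- runif(1L) >= zero_sensor_prob
        if (has_sensor) {
          seq <- mutate_sequence(pool$families$centroid[fam_idx], pool$mutation_rate)
          lay <- hk_gene_layout(nchar(seq))
          sensor_hit <- tibble(
            metagenome_id = mg, gene_id = gene_id,
            pfam_acc = pool$families$pfam_acc[fam_idx],
            ali_start = lay$sensors[[1]][["start"]],
            ali_end = lay$sensors[[1]][["end"]],
            gene_copy_number = copy, protein_length = lay$protein_length
          )
          seq_id <- sprintf("%s|1|%s", gene_id, pool$families$pfam_acc[fam_idx])
          sens_rows[[length(sens_rows) + 1L]] <- tibble(
            seq_id = seq_id, gene_id = gene_id, metagenome_id = mg,
            domain_index = 1L, pfam_acc = pool$families$pfam_acc[fam_idx],
            ali_start = sensor_hit$ali_start, ali_end = sensor_hit$ali_end,
            sequence = seq, copy_number = copy
          )
          fam_of_seq[seq_id] <- fam
          protein_seq <- build_protein(lay, seq)
        } else {
          lay <- hk_gene_layout(integer(0))
          sensor_hit <- NULL
          protein_seq <- build_protein(lay, character(0))
        }
        prot_rows[[length(prot_rows) + 1L]] <- tibble(
          gene_id = gene_id, sequence = protein_seq
        )
        conserved <- tibble(
          metagenome_id = mg, gene_id = gene_id,
          pfam_acc = c("PF00512", "PF02518"),
          ali_start = c(lay$hiska[["start"]], lay$hatpase[["start"]]),
          ali_end = c(lay$hiska[["end"]], lay$hatpase[["end"]]),
          gene_copy_number = copy, protein_length = lay$protein_length
        )
        gene_rows[[length(gene_rows) + 1L]] <- bind_rows(sensor_hit, conserved)
        hk_fam <- c(hk_fam, fam); hk_copy <- c(hk_copy, copy)
        hk_has_sensor <- c(hk_has_sensor, has_sensor)
      }

      bg_copy <- 1 + rgeom(n_bg, 0.5)
      if (n_bg > 0) {
        bg_len <- sample(150:600, n_bg, replace = TRUE)
        gene_rows[[length(gene_rows) + 1L]] <- tibble(
          metagenome_id = mg,
          gene_id = sprintf("%s_b%05d", mg, seq_len(n_bg)),
          pfam_acc = BACKGROUND_ACC,
          ali_start = 1L, ali_end = bg_len,
          gene_copy_number = bg_copy, protein_length = bg_len
        )
      }

      total_copy <- sum(hk_copy) + sum(bg_copy)
      contributing <- hk_has_sensor
      pf <- tibble(
        metagenome_id = mg,
        family_id = pool$families$family_id,
        fraction = map_dbl(pool$families$family_id, function(fm) {
          sum(hk_copy[contributing & hk_fam == fm]) / total_copy
        })
      )
      planted[[length(planted) + 1L]] <- pf
      sensor_frac[[length(sensor_frac) + 1L]] <- tibble(
        metagenome_id = mg,
        sensor_fraction = sum(hk_copy[contributing]) / total_copy,
        total_copy = total_copy
      )

      phys <- map_dbl(s$physical_params %||% list(), function(ms) {
        rnorm(1L, ms[[1]], ms[[2]])
      })
      meta_row <- tibble(metagenome_id = mg, ecosystem = s$name,
                         condition = s$condition)
      if (length(phys) > 0) {
        meta_row <- bind_cols(meta_row, as_tibble(as.list(phys)))
      }
      meta[[length(meta) + 1L]] <- meta_row
      ann[[length(ann) + 1L]] <- bind_rows(gene_rows)
      if (length(sens_rows)) sens[[length(sens) + 1L]] <- bind_rows(sens_rows)
      if (length(prot_rows)) prot[[length(prot) + 1L]] <- bind_rows(prot_rows)
    }
  }

  empty_ann <- tibble(
    metagenome_id = character(), gene_id = character(), pfam_acc = character(),
    ali_start = integer(), ali_end = integer(),
    gene_copy_number = numeric(), protein_length = integer()
  )
  empty_sens <- tibble(
    seq_id = character(), gene_id = character(), metagenome_id = character(),
    domain_index = integer(), pfam_acc = character(),
    ali_start = integer(), ali_end = integer(),
    sequence = character(), copy_number = numeric()
  )

  metadata <- if (length(meta)) bind_rows(meta) else
    tibble(metagenome_id = character(), ecosystem = character(),
           condition = character())

  structure(
    list(
      annotations = if (length(ann)) bind_rows(ann) else empty_ann,
      sensors = if (length(sens)) bind_rows(sens) else empty_sens,
      proteins = if (length(prot)) bind_rows(prot) else
        tibble(gene_id = character(), sequence = character()),
      metadata = metadata,
      truth = list(
        family_of_sequence = fam_of_seq,
        ecosystem_of_sample = setNames(metadata$ecosystem, metadata$metagenome_id),
        planted_fractions = if (length(planted)) bind_rows(planted) else
          tibble(metagenome_id = character(), family_id = character(),
                 fraction = numeric()),
        sensor_fraction = if (length(sensor_frac)) bind_rows(sensor_frac) else
          tibble(metagenome_id = character(), sensor_fraction = numeric(),
                 total_copy = numeric())
      ),
      pool = pool
    ),
    class = "sensor_corpus"
  )
}

#' Inject multi-domain histidine kinases into a corpus
#'
#' Real HK proteins can carry anywhere from zero to 32 sensory domains;
#' the generator emits single-sensor genes, and this step rebuilds a random
#' subset of them with additional same-family sensor domains (up to
#' `max_domains` per gene) so that domain-count distributions and multi-hit
#' excision are exercised. When any genes are selected, the first selected
#' gene receives exactly `max_domains` domains. Injected coordinate
#' intervals are non-overlapping and ordered by construction, and the
#' protein is re-laid-out to fit them; `max_domains` that cannot fit under
#' the maximum protein length is an error.
#'
#' @param corpus A `sensor_corpus`.
#' @param max_domains Maximum sensor domains per gene (>= 1).
#' @param seed Integer seed.
#' @param prob Probability that an eligible single-sensor HK gene is
#'   expanded.
#' @return The modified `sensor_corpus`. Planted per-family fractions are
#'   unchanged: extra domains always come from the gene's own family, and
#'   profiling counts a gene once per family.
#' @export
inject_multidomain_hk <- function(corpus, max_domains, seed = 1, prob = 0.25) {
  stopifnot(inherits(corpus, "sensor_corpus"))
  if (max_domains < 1) abort("`max_domains` must be >= 1")
  max_sensor_len <- max(corpus$pool$families$length)
  need <- 10L + max_domains * (max_sensor_len + DOMAIN_LINKER) +
    (HISKA_LEN + DOMAIN_LINKER) + (HATPASE_LEN + DOMAIN_LINKER) + 10L
  if (need > MAX_PROTEIN_LEN) {
    abort(sprintf(
      "max_domains = %d cannot fit in a protein of length <= %d",
      max_domains, MAX_PROTEIN_LEN
    ))
  }
  if (max_domains == 1 || nrow(corpus$sensors) == 0) return(corpus)

  set.seed(as.integer(seed))
  eligible <- corpus$sensors$seq_id  # one row per single-sensor gene
  pick <- runif(length(eligible)) < prob
  if (!any(pick)) pick[1L] <- TRUE
  chosen <- which(pick)
  n_extra <- integer(length(chosen))
  n_extra[1L] <- max_domains - 1L
  if (length(chosen) > 1) {
    n_extra[-1L] <- sample.int(max_domains - 1L, length(chosen) - 1L,
                               replace = TRUE)
  }

  fam_tbl <- corpus$pool$families
  fam_of_seq <- corpus$truth$family_of_sequence
  ann <- corpus$annotations
  sens <- corpus$sensors
  prot <- corpus$proteins

  for (k in seq_along(chosen)) {
    row <- sens[chosen[k], ]
    fam <- fam_of_seq[[row$seq_id]]
    fam_idx <- match(fam, fam_tbl$family_id)
    extra_seqs <- map_chr(seq_len(n_extra[k]), function(j) {
      mutate_sequence(fam_tbl$centroid[fam_idx], corpus$pool$mutation_rate)
    })
    all_seqs <- c(row$sequence, extra_seqs)
    lay <- hk_gene_layout(nchar(all_seqs))

    # drop the gene's old rows, rebuild with the new layout
    gene_mask <- ann$gene_id == row$gene_id
    keep_ann <- ann[!gene_mask, ]
    starts <- map_int(lay$sensors, function(x) x[["start"]])
    ends <- map_int(lay$sensors, function(x) x[["end"]])
    new_ann <- tibble(
      metagenome_id = row$metagenome_id, gene_id = row$gene_id,
      pfam_acc = c(rep(row$pfam_acc, length(all_seqs)), "PF00512", "PF02518"),
      ali_start = c(starts, lay$hiska[["start"]], lay$hatpase[["start"]]),
      ali_end = c(ends, lay$hiska[["end"]], lay$hatpase[["end"]]),
      gene_copy_number = row$copy_number,
      protein_length = lay$protein_length
    )
    ann <- bind_rows(keep_ann, new_ann)

    new_ids <- sprintf("%s|%d|%s", row$gene_id, seq_along(all_seqs), row$pfam_acc)
    sens <- sens[-chosen[k], ]
    new_sens <- tibble(
      seq_id = new_ids, gene_id = row$gene_id,
      metagenome_id = row$metagenome_id,
      domain_index = seq_along(all_seqs), pfam_acc = row$pfam_acc,
      ali_start = starts, ali_end = ends,
      sequence = all_seqs, copy_number = row$copy_number
    )
    sens <- bind_rows(sens, new_sens)
    fam_of_seq <- fam_of_seq[names(fam_of_seq) != row$seq_id]
    fam_of_seq[new_ids] <- fam
    prot$sequence[prot$gene_id == row$gene_id] <- build_protein(lay, all_seqs)

    # recompute chosen indices shift: rebuild mask positions
    if (k < length(chosen)) {
      chosen[(k + 1):length(chosen)] <-
        match(eligible[pick][(k + 1):length(chosen)], sens$seq_id)
    }
  }

  # enforce the non-overlap invariant on everything we rebuilt
  bad <- sens |>
    arrange(.data$gene_id, .data$ali_start) |>
    group_by(.data$gene_id) |>
    filter(n() > 1, .data$ali_start <= lag(.data$ali_end, default = -1L)) |>
    ungroup()
  if (nrow(bad) > 0) {
    abort("internal error: injected domain intervals overlap")
  }

  corpus$annotations <- ann
  corpus$sensors <- sens
  corpus$proteins <- prot
  corpus$truth$family_of_sequence <- fam_of_seq
  corpus
}

#' Per-metagenome total gene copy number
#'
#' Sums the copy-number estimate over distinct genes (the annotation table
#' has one row per domain hit, so genes are first deduplicated).
#'
#' @param annotations Annotation tibble.
#' @return Tibble with `metagenome_id` and `total_copy`.
#' @export
gene_copy_totals <- function(annotations) {
  assert_columns(annotations, c("metagenome_id", "gene_id", "gene_copy_number"),
                 "annotation table")
  annotations |>
    distinct(.data$metagenome_id, .data$gene_id, .data$gene_copy_number) |>
    group_by(.data$metagenome_id) |>
    summarise(total_copy = sum(.data$gene_copy_number), .groups = "drop")
}

#' Write a synthetic corpus to a directory
#'
#' Emits the pipeline's flat-file dialects: `annotations.tsv`,
#' `sensors.faa`, `metadata.tsv` and `truth.json`.
#'
#' @param corpus A `sensor_corpus`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "sensor_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotations = file.path(dir, "annotations.tsv"),
    sensors = file.path(dir, "sensors.faa"),
    proteins = file.path(dir, "proteins.faa"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_annotations(corpus$annotations, paths[["annotations"]])
  write_sensor_fasta(corpus$sensors, paths[["sensors"]])
  write_sensor_fasta(
    corpus$proteins |> mutate(seq_id = .data$gene_id),
    paths[["proteins"]]
  )
  write_metadata(corpus$metadata, paths[["metadata"]])
  jsonlite::write_json(
    list(
      family_of_sequence = as.list(corpus$truth$family_of_sequence),
      ecosystem_of_sample = as.list(corpus$truth$ecosystem_of_sample),
      planted_fractions = corpus$truth$planted_fractions,
      sensor_fraction = corpus$truth$sensor_fraction
    ),
    paths[["truth"]],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
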