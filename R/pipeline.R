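# End-to-end orchestration: one configuration object drives
# simulate/ingest -> extract -> cluster -> profile -> metrics -> train ->
# explain, with every artifact checksummed into a manifest.

default_run_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_families = 24L,
      seq_len_range = c(60L, 120L),
      mutation_rate = 0.05,
      dirichlet_concentration = 50,
      max_domains = 4L,
      inject_prob = 0.1,
      ecosystems = NULL  # list of ecosystem_spec() or arg lists
    ),
    inputs = list(annotations = NULL, proteins = NULL, metadata = NULL,
                  sensor_accs = NULL),
    cluster = list(min_identity = 0.5, coverage_mode = "bidirectional",
                   coverage_fraction = 0.8, backend = "greedy",
                   tool_path = "mmseqs"),
    profile = list(min_prevalence = 1L, min_per_class = 0L,
                   drop_labels = "Unclassified", label_field = "ecosystem"),
    metrics = list(by = "ecosystem", rarity_max_ecosystems = 1L),
    train = list(enabled = TRUE, label_field = "ecosystem",
                 learning_rate = 0.1, tree_depth = 6, l2_leaf_reg = 1,
                 nrounds = 150L,
                 fractions = c(train = 0.7, test = 0.2, validation = 0.1)),
    explain = list(enabled = TRUE, top = 20L, perplexity = 30)
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the stage defaults; unknown keys at either
#' level are rejected so typos cannot silently fall back to defaults.
#' Every random stage derives its seed from the single `seed` entry.
#'
#' @param ... Named stage blocks (`seed`, `simulate`, `inputs`, `cluster`,
#'   `profile`, `metrics`, `train`, `explain`), each a named list of
#'   overrides.
#' @return A `run_config` object.
#' @export
run_config <- function(...) {
  user <- list(...)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in names(user)) {
    if (key == "seed") {
      base$seed <- as.integer(user$seed)
      next
    }
    sub_unknown <- setdiff(names(user[[key]]), names(base[[key]]))
    if (length(sub_unknown) > 0) {
      abort(sprintf("unknown config key(s) under '%s': %s", key,
                    paste(sub_unknown, collapse = ", ")))
    }
    base[[key]] <- modifyList(base[[key]], user[[key]])
  }
  structure(base, class = "run_config")
}

#' Validate pipeline input files
#'
#' Schema checks with per-line diagnostics for the three flat inputs:
#' annotation TSV (column presence, coordinate sanity, copy numbers),
#' metadata TSV (required columns), and sensor/protein FASTA (duplicate
#' ids, empty sequences).
#'
#' @param annotations,metadata,fasta Optional file paths; only supplied
#'   ones are checked.
#' @return Tibble with `file`, `line`, `problem`; zero rows when all
#'   supplied inputs are well formed.
#' @export
validate_inputs <- function(annotations = NULL, metadata = NULL,
                            fasta = NULL) {
  issues <- list()
  note <- function(file, line, problem) {
    issues[[length(issues) + 1L]] <<- tibble(
      file = file, line = as.integer(line), problem = problem
    )
  }

  if (!is.null(annotations)) {
    df <- readr::read_tsv(annotations, show_col_types = FALSE,
                          progress = FALSE)
    missing <- setdiff(ANNOTATION_COLS, names(df))
    if (length(missing) > 0) {
      note(annotations, 1L,
           sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    } else {
      bad_coord <- which(df$ali_end < df$ali_start | df$ali_start < 1)
      for (i in bad_coord) {
        note(annotations, i + 1L,
             sprintf("gene %s: end %d < start %d or start < 1",
                     df$gene_id[i], df$ali_end[i], df$ali_start[i]))
      }
      bad_len <- which(df$ali_end > df$protein_length)
      for (i in bad_len) {
        note(annotations, i + 1L,
             sprintf("gene %s: hit end %d exceeds protein length %d",
                     df$gene_id[i], df$ali_end[i], df$protein_length[i]))
      }
      bad_copy <- which(df$gene_copy_number < 0)
      for (i in bad_copy) {
        note(annotations, i + 1L,
             sprintf("gene %s: negative copy number", df$gene_id[i]))
      }
    }
  }

  if (!is.null(metadata)) {
    df <- readr::read_tsv(metadata, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(c("metagenome_id", "ecosystem"), names(df))
    if (length(missing) > 0) {
      note(metadata, 1L,
           sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    } else if (anyDuplicated(df$metagenome_id)) {
      dup <- which(duplicated(df$metagenome_id))
      for (i in dup) {
        note(metadata, i + 1L,
             sprintf("duplicate metagenome id %s", df$metagenome_id[i]))
      }
    }
  }

  if (!is.null(fasta)) {
    lines <- readLines(fasta)
    headers <- which(startsWith(lines, ">"))
    ids <- sub("^>", "", lines[headers])
    dup <- which(duplicated(ids))
    for (i in dup) {
      note(fasta, headers[i], sprintf("duplicate FASTA id %s", ids[i]))
    }
    ends <- c(headers[-1] - 1L, length(lines))
    for (j in seq_along(headers)) {
      body <- lines[setdiff(seq(headers[j], ends[j]), headers[j])]
      if (sum(nchar(body)) == 0) {
        note(fasta, headers[j], sprintf("empty sequence for id %s", ids[j]))
      }
    }
  }

  if (length(issues) == 0) {
    tibble(file = character(), line = integer(), problem = character())
  } else {
    bind_rows(issues)
  }
}

# Accept ecosystem definitions as spec objects, argument lists, or the
# row-wise data frame a JSON config parses into.
as_ecosystem_specs <- function(ecosystems) {
  if (is.data.frame(ecosystems)) {
    ecosystems <- lapply(seq_len(nrow(ecosystems)), function(i) {
      row <- lapply(ecosystems, function(col) {
        v <- col[[i]]
        if (is.list(v) && length(v) == 1 && !is.list(v[[1]])) v[[1]] else v
      })
      row[!vapply(row, function(v) is.null(v) ||
                    (length(v) == 1 && !is.list(v) && is.na(v)), logical(1))]
    })
  }
  map(ecosystems, function(s) {
    if (inherits(s, "ecosystem_spec")) s else do.call(ecosystem_spec, s)
  })
}

write_stage <- function(manifest, stage, path) {
  bind_rows(manifest, tibble(
    stage = stage, file = basename(path),
    md5 = unname(tools::md5sum(path))
  ))
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or ingest flat files),
#' extract, cluster, profile, metrics and optionally train and explain —
#' writing every stage artifact under `outdir` and an md5 manifest
#' (`manifest.json`) listing them. Re-running with an identical
#' configuration reproduces the checksums of every stage. A stage failure
#' propagates as an error naming the stage; artifacts already written are
#' retained.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with the stage results (`corpus`, `domains`,
#'   `assignment`, `profile`, `filtered`, `metrics`, `training`,
#'   `attribution`) and the `manifest` tibble.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble(stage = character(), file = character(),
                     md5 = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # --- simulate or ingest -------------------------------------------------
  if (!is.null(cfg$simulate$ecosystems)) {
    corpus <- stage("simulate", {
      sim <- cfg$simulate
      specs <- as_ecosystem_specs(sim$ecosystems)
      pool <- make_family_pool(
        n_families = sim$n_families, seq_len_range = sim$seq_len_range,
        mutation_rate = sim$mutation_rate, seed = derive_seed(cfg$seed, 1L)
      )
      corpus <- generate_corpus(
        specs, pool, seed = derive_seed(cfg$seed, 2L),
        dirichlet_concentration = sim$dirichlet_concentration
      )
      if (sim$max_domains > 1) {
        corpus <- inject_multidomain_hk(
          corpus, max_domains = sim$max_domains,
          seed = derive_seed(cfg$seed, 3L), prob = sim$inject_prob
        )
      }
      corpus
    })
    paths <- write_corpus(corpus, outdir)
    for (p in paths) manifest <- write_stage(manifest, "simulate", p)
    annotations <- corpus$annotations
    proteins <- setNames(corpus$proteins$sequence, corpus$proteins$gene_id)
    meta <- corpus$metadata
    sensor_accs <- unique(corpus$pool$families$pfam_acc)
  } else {
    corpus <- NULL
    stage("ingest", {
      for (p in c(cfg$inputs$annotations, cfg$inputs$proteins,
                  cfg$inputs$metadata)) {
        if (is.null(p) || !file.exists(p)) {
          abort(sprintf("missing input path: %s", p %||% "<unset>"))
        }
      }
    })
    annotations <- read_annotations(cfg$inputs$annotations)
    prot_tbl <- read_sensor_fasta(cfg$inputs$proteins)
    proteins <- setNames(prot_tbl$sequence, prot_tbl$seq_id)
    meta <- read_metadata(cfg$inputs$metadata)
    sensor_accs <- cfg$inputs$sensor_accs %||%
      setdiff(unique(annotations$pfam_acc),
              c(HK_CONSERVED_ACCS, BACKGROUND_ACC))
  }

  # --- extract ------------------------------------------------------------
  hkcfg <- hk_config(sensor_accs = sensor_accs)
  domains <- stage("extract", {
    hk <- identify_hk(annotations, hkcfg)
    excise_sensors(hk, proteins, hkcfg)
  })
  write_sensor_fasta(domains, file.path(outdir, "extracted_sensors.faa"))
  manifest <- write_stage(manifest, "extract",
                          file.path(outdir, "extracted_sensors.faa"))

  # --- cluster ------------------------------------------------------------
  params <- cluster_params(cfg$cluster$min_identity, cfg$cluster$coverage_mode,
                           cfg$cluster$coverage_fraction)
  assignment <- stage("cluster", {
    if (cfg$cluster$backend == "greedy") {
      cluster_sensors(domains, params)
    } else {
      cluster_external(file.path(outdir, "extracted_sensors.faa"), params,
                       tool_path = cfg$cluster$tool_path)
    }
  })
  clu_path <- file.path(outdir, "clusters.tsv")
  tidy(assignment) |> readr::write_tsv(clu_path, progress = FALSE)
  manifest <- write_stage(manifest, "cluster", clu_path)

  # --- profile ------------------------------------------------------------
  prof <- stage("profile", {
    build_matrix(domains, assignment, gene_copy_totals(annotations), meta)
  })
  filtered <- stage("profile", {
    prof |>
      filter_clusters(min_prevalence = cfg$profile$min_prevalence) |>
      filter_samples(min_per_class = cfg$profile$min_per_class,
                     drop_labels = cfg$profile$drop_labels,
                     label_field = cfg$profile$label_field)
  })
  mat_path <- file.path(outdir, "profile_matrix.tsv")
  write_profile_matrix(prof, mat_path, format = "dense")
  manifest <- write_stage(manifest, "profile", mat_path)

  # --- metrics ------------------------------------------------------------
  metrics <- stage("metrics", {
    list(
      table = ecosystem_metrics(prof, by = cfg$metrics$by),
      correlation = if (length(unique(meta[[cfg$metrics$by]])) >= 2) {
        ecosystem_correlation(prof, by = cfg$metrics$by)
      },
      rare = rare_cluster_enrichment(
        prof, by = cfg$metrics$by,
        rarity_max_ecosystems = cfg$metrics$rarity_max_ecosystems
      )
    )
  })
  met_path <- file.path(outdir, "ecosystem_metrics.tsv")
  readr::write_tsv(metrics$table, met_path, progress = FALSE)
  manifest <- write_stage(manifest, "metrics", met_path)

  # --- train --------------------------------------------------------------
  training <- NULL
  attribution <- NULL
  if (isTRUE(cfg$train$enabled)) {
    training <- stage("train", {
      tr <- cfg$train
      mcfg <- model_config(
        "multiclass", learning_rate = tr$learning_rate,
        tree_depth = tr$tree_depth, l2_leaf_reg = tr$l2_leaf_reg,
        nrounds = tr$nrounds, seed = derive_seed(cfg$seed, 4L)
      )
      labels <- setNames(as.character(filtered$meta[[tr$label_field]]),
                         filtered$meta$metagenome_id)
      split <- split_profile(filtered, tr$label_field,
                             fractions = tr$fractions,
                             seed = derive_seed(cfg$seed, 5L))
      gs <- grid_search(
        filtered$values[split$train, , drop = FALSE], labels[split$train],
        filtered$values[split$validation, , drop = FALSE],
        labels[split$validation], mcfg
      )
      eval <- evaluate(gs$model,
                       filtered$values[split$test, , drop = FALSE],
                       labels[split$test])
      list(model = gs$model, best_params = gs$best_params, split = split,
           eval = eval)
    })
    rep_path <- file.path(outdir, "classification_report.json")
    jsonlite::write_json(
      list(
        accuracy = training$eval$accuracy,
        macro_f1 = mean(training$eval$f1$f1, na.rm = TRUE),
        best_params = as.list(training$best_params),
        n_test = training$eval$n
      ),
      rep_path, auto_unbox = TRUE, digits = NA
    )
    conf_path <- file.path(outdir, "confusion_matrix.tsv")
    tidy(training$eval) |> readr::write_tsv(conf_path, progress = FALSE)
    manifest <- write_stage(manifest, "train", rep_path)
    manifest <- write_stage(manifest, "train", conf_path)
  }

  # --- explain ------------------------------------------------------------
  if (isTRUE(cfg$explain$enabled) && !is.null(training)) {
    attribution <- stage("explain", {
      attribute(training$model,
                filtered$values[training$split$test, , drop = FALSE])
    })
    rank_path <- file.path(outdir, "feature_ranking.tsv")
    rank_features(attribution, scope = "global") |>
      head(cfg$explain$top) |>
      readr::write_tsv(rank_path, progress = FALSE)
    manifest <- write_stage(manifest, "explain", rank_path)
    if (nrow(filtered$values) >= 3) {
      emb <- stage("explain", {
        embed_profile(filtered, seed = derive_seed(cfg$seed, 6L),
                      perplexity = cfg$explain$perplexity)
      })
      emb_path <- file.path(outdir, "embedding.tsv")
      readr::write_tsv(emb, emb_path, progress = FALSE)
      manifest <- write_stage(manifest, "explain", emb_path)
    }
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    corpus = corpus, domains = domains, assignment = assignment,
    profile = prof, filtered = filtered, metrics = metrics,
    training = training, attribution = attribution, manifest = manifest
  ))
}
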