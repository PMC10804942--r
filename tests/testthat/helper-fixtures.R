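# Shared fixture builders. Everything is generated in code at test time;
# the small corpora here mirror the generator defaults at reduced size so
# the suite stays fast.

# Disjoint-support corpus: each ecosystem draws from its own block of
# families, so classes are separable by construction.
disjoint_corpus <- function(n_classes = 4, per_class = 30, n_families = 12,
                            seed = 21, sensor_fraction = 0.12,
                            background_genes = 100, mutation_rate = 0.05) {
  stopifnot(n_families %% n_classes == 0)
  pool <- make_family_pool(n_families, c(60, 90), mutation_rate,
                           seed = seed + 1)
  block <- n_families / n_classes
  names <- c(
    "Environmental:Aquatic:Marine",
    "Environmental:Terrestrial:Soil",
    "Host-associated:Human:Large Intestine",
    "Engineered:Bioreactor:Anaerobic",
    "Environmental:Aquatic:River",
    "Host-associated:Human:Oral Cavity"
  )[seq_len(n_classes)]
  specs <- lapply(seq_len(n_classes), function(k) {
    w <- rep(0, n_families)
    w[((k - 1) * block + 1):(k * block)] <- 1
    ecosystem_spec(names[k], per_class, w,
                   sensor_fraction_mean = sensor_fraction,
                   background_genes_mean = background_genes)
  })
  generate_corpus(specs, pool, seed = seed)
}

# Run extraction + clustering + profiling on a corpus with the pool's
# accession set.
corpus_profile <- function(corpus, min_identity = 0.8, coverage = 0.8) {
  cfg <- hk_config(sensor_accs = unique(corpus$pool$families$pfam_acc))
  proteins <- setNames(corpus$proteins$sequence, corpus$proteins$gene_id)
  dom <- excise_sensors(identify_hk(corpus$annotations, cfg), proteins, cfg)
  asg <- cluster_sensors(dom, cluster_params(min_identity, "bidirectional",
                                             coverage))
  prof <- build_matrix(dom, asg, gene_copy_totals(corpus$annotations),
                       corpus$metadata)
  list(cfg = cfg, domains = dom, assignment = asg, profile = prof)
}

# Hand-built sensor profile from an explicit value matrix.
toy_profile <- function(values, ecosystems,
                        totals = rep(100, nrow(values))) {
  rownames(values) <- sprintf("MG%05d", seq_len(nrow(values)))
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("cluster%05d", seq_len(ncol(values)))
  }
  sensorscape:::new_sensor_profile(
    values,
    tibble::tibble(metagenome_id = rownames(values), ecosystem = ecosystems),
    stats::setNames(totals, rownames(values))
  )
}

# Minimal hand-written annotation fixture: three genes, one true HK.
toy_annotations <- function() {
  tibble::tribble(
    ~metagenome_id, ~gene_id, ~pfam_acc, ~ali_start, ~ali_end,
    ~gene_copy_number, ~protein_length,
    "M1", "g1", "PF02518", 201L, 300L, 2, 320L,
    "M1", "g1", "PF00512", 101L, 190L, 2, 320L,
    "M1", "g1", "PF90001", 5L, 64L, 2, 320L,
    "M1", "g2", "PF02518", 101L, 200L, 1, 220L,
    "M1", "g3", "PF90001", 10L, 60L, 3, 100L
  )
}
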