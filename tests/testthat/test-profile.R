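test_that("matrix values are copy fractions of the sample total", {
  dom <- tibble::tibble(
    seq_id = "g1|1|PF90001", gene_id = "g1", metagenome_id = "M1",
    copy_number = 5
  )
  asg <- sensorscape:::new_cluster_assignment(
    cluster_of = c("g1|1|PF90001" = "c1"), centroid_of = c(c1 = "g1|1|PF90001")
  )
  totals <- tibble::tibble(metagenome_id = c("M1", "M2"),
                           total_copy = c(100, 50))
  m <- build_matrix(dom, asg, totals)
  expect_equal(unname(m$values["M1", "c1"]), 0.05)
  # metagenome with no sensors keeps an all-zero row
  expect_equal(unname(m$values["M2", "c1"]), 0)
  expect_equal(dim(m), c(2L, 1L))

  expect_error(
    build_matrix(dom, asg, tibble::tibble(metagenome_id = "M1",
                                          total_copy = 0)),
    "positive total"
  )
  expect_error(
    build_matrix(dplyr::mutate(dom, seq_id = "other"), asg, totals),
    "without cluster assignment"
  )
})

test_that("a multi-cluster gene contributes its copy number to each cluster once", {
  dom <- tibble::tibble(
    seq_id = c("g1|1|A", "g1|2|A", "g1|3|B"),
    gene_id = "g1", metagenome_id = "M1", copy_number = 4
  )
  asg <- sensorscape:::new_cluster_assignment(
    cluster_of = c("g1|1|A" = "c1", "g1|2|A" = "c1", "g1|3|B" = "c2"),
    centroid_of = c(c1 = "g1|1|A", c2 = "g1|3|B")
  )
  totals <- tibble::tibble(metagenome_id = "M1", total_copy = 40)
  m <- build_matrix(dom, asg, totals)
  # two domains in c1 count the gene once; the c2 domain counts it again
  expect_equal(unname(m$values["M1", ]), c(0.1, 0.1))
})

test_that("conservation: row sums times totals equal sensor copy sums", {
  for (seed in c(5, 23)) {
    corpus <- disjoint_corpus(n_classes = 2, per_class = 8, n_families = 6,
                              seed = seed)
    res <- corpus_profile(corpus)
    m <- res$profile
    # per-gene accounting: each sensor gene counted once per cluster it hits
    expected <- res$domains |>
      dplyr::mutate(cluster = res$assignment$cluster_of[seq_id]) |>
      dplyr::distinct(metagenome_id, gene_id, cluster, copy_number) |>
      dplyr::group_by(metagenome_id) |>
      dplyr::summarise(copy = sum(copy_number))
    got <- rowSums(m$values)[expected$metagenome_id] *
      m$totals[expected$metagenome_id]
    expect_equal(unname(got), expected$copy, tolerance = 1e-9)
  }
})

test_that("planted fractions are recovered exactly at zero mutation", {
  pool <- make_family_pool(5, c(60, 90), mutation_rate = 0, seed = 13)
  corpus <- generate_corpus(
    list(ecosystem_spec("A:B:C", 6, rep(1, 5), 0.2, 80),
         ecosystem_spec("D:E:F", 6, rep(1, 5), 0.1, 80)),
    pool, seed = 8
  )
  res <- corpus_profile(corpus, min_identity = 0.95, coverage = 0.95)
  truth <- corpus$truth$planted_fractions |>
    tidyr::pivot_wider(names_from = family_id, values_from = fraction)
  v <- res$profile$values
  tm <- as.matrix(truth[match(rownames(v), truth$metagenome_id), -1])
  # clustering is perfect, so sorted row profiles must agree exactly
  expect_equal(dim(v), dim(tm))
  expect_equal(t(apply(v, 1, sort)), t(apply(tm, 1, sort)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cluster prevalence filtering uses presence counts at the threshold", {
  set.seed(2)
  values <- matrix(0, 10, 3)
  values[1:5, 1] <- 0.01   # prevalence 5
  values[1:4, 2] <- 0.02   # prevalence 4
  values[1, 3] <- 0.03     # prevalence 1
  m <- toy_profile(values, rep("A:B:C", 10))

  expect_equal(ncol(filter_clusters(m, 1)$values), 3)  # unchanged
  f5 <- filter_clusters(m, 5)
  expect_equal(colnames(f5$values), "cluster00001")
  # boundary: prevalence 4 < 5 dropped
  expect_false("cluster00002" %in% colnames(f5$values))
  # values untouched (no renormalization)
  expect_equal(f5$values[, 1], m$values[, 1])
  # idempotent
  expect_identical(filter_clusters(f5, 5)$values, f5$values)
  # direct-count invariant
  expect_true(all(colSums(filter_clusters(m, 4)$values > 0) >= 4))
  expect_warning(filter_clusters(m, 100), "no cluster")
})

test_that("sample filtering is strictly greater-than and drops listed labels", {
  values <- matrix(0.01, 62, 2)
  labels <- c(rep("A:B:C", 31), rep("D:E:F", 30), "Unclassified")
  m <- toy_profile(values, labels)

  f <- filter_samples(m, min_per_class = 30)
  expect_equal(unique(f$meta$ecosystem), "A:B:C")
  expect_equal(nrow(f$values), 31)

  # drop_labels applies regardless of class size, including path levels
  m2 <- toy_profile(matrix(0.01, 4, 2),
                    c("Environmental:Unclassified:X",
                      "Unclassified", "A:B:C", "A:B:C"))
  f2 <- filter_samples(m2, min_per_class = 0)
  expect_equal(nrow(f2$values), 2)
  expect_true(all(f2$meta$ecosystem == "A:B:C"))

  # everything removed is an error
  expect_error(filter_samples(m, min_per_class = 100), "every row")
})

test_that("sensor fraction is the unfiltered row sum", {
  values <- matrix(c(0.02, 0.03, 0, 0), 2, 2)
  m <- toy_profile(values, c("A:B:C", "D:E:F"))
  sf <- sensor_fraction(m)
  expect_equal(sf$sensor_fraction, c(0.02, 0.03))
  zero <- toy_profile(matrix(0, 1, 2), "A:B:C")
  expect_equal(sensor_fraction(zero)$sensor_fraction, 0)

  # on a generated corpus the row sums match the generator's own record
  corpus <- disjoint_corpus(n_classes = 2, per_class = 5, n_families = 4,
                            seed = 31)
  res <- corpus_profile(corpus)
  truth <- corpus$truth$sensor_fraction
  got <- sensor_fraction(res$profile)
  expect_equal(
    got$sensor_fraction[match(truth$metagenome_id, got$metagenome_id)],
    truth$sensor_fraction,
    tolerance = 1e-12
  )
})

test_that("profile round-trips through dense and sparse TSV", {
  corpus <- disjoint_corpus(n_classes = 2, per_class = 4, n_families = 4,
                            seed = 41)
  m <- corpus_profile(corpus)$profile
  dense <- withr::local_tempfile(fileext = ".tsv")
  sparse <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(m, dense, "dense")
  write_profile_matrix(m, sparse, "sparse")
  d <- readr::read_tsv(dense, show_col_types = FALSE)
  expect_equal(nrow(d), nrow(m$values))
  expect_equal(as.matrix(d[, -1]), m$values, ignore_attr = TRUE)
  s <- readr::read_tsv(sparse, show_col_types = FALSE)
  expect_equal(nrow(s), sum(m$values > 0))
})
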