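test_that("deduplication counts exact duplicates", {
  dom <- tibble::tibble(
    seq_id = c("a", "b", "c"),
    sequence = c("AAA", "AAA", "AAC")
  )
  u <- dedup(dom)
  expect_equal(nrow(u), 2)
  expect_equal(sum(u$multiplicity), 3)
  expect_equal(u$multiplicity[u$sequence == "AAA"], 2)
  expect_identical(u$uid[u$sequence == "AAA"], "a")

  all_distinct <- tibble::tibble(seq_id = c("x", "y"),
                                 sequence = c("AA", "CC"))
  expect_identical(dedup(all_distinct)$uid, c("x", "y"))
  expect_error(dedup(tibble::tibble(seq_id = "z", sequence = "")), "empty")
})

test_that("pairwise identity matches its definition on simple cases", {
  expect_equal(unname(pairwise_identity("KLMNP", "KLMNP")),
               c(1, 1))
  st <- pairwise_identity("AAAA", "AAAT")
  expect_equal(unname(st[["identity"]]), 0.75)
  expect_equal(unname(st[["coverage"]]), 1)
  # bidirectional coverage is symmetric
  a <- "ACDEFGHIKLMNPQRSTVWY"; b <- "ACDEFGHIKL"
  expect_equal(pairwise_identity(a, b)[["coverage"]],
               pairwise_identity(b, a)[["coverage"]])
  expect_error(pairwise_identity("", "A"), "nonempty")
})

test_that("compiled aligner agrees with the plain-R DP oracle on random pairs", {
  set.seed(42)
  for (rep in 1:40) {
    pair <- random_seqs(2, c(40, 100))
    mine <- sensorscape:::.nw_align_stats(pair[[1]], pair[[2]])
    ref <- oracle_align(pair[[1]], pair[[2]])
    expect_equal(mine$score, ref$score)
    expect_equal(mine$matches, ref$matches)
    expect_equal(mine$pairs, ref$pairs)
    expect_equal(mine$columns, ref$columns)
  }
  # and with mutated/related pairs, where gaps actually matter
  for (rep in 1:20) {
    a <- random_seqs(1, c(50, 80))[[1]]
    b <- paste(sample(strsplit(a, "")[[1]])[1:40], collapse = "")
    mine <- sensorscape:::.nw_align_stats(a, b)
    ref <- oracle_align(a, b)
    expect_equal(mine$matches, ref$matches)
    expect_equal(mine$columns, ref$columns)
  }
})

test_that("alignment score cross-checks against Biostrings", {
  sub <- matrix(0L, 20, 20,
                dimnames = list(sensorscape:::AA_ALPHABET,
                                sensorscape:::AA_ALPHABET))
  diag(sub) <- 1L
  set.seed(7)
  for (rep in 1:10) {
    pair <- random_seqs(2, c(30, 70))
    ref <- Biostrings::pairwiseAlignment(
      pair[[1]], pair[[2]], type = "global", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = 1
    )
    mine <- sensorscape:::.nw_align_stats(pair[[1]], pair[[2]])
    expect_equal(mine$score, Biostrings::score(ref))
  }
})

test_that("greedy clustering handles degenerate inputs", {
  same <- setNames(rep("KLMNPQ", 3), c("a", "b", "c"))
  asg <- cluster_greedy(same, cluster_params(0.9, "bidirectional", 0.9))
  expect_equal(length(asg$centroid_of), 1)
  expect_true(all(asg$cluster_of == asg$cluster_of[[1]]))
  # centroid is a member of its own cluster
  expect_true(all(unname(asg$centroid_of) %in% names(asg$cluster_of)))

  distinct <- random_seqs(5, c(30, 40))
  asg1 <- cluster_greedy(distinct, cluster_params(1.0, "bidirectional", 1.0))
  expect_equal(length(asg1$centroid_of), 5)
})

test_that("greedy clustering equals the brute-force full-pairwise reference", {
  params <- cluster_params(0.5, "bidirectional", 0.8)
  set.seed(11)
  for (rep in 1:5) {
    seqs <- random_seqs(sample(10:30, 1), c(20, 60))
    fast <- cluster_greedy(seqs, params)
    # map cluster ids back to centroid seq ids for comparison
    fast_named <- setNames(
      unname(fast$centroid_of[fast$cluster_of]), names(fast$cluster_of)
    )
    ref <- oracle_cluster_greedy(seqs, params)
    expect_true(same_partition(fast_named, ref))
  }
})

test_that("partition properties and identity threshold monotonicity hold", {
  set.seed(3)
  pool <- make_family_pool(6, c(40, 70), 0.1, seed = 8)
  seqs <- unlist(lapply(seq_len(6), function(k) {
    v <- vapply(1:5, function(i) {
      sensorscape:::mutate_sequence(pool$families$centroid[k], 0.1)
    }, character(1))
    setNames(v, sprintf("f%d_%d", k, 1:5))
  }))

  thresholds <- c(0.4, 0.6, 0.8, 0.95)
  n_clusters <- vapply(thresholds, function(th) {
    asg <- cluster_greedy(seqs, cluster_params(th, "bidirectional", 0.8))
    # partition: disjoint and exhaustive
    expect_setequal(names(asg$cluster_of), names(seqs))
    # centroid property: every member within min_identity of its centroid
    cent_seq <- seqs[asg$centroid_of[asg$cluster_of]]
    for (i in seq_along(seqs)) {
      st <- pairwise_identity(seqs[[names(asg$cluster_of)[i]]],
                              unname(cent_seq[i]))
      expect_gte(st[["identity"]], th)
    }
    length(asg$centroid_of)
  }, numeric(1))
  expect_true(!is.unsorted(n_clusters))
})

test_that("planted families are recovered exactly at the working threshold", {
  pool <- make_family_pool(10, c(60, 120), 0.05, seed = 7)
  members <- unlist(lapply(seq_len(10), function(k) {
    v <- vapply(1:8, function(i) {
      sensorscape:::mutate_sequence(pool$families$centroid[k], 0.05)
    }, character(1))
    setNames(v, sprintf("fam%02d_m%d", k, 1:8))
  }))
  set.seed(5)
  asg <- cluster_greedy(members, cluster_params(0.8, "bidirectional", 0.8))
  truth <- sub("_m\\d+$", "", names(members))
  ari <- adjusted_rand(truth, asg$cluster_of[names(members)])
  expect_equal(ari, 1.0)
})

test_that("external backend errors explicitly when the tool is missing", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "KKKK"), fa)
  expect_error(
    cluster_external(fa, tool_path = "definitely-not-a-real-binary"),
    "external clustering tool unavailable"
  )
})

test_that("cluster TSV parsing round-trips and rejects malformed files", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\ta", "a\tb", "c\tc"), tsv)
  asg <- read_cluster_tsv(tsv)
  expect_equal(length(asg$centroid_of), 2)
  expect_equal(unname(asg$cluster_of[c("a", "b")]),
               rep(asg$cluster_of[["a"]], 2))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "c\tb"), bad)  # member in two clusters
  expect_error(read_cluster_tsv(bad), "malformed|more than one")
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb", bad2)  # representative not a member of its cluster
  expect_error(read_cluster_tsv(bad2), "representative")
})

test_that("cluster_sensors propagates clusters across duplicates", {
  dom <- tibble::tibble(
    seq_id = c("a", "b", "c", "d"),
    sequence = c("KLMNPQRSTV", "KLMNPQRSTV", "KLMNPQRSTV", "ACDEFGHIKW")
  )
  asg <- cluster_sensors(dom, cluster_params(0.9, "bidirectional", 0.9))
  expect_setequal(names(asg$cluster_of), dom$seq_id)
  expect_equal(asg$cluster_of[["a"]], asg$cluster_of[["b"]])
  expect_equal(asg$cluster_of[["a"]], asg$cluster_of[["c"]])
  expect_false(asg$cluster_of[["a"]] == asg$cluster_of[["d"]])
})
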