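# A small separable two-class matrix used by several tests: class "pos"
# has mass on the first feature block, class "neg" on the second.
separable_xy <- function(n_per_class = 40, p = 6, seed = 2) {
  set.seed(seed)
  x <- rbind(
    cbind(matrix(runif(n_per_class * p / 2, 0.05, 0.1), n_per_class),
          matrix(0, n_per_class, p / 2)),
    cbind(matrix(0, n_per_class, p / 2),
          matrix(runif(n_per_class * p / 2, 0.05, 0.1), n_per_class))
  )
  rownames(x) <- sprintf("S%03d", seq_len(2 * n_per_class))
  colnames(x) <- sprintf("cluster%05d", seq_len(p))
  list(x = x, y = rep(c("pos", "neg"), each = n_per_class))
}

test_that("splits are disjoint, exhaustive, stratified and seeded", {
  labels <- setNames(rep(c("a", "b"), each = 50), sprintf("S%03d", 1:100))
  sp <- split_profile(labels, seed = 5)
  expect_equal(sort(lengths(sp)), sort(c(train = 70L, test = 20L,
                                         validation = 10L)))
  expect_setequal(unlist(sp), names(labels))
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(length(intersect(sp$train, sp$validation)), 0)

  # per-class proportions within one sample of exact
  for (part in names(sp)) {
    tab <- table(labels[sp[[part]]])
    expect_lte(max(abs(tab - mean(tab))), 1)
  }

  # deterministic given seed
  expect_identical(split_profile(labels, seed = 5), sp)
  expect_false(identical(split_profile(labels, seed = 6), sp))

  # class too small to stratify errors with its name
  tiny <- setNames(c("a", "a", "a", "rare", "rare"), paste0("m", 1:5))
  expect_error(split_profile(tiny, seed = 1), "rare")
})

test_that("classifier reaches perfect accuracy on separable data", {
  d <- separable_xy()
  sp <- split_profile(setNames(d$y, rownames(d$x)), seed = 3)
  cfg <- model_config("multiclass", nrounds = 50, seed = 7)
  fit <- train_classifier(d$x[sp$train, ], d$y[match(sp$train, rownames(d$x))],
                          cfg)
  ev <- evaluate(fit, d$x[sp$test, ], d$y[match(sp$test, rownames(d$x))])
  expect_equal(ev$accuracy, 1.0)
  # confusion-matrix trace over total equals accuracy, exactly
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion), ev$accuracy)
  expect_equal(ev$f1$f1, c(1, 1))

  # single-class training is an error
  expect_error(train_classifier(d$x, rep("one", nrow(d$x)), cfg),
               "single class")
})

test_that("training is reproducible given the seed", {
  d <- separable_xy()
  cfg <- model_config("multiclass", nrounds = 30, seed = 11)
  f1 <- train_classifier(d$x, d$y, cfg)
  f2 <- train_classifier(d$x, d$y, cfg)
  expect_equal(predict(f1, d$x, type = "prob"),
               predict(f2, d$x, type = "prob"))
})

test_that("label-permuted data scores near chance", {
  corpus <- disjoint_corpus(n_classes = 4, per_class = 25, seed = 77)
  res <- corpus_profile(corpus)
  labels <- setNames(res$profile$meta$ecosystem,
                     res$profile$meta$metagenome_id)
  set.seed(99)
  permuted <- setNames(sample(labels), names(labels))
  sp <- split_profile(permuted, seed = 8)
  cfg <- model_config("multiclass", nrounds = 60, seed = 7)
  fit <- train_classifier(res$profile$values[sp$train, ],
                          permuted[sp$train], cfg)
  ev <- evaluate(fit, res$profile$values[sp$test, ], permuted[sp$test])
  # 95% binomial interval around 1/4 at the test size
  half_width <- 1.96 * sqrt(0.25 * 0.75 / ev$n)
  expect_gte(ev$accuracy, 0.25 - half_width)
  expect_lte(ev$accuracy, 0.25 + half_width)
})

test_that("evaluation report matches a hand-counted confusion matrix", {
  d <- separable_xy(n_per_class = 10)
  cfg <- model_config("multiclass", nrounds = 20, seed = 1)
  fit <- train_classifier(d$x, d$y, cfg)
  pred <- predict(fit, d$x, type = "class")
  ev <- evaluate(fit, d$x, d$y)
  for (truth in c("pos", "neg")) {
    for (p in c("pos", "neg")) {
      expect_equal(
        unname(ev$confusion[truth, p]),
        sum(d$y == truth & pred == p)
      )
    }
  }
  # row sums equal per-class test counts
  expect_equal(unname(rowSums(ev$confusion)), unname(table(d$y)[c("neg", "pos")]),
               ignore_attr = TRUE)
  # a label unseen in training appears as its own flagged row
  y2 <- d$y; y2[1] <- "mystery"
  expect_warning(ev2 <- evaluate(fit, d$x, y2), "unseen")
  expect_true("mystery" %in% rownames(ev2$confusion))
  expect_equal(sum(ev2$confusion["mystery", ]), 1)
})

test_that("grid search is exhaustive, tie-stable and finds the good setting", {
  d <- separable_xy(n_per_class = 30)
  sp <- split_profile(setNames(d$y, rownames(d$x)), seed = 3)
  tr <- function(part) d$x[sp[[part]], ]
  lab <- function(part) d$y[match(sp[[part]], rownames(d$x))]

  # 1-point grid returns that point
  one <- model_config("multiclass", learning_rate = 0.2, tree_depth = 3,
                      nrounds = 20, seed = 5)
  g1 <- grid_search(tr("train"), lab("train"), tr("validation"),
                    lab("validation"), one)
  expect_equal(nrow(g1$log), 1)
  expect_equal(g1$best_params$learning_rate, 0.2)

  # crippled vs sensible settings: an XOR-structured label needs depth > 1,
  # so the stump setting loses and the deeper tree wins on the validation set
  set.seed(21)
  xx <- matrix(runif(160 * 4, 0, 0.1), 160, 4,
               dimnames = list(sprintf("X%03d", 1:160), paste0("f", 1:4)))
  yy <- ifelse(xor(xx[, 1] > 0.05, xx[, 2] > 0.05), "odd", "even")
  spx <- split_profile(setNames(yy, rownames(xx)), seed = 2)
  mixed <- model_config("multiclass", learning_rate = 0.3,
                        tree_depth = c(1, 4), nrounds = 60, seed = 5)
  g2 <- grid_search(xx[spx$train, ], yy[match(spx$train, rownames(xx))],
                    xx[spx$validation, ], yy[match(spx$validation, rownames(xx))],
                    mixed)
  expect_equal(nrow(g2$log), 2)  # full Cartesian product
  expect_equal(g2$best_params$tree_depth, 4)
  expect_gt(g2$log$metric[g2$log$tree_depth == 4],
            g2$log$metric[g2$log$tree_depth == 1])

  # ties break to the first grid point
  tie <- model_config("multiclass", learning_rate = c(0.2, 0.3),
                      tree_depth = 3, nrounds = 25, seed = 5)
  g3 <- grid_search(tr("train"), lab("train"), tr("validation"),
                    lab("validation"), tie)
  if (g3$log$metric[1] == g3$log$metric[2]) {
    expect_equal(g3$best_params$learning_rate, 0.2)
  }
})

test_that("regressor recovers a planted signal and the mean scores zero", {
  set.seed(6)
  n <- 150
  x <- matrix(runif(n * 5, 0, 0.05), n, 5,
              dimnames = list(sprintf("S%03d", 1:n),
                              sprintf("cluster%05d", 1:5)))
  y <- 2 + 100 * x[, 1] - 50 * x[, 2]
  cfg <- model_config("regression", learning_rate = 0.1, tree_depth = 2,
                      nrounds = 400, seed = 3)
  fit <- train_regressor(x[1:100, ], y[1:100], cfg)
  expect_gte(evaluate_r2(fit, x[101:150, ], y[101:150]), 0.9)

  # target independent of features generalizes at chance
  y_null <- rnorm(n)
  fit0 <- train_regressor(x[1:100, ], y_null[1:100], cfg)
  expect_lte(evaluate_r2(fit0, x[101:150, ], y_null[101:150]), 0.1)

  # predicting the held-out mean gives R^2 = 0 by definition
  expect_equal(sensorscape:::r_squared(y, rep(mean(y), n)), 0)
  expect_error(train_regressor(x, rep(1, n), cfg), "constant")
})

test_that("cluster features beat Pfam features on a confusable corpus", {
  # families 1 and 2 share one Pfam accession but separate the two
  # ecosystems; Pfam-level features collapse them
  pool <- make_family_pool(
    2, c(60, 90), 0.05, seed = 15,
    pfam_accs = c("PF91111", "PF91111")
  )
  specs <- list(
    ecosystem_spec("Environmental:Aquatic:Marine", 40, c(1, 0), 0.12, 80),
    ecosystem_spec("Host-associated:Human:Skin", 40, c(0, 1), 0.12, 80)
  )
  corpus <- generate_corpus(specs, pool, seed = 23)
  res <- corpus_profile(corpus)
  pf_map <- cluster_pfam_map(res$assignment, res$domains)
  expect_equal(length(unique(pf_map$pfam_acc)), 1)

  cmp <- feature_set_comparison(
    res$profile, pf_map, "ecosystem",
    model_config("multiclass", nrounds = 60, seed = 9)
  )
  expect_equal(cmp$comparison$n_features, c(2L, 1L))
  expect_gte(cmp$cluster$accuracy - cmp$pfam$accuracy, 0.3)

  # a matrix compared against itself gives identical accuracy
  self_map <- tibble::tibble(
    cluster_id = colnames(res$profile$values),
    pfam_acc = colnames(res$profile$values)
  )
  cmp_self <- feature_set_comparison(
    res$profile, self_map, "ecosystem",
    model_config("multiclass", nrounds = 40, seed = 9)
  )
  expect_equal(cmp_self$cluster$accuracy, cmp_self$pfam$accuracy)
})

test_that("one Pfam per family gives feature-set parity within noise", {
  corpus <- disjoint_corpus(n_classes = 2, per_class = 30, n_families = 4,
                            seed = 55)
  res <- corpus_profile(corpus)
  pf_map <- cluster_pfam_map(res$assignment, res$domains)
  cmp <- feature_set_comparison(
    res$profile, pf_map, "ecosystem",
    model_config("multiclass", nrounds = 50, seed = 9)
  )
  expect_lte(abs(cmp$cluster$accuracy - cmp$pfam$accuracy), 0.1)
})

test_that("tidy and glance summarise an evaluation", {
  d <- separable_xy(n_per_class = 15)
  fit <- train_classifier(d$x, d$y, model_config("multiclass", nrounds = 20,
                                                 seed = 1))
  ev <- evaluate(fit, d$x, d$y)
  td <- tidy(ev)
  expect_setequal(names(td), c("true", "predicted", "n"))
  expect_equal(sum(td$n), 30)
  gl <- glance(ev)
  expect_equal(gl$accuracy, ev$accuracy)
  expect_equal(gl$n_classes, 2L)
})
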