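toy_map <- function(F_, n = 40) {
  spectrum_map(F_, log_grid2d(n1 = nrow(F_), n2 = ncol(F_)))
}

test_that("featurization is deterministic and handles degenerate maps", {
  z <- toy_map(matrix(0, 40, 40))
  expect_equal(featurize(z, "grid"), structure(rep(0, 1024),
               featurizer = "grid", params = list(blocks = 32)),
               ignore_attr = TRUE)
  set.seed(2)
  F_ <- matrix(rexp(1600), 40, 40)
  m <- toy_map(F_)
  expect_identical(featurize(m, "grid"), featurize(m, "grid"))
  expect_equal(sqrt(sum(featurize(m, "grid")^2)), 1)
  expect_error(featurize(m, "nope"), "arg")
  expect_error(featurize(m, "embedding"), "embed_fn")
  expect_equal(featurize(m, "embedding", embed_fn = function(x) c(1, 2)),
               c(1, 2), ignore_attr = TRUE)
  expect_length(featurize(m, "peaks"), 13)
})

test_that("oxygenated and oxidized fingerprints are far apart in feature space", {
  sch <- fast_scheme()
  spo <- invert_decay(simulate_decay(preset_phenotype("oxygenated"), sch))
  spx <- invert_decay(simulate_decay(preset_phenotype("oxidized"), sch))
  fo <- featurize(spo, "peaks")
  fx <- featurize(spx, "peaks")
  expect_gt(sqrt(sum((fo - fx)^2)), 0.5)
})

test_that("classical MDS reproduces exact low-dimensional configurations", {
  # three mutually equidistant subjects embed as an equilateral triangle
  D <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  xy <- reduce_dimension(D, "mds")
  d <- as.vector(stats::dist(xy))
  expect_equal(max(d) / min(d), 1, tolerance = 1e-6)
  # distances that are already 2D-Euclidean embed with zero stress
  set.seed(5)
  pts <- matrix(rnorm(20), 10, 2)
  xy2 <- reduce_dimension(stats::dist(pts), "mds")
  expect_lt(attr(xy2, "stress"), 1e-10)
  expect_error(reduce_dimension(matrix(rnorm(4), 2, 2)), "3 subjects")
})

test_that("t-SNE and Isomap embed cohorts into two seeded, separated dimensions", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  for (m in c("tsne", "isomap")) {
    xy <- reduce_dimension(x, m, seed = 3)
    expect_equal(dim(xy), c(40L, 2L))
    between <- sqrt(sum((colMeans(xy[1:20, ]) - colMeans(xy[21:40, ]))^2))
    within <- mean(c(stats::dist(xy[1:20, ]), stats::dist(xy[21:40, ])))
    expect_gt(between, within)
  }
  expect_identical(reduce_dimension(x, "tsne", seed = 3),
                   reduce_dimension(x, "tsne", seed = 3))
})

test_that("hierarchical clustering merges duplicates first and recovers clean clusters", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 1))
  cl <- cluster_and_heatmap(x)
  expect_equal(min(cl$hclust$height), 0)
  expect_equal(dim(cl$dist_ordered), c(4L, 4L))
  single <- cluster_and_heatmap(matrix(1, 1, 2))
  expect_null(single$hclust)

  set.seed(9)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  lab <- rep(1:3, each = 8)
  pts <- centers[lab, ] + matrix(rnorm(48, sd = 0.3), 24, 2)
  cl3 <- cluster_and_heatmap(pts)
  got <- stats::cutree(cl3$hclust, k = 3)
  expect_equal(mclust::adjustedRandIndex(got, lab), 1)
})

test_that("the separation test matches a hand-computed Welch t instance", {
  # frozen closed-form oracle: x = (1,2,3,4), y = (6,7,9)
  # mean diff = -4.8333, se = sqrt(var(x)/4 + var(y)/3) = sqrt(5/12 + 7/3/3)
  x <- c(1, 2, 3, 4)
  y <- c(6, 7, 9)
  se <- sqrt(stats::var(x) / 4 + stats::var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  res <- separation_test(c(x, y), rep(c("a", "b"), c(4, 3)))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)

  same <- separation_test(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  sep <- separation_test(c(0, 0, 0, 1, 1, 1) + rnorm(6, sd = 1e-6),
                         rep(c("a", "b"), each = 3))
  expect_lt(sep$p_value, 1e-3)
  expect_error(separation_test(1:5, c("a", "a", "b", "b", "c")), "2 groups")
  expect_error(separation_test(1:3, c("a", "a", "b")), "at least 2")
  # pooled-variance form agrees with the classic formula
  pooled <- separation_test(c(x, y), rep(c("a", "b"), c(4, 3)), welch = FALSE)
  sp2 <- ((4 - 1) * stats::var(x) + (3 - 1) * stats::var(y)) / (4 + 3 - 2)
  expect_equal(pooled$statistic,
               (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3)),
               tolerance = 1e-12)
})

test_that("confusion metrics reproduce hand-computed values and identities", {
  m <- confusion_metrics(tp = 3, tn = 5, fp = 1, fn = 1)
  expect_equal(m$ca, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  # F1 is the harmonic mean of precision and sensitivity for any table
  set.seed(3)
  for (i in 1:25) {
    v <- rmultinom(1, 40, rep(0.25, 4))
    mm <- confusion_metrics(v[1], v[2], v[3], v[4])
    if (!is.na(mm$f1))
      expect_equal(mm$f1, 2 / (1 / mm$precision + 1 / mm$sensitivity))
  }
  # zero denominators are missing, never zero
  m0 <- confusion_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.na(m0$sensitivity))
  expect_true(is.na(m0$precision))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(13)
  sc <- rnorm(40)
  y <- sc + rnorm(40) > 0
  got <- auc_rank(sc, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_rank(c(1, 1, 2, 2), c(FALSE, TRUE, FALSE, TRUE)), 0.5)
})

test_that("perfectly separable features give perfect scores for every model", {
  set.seed(4)
  x <- cbind(c(rnorm(10, -4), rnorm(10, 4)), matrix(rnorm(40), 20, 2))
  y <- rep(c("non_disease", "disease"), each = 10)
  for (m in c("logistic_regression", "knn", "neural_network", "naive_bayes")) {
    r <- train_evaluate(x, y, m, "loo", seed = 1)
    expect_equal(r$metrics$ca, 1)
    expect_equal(r$auc, 1)
    expect_equal(sum(r$confusion), 20)
  }
})

test_that("leave-one-out is seed-independent for the deterministic models", {
  set.seed(6)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("a", "b"), 10)
  for (m in c("logistic_regression", "knn", "naive_bayes")) {
    r1 <- train_evaluate(x, y, m, "loo", seed = 1)
    r2 <- train_evaluate(x, y, m, "loo", seed = 999)
    expect_identical(r1$scores, r2$scores)
  }
})

test_that("label permutation drives accuracy to chance", {
  set.seed(10)
  x <- matrix(rnorm(32 * 4), 32, 4)
  cas <- sapply(1:20, function(s) {
    set.seed(s)
    y <- sample(rep(c("a", "b"), 16))
    suppressWarnings(
      train_evaluate(x, y, "logistic_regression", 5, seed = s)$metrics$ca)
  })
  expect_gt(mean(cas), 0.35)
  expect_lt(mean(cas), 0.65)
})

test_that("degenerate classification inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(train_evaluate(x, rep("a", 10), "knn"), "single class")
  expect_error(train_evaluate(x, rep(c("a", "b"), 5), "knn", protocol = 1),
               "protocol")
})
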