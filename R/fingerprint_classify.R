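#' Convert a spectrum map into a feature vector
#'
#' Deterministic featurizations of the T1-T2 correlation map ("molecular
#' fingerprint") for machine learning:
#' \describe{
#'   \item{`"grid"`}{log-intensity `log10(F + eps)` with
#'     `eps = 1e-6 * max(F)`, block-averaged down to 32 x 32, flattened and
#'     L2-normalized. An all-zero map yields the zero vector.}
#'   \item{`"peaks"`}{concatenation of (log10 T1, log10 T2, A-ratio, volume)
#'     for the R, S and T slots (zeros when a slot is unassigned) plus the
#'     tail extent in decades.}
#'   \item{`"embedding"`}{delegates to a user-supplied callable
#'     `embed_fn(map)` returning a numeric vector (pluggable image
#'     embedding, e.g. a CNN; not part of the default path).}
#' }
#'
#' @param map A [spectrum_map()].
#' @param method One of `"grid"`, `"peaks"`, `"embedding"`.
#' @param embed_fn Callable for `method = "embedding"`.
#' @param blocks Output side length for the grid method (default 32).
#' @return Numeric feature vector with attributes `featurizer` and `params`.
#' @export
featurize <- function(map, method = c("grid", "peaks", "embedding"),
                      embed_fn = NULL, blocks = 32) {
  stopifnot(inherits(map, "spectrum_map"))
  method <- match.arg(method)
  v <- switch(method,
    grid = {
      F_ <- map$intensity
      m <- max(F_)
      if (m <= 0) {
        rep(0, blocks * blocks)
      } else {
        G <- log10(F_ + 1e-6 * m)
        bi <- ceiling(seq_len(nrow(G)) / nrow(G) * blocks)
        bj <- ceiling(seq_len(ncol(G)) / ncol(G) * blocks)
        agg <- rowsum(G, bi)
        agg <- t(rowsum(t(agg), bj))
        cnt <- outer(tabulate(bi, blocks), tabulate(bj, blocks))
        x <- as.vector(agg / cnt)
        x / sqrt(sum(x^2))
      }
    },
    peaks = {
      rep_ <- classify_peaks_rst(detect_peaks(map))
      p <- rep_$peaks
      slot <- function(lab) {
        i <- which(p$label == lab)
        if (length(i) == 1L)
          c(log10(p$t1_ms[i]), log10(p$t2_ms[i]), p$a_ratio[i], p$volume[i])
        else c(0, 0, 0, 0)
      }
      c(slot("R"), slot("S"), slot("T"), rep_$tail_extent_decades)
    },
    embedding = {
      if (!is.function(embed_fn))
        stop("method 'embedding' requires a callable embed_fn")
      as.numeric(embed_fn(map))
    })
  attr(v, "featurizer") <- method
  attr(v, "params") <- if (method == "grid") list(blocks = blocks) else list()
  v
}

#' Featurize a list of spectrum maps into a feature matrix
#'
#' @param maps Named list of [spectrum_map()] objects (one per subject).
#' @param method,... Passed to [featurize()].
#' @return Numeric matrix, one row per subject.
#' @export
featurize_cohort <- function(maps, method = "grid", ...) {
  feats <- lapply(maps, featurize, method = method, ...)
  len <- unique(vapply(feats, length, integer(1)))
  stopifnot(length(len) == 1L)
  do.call(rbind, lapply(feats, as.numeric))
}

# Stress of a 2D configuration against target distances
.mds_stress <- function(X, D) {
  d <- as.matrix(stats::dist(X))
  Dm <- as.matrix(D)
  sum((Dm[upper.tri(Dm)] - d[upper.tri(d)])^2)
}

#' Reduce fingerprint features to two dimensions
#'
#' Default is metric MDS with classical (Torgersen) initialization --- the
#' principal coordinates of the double-centered squared-distance matrix ---
#' refined by SMACOF stress majorization capped at `max_iter` iterations
#' (default 300) on pairwise Euclidean distances. `"isomap"` and `"tsne"`
#' are offered behind the same interface; t-SNE is stochastic and seeded.
#'
#' @param features Numeric matrix (subjects x features) or a `dist` object.
#' @param method `"mds"` (default), `"tsne"` or `"isomap"`.
#' @param max_iter Majorization iteration cap for MDS (default 300).
#' @param seed Seed for t-SNE initialization.
#' @param perplexity t-SNE perplexity (default `min(10, (n - 1) / 3)`).
#' @param k Isomap neighbourhood size (default `min(n - 1, 5)`).
#' @return An `n x 2` coordinate matrix; for MDS with attribute `stress`
#'   (raw stress, 0 for perfectly 2D-Euclidean distances).
#' @export
reduce_dimension <- function(features, method = c("mds", "tsne", "isomap"),
                             max_iter = 300, seed = 1L,
                             perplexity = NULL, k = NULL) {
  method <- match.arg(method)
  D <- if (inherits(features, "dist")) features else stats::dist(features)
  n <- attr(D, "Size")
  if (n < 3) stop("at least 3 subjects are required")
  coords <- switch(method,
    mds = {
      X <- stats::cmdscale(D, k = 2)
      if (ncol(X) < 2) X <- cbind(X, 0)
      Dm <- as.matrix(D)
      stress <- .mds_stress(X, D)
      for (it in seq_len(max_iter)) {
        dX <- as.matrix(stats::dist(X))
        B <- ifelse(dX > 0, -Dm / pmax(dX, 1e-300), 0)
        diag(B) <- 0
        diag(B) <- -rowSums(B)
        X_new <- B %*% X / n
        s_new <- .mds_stress(X_new, D)
        if (s_new > stress - 1e-12 * (1 + stress)) break
        X <- X_new
        stress <- s_new
      }
      attr(X, "stress") <- stress
      X
    },
    isomap = {
      if (is.null(k)) k <- min(n - 1, 5)
      # grow the neighbourhood until the graph is connected
      res <- NULL
      while (is.null(res) && k <= n - 1) {
        res <- tryCatch(vegan::isomap(D, ndim = 2, k = k),
                        error = function(e) NULL)
        if (is.null(res)) k <- min(n - 1, max(k + 1, 2 * k))
      }
      if (is.null(res)) stop("isomap neighbourhood graph cannot be connected")
      as.matrix(res$points[, 1:2])
    },
    tsne = {
      if (is.null(perplexity)) perplexity <- min(10, (n - 1) / 3)
      .tsne(as.matrix(D), perplexity = perplexity, seed = seed)
    })
  rownames(coords) <- if (inherits(features, "dist"))
    attr(D, "Labels") else rownames(features)
  coords
}

# Compact exact-gradient t-SNE on a precomputed distance matrix: binary
# search of per-point bandwidths to the target perplexity, symmetrized P,
# early exaggeration, momentum gradient descent. Adequate for cohort-sized
# problems (tens of subjects).
.tsne <- function(Dm, perplexity = 10, seed = 1L, n_iter = 500,
                  eta = 100, momentum = c(0.5, 0.8), exaggeration = 4) {
  n <- nrow(Dm)
  D2 <- Dm^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(di), length(di)) else p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) momentum[1] else momentum[2]
    dY <- mom * dY - eta * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Average-linkage hierarchical clustering with an ordered distance matrix
#'
#' Agglomerative clustering on Euclidean distances, returning the merge tree
#' and the leaf-ordered pairwise distance matrix ready for heat-map
#' rendering (larger distance = hotter).
#'
#' @param features Numeric matrix (subjects x features) or `dist`.
#' @return List with `hclust` (the tree), `order` (leaf order) and
#'   `dist_ordered` (reordered distance matrix).
#' @export
cluster_and_heatmap <- function(features) {
  D <- if (inherits(features, "dist")) features else stats::dist(features)
  n <- attr(D, "Size")
  if (n < 2) {
    return(list(hclust = NULL, order = 1L,
                dist_ordered = matrix(0, 1, 1)))
  }
  hc <- stats::hclust(D, method = "average")
  Dm <- as.matrix(D)[hc$order, hc$order]
  list(hclust = hc, order = hc$order, dist_ordered = Dm)
}

#' Two-sample separation test between groups
#'
#' Two-tailed two-sample t test on the first reduced coordinate (or any
#' numeric feature): Welch's unequal-variance form by default, classic
#' pooled-variance Student's form with `welch = FALSE`.
#'
#' @param x Numeric vector, or a matrix whose first column is tested.
#' @param labels Two-level grouping with at least 2 observations per group.
#' @param welch Use the Welch variant (default TRUE).
#' @return List with `statistic`, `p_value`, `df` and group means.
#' @export
separation_test <- function(x, labels, welch = TRUE) {
  if (is.matrix(x)) x <- x[, 1]
  g <- factor(labels)
  if (nlevels(g) != 2) stop("exactly 2 groups are required")
  if (any(table(g) < 2)) stop("each group needs at least 2 observations")
  x1 <- x[g == levels(g)[1]]
  x2 <- x[g == levels(g)[2]]
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    same <- isTRUE(all.equal(mean(x1), mean(x2)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                df = NA_real_, means = c(mean(x1), mean(x2))))
  }
  tt <- stats::t.test(x1, x2, var.equal = !welch, alternative = "two.sided")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), means = unname(tt$estimate))
}

#' Classification metrics from a confusion table
#'
#' CA = (TP+TN)/N, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), F1 = harmonic mean of precision and sensitivity.
#' A metric with a zero denominator is reported as `NA` (missing), never 0.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return Named list of metrics.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(ca = ratio(tp + tn, tp + tn + fp + fn),
       sensitivity = sens,
       specificity = ratio(tn, tn + fp),
       precision = prec,
       f1 = f1)
}

#' AUC by the rank-sum (Mann-Whitney) identity
#'
#' Area under the ROC curve computed from pooled decision scores: the
#' probability that a random positive outscores a random negative, with
#' midranks for ties.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Logical or two-level factor; the second level / `TRUE` is
#'   positive.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == levels(factor(labels))[2]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, shuffle (seeded) and deal
# round-robin across k folds.
.make_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  set.seed(seed)
  for (lv in levels(factor(labels))) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Project held-out rows onto the leading principal components of the
# training fold (variance-scaled). Keeps the 32-unit network well-posed for
# image-sized feature vectors and decorrelates inputs for naive Bayes.
.pca_fold <- function(x_tr, x_te, rank = 20L) {
  mu <- colMeans(x_tr)
  xc <- sweep(x_tr, 2, mu)
  r <- min(rank, nrow(x_tr) - 1L, ncol(x_tr))
  V <- svd(xc, nu = 0, nv = r)$v
  z_tr <- xc %*% V
  z_te <- sweep(x_te, 2, mu, check.margin = FALSE) %*% V
  sdv <- apply(z_tr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(tr = sweep(z_tr, 2, sdv, "/"), te = sweep(z_te, 2, sdv, "/"))
}

# Per-model fit + score(P positive). kNN operates on the feature metric as
# the featurizer produced it; ridge logistic, the neural network and naive
# Bayes first project onto the training fold's principal components.
.fit_score <- function(model, x_tr, y_tr, x_te, seed_fit) {
  pos <- levels(y_tr)[2]
  switch(model,
    logistic_regression = {
      z <- .pca_fold(x_tr, x_te)
      fit <- glmnet::glmnet(z$tr, y_tr, family = "binomial", alpha = 0,
                            lambda = 1 / nrow(z$tr), standardize = FALSE)
      as.numeric(stats::predict(fit, newx = z$te, type = "response"))
    },
    knn = {
      kk <- min(3L, nrow(x_tr))
      pr <- class::knn(x_tr, x_te, cl = y_tr, k = kk, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    },
    neural_network = {
      z <- .pca_fold(x_tr, x_te)
      set.seed(seed_fit)
      fit <- nnet::nnet(z$tr, as.numeric(y_tr == pos), size = 32,
                        decay = 1e-3, maxit = 500, entropy = TRUE,
                        trace = FALSE, MaxNWts = 1e5)
      as.numeric(stats::predict(fit, z$te))
    },
    naive_bayes = {
      # per-class Gaussian variances need several observations per component:
      # cap the projection at sqrt(n) components
      z <- .pca_fold(x_tr, x_te, rank = max(2L, floor(sqrt(nrow(x_tr)))))
      df_tr <- as.data.frame(z$tr)
      df_te <- as.data.frame(z$te)
      colnames(df_te) <- colnames(df_tr)
      fit <- e1071::naiveBayes(df_tr, y_tr)
      # floor per-class Gaussian spreads: zero within-class variance would
      # produce degenerate densities
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      stats::predict(fit, df_te, type = "raw")[, pos]
    },
    stop("unknown model '", model, "'"))
}

#' Train and evaluate a classifier by cross-validation
#'
#' Stratified k-fold (k in 2, 3, 5, ...) or leave-one-out cross-validation
#' of one of four supervised models on fingerprint features. Out-of-fold
#' decision scores are pooled; the confusion table (score threshold 0.5)
#' yields CA, sensitivity, specificity, precision and F1, and AUC comes from
#' the pooled scores by the rank statistic. Deterministic given `seed`
#' (leave-one-out is seed-independent for the deterministic models).
#'
#' Model defaults: ridge logistic regression (lambda = 1/n); kNN with k = 3
#' on the feature metric as given; a single-hidden-layer neural network (32
#' logistic units, weight decay 1e-3, up to 500 epochs, seeded
#' initialization) preceded by a training-fold principal-component
#' projection (up to 20 components); Gaussian naive Bayes.
#'
#' @param features Numeric matrix (subjects x features).
#' @param labels Two-level factor/character; the second factor level is the
#'   positive class (for `c("non_disease", "disease")`, disease).
#' @param model One of `"logistic_regression"`, `"knn"`, `"neural_network"`,
#'   `"naive_bayes"`.
#' @param protocol `"loo"` or an integer k >= 2.
#' @param seed Integer seed for fold shuffling and network initialization.
#' @return An object of class `classification_result`: confusion counts,
#'   `$metrics`, `$auc`, pooled `$scores` and `$predicted`.
#' @export
train_evaluate <- function(features, labels,
                           model = c("logistic_regression", "knn",
                                     "neural_network", "naive_bayes"),
                           protocol = "loo", seed = 1L) {
  model <- match.arg(model)
  x <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("labels contain a single class")
  if (nlevels(y) != 2) stop("binary labels are required")
  n <- nrow(x)
  stopifnot(length(y) == n)
  loo <- identical(protocol, "loo")
  k <- if (loo) n else as.integer(protocol)
  if (!loo && (is.na(k) || k < 2 || k > n))
    stop("protocol must be 'loo' or an integer fold count in [2, n]")
  fold <- if (loo) seq_len(n) else .make_folds(y, k, seed)
  scores <- numeric(n)
  for (f in sort(unique(fold))) {
    te <- which(fold == f)
    tr <- setdiff(seq_len(n), te)
    if (nlevels(droplevels(y[tr])) < 2)
      stop("a training fold lost one class; use fewer folds")
    scores[te] <- .fit_score(model, x[tr, , drop = FALSE], y[tr],
                             x[te, , drop = FALSE],
                             seed_fit = seed + 1000L * f)
  }
  pos <- levels(y)[2]
  pred <- factor(ifelse(scores >= 0.5, pos, levels(y)[1]), levels = levels(y))
  tp <- sum(pred == pos & y == pos)
  tn <- sum(pred != pos & y != pos)
  fp <- sum(pred == pos & y != pos)
  fn <- sum(pred != pos & y == pos)
  structure(list(model = model,
                 protocol = if (loo) "loo" else k,
                 confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 metrics = confusion_metrics(tp, tn, fp, fn),
                 auc = auc_rank(scores, y == pos),
                 scores = scores, predicted = pred, labels = y,
                 seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s (%s CV): CA %.3f, AUC %.3f, sens %.3f, spec %.3f, prec %.3f, F1 %.3f\n",
              x$model,
              if (identical(x$protocol, "loo")) "leave-one-out"
              else paste0(x$protocol, "-fold"),
              x$metrics$ca, x$auc, x$metrics$sensitivity,
              x$metrics$specificity, x$metrics$precision, x$metrics$f1))
  invisible(x)
}
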