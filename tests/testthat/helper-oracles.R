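# Shared oracles and fixtures, independent of the implementation paths they
# check.

# Brute-force forward model: explicit triple loop over (t1, t2, component).
simulate_decay_naive <- function(model, scheme, efficiency = 1) {
  comps <- model_components(model)
  t1 <- scheme$t1_ladder_ms
  t2 <- scheme$t2_times_ms
  sig <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      s <- 0
      for (cm in comps) {
        s <- s + cm$amplitude *
          (1 - 2 * efficiency * exp(-t1[i] / cm$t1_ms)) *
          exp(-t2[j] / cm$t2_ms)
      }
      sig[i, j] <- s
    }
  }
  sig
}

# Exact solution of min ||C x - d||^2 + alpha ||x||^2 s.t. x >= 0 by
# exhaustive enumeration of KKT active sets (feasible for <= ~16 variables).
nnqp_enumerate <- function(C, d, alpha = 0) {
  n <- ncol(C)
  stopifnot(n <= 16)
  Q <- crossprod(C)
  diag(Q) <- diag(Q) + alpha
  b <- crossprod(C, d)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^n - 1)) {
    free <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    x <- numeric(n)
    if (any(free)) {
      sol <- tryCatch(solve(Q[free, free, drop = FALSE], b[free]),
                      error = function(e) NULL)
      if (is.null(sol) || any(sol < 0)) next
      x[free] <- sol
    }
    grad <- Q %*% x - b
    if (any(grad[!free] < -1e-9)) next
    obj <- sum((C %*% x - d)^2) + alpha * sum(x^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- x
    }
  }
  list(x = best, objective = best_obj)
}

# Toy compressed problem from explicit small kernels.
toy_problem <- function(K1, K2, M, trunc = 1e-12) {
  compress_problem(K1, K2, M, trunc_threshold = trunc)
}

# Position error of a map coordinate in grid cells.
cells_off <- function(value_ms, target_ms, grid_axis_ms) {
  step <- diff(log10(grid_axis_ms[1:2]))
  log10(value_ms / target_ms) / step
}

# Small, fast acquisition for module-level inversion tests.
fast_scheme <- function(n_echoes = 800, noise_sd = 0) {
  acquisition_scheme(n_echoes = n_echoes, noise_sd = noise_sd)
}
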