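#' Logarithmic T1-T2 inversion grid
#'
#' The grid on which the T1-T2 distribution (the correlation map) is
#' reconstructed. Both axes are log-spaced. Defaults (100 x 100 points,
#' T1 in \[1, 1e4\] ms, T2 in \[0.05, 1e3\] ms) enclose all reference
#' reservoir coordinates of red blood cells with margin.
#'
#' @param t1_range,t2_range Length-2 positive bounds in ms.
#' @param n1,n2 Number of grid points per axis.
#' @return An object of class `log_grid2d` with fields `t1_grid_ms`,
#'   `t2_grid_ms`, `n1`, `n2`.
#' @export
log_grid2d <- function(t1_range = c(1, 1e4), t2_range = c(0.05, 1e3),
                       n1 = 100, n2 = 100) {
  stopifnot(length(t1_range) == 2L, length(t2_range) == 2L,
            all(t1_range > 0), all(t2_range > 0),
            t1_range[1] < t1_range[2], t2_range[1] < t2_range[2],
            n1 >= 2, n2 >= 2)
  structure(list(
    t1_grid_ms = 10^seq(log10(t1_range[1]), log10(t1_range[2]),
                        length.out = n1),
    t2_grid_ms = 10^seq(log10(t2_range[1]), log10(t2_range[2]),
                        length.out = n2),
    n1 = as.integer(n1), n2 = as.integer(n2)),
    class = "log_grid2d")
}

#' Build the separable IR-CPMG kernels
#'
#' The forward map from a T1-T2 distribution F to the measured decay matrix
#' is separable: `M = K1 F t(K2)` with the inversion-recovery kernel
#' `K1[i, p] = 1 - 2 exp(-t1_i / T1_p)` and the CPMG kernel
#' `K2[j, q] = exp(-t2_j / T2_q)`.
#'
#' @param scheme An [acquisition_scheme()].
#' @param grid A [log_grid2d()].
#' @return List with matrices `K1` (`n_t1_steps x n1`) and `K2`
#'   (`n_echoes x n2`).
#' @export
build_kernels <- function(scheme, grid) {
  stopifnot(inherits(scheme, "acquisition_scheme"),
            inherits(grid, "log_grid2d"))
  K1 <- 1 - 2 * exp(-outer(scheme$t1_ladder_ms, 1 / grid$t1_grid_ms))
  K2 <- exp(-outer(scheme$t2_times_ms, 1 / grid$t2_grid_ms))
  list(K1 = K1, K2 = K2)
}

#' Estimate the per-point noise level of a decay matrix
#'
#' Standard deviation of successive echo differences over the second half of
#' the echo train (where the true signal varies slowly), divided by sqrt(2).
#'
#' @param signal Decay matrix (t1 steps x echoes).
#' @return Estimated per-point noise standard deviation.
#' @export
estimate_noise_sd <- function(signal) {
  stopifnot(is.matrix(signal), ncol(signal) >= 4)
  late <- signal[, (ncol(signal) %/% 2):ncol(signal), drop = FALSE]
  stats::sd(diff(t(late))) / sqrt(2)
}

#' Compress the inversion problem by truncated SVD of both kernels
#'
#' The exponential kernels have rapidly decaying singular spectra, so the
#' data can be projected onto a small subspace without loss of information
#' beyond the truncation threshold; this is what makes the inversion
#' tractable at full acquisition sizes.
#'
#' @param K1,K2 Kernels from [build_kernels()] (K2 possibly echo-binned).
#' @param data A [decay_data()] or a plain numeric matrix of matching shape.
#' @param trunc_threshold Singular values below `trunc_threshold` times the
#'   largest are discarded (default 1e-4).
#' @param svd1,svd2 Optional precomputed `svd(K1)` / `svd(K2)` (reused across
#'   subjects sharing one acquisition scheme).
#' @return An object of class `compressed_problem`: `K1t`, `K2t` (truncated
#'   factors `S V^T` of each kernel), `data_proj` (`U1^T M U2`), ranks
#'   `r1`, `r2`, and `lipschitz` = `(s1_max * s2_max)^2`, the curvature
#'   scale of the smooth data-misfit term.
#' @export
compress_problem <- function(K1, K2, data, trunc_threshold = 1e-4,
                             svd1 = NULL, svd2 = NULL) {
  M <- if (inherits(data, "decay_data")) data$signal else data
  stopifnot(is.matrix(M))
  if (nrow(M) != nrow(K1) || ncol(M) != nrow(K2))
    stop("data dimensions do not match kernel axes")
  if (all(M == 0)) stop("degenerate all-zero data")
  if (is.null(svd1)) svd1 <- svd(K1)
  if (is.null(svd2)) svd2 <- svd(K2)
  r1 <- sum(svd1$d >= trunc_threshold * svd1$d[1])
  r2 <- sum(svd2$d >= trunc_threshold * svd2$d[1])
  K1t <- svd1$d[seq_len(r1)] * t(svd1$v[, seq_len(r1), drop = FALSE])
  K2t <- svd2$d[seq_len(r2)] * t(svd2$v[, seq_len(r2), drop = FALSE])
  data_proj <- crossprod(svd1$u[, seq_len(r1), drop = FALSE], M) %*%
    svd2$u[, seq_len(r2), drop = FALSE]
  structure(list(K1t = K1t, K2t = K2t, data_proj = data_proj,
                 r1 = r1, r2 = r2,
                 lipschitz = (svd1$d[1] * svd2$d[1])^2,
                 trunc_threshold = trunc_threshold),
            class = "compressed_problem")
}

#' Spectrum map container
#'
#' @param intensity Non-negative matrix `n1 x n2` over `grid`.
#' @param grid A [log_grid2d()].
#' @param alpha,n_iterations Solver settings used.
#' @param residual_fro Final Frobenius data misfit (compressed domain).
#' @param objective_trace Optional numeric vector of per-iteration objectives.
#' @return An object of class `spectrum_map`.
#' @export
spectrum_map <- function(intensity, grid, alpha = NA_real_,
                         n_iterations = NA_integer_, residual_fro = NA_real_,
                         objective_trace = NULL) {
  stopifnot(is.matrix(intensity), inherits(grid, "log_grid2d"),
            nrow(intensity) == grid$n1, ncol(intensity) == grid$n2)
  if (any(intensity < 0)) stop("spectrum intensity must be non-negative")
  structure(list(intensity = intensity, grid = grid, alpha = alpha,
                 n_iterations = n_iterations, residual_fro = residual_fro,
                 objective_trace = objective_trace),
            class = "spectrum_map")
}

#' @export
print.spectrum_map <- function(x, ...) {
  cat(sprintf(
    "T1-T2 spectrum map: %d x %d grid, alpha = %g, %s iterations, residual = %.4g\n",
    x$grid$n1, x$grid$n2, x$alpha, format(x$n_iterations), x$residual_fro))
  invisible(x)
}

# Non-negative least squares by the Lawson-Hanson active-set method.
# Deterministic; runs until the maximal passive-set gradient falls to a
# numerical floor, so weakly determined components are still placed.
nnls_lh <- function(C, d, itmax = 3000) {
  n <- ncol(C)
  x <- numeric(n)
  P <- logical(n)
  r <- d
  w <- as.vector(crossprod(C, r))
  tol <- 1e-10 * sqrt(sum(d^2))
  it <- 0
  repeat {
    ww <- w
    ww[P] <- -Inf
    jmax <- which.max(ww)
    if (ww[jmax] <= tol || all(P)) break
    P[jmax] <- TRUE
    repeat {
      it <- it + 1
      if (it > itmax) return(list(x = x, resid2 = sum(r^2), iters = it))
      z <- numeric(n)
      z[P] <- qr.coef(qr(C[, P, drop = FALSE]), d)
      z[is.na(z)] <- 0
      if (all(z[P] > 1e-14)) {
        x <- z
        break
      }
      neg <- P & (z <= 1e-14)
      a <- min(x[neg] / (x[neg] - z[neg] + 1e-300))
      x <- pmax(x + a * (z - x), 0)
      P[P & x <= 1e-14] <- FALSE
      x[!P] <- 0
    }
    r <- d - C[, P, drop = FALSE] %*% x[P, drop = FALSE]
    w <- as.vector(crossprod(C, r))
  }
  list(x = x, resid2 = sum(r^2), iters = it)
}

# Separable Gaussian smoothing in grid-cell units (nominal resolution of the
# reconstruction; sub-cell structure is not claimed by the method).
smooth_map <- function(F_, sd_cells) {
  if (sd_cells <= 0) return(F_)
  h <- ceiling(3 * sd_cells)
  k <- stats::dnorm(-h:h, sd = sd_cells)
  k <- k / sum(k)
  conv1 <- function(X) {
    Xp <- rbind(matrix(0, h, ncol(X)), X, matrix(0, h, ncol(X)))
    out <- 0
    for (i in seq_along(k))
      out <- out + k[i] * Xp[i:(i + nrow(X) - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(F_))))
}

#' Solve the non-negative Tikhonov problem by FISTA
#'
#' Minimizes
#' \deqn{\| \tilde M - \tilde K_1 F \tilde K_2^T \|_F^2 + \alpha \|F\|_F^2
#'       \quad \mathrm{s.t.}\ F \ge 0}
#' by accelerated proximal gradient descent (FISTA): a gradient step on the
#' smooth sum (data misfit plus the zeroth-order Tikhonov term) in a
#' diagonal majorizer metric (Gershgorin row-sum bound on the separable
#' Hessian, which gives per-cell step sizes far better adapted to the
#' enormous dynamic range of the exponential-kernel curvatures than the
#' scalar Lipschitz constant), followed by projection onto the non-negative
#' orthant, with Nesterov momentum. A candidate iterate that would increase
#' the objective is rejected and the momentum restarted, so the objective is
#' non-increasing by construction.
#'
#' @param problem A [compress_problem()] result.
#' @param alpha Tikhonov smoothing weight (default 1).
#' @param n_iterations Iteration budget (default 5000).
#' @param grid Optional [log_grid2d()] attached to the returned map; when
#'   `NULL` a unit log grid of matching size is fabricated (useful for toy
#'   problems).
#' @param trace Keep the per-iteration objective trace (default TRUE).
#' @param init Optional starting matrix (default zero).
#' @param support Optional logical matrix; cells outside it are pinned to 0
#'   (used to exclude grid regions the data cannot determine).
#' @return A [spectrum_map()].
#' @export
fista_solve <- function(problem, alpha = 1, n_iterations = 5000,
                        grid = NULL, trace = TRUE, init = NULL,
                        support = NULL) {
  stopifnot(inherits(problem, "compressed_problem"),
            alpha >= 0, n_iterations >= 1)
  Mp <- problem$data_proj
  if (any(!is.finite(Mp))) stop("non-finite values in the projected data")
  G1 <- problem$K1t
  G2 <- problem$K2t
  n1 <- ncol(G1)
  n2 <- ncol(G2)
  rs1 <- rowSums(abs(crossprod(G1)))
  rs2 <- rowSums(abs(crossprod(G2)))
  D <- 2 * outer(rs1, rs2) + 2 * alpha
  project <- function(F_) {
    F_ <- pmax(F_, 0)
    if (!is.null(support)) F_[!support] <- 0
    F_
  }
  obj_of <- function(F_, fit) sum((Mp - fit)^2) + alpha * sum(F_^2)
  F_cur <- if (is.null(init)) matrix(0, n1, n2) else project(init)
  fit_cur <- G1 %*% F_cur %*% t(G2)
  obj_cur <- obj_of(F_cur, fit_cur)
  Y <- F_cur
  fit_Y <- fit_cur
  tk <- 1
  objs <- if (trace) numeric(n_iterations) else NULL
  for (it in seq_len(n_iterations)) {
    grad <- 2 * (crossprod(G1, fit_Y - Mp) %*% G2) + 2 * alpha * Y
    cand <- project(Y - grad / D)
    fit_cand <- G1 %*% cand %*% t(G2)
    obj_cand <- obj_of(cand, fit_cand)
    if (obj_cand <= obj_cur) {
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Y <- cand + ((tk - 1) / t_new) * (cand - F_cur)
      fit_Y <- G1 %*% Y %*% t(G2)
      F_cur <- cand
      fit_cur <- fit_cand
      obj_cur <- obj_cand
      tk <- t_new
    } else {
      # monotone restart: retry as a plain projected-gradient step
      tk <- 1
      Y <- F_cur
      fit_Y <- fit_cur
    }
    if (trace) objs[it] <- obj_cur
  }
  if (is.null(grid)) {
    grid <- log_grid2d(c(1, 10^max(n1 - 1, 1)), c(1, 10^max(n2 - 1, 1)),
                       n1 = n1, n2 = n2)
  }
  spectrum_map(F_cur, grid, alpha = alpha, n_iterations = n_iterations,
               residual_fro = sqrt(sum((Mp - fit_cur)^2)),
               objective_trace = objs)
}

#' Precompute the inversion operator for an acquisition scheme and grid
#'
#' Builds the kernels, the logarithmic echo binning, the truncated SVD
#' compression, the column norms and the sensitivity support once, so that
#' many decay matrices sharing one scheme (a cohort) can be inverted without
#' repeating the setup.
#'
#' Echoes are averaged into logarithmically spaced bins (equal weight per
#' decade of decay) before compression; this prevents the long bulk-water
#' decay, which dominates a linearly sampled echo train, from overwhelming
#' the short-T2 information carried by the early echoes. Grid cells whose
#' T2 lies below the first echo time, or whose kernel column norm is
#' negligible, are outside the data's sensitivity support and are excluded
#' from the fit.
#'
#' @param scheme An [acquisition_scheme()].
#' @param grid A [log_grid2d()].
#' @param trunc_threshold SVD truncation (default 1e-4).
#' @param n_echo_bins Target number of logarithmic echo bins (default 100).
#' @return An object of class `inversion_operator`.
#' @export
inversion_operator <- function(scheme, grid, trunc_threshold = 1e-4,
                               n_echo_bins = 100) {
  stopifnot(inherits(scheme, "acquisition_scheme"),
            inherits(grid, "log_grid2d"))
  ker <- build_kernels(scheme, grid)
  ne <- scheme$n_echoes
  edges <- unique(round(10^seq(0, log10(ne), length.out =
                                 min(n_echo_bins, ne) + 1)))
  bin <- findInterval(seq_len(ne), edges, rightmost.closed = TRUE)
  bin_counts <- as.vector(table(bin))
  bin_rows <- function(X) rowsum(X, bin) / bin_counts
  K2b <- bin_rows(ker$K2)
  svd1 <- svd(ker$K1)
  svd2 <- svd(K2b)
  support <- outer(rep(TRUE, grid$n1),
                   grid$t2_grid_ms >= scheme$echo_time_us / 1000)
  colnorms <- outer(sqrt(colSums(ker$K1^2)), sqrt(colSums(K2b^2)))
  structure(list(scheme = scheme, grid = grid, K1 = ker$K1, K2b = K2b,
                 bin = bin, svd1 = svd1, svd2 = svd2,
                 trunc_threshold = trunc_threshold,
                 support = support, colnorms = colnorms),
            class = "inversion_operator")
}

#' Invert decay data into a T1-T2 spectrum map
#'
#' The two-dimensional inverse Laplace transform. The pipeline is:
#' logarithmic echo binning, separable-kernel construction, truncated-SVD
#' compression (see [inversion_operator()]), a column-normalized
#' Lawson-Hanson non-negative least-squares solve that places the relaxation
#' components (and initializes the iterative solver; the compressed problem
#' is far too ill-conditioned for any fixed iteration budget from a cold
#' start), [fista_solve()] at the requested smoothing weight for
#' `n_iterations` iterations, and finally rendering at the method's nominal
#' resolution (a Gaussian of `resolution_cells` grid cells; sub-cell
#' structure in a regularized inversion is not meaningful).
#'
#' With `alpha_scale = "noise"` (default) the smoothing weight passed to the
#' solver is `alpha * sigma^2`, with `sigma` the noise level estimated from
#' the data ([estimate_noise_sd()]): the conventional chi-squared-weighted
#' misfit form, under which `alpha = 1` means "smooth at the noise level".
#' Noiseless data therefore gets an essentially unregularized (sharp)
#' solution. `alpha_scale = "absolute"` passes `alpha` through unchanged.
#'
#' @param data A [decay_data()].
#' @param grid A [log_grid2d()] (default 100 x 100).
#' @param alpha Smoothing weight (default 1).
#' @param n_iterations FISTA iteration budget (default 5000).
#' @param trunc_threshold SVD truncation (default 1e-4).
#' @param operator Optional precomputed [inversion_operator()] (must match
#'   `data`'s scheme and `grid`); built on the fly when `NULL`.
#' @param n_echo_bins Logarithmic echo bins (default 100).
#' @param resolution_cells Rendering resolution in grid cells (default 1.5).
#' @param alpha_scale `"noise"` (default) or `"absolute"`, see Details.
#' @param trace Keep the solver objective trace (default FALSE).
#' @return A [spectrum_map()] on `grid`.
#' @export
#' @examples
#' sch <- acquisition_scheme(n_echoes = 500, noise_sd = 0)
#' d <- simulate_decay(preset_phenotype("oxygenated"), sch)
#' g <- log_grid2d(n1 = 40, n2 = 40)
#' sp <- invert_decay(d, g, n_iterations = 200)
invert_decay <- function(data, grid = log_grid2d(), alpha = 1,
                         n_iterations = 5000, trunc_threshold = 1e-4,
                         operator = NULL, n_echo_bins = 100,
                         resolution_cells = 1.5,
                         alpha_scale = c("noise", "absolute"),
                         trace = FALSE) {
  stopifnot(inherits(data, "decay_data"))
  alpha_scale <- match.arg(alpha_scale)
  if (all(data$signal == 0)) {
    return(spectrum_map(matrix(0, grid$n1, grid$n2), grid, alpha = alpha,
                        n_iterations = 0L, residual_fro = 0))
  }
  if (is.null(operator))
    operator <- inversion_operator(data$scheme, grid, trunc_threshold,
                                   n_echo_bins)
  op <- operator
  Mb <- t(rowsum(t(data$signal), op$bin) / as.vector(table(op$bin)))
  prob <- compress_problem(op$K1, op$K2b, Mb, op$trunc_threshold,
                           svd1 = op$svd1, svd2 = op$svd2)
  alpha_eff <- if (alpha_scale == "noise")
    alpha * estimate_noise_sd(data$signal)^2 else alpha
  # active-set placement on the column-normalized compressed dictionary
  C <- kronecker(prob$K2t, prob$K1t)
  cn <- as.vector(op$colnorms)
  keep <- as.vector(op$support) & (cn >= 1e-3 * max(cn))
  Cn <- sweep(C[, keep, drop = FALSE], 2, cn[keep], "/")
  sol <- nnls_lh(Cn, as.vector(prob$data_proj))
  x <- numeric(grid$n1 * grid$n2)
  x[keep] <- sol$x / cn[keep]
  F0 <- matrix(x, grid$n1, grid$n2)
  sp <- fista_solve(prob, alpha = alpha_eff, n_iterations = n_iterations,
                    grid = grid, trace = trace, init = F0,
                    support = op$support)
  spectrum_map(smooth_map(sp$intensity, resolution_cells), grid,
               alpha = alpha, n_iterations = n_iterations,
               residual_fro = sp$residual_fro,
               objective_trace = sp$objective_trace)
}
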