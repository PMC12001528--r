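#' Functional principal component analysis of a trajectory family
#'
#' Treats each trajectory as a sampled curve `X_i(t)` and decomposes the
#' family about its mean via the Karhunen-Loeve expansion
#' `X_i(t) = mu(t) + sum_k xi_ik phi_k(t)`: the eigenfunctions `phi_k` of the
#' sample covariance are the dominant modes of variation, and each curve is
#' summarised by its scores `xi_ik`. With a handful of timepoints the
#' analysis is carried out directly on the observed grid as a
#' quadrature-weighted PCA: the covariance matrix `C(s, t)` (denominator
#' `n - 1`) is symmetrised as `W^{1/2} C W^{1/2}` with `W` the diagonal of
#' quadrature weights, eigen-decomposed, and eigenvectors are mapped back by
#' `W^{-1/2}` so that eigenfunctions are orthonormal under the weighted
#' inner product `<f, g> = sum_t w_t f(t) g(t)`. Trapezoid-rule weights
#' (default) respect the irregular spacing of typical sampling designs;
#' `weights = "uniform"` sets all weights to 1, making the fit identical to
#' ordinary PCA of the curve matrix. Eigenfunction signs follow the
#' convention `sum_t w_t phi_k(t) >= 0` (first nonzero element positive on
#' ties), so score signs are reproducible; with it, the first score of a
#' perturbation-recovery family typically tracks the overall magnitude of
#' displacement and the second the timing of the recovery.
#'
#' @param trajectories Long trajectory tibble in which every
#'   `(subject, condition)` group covers the common grid (see
#'   [complete_trajectories()]); at least 2 trajectories.
#' @param K Number of components to retain (default 2);
#'   `K <= min(n - 1, m)` for `n` trajectories on an `m`-point grid.
#' @param weights `"trapezoid"` (default) or `"uniform"` quadrature; grids
#'   with fewer than 3 points fall back to uniform.
#' @return An object of class `mbr_fpca`: `grid`, `mean_curve`, matrix `phi`
#'   (`m x K`), `lambda` (first `K` eigenvalues), `lambda_total` (trace of
#'   the weighted covariance), `explained_fraction`, `weights`, `K`, `n`,
#'   and `scores` — the score tibble for the fitting set (also returned by
#'   [fpca_scores()]). [tidy()] tabulates the components, [glance()] the
#'   fit.
#' @export
fpca_fit <- function(trajectories, K = 2, weights = c("trapezoid", "uniform")) {
  weights <- match.arg(weights)
  tm <- trajectory_matrix(trajectories)
  x <- tm$x
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2) stop("functional PCA needs at least 2 trajectories")
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K != round(K)) {
    stop("K must be a positive integer")
  }
  if (K > min(n - 1, m)) {
    stop("K too large: at most min(n - 1, m) = ", min(n - 1, m), " components")
  }

  w <- quadrature_weights(tm$times, weights)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  covmat <- crossprod(xc) / (n - 1)
  sw <- sqrt(w)
  b <- covmat * tcrossprod(sw) # W^{1/2} C W^{1/2}
  eig <- eigen(b, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  lambda_total <- sum(lambda)

  phi <- eig$vectors[, seq_len(K), drop = FALSE] / sw
  # normalise under <.,.>_w and fix signs
  for (k in seq_len(K)) {
    nrm <- sqrt(sum(w * phi[, k]^2))
    if (nrm > 0) phi[, k] <- phi[, k] / nrm
    s <- sum(w * phi[, k])
    if (abs(s) < 1e-12) {
      nz <- which(abs(phi[, k]) > 1e-12)[1]
      s <- if (length(nz) && !is.na(nz)) phi[nz, k] else 1
    }
    if (s < 0) phi[, k] <- -phi[, k]
  }

  model <- structure(
    list(
      grid = tm$times, mean_curve = mu, phi = phi,
      lambda = lambda[seq_len(K)], lambda_total = lambda_total,
      explained_fraction = if (lambda_total > 0) lambda[seq_len(K)] / lambda_total
                           else rep(0, K),
      weights = w, weight_scheme = weights, K = K, n = n
    ),
    class = "mbr_fpca"
  )
  model$scores <- fpca_scores(model, trajectories)
  model
}

quadrature_weights <- function(times, scheme) {
  m <- length(times)
  if (scheme == "uniform" || m < 3) return(rep(1, m))
  dt <- diff(times)
  c(dt[1] / 2, (dt[-length(dt)] + dt[-1]) / 2, dt[length(dt)] / 2)
}

#' @export
print.mbr_fpca <- function(x, ...) {
  cat("Functional PCA:", x$n, "trajectories on a", length(x$grid), "point grid\n")
  cat("Explained variance:",
      paste(sprintf("FPCA%d %.1f%%", seq_len(x$K), 100 * x$explained_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mbr_fpca <- function(x, ...) {
  tibble::tibble(
    component = paste0("FPCA", seq_len(x$K)),
    eigenvalue = x$lambda,
    explained_fraction = x$explained_fraction,
    cumulative = cumsum(x$explained_fraction)
  )
}

#' @exportS3Method generics::glance
glance.mbr_fpca <- function(x, ...) {
  tibble::tibble(
    n_trajectories = x$n,
    n_timepoints = length(x$grid),
    K = x$K,
    total_variance = x$lambda_total,
    explained_K = sum(x$explained_fraction)
  )
}

#' Functional PCA scores of trajectories
#'
#' Projects each curve on the eigenfunctions:
#' `xi_ik = sum_t w_t (X_i(t) - mu(t)) phi_k(t)`, the quadrature form of the
#' score integral. Scores computed on the fitting set average to zero.
#'
#' @param model An `mbr_fpca` fit.
#' @param trajectories Long trajectory tibble on the model grid.
#' @return A tibble: `subject_id`, `condition`, `FPCA1` ... `FPCAK`.
#' @export
fpca_scores <- function(model, trajectories) {
  stopifnot(inherits(model, "mbr_fpca"))
  tm <- trajectory_matrix(trajectories, grid = model$grid)
  xc <- sweep(tm$x, 2, model$mean_curve, "-")
  xi <- xc %*% (model$phi * model$weights)
  colnames(xi) <- paste0("FPCA", seq_len(model$K))
  dplyr::bind_cols(tm$ids, tibble::as_tibble(xi))
}

#' Reconstruct trajectories from truncated score expansions
#'
#' Rebuilds each curve as `mu(t) + sum_{k <= N} xi_ik phi_k(t)`; larger `N`
#' recovers more of the variability, and `N = 0` returns the mean curve for
#' every trajectory.
#'
#' @param model An `mbr_fpca` fit.
#' @param scores Score tibble from [fpca_scores()].
#' @param N Truncation order, `0 <= N <= K` (default all `K` components).
#' @return A long trajectory tibble with the reconstructed `distance`.
#' @export
fpca_reconstruct <- function(model, scores, N = model$K) {
  stopifnot(inherits(model, "mbr_fpca"))
  if (!is.numeric(N) || length(N) != 1 || N < 0 || N != round(N)) {
    stop("N must be a non-negative integer")
  }
  if (N > model$K) stop("N exceeds the number of fitted components K = ", model$K)
  xi <- as.matrix(scores[, paste0("FPCA", seq_len(model$K)), drop = FALSE])
  fitted <- matrix(model$mean_curve, nrow(xi), length(model$grid), byrow = TRUE)
  if (N > 0) {
    fitted <- fitted +
      xi[, seq_len(N), drop = FALSE] %*% t(model$phi[, seq_len(N), drop = FALSE])
  }
  long_curves(scores[, c("subject_id", "condition")], model$grid, fitted)
}

#' Simulate trajectory families over a score grid
#'
#' Generates one synthetic curve `mu + a phi_1 + b phi_2` for every pair
#' `(a, b)` in the Cartesian product of the supplied score values — a direct
#' way to visualise how the two scores jointly shape
#' perturbation-and-recovery behaviour.
#'
#' @param model An `mbr_fpca` fit with `K >= 2`.
#' @param xi1_values,xi2_values Numeric vectors of first- and second-score
#'   values.
#' @return A long trajectory tibble with one simulated curve per grid cell,
#'   labelled by columns `xi1` and `xi2` (`length(xi1_values) *
#'   length(xi2_values)` curves in total).
#' @export
simulate_family <- function(model, xi1_values, xi2_values) {
  stopifnot(inherits(model, "mbr_fpca"))
  if (model$K < 2) stop("score-grid simulation needs a model with K >= 2")
  grid <- expand.grid(xi2 = xi2_values, xi1 = xi1_values)[, c("xi1", "xi2")]
  curves <- matrix(model$mean_curve, nrow(grid), length(model$grid), byrow = TRUE) +
    as.matrix(grid) %*% t(model$phi[, 1:2, drop = FALSE])
  ids <- tibble::tibble(
    subject_id = sprintf("sim%03d", seq_len(nrow(grid))),
    condition = "simulated"
  )
  out <- long_curves(ids, model$grid, curves)
  dplyr::left_join(
    out,
    dplyr::bind_cols(ids, tibble::as_tibble(grid)),
    by = c("subject_id", "condition")
  )
}

long_curves <- function(ids, times, x) {
  n <- nrow(x)
  tibble::tibble(
    subject_id = rep(ids$subject_id, each = length(times)),
    condition = rep(ids$condition, each = length(times)),
    time_h = rep(times, n),
    distance = as.vector(t(x)),
    is_baseline = FALSE
  )
}

#' Correlation between scores and distances over time
#'
#' Pearson correlation, across trajectories, between each score column and
#' the distance at each grid time — the diagnostic that shows which aspects
#' of the curves each score encodes (e.g. a first score correlated with the
#' distance at all timepoints reads as overall perturbation magnitude).
#'
#' @param scores Score tibble from [fpca_scores()].
#' @param trajectories The matching trajectory tibble (same trajectories, on
#'   one common grid); at least 3 trajectories.
#' @return A tibble `score`, `time_h`, `correlation`; cells where either
#'   variable is constant are `NA`.
#' @export
score_distance_correlation <- function(scores, trajectories) {
  tm <- trajectory_matrix(trajectories)
  key <- paste(tm$ids$subject_id, tm$ids$condition, sep = "\r")
  skey <- paste(scores$subject_id, scores$condition, sep = "\r")
  if (!setequal(key, skey) || nrow(scores) != nrow(tm$x)) {
    stop("scores and trajectories cover different (subject, condition) sets")
  }
  if (nrow(scores) < 3) stop("need at least 3 trajectories for correlations")
  x <- tm$x[match(skey, key), , drop = FALSE]
  score_cols <- grep("^FPCA[0-9]+$", names(scores), value = TRUE)
  purrr::map_dfr(score_cols, function(sc) {
    xi <- scores[[sc]]
    tibble::tibble(
      score = sc,
      time_h = tm$times,
      correlation = vapply(seq_along(tm$times), function(j) {
        d <- x[, j]
        if (stats::sd(d) == 0 || stats::sd(xi) == 0) return(NA_real_)
        stats::cor(xi, d)
      }, numeric(1))
    )
  })
}

#' Per-group score summaries
#'
#' Arithmetic mean and sample standard deviation (n - 1) of each score
#' within groups; the standard deviation is `NA` for singleton groups.
#'
#' @param scores Score tibble.
#' @param by Grouping column (default `"condition"`).
#' @return A tibble with one row per group and score: `by`, `score`,
#'   `mean`, `sd`, `n`.
#' @export
score_group_summary <- function(scores, by = "condition") {
  if (!by %in% names(scores)) stop("grouping column not found: ", by)
  score_cols <- grep("^FPCA[0-9]+$", names(scores), value = TRUE)
  if (!length(score_cols)) stop("no FPCA score columns found")
  long <- tidyr::pivot_longer(scores[, c(by, score_cols)],
                              dplyr::all_of(score_cols),
                              names_to = "score", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data[[by]], .data$score),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), NA_real_),
    n = dplyr::n(),
    .groups = "drop"
  )
}
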