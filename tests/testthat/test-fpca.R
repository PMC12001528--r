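# random smooth-ish curve family on the default grid
random_family <- function(n, times = default_grid, seed = 1) {
  withr::with_seed(seed, {
    w <- trapz_weights(times)
    phi <- orthonormal_pair(length(times), w, seed = seed + 100)
    mu <- 5 * sin(seq(0, pi, length.out = length(times)))
    x <- matrix(mu, n, length(times), byrow = TRUE) +
      cbind(rnorm(n, 0, 2), rnorm(n, 0, 1)) %*% t(phi) +
      matrix(rnorm(n * length(times), 0, 0.1), n)
    make_traj(x, times)
  })
}

test_that("identical trajectories give zero eigenvalues and the common mean", {
  x <- rbind(c(0, 2, 4, 3, 1, 0), c(0, 2, 4, 3, 1, 0), c(0, 2, 4, 3, 1, 0))
  m <- fpca_fit(make_traj(x, default_grid), K = 2)
  expect_equal(m$mean_curve, x[1, ], ignore_attr = TRUE)
  expect_equal(m$lambda, c(0, 0), tolerance = 1e-12)
  expect_equal(m$lambda_total, 0, tolerance = 1e-12)
})

test_that("two-curve family recovers the generating mode (brute-force oracle)", {
  times <- default_grid
  w <- trapz_weights(times)
  phi <- orthonormal_pair(6, w, seed = 3)[, 1]
  mu <- c(0, 2, 5, 4, 2, 1)
  traj <- make_traj(rbind(mu + phi, mu - phi), times)
  m <- fpca_fit(traj, K = 1)

  # oracle: eigendecomposition of W^{1/2} C W^{1/2} done from scratch
  covmat <- 2 * tcrossprod(phi) # n = 2, denominator n - 1
  oracle <- eigen(diag(sqrt(w)) %*% covmat %*% diag(sqrt(w)), symmetric = TRUE)
  expect_equal(m$lambda[1], oracle$values[1], tolerance = 1e-10)
  expect_equal(m$lambda[1], 2, tolerance = 1e-10) # 2 <phi,phi>_w
  expect_equal(m$explained_fraction[1], 1, tolerance = 1e-10)
  expect_equal(m$mean_curve, mu, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(abs(m$phi[, 1]), abs(phi), tolerance = 1e-8)
  expect_setequal(round(m$scores$FPCA1, 8), c(1, -1))
})

test_that("eigenfunctions are w-orthonormal with non-increasing eigenvalues", {
  for (seed in 1:5) {
    m <- fpca_fit(random_family(15, seed = seed), K = 4)
    gram <- t(m$phi) %*% (m$phi * m$weights)
    expect_equal(gram, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(m$lambda) <= 1e-10))
    expect_true(all(m$lambda >= 0))
    expect_lte(sum(m$explained_fraction), 1 + 1e-10)
    # sign convention: non-negative weighted integral
    expect_true(all(colSums(m$phi * m$weights) >= -1e-9))
  }
})

test_that("the eigenvalue total preserves the weighted covariance trace", {
  for (seed in 1:5) {
    traj <- random_family(12, seed = seed)
    m <- fpca_fit(traj, K = 2)
    x <- trajectory_matrix(traj)$x
    cvar <- apply(x, 2, stats::var) # diagonal of C, n - 1 denominator
    expect_equal(m$lambda_total, sum(m$weights * cvar), tolerance = 1e-8)
  }
})

test_that("uniform weights reproduce ordinary matrix PCA", {
  traj <- random_family(20, seed = 9)
  m <- fpca_fit(traj, K = 3, weights = "uniform")
  x <- trajectory_matrix(traj)$x
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(m$lambda[1:3], (pca$sdev^2)[1:3], tolerance = 1e-8)
  for (k in 1:3) {
    expect_equal(abs(m$phi[, k]), abs(pca$rotation[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("scores are quadrature projections: mean curve maps to zero, modes to coordinates", {
  traj <- random_family(10, seed = 4)
  m <- fpca_fit(traj, K = 2)

  mean_traj <- make_traj(matrix(m$mean_curve, 1), m$grid)
  expect_equal(unlist(fpca_scores(m, mean_traj)[, c("FPCA1", "FPCA2")]),
               c(FPCA1 = 0, FPCA2 = 0), tolerance = 1e-10)

  shifted <- make_traj(matrix(m$mean_curve + 2.5 * m$phi[, 1], 1), m$grid)
  sc <- fpca_scores(m, shifted)
  expect_equal(sc$FPCA1, 2.5, tolerance = 1e-10)
  expect_equal(sc$FPCA2, 0, tolerance = 1e-10)

  # fitting-set scores are centred
  expect_equal(colMeans(as.matrix(m$scores[, c("FPCA1", "FPCA2")])),
               c(FPCA1 = 0, FPCA2 = 0), tolerance = 1e-8)
})

test_that("score computation rejects a mismatched grid", {
  m <- fpca_fit(random_family(6, seed = 2), K = 1)
  other <- make_traj(matrix(1:4, 1), c(0, 1, 2, 3))
  expect_error(fpca_scores(m, other), "grid")
})

test_that("reconstruction improves with N and is exact at full rank", {
  traj <- random_family(8, seed = 5)
  m <- fpca_fit(traj, K = 6) # full rank: K = m
  x <- trajectory_matrix(traj)$x

  rec0 <- trajectory_matrix(fpca_reconstruct(m, m$scores, N = 0))$x
  expect_equal(rec0, matrix(m$mean_curve, 8, 6, byrow = TRUE), ignore_attr = TRUE)

  errs <- vapply(0:6, function(N) {
    max(abs(trajectory_matrix(fpca_reconstruct(m, m$scores, N = N))$x - x))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9)) # non-increasing error in N
  expect_lte(errs[7], 1e-8)            # spectral completeness on the fitting set
  expect_error(fpca_reconstruct(m, m$scores, N = 7), "exceeds")
})

test_that("simulated score-grid families have the right cardinality and round-trip", {
  m <- fpca_fit(random_family(10, seed = 6), K = 2)

  just_mean <- simulate_family(m, 0, 0)
  expect_equal(dplyr::n_distinct(just_mean$subject_id), 1)
  expect_equal(just_mean$distance, m$mean_curve, ignore_attr = TRUE)

  one_mode <- simulate_family(m, 3.7, 0)
  expect_equal(one_mode$distance, m$mean_curve + 3.7 * m$phi[, 1],
               ignore_attr = TRUE, tolerance = 1e-12)

  fam <- simulate_family(m, c(-25, -6, 4), c(-16, -4, 4))
  expect_equal(dplyr::n_distinct(fam$subject_id), 9)
  sc <- fpca_scores(m, fam)
  labels <- dplyr::distinct(fam[, c("subject_id", "xi1", "xi2")])
  joined <- dplyr::inner_join(sc, labels, by = "subject_id")
  expect_equal(joined$FPCA1, joined$xi1, tolerance = 1e-8)
  expect_equal(joined$FPCA2, joined$xi2, tolerance = 1e-8)

  m1 <- fpca_fit(random_family(10, seed = 6), K = 1)
  expect_error(simulate_family(m1, 0, 0), "K >= 2")
})

test_that("score-distance correlations match a direct Pearson computation", {
  traj <- random_family(12, seed = 8)
  m <- fpca_fit(traj, K = 2)
  corr <- score_distance_correlation(m$scores, traj)
  x <- trajectory_matrix(traj)$x
  for (j in seq_along(m$grid)) {
    expect_equal(
      dplyr::filter(corr, score == "FPCA1", time_h == m$grid[j])$correlation,
      stats::cor(m$scores$FPCA1, x[, j]), tolerance = 1e-12
    )
  }

  # distances affine in the score -> correlation exactly 1
  xi <- m$scores$FPCA1
  affine <- make_traj(cbind(2 * xi + 5, -1 * xi + 2), c(0, 3))
  sc <- tibble::tibble(subject_id = unique(affine$subject_id),
                       condition = "c1", FPCA1 = xi)
  ca <- score_distance_correlation(sc, affine)
  expect_equal(ca$correlation, c(1, -1), tolerance = 1e-12)

  # constant distances at a time -> NA cell
  const <- make_traj(cbind(xi, rep(7, 12)), c(0, 3))
  cc <- score_distance_correlation(sc, const)
  expect_true(is.na(cc$correlation[cc$time_h == 3]))
  expect_error(score_distance_correlation(sc[1:2, ], affine), "different|at least 3")
})

test_that("per-group score summaries use the sample sd with NA for singletons", {
  scores <- tibble::tibble(
    subject_id = c("a", "b", "c"), condition = c("g1", "g1", "g2"),
    FPCA1 = c(-1, 1, 4), FPCA2 = c(2, 2, 0)
  )
  s <- score_group_summary(scores)
  g1_f1 <- dplyr::filter(s, condition == "g1", score == "FPCA1")
  expect_equal(g1_f1$mean, 0)
  expect_equal(g1_f1$sd, sqrt(2))
  expect_equal(dplyr::filter(s, condition == "g1", score == "FPCA2")$sd, 0)
  expect_true(is.na(dplyr::filter(s, condition == "g2", score == "FPCA1")$sd))
  expect_error(score_group_summary(scores, by = "nope"), "grouping column")
})

test_that("known two-mode families are recovered across seeds", {
  times <- default_grid
  w <- trapz_weights(times)
  frac_err <- numeric(0)
  for (seed in 1:20) {
    phi <- orthonormal_pair(6, w, seed = 40 + seed)
    withr::with_seed(seed, {
      xi1 <- rnorm(200); xi2 <- rnorm(200)
    })
    # realise the target variances (4, 1) exactly in the sample
    xi1 <- (xi1 - mean(xi1)) / sd(xi1) * 2
    xi2 <- (xi2 - mean(xi2)) / sd(xi2) * 1
    x <- matrix(3, 200, 6) + cbind(xi1, xi2) %*% t(phi)
    m <- fpca_fit(make_traj(x, times), K = 2)
    frac_err <- c(frac_err, abs(m$explained_fraction - c(0.8, 0.2)))
    expect_gte(abs(cor(m$scores$FPCA1, xi1)), 0.99)
    expect_gte(abs(cor(m$scores$FPCA2, xi2)), 0.99)
  }
  expect_lte(max(frac_err), 0.03)
})

test_that("fpca_fit rejects undersized or malformed input", {
  expect_error(fpca_fit(make_traj(matrix(1:6, 1), default_grid)), "at least 2")
  traj <- random_family(4, seed = 1)
  expect_error(fpca_fit(traj, K = 4), "K too large")
  expect_error(fpca_fit(traj, K = 0), "positive integer")
  bad <- traj
  bad$distance[3] <- Inf
  expect_error(fpca_fit(bad), "non-finite")
})
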