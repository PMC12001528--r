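# Shared fixtures and independent oracles used across the test files.

# random strictly positive composition-like vector
rand_positive <- function(d) rgamma(d, shape = 0.8) + 1e-6

# wide abundance tibble from a samples x taxa matrix
make_table <- function(m, sample_ids = sprintf("s%03d", seq_len(nrow(m))),
                       taxon_ids = sprintf("t%03d", seq_len(ncol(m)))) {
  rownames(m) <- sample_ids
  colnames(m) <- taxon_ids
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), tibble::as_tibble(m))
}

# independent CLR / distance oracles (straight from the definitions)
oracle_clr <- function(x) log(x) - mean(log(x))
oracle_aitchison <- function(u, v) {
  u <- u / sum(u); v <- v / sum(v)
  sqrt(sum((oracle_clr(u) - oracle_clr(v))^2))
}

# brute-force halfspace depth over a fan of directions
oracle_depth <- function(p, cloud, n_dir = 3600) {
  ang <- seq(0, pi, length.out = n_dir)
  v <- sweep(as.matrix(cloud), 2, p)
  counts <- vapply(ang, function(a) {
    proj <- v %*% c(cos(a), sin(a))
    min(sum(proj >= -1e-9), sum(-proj >= -1e-9))
  }, numeric(1))
  min(counts)
}

# long trajectory tibble from a curves matrix (rows = trajectories)
make_traj <- function(x, times, conditions = "c1") {
  n <- nrow(x)
  if (length(conditions) == 1) conditions <- rep(conditions, n)
  tibble::tibble(
    subject_id = rep(sprintf("s%03d", seq_len(n)), each = length(times)),
    condition = rep(conditions, each = length(times)),
    time_h = rep(times, n),
    distance = as.vector(t(x)),
    is_baseline = FALSE
  )
}

# two vectors orthonormal under the quadrature weights w (Gram-Schmidt)
orthonormal_pair <- function(m, w, seed = 1) {
  withr::with_seed(seed, {
    a <- stats::rnorm(m)
    b <- stats::rnorm(m)
  })
  a <- a / sqrt(sum(w * a^2))
  b <- b - sum(w * a * b) * a
  b <- b / sqrt(sum(w * b^2))
  cbind(a, b)
}

default_grid <- c(0, 0.5, 3, 6, 24, 48)

trapz_weights <- function(times) {
  dt <- diff(times)
  c(dt[1] / 2, (dt[-length(dt)] + dt[-1]) / 2, dt[length(dt)] / 2)
}
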