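# two-subject fixture with hand-computable distances
two_subject_fixture <- function() {
  m <- rbind(
    c(0.8, 0.2), # s1 baseline
    c(0.2, 0.8), # s1 at 3 h -> distance sqrt(2) log 4
    c(0.5, 0.5), # s2 baseline
    c(0.5, 0.5)  # s2 at 3 h -> distance 0
  )
  tbl <- make_table(m, sample_ids = c("a0", "a3", "b0", "b3"))
  meta <- tibble::tibble(
    sample_id = c("a0", "a3", "b0", "b3"),
    subject_id = c("A", "A", "B", "B"),
    condition = "run",
    time_h = c(0, 3, 0, 3),
    is_baseline = c(TRUE, FALSE, TRUE, FALSE)
  )
  list(table = tbl, meta = meta)
}

test_that("distances from baseline match the Aitchison oracle", {
  fx <- two_subject_fixture()
  traj <- build_trajectories(fx$table, fx$meta)
  a <- dplyr::filter(traj, subject_id == "A")
  expect_equal(a$time_h, c(0, 3))
  expect_equal(a$distance, c(0, sqrt(2) * log(4)), tolerance = 1e-9)
  expect_equal(a$distance[2], 1.960516, tolerance = 1e-6)
  b <- dplyr::filter(traj, subject_id == "B")
  expect_equal(b$distance, c(0, 0))
  expect_identical(traj$is_baseline, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("include_t0 controls the anchoring point", {
  fx <- two_subject_fixture()
  with_t0 <- build_trajectories(fx$table, fx$meta, include_t0 = TRUE)
  without <- build_trajectories(fx$table, fx$meta, include_t0 = FALSE)
  expect_equal(nrow(with_t0) - nrow(without), 2) # one anchor per trajectory
  expect_true(all(with_t0$distance[with_t0$is_baseline] == 0))
  expect_false(any(without$is_baseline))
})

test_that("baseline resolution errors name the offending group", {
  fx <- two_subject_fixture()
  meta_nobase <- dplyr::mutate(fx$meta, is_baseline = FALSE)
  expect_error(build_trajectories(fx$table, meta_nobase), "\\(A, run\\)")
  expect_error(
    build_trajectories(fx$table, fx$meta, baseline_mode = "fixed_sample",
                       fixed_baseline = "nope"),
    "not found: nope"
  )
  expect_error(
    build_trajectories(fx$table, fx$meta, baseline_mode = "fixed_sample"),
    "fixed_baseline is required"
  )
  meta_extra <- dplyr::bind_rows(fx$meta, tibble::tibble(
    sample_id = "ghost", subject_id = "C", condition = "run",
    time_h = 0, is_baseline = TRUE))
  expect_error(build_trajectories(fx$table, meta_extra), "absent from table: ghost")
})

test_that("a fixed baseline sample is used for every trajectory", {
  fx <- two_subject_fixture()
  traj <- build_trajectories(fx$table, fx$meta, baseline_mode = "fixed_sample",
                             fixed_baseline = "a0")
  b3 <- dplyr::filter(traj, subject_id == "B", time_h == 3)
  expect_equal(b3$distance, aitchison_distance(c(0.5, 0.5), c(0.8, 0.2)),
               tolerance = 1e-12)
})

test_that("trajectories inherit Aitchison scale invariance", {
  fx <- two_subject_fixture()
  scaled <- fx$table
  scaled[2, -1] <- scaled[2, -1] * 37.5 # rescale one sample row
  expect_equal(build_trajectories(scaled, fx$meta),
               build_trajectories(fx$table, fx$meta), tolerance = 1e-12)
})

test_that("taxon-subset trajectories equal distances on re-closed subcompositions", {
  set.seed(707)
  m <- matrix(rgamma(8 * 6, 1) + 0.01, 8, 6)
  m <- m / rowSums(m)
  tbl <- make_table(m)
  meta <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:8),
    subject_id = rep(c("A", "B"), each = 4),
    condition = "run",
    time_h = rep(c(0, 3, 6, 24), 2),
    is_baseline = rep(c(TRUE, FALSE, FALSE, FALSE), 2)
  )
  taxa <- c("t002", "t005", "t006")
  traj_sub <- build_trajectories(subset_and_reclose(tbl, taxa), meta)
  idx <- c(2, 5, 6)
  d_manual <- aitchison_distance(close_composition(m[2, idx]),
                                 close_composition(m[1, idx]))
  got <- dplyr::filter(traj_sub, subject_id == "A", time_h == 3)$distance
  expect_equal(got, d_manual, tolerance = 1e-12)
})

test_that("group mean/SE follow the n-1 convention with NA for singletons", {
  traj <- tibble::tibble(
    subject_id = c("A", "B"), condition = "run",
    time_h = 3, distance = c(1, 3), is_baseline = FALSE
  )
  s <- group_mean_se(traj)
  expect_equal(s$mean_distance, 2)
  expect_equal(s$se, 1) # sd = sqrt(2), se = sqrt(2)/sqrt(2)
  expect_equal(s$n, 2L)

  twin <- make_traj(rbind(c(1, 2), c(1, 2)), c(3, 6))
  expect_equal(group_mean_se(twin)$se, c(0, 0))

  single <- make_traj(rbind(c(1, 2)), c(3, 6))
  expect_true(all(is.na(group_mean_se(single)$se)))
  expect_equal(group_mean_se(single)$mean_distance, c(1, 2))
  expect_error(group_mean_se(traj, by = "nope"), "grouping column")
})

test_that("overall mean distance pools non-baseline points only", {
  traj <- tibble::tibble(
    subject_id = c("A", "A", "B"), condition = "run",
    time_h = c(0, 3, 3), distance = c(0, 0, 2),
    is_baseline = c(TRUE, FALSE, FALSE)
  )
  out <- overall_mean_distance(traj)
  expect_equal(out$mean_distance, 1)
  expect_equal(out$se, 1)
  expect_equal(out$n, 2L)

  const <- make_traj(rbind(c(5, 5), c(5, 5)), c(3, 6))
  expect_equal(overall_mean_distance(const)$mean_distance, 5)
  expect_equal(overall_mean_distance(const)$se, 0)
  expect_error(overall_mean_distance(traj[traj$is_baseline, ]), "no non-baseline")
})

test_that("grid completion drops or interpolates incomplete trajectories", {
  full <- make_traj(rbind(c(0, 2, 4, 2), c(0, 1, 2, 1)), c(0, 3, 6, 24))
  gap <- tibble::tibble(subject_id = "s999", condition = "c1",
                        time_h = c(0, 3, 24), distance = c(0, 3, 1),
                        is_baseline = FALSE)
  traj <- dplyr::bind_rows(full, gap)

  dropped <- complete_trajectories(traj, "drop")
  expect_false("s999" %in% dropped$subject_id)
  expect_equal(nrow(dropped), 8)

  interp <- complete_trajectories(traj, "interpolate")
  expect_true("s999" %in% interp$subject_id)
  filled <- dplyr::filter(interp, subject_id == "s999", time_h == 6)$distance
  expect_equal(filled, approx(c(3, 24), c(3, 1), xout = 6)$y)

  # a trajectory missing the last grid point cannot be interpolated
  tail_gap <- tibble::tibble(subject_id = "s998", condition = "c1",
                             time_h = c(0, 3, 6), distance = c(0, 3, 1),
                             is_baseline = FALSE)
  out <- complete_trajectories(dplyr::bind_rows(full, tail_gap), "interpolate")
  expect_false("s998" %in% out$subject_id)
})
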