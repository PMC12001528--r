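#' Build Aitchison-distance trajectories from a baseline
#'
#' For each `(subject, condition)` group the composition at every timepoint
#' is compared with a reference ("baseline") composition by Aitchison
#' distance, producing one distance-versus-time trajectory per group. Two
#' baseline modes are supported:
#'
#' * `"per_condition"`: the sample flagged `is_baseline` within each
#'   `(subject, condition)` group (e.g. the pre-exercise sample of that
#'   exercise bout); exactly one such flag per group is required.
#' * `"fixed_sample"`: a single named sample is the reference for every
#'   trajectory, useful for measuring long-term drift of the baseline state
#'   itself.
#'
#' @param table Strictly positive abundance table (zeros already replaced,
#'   typically restricted with [subset_and_reclose()]).
#' @param meta Sample metadata (see [read_sample_metadata()]); it must cover
#'   every sample used.
#' @param baseline_mode `"per_condition"` (default) or `"fixed_sample"`.
#' @param fixed_baseline Sample id of the common reference, required when
#'   `baseline_mode = "fixed_sample"`.
#' @param include_t0 Prepend the baseline point itself, at its own time with
#'   distance 0 (default `TRUE`); anchoring every curve at zero stabilises
#'   the functional mean at the start of the grid.
#' @return A long tibble — the trajectory set — with columns `subject_id`,
#'   `condition`, `time_h`, `distance`, `is_baseline`, sorted by group and
#'   time.
#' @export
build_trajectories <- function(table, meta,
                               baseline_mode = c("per_condition", "fixed_sample"),
                               fixed_baseline = NULL,
                               include_t0 = TRUE) {
  baseline_mode <- match.arg(baseline_mode)
  meta <- validate_metadata(meta)
  m <- abundance_matrix(table)
  if (any(m <= 0)) stop("zeros must be replaced before computing distances")

  absent <- setdiff(meta$sample_id, rownames(m))
  if (length(absent)) {
    stop("sample(s) in metadata absent from table: ", paste(absent, collapse = ", "))
  }

  if (baseline_mode == "fixed_sample") {
    if (is.null(fixed_baseline)) stop("fixed_baseline is required for baseline_mode = \"fixed_sample\"")
    if (!fixed_baseline %in% rownames(m)) stop("fixed_baseline sample not found: ", fixed_baseline)
  }

  groups <- dplyr::group_split(dplyr::group_by(meta, .data$subject_id, .data$condition))
  rows <- purrr::map(groups, function(g) {
    if (baseline_mode == "per_condition") {
      nb <- sum(g$is_baseline)
      if (nb != 1) {
        stop("expected exactly one baseline for (", g$subject_id[1], ", ",
             g$condition[1], "); found ", nb)
      }
      base_id <- g$sample_id[g$is_baseline]
      base_time <- g$time_h[g$is_baseline]
    } else {
      base_id <- fixed_baseline
      base_time <- min(g$time_h)
    }
    base_comp <- m[base_id, ]
    obs <- g[!(g$sample_id == base_id), , drop = FALSE]
    d <- vapply(obs$sample_id, function(s) aitchison_distance(m[s, ], base_comp),
                numeric(1))
    out <- tibble::tibble(
      subject_id = g$subject_id[1], condition = g$condition[1],
      time_h = obs$time_h, distance = unname(d), is_baseline = FALSE
    )
    if (include_t0 && baseline_mode == "per_condition") {
      out <- dplyr::bind_rows(
        tibble::tibble(subject_id = g$subject_id[1], condition = g$condition[1],
                       time_h = base_time, distance = 0, is_baseline = TRUE),
        out
      )
    }
    dplyr::arrange(out, .data$time_h)
  })
  dplyr::bind_rows(rows)
}

#' Group mean and standard error of trajectories over time
#'
#' At each observed time the distances of all trajectories in a group are
#' averaged; the standard error is the sample standard deviation (n - 1
#' denominator) divided by `sqrt(n)`, reported as `NA` when only one
#' trajectory contributes.
#'
#' @param trajectories Long trajectory tibble from [build_trajectories()].
#' @param by Grouping column name (default `"condition"`).
#' @return A tibble with `by`, `time_h`, `mean_distance`, `se`, `n`.
#' @export
group_mean_se <- function(trajectories, by = "condition") {
  check_trajectories(trajectories)
  if (!by %in% names(trajectories)) stop("grouping column not found: ", by)
  dplyr::summarise(
    dplyr::group_by(trajectories, .data[[by]], .data$time_h),
    mean_distance = mean(.data$distance),
    se = ifelse(dplyr::n() > 1, stats::sd(.data$distance) / sqrt(dplyr::n()), NA_real_),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Pooled mean distance from baseline
#'
#' Pools every non-baseline point of every trajectory and reports the mean
#' distance with its standard error — the single-number summary of how far,
#' on average, the community moved from its reference state.
#'
#' @param trajectories Long trajectory tibble.
#' @return One-row tibble with `mean_distance`, `se`, `n`.
#' @export
overall_mean_distance <- function(trajectories) {
  check_trajectories(trajectories)
  d <- trajectories$distance[!trajectories$is_baseline]
  if (!length(d)) stop("no non-baseline points to summarise")
  tibble::tibble(
    mean_distance = mean(d),
    se = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
    n = length(d)
  )
}

#' Align trajectories on the common time grid
#'
#' Functional PCA needs every trajectory observed on the same grid (the
#' sorted union of observed times). Groups with missing grid points are
#' either dropped (`"drop"`, default) or filled by linear interpolation
#' between their observed points (`"interpolate"`; no extrapolation —
#' a group missing an endpoint of the grid is dropped either way).
#'
#' @param trajectories Long trajectory tibble.
#' @param missing `"drop"` or `"interpolate"`.
#' @return A long trajectory tibble in which every `(subject, condition)`
#'   group covers the full grid.
#' @export
complete_trajectories <- function(trajectories, missing = c("drop", "interpolate")) {
  missing <- match.arg(missing)
  check_trajectories(trajectories)
  grid <- sort(unique(trajectories$time_h))
  groups <- dplyr::group_split(
    dplyr::group_by(trajectories, .data$subject_id, .data$condition)
  )
  rows <- purrr::map(groups, function(g) {
    have <- grid %in% g$time_h
    if (all(have)) return(dplyr::arrange(g, .data$time_h))
    if (missing == "drop") return(NULL)
    if (min(g$time_h) > grid[1] || max(g$time_h) < grid[length(grid)]) return(NULL)
    fit <- stats::approx(g$time_h, g$distance, xout = grid)
    tibble::tibble(
      subject_id = g$subject_id[1], condition = g$condition[1],
      time_h = grid, distance = fit$y,
      is_baseline = grid %in% g$time_h[g$is_baseline]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) stop("no trajectory covers the common grid")
  out
}

check_trajectories <- function(trajectories) {
  required <- c("subject_id", "condition", "time_h", "distance")
  missing <- setdiff(required, names(trajectories))
  if (length(missing)) {
    stop("trajectory table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(trajectories)) stop("empty trajectory set")
  if (!"is_baseline" %in% names(trajectories)) {
    trajectories$is_baseline <- FALSE
  }
  invisible(trajectories)
}

# trajectory long table -> curves matrix (rows = trajectories) on a checked grid
trajectory_matrix <- function(trajectories, grid = NULL) {
  check_trajectories(trajectories)
  wide <- tidyr::pivot_wider(
    trajectories[, c("subject_id", "condition", "time_h", "distance")],
    names_from = "time_h", values_from = "distance"
  )
  times <- sort(as.numeric(setdiff(names(wide), c("subject_id", "condition"))))
  if (!is.null(grid)) {
    if (length(times) != length(grid) || any(abs(times - grid) > 1e-9)) {
      stop("trajectory grid does not match the model grid; ",
           "use complete_trajectories() first")
    }
    times <- grid
  }
  x <- as.matrix(wide[, as.character(times), drop = FALSE])
  if (anyNA(x)) {
    bad <- wide[rowSums(is.na(x)) > 0, c("subject_id", "condition")]
    stop("trajectories with missing grid points (use complete_trajectories()): ",
         paste(paste(bad$subject_id, bad$condition, sep = "/"), collapse = ", "))
  }
  if (any(!is.finite(x))) stop("non-finite distances in trajectory set")
  list(ids = wide[, c("subject_id", "condition")], times = times, x = x)
}
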