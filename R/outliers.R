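#' Tukey halfspace depth of a point in a 2-D cloud
#'
#' The halfspace (Tukey) depth of `p` is the minimum, over all closed
#' halfplanes whose boundary passes through `p`, of the number of cloud
#' points the halfplane contains; deep points are central, points outside
#' the convex hull have depth 0. Computed exactly by an angular sweep: the
#' count only changes when the boundary line rotates past a cloud point, so
#' the minimum over the arcs between consecutive point angles is the global
#' minimum.
#'
#' @param p Numeric length-2 point.
#' @param cloud Numeric `n x 2` matrix (or data frame) of points, `n >= 1`.
#' @return Integer depth in `[0, n]`.
#' @export
halfspace_depth <- function(p, cloud) {
  cloud <- as.matrix(cloud)
  if (!is.numeric(p) || length(p) != 2 || !all(is.finite(p))) {
    stop("p must be a finite 2-vector")
  }
  if (ncol(cloud) != 2 || !all(is.finite(cloud))) {
    stop("cloud must be a finite n x 2 matrix")
  }
  v <- sweep(cloud, 2, p)
  r <- sqrt(rowSums(v^2))
  coincident <- r <= 1e-12
  c0 <- sum(coincident)
  if (all(coincident)) return(nrow(cloud))
  th <- sort(atan2(v[!coincident, 2], v[!coincident, 1]))
  tp <- c(th, th + 2 * pi)
  # minimum count over closed arcs (th_i, th_i + pi]
  hi <- findInterval(th + pi + 1e-12, tp)
  lo <- findInterval(th + 1e-12, tp)
  c0 + min(hi - lo)
}

#' Bagplot of a bivariate point cloud
#'
#' A bivariate generalisation of the boxplot built on halfspace depth: the
#' depth median is the centroid of the deepest points, the "bag" is the
#' convex hull of the deepest half of the data (`ceiling(n/2)` points; depth
#' ties at the cut are resolved by distance to the median, exact ties
#' included), and the "fence" is the bag inflated by a factor of 3 about the
#' depth median. Points strictly outside the fence are flagged as outliers.
#'
#' @param points Numeric `n x 2` matrix or a data frame with two numeric
#'   columns; `n >= 10`.
#' @param fence_factor Inflation factor of the fence about the depth median
#'   (default 3, the conventional bagplot constant).
#' @return An object of class `mbr_bagplot`: `points`, integer `depths`,
#'   `depth_median` (length-2), logical `in_bag`, `bag_hull` and
#'   `fence_hull` (vertex matrices), and logical `outlier` flags. [tidy()]
#'   returns the per-point table.
#' @export
bagplot_fit <- function(points, fence_factor = 3) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || !all(is.finite(pts))) stop("points must be a finite n x 2 matrix")
  n <- nrow(pts)
  if (n < 10) stop("too few points for bagplot (need at least 10)")
  ctr <- sweep(pts, 2, colMeans(pts))
  if (svd(ctr, nu = 0, nv = 0)$d[2] < 1e-10 * max(svd(ctr, nu = 0, nv = 0)$d[1], 1)) {
    stop("degenerate 2-D configuration: points are collinear")
  }

  depths <- vapply(seq_len(n), function(i) halfspace_depth(pts[i, ], pts), numeric(1))
  dm <- colMeans(pts[depths == max(depths), , drop = FALSE])
  dist_dm <- sqrt(rowSums(sweep(pts, 2, dm)^2))

  ord <- order(-depths, dist_dm)
  m <- ceiling(n / 2)
  cut_depth <- depths[ord[m]]
  cut_dist <- dist_dm[ord[m]]
  in_bag <- logical(n)
  in_bag[ord[seq_len(m)]] <- TRUE
  # exact ties with the cut point are included
  in_bag[depths == cut_depth & abs(dist_dm - cut_dist) <= 1e-12] <- TRUE

  bag_pts <- pts[in_bag, , drop = FALSE]
  hull_idx <- grDevices::chull(bag_pts)
  bag_hull <- bag_pts[hull_idx, , drop = FALSE]
  if (nrow(unique(bag_hull)) < 3) stop("degenerate 2-D configuration: bag is collinear")
  fence_hull <- sweep(sweep(bag_hull, 2, dm) * fence_factor, 2, dm, "+")
  outlier <- !points_in_convex(pts, fence_hull)

  structure(
    list(points = pts, depths = as.integer(depths), depth_median = dm,
         in_bag = in_bag, bag_hull = bag_hull, fence_hull = fence_hull,
         fence_factor = fence_factor, outlier = outlier),
    class = "mbr_bagplot"
  )
}

# which rows of pts lie inside (or on) the convex polygon with vertices hull
points_in_convex <- function(pts, hull) {
  # orient counter-clockwise
  k <- nrow(hull)
  area2 <- sum(hull[, 1] * hull[c(2:k, 1), 2] - hull[c(2:k, 1), 1] * hull[, 2])
  if (area2 < 0) hull <- hull[k:1, , drop = FALSE]
  scale <- max(abs(hull), 1)
  inside <- rep(TRUE, nrow(pts))
  for (e in seq_len(k)) {
    a <- hull[e, ]
    b <- hull[if (e == k) 1 else e + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cross >= -1e-9 * scale^2
  }
  inside
}

#' @export
print.mbr_bagplot <- function(x, ...) {
  cat("Bagplot of", nrow(x$points), "points:",
      sum(x$in_bag), "in the bag,", sum(x$outlier), "outlier(s)\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mbr_bagplot <- function(x, ...) {
  tibble::tibble(
    x = x$points[, 1], y = x$points[, 2],
    depth = x$depths, in_bag = x$in_bag, outlier = x$outlier
  )
}

#' @exportS3Method generics::glance
glance.mbr_bagplot <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$points),
    n_bag = sum(x$in_bag),
    n_outliers = sum(x$outlier),
    median_x = x$depth_median[1],
    median_y = x$depth_median[2]
  )
}

#' Flag atypical trajectories on the score plane
#'
#' Applies [bagplot_fit()] to the `(FPCA1, FPCA2)` columns of a score table
#' and annotates each trajectory, flagging those whose score pair lies
#' beyond the bagplot fence — trajectories whose shape is globally atypical
#' in the family, without pre-committing to any single curve feature.
#'
#' @param scores Score tibble from [fpca_scores()] with at least 10 rows and
#'   columns `FPCA1`, `FPCA2`.
#' @param fence_factor Passed to [bagplot_fit()].
#' @return `scores` with added columns `depth` and `outlier`; the underlying
#'   `mbr_bagplot` is attached as attribute `"bagplot"`.
#' @export
flag_outlier_trajectories <- function(scores, fence_factor = 3) {
  if (!all(c("FPCA1", "FPCA2") %in% names(scores))) {
    stop("scores must have FPCA1 and FPCA2 columns")
  }
  bp <- bagplot_fit(as.matrix(scores[, c("FPCA1", "FPCA2")]), fence_factor)
  out <- dplyr::mutate(scores, depth = bp$depths, outlier = bp$outlier)
  attr(out, "bagplot") <- bp
  out
}
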