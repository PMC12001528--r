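#' Close a non-negative vector to a composition
#'
#' Rescales a vector of non-negative parts so that it sums to one. Closure
#' discards absolute scale and keeps only the relative information, which is
#' all that a sequencing count vector carries about the community it samples.
#'
#' @param x Numeric vector of non-negative parts with at least one positive
#'   entry.
#' @return Numeric vector proportional to `x` and summing to 1.
#' @examples
#' close_composition(c(1, 1, 2))
#' @export
close_composition <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("composition must be numeric with no missing values")
  if (any(x < 0)) stop("composition has negative entries")
  s <- sum(x)
  if (s <= 0) stop("empty composition: all entries are zero")
  x / s
}

#' Centred log-ratio transform
#'
#' Maps a strictly positive composition to the Euclidean space of zero-sum
#' vectors: `clr(u)_k = log(u_k) - mean(log(u))`, i.e. the log of each part
#' relative to the geometric mean. Natural logarithms are used throughout the
#' package.
#'
#' @param x Strictly positive numeric vector (closure is not required; the
#'   transform is scale invariant).
#' @return Numeric vector of the same length summing to 0.
#' @examples
#' clr(c(0.8, 0.2))
#' @export
clr <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("composition must be numeric with no missing values")
  if (any(x <= 0)) stop("zeros must be replaced before CLR")
  lx <- log(x)
  lx - mean(lx)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the centred log-ratio transforms of two
#' strictly positive vectors. The distance is scale invariant (closure is
#' optional), symmetric, and zero exactly when the two vectors are
#' proportional. Unlike e.g. the Jensen-Shannon divergence it is a true
#' metric that behaves consistently under taxon selection.
#'
#' @param u,v Strictly positive numeric vectors of equal length `D >= 2`.
#' @return Non-negative scalar distance.
#' @examples
#' aitchison_distance(c(0.8, 0.2), c(0.2, 0.8))
#' @export
aitchison_distance <- function(u, v) {
  if (length(u) != length(v)) stop("compositions have different lengths")
  if (length(u) < 2) stop("a composition needs at least 2 parts")
  sqrt(sum((clr(u) - clr(v))^2))
}

#' Replace zeros in an abundance table
#'
#' Log-ratio methods require strictly positive parts, so zeros must be
#' imputed first. Two schemes are provided:
#'
#' * `"multiplicative"`: each zero in a row of proportions is set to `delta`
#'   and the nonzero parts of a row with `z` zeros are multiplied by
#'   `1 - z * delta`, so the row still sums to 1 and all ratios between
#'   nonzero parts are preserved. Rows without zeros are untouched.
#' * `"bayes_multiplicative"`: for count data, a geometric
#'   Bayesian-multiplicative replacement under a uniform prior (one
#'   pseudo-count per taxon): a zero cell in a row with total `n_i` over `D`
#'   taxa becomes `1 / (n_i + D)` of the row, and nonzero parts are shrunk
#'   multiplicatively to keep the row closed. Requires counts (rows not
#'   already summing to 1).
#'
#' Rows that sum to approximately 1 (within `1e-6`) are treated as
#' proportions; any other row is treated as counts and closed first.
#'
#' @param table Abundance table: a data frame whose first column is
#'   `sample_id` and whose remaining columns are non-negative numeric taxa
#'   abundances (counts or proportions). See [read_abundance_table()].
#' @param method `"multiplicative"` (default) or `"bayes_multiplicative"`.
#' @param delta Replacement value for the multiplicative method, either a
#'   positive number smaller than the smallest nonzero proportion in the
#'   table, or `"auto"` (default), which uses 0.65 times that smallest
#'   nonzero proportion.
#' @return A tibble of the same shape with strictly positive closed rows.
#' @examples
#' tbl <- tibble::tibble(sample_id = "s1", A = 0, B = 0.5, C = 0.5)
#' replace_zeros(tbl, delta = 0.01)
#' @export
replace_zeros <- function(table,
                          method = c("multiplicative", "bayes_multiplicative"),
                          delta = "auto") {
  method <- match.arg(method)
  m <- abundance_matrix(table)
  is_counts <- abs(rowSums(m) - 1) > 1e-6
  p <- m / rowSums(m)

  if (method == "bayes_multiplicative") {
    if (!all(is_counts)) {
      stop("bayes_multiplicative zero replacement needs count rows; ",
           "use method = \"multiplicative\" for proportions")
    }
    out <- t(vapply(seq_len(nrow(m)), function(i) {
      row <- m[i, ]
      z <- row == 0
      if (!any(z)) return(row / sum(row))
      repl <- 1 / (sum(row) + ncol(m))
      adj <- row / sum(row) * (1 - sum(z) * repl)
      adj[z] <- repl
      adj
    }, numeric(ncol(m))))
  } else {
    if (identical(delta, "auto")) {
      delta <- 0.65 * min(p[p > 0])
    }
    if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
      stop("delta must be a single positive number or \"auto\"")
    }
    if (delta >= min(p[p > 0])) {
      stop("delta too large: must be below the smallest nonzero proportion (",
           format(min(p[p > 0])), ")")
    }
    nz <- rowSums(p == 0)
    bad <- nz * delta >= 1
    if (any(bad)) {
      stop("delta too large: rows ", paste(rownames(m)[bad], collapse = ", "),
           " would lose all mass")
    }
    out <- p * (1 - nz * delta)
    out[p == 0] <- delta
  }
  dimnames(out) <- dimnames(m)
  matrix_to_abundance(out)
}

#' Close every row of an abundance table
#'
#' @param table Abundance table (see [replace_zeros()] for the layout).
#' @return A tibble with every row summing to 1.
#' @export
close_rows <- function(table) {
  m <- abundance_matrix(table)
  matrix_to_abundance(m / rowSums(m))
}

#' CLR-transform every row of an abundance table
#'
#' @param table Strictly positive abundance table.
#' @return A tibble of the same shape holding centred log-ratios.
#' @export
clr_transform <- function(table) {
  m <- abundance_matrix(table)
  if (any(m <= 0)) stop("zeros must be replaced before CLR")
  lm <- log(m)
  matrix_to_abundance(lm - rowMeans(lm))
}

# ---- internal helpers --------------------------------------------------

# Validated samples x taxa matrix from the wide tibble layout.
abundance_matrix <- function(table) {
  if (!is.data.frame(table) || ncol(table) < 2) {
    stop("abundance table must be a data frame: sample_id column plus taxa columns")
  }
  ids <- as.character(table[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  taxa <- names(table)[-1]
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon_id: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  m <- as.matrix(table[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("abundance values must be numeric with no missing cells")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample ", ids[bad[1]], ", taxon ", taxa[bad[2]])
  }
  zero <- rowSums(m) <= 0
  if (any(zero)) {
    stop("sample(s) with zero total abundance: ", paste(ids[zero], collapse = ", "))
  }
  rownames(m) <- ids
  m
}

matrix_to_abundance <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m)
  )
}
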