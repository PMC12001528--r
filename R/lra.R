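#' Log-ratio analysis of an abundance table
#'
#' Log-ratio analysis (LRA) is a weighted principal component analysis of the
#' log-transformed composition matrix, with uniform row weights `r_i = 1/n`
#' and the mean closed abundance of each taxon as its column weight `c_j`.
#' The log matrix is double centred — rows against the column weights (a
#' weighted centred log-ratio) and then columns against the row weights — to
#' give `y_ij`, and the total log-ratio variance is
#' `sum_ij r_i c_j y_ij^2`. The per-taxon share of that total,
#' `contribution_j = sum_i r_i c_j y_ij^2 / total`, ranks taxa by how much
#' compositional variation they carry, independently of their average
#' abundance; [select_taxa()] then keeps the smallest set reaching a target
#' share. Equivalently the total is a column-weighted average of the
#' pairwise log-ratio variances `Var(log(p_j / p_k))` — the identity the test
#' suite uses as an oracle.
#'
#' @param table Strictly positive abundance table (zeros already replaced;
#'   rows are closed internally).
#' @return An object of class `mbr_lra` with elements `taxon_ids`,
#'   `contributions` (named, summing to 1), `total_variance`, `row_weights`,
#'   `column_weights`, and the double-centred matrix `centered_matrix`.
#'   Use [tidy()] for a ranked tibble or [glance()] for a one-row summary.
#' @examples
#' tbl <- tibble::tibble(sample_id = c("a", "b"), t1 = c(0.8, 0.2), t2 = c(0.2, 0.8))
#' lra_fit(tbl)
#' @export
lra_fit <- function(table) {
  m <- abundance_matrix(table)
  if (nrow(m) < 2) stop("log-ratio analysis needs at least 2 samples")
  if (any(m <= 0)) stop("zeros must be replaced before log-ratio analysis")
  p <- m / rowSums(m)
  n <- nrow(p)
  r <- rep(1 / n, n)
  cw <- colMeans(p)
  cw <- cw / sum(cw)

  l <- log(p)
  a <- l - drop(l %*% cw)              # row-centre with column weights
  y <- sweep(a, 2, colMeans(a), "-")   # column-centre with uniform row weights

  cell_var <- (y^2) * rep(r, ncol(y)) * rep(cw, each = n)
  total <- sum(cell_var)
  if (total <= .Machine$double.eps * n * ncol(y)) {
    stop("no compositional variation: all samples are identical compositions")
  }
  structure(
    list(
      taxon_ids = colnames(p),
      contributions = colSums(cell_var) / total,
      total_variance = total,
      row_weights = r,
      column_weights = cw,
      centered_matrix = y
    ),
    class = "mbr_lra"
  )
}

#' @export
print.mbr_lra <- function(x, ...) {
  cat("Log-ratio analysis:", length(x$taxon_ids), "taxa,",
      length(x$row_weights), "samples\n")
  cat("Total log-ratio variance:", format(x$total_variance, digits = 6), "\n")
  top <- utils::head(sort(x$contributions, decreasing = TRUE), 5)
  cat("Top contributions:\n")
  print(round(top, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mbr_lra <- function(x, ...) {
  out <- tibble::tibble(
    taxon_id = names(x$contributions),
    contribution = unname(x$contributions)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$contribution), .data$taxon_id)
  dplyr::mutate(out, rank = dplyr::row_number(),
                cumulative = cumsum(.data$contribution))
}

#' @exportS3Method generics::glance
glance.mbr_lra <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$row_weights),
    n_taxa = length(x$taxon_ids),
    total_variance = x$total_variance
  )
}

#' Select the smallest taxon set explaining a variance share
#'
#' Ranks taxa by decreasing contribution to the total log-ratio variance
#' (ties broken alphabetically by taxon id) and returns the shortest prefix
#' whose cumulative contribution reaches `threshold`.
#'
#' @param result An `mbr_lra` fit from [lra_fit()].
#' @param threshold Target cumulative variance share in `(0, 1]`
#'   (default 0.9).
#' @return A tibble with columns `rank`, `taxon_id`, `contribution`,
#'   `cumulative`, one row per selected taxon in rank order.
#' @export
select_taxa <- function(result, threshold = 0.9) {
  if (!inherits(result, "mbr_lra")) stop("result must come from lra_fit()")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]")
  }
  ranked <- tidy.mbr_lra(result)
  keep <- which(ranked$cumulative >= threshold - 1e-12)[1]
  if (is.na(keep)) keep <- nrow(ranked) # numerical guard; cumulative ends at 1
  ranked[seq_len(keep), c("rank", "taxon_id", "contribution", "cumulative")]
}

#' Restrict an abundance table to a taxon subset and re-close
#'
#' Keeps the named taxa and rescales each row of the subcomposition to sum
#' to 1, so downstream distances are computed on the selected parts only.
#'
#' @param table Abundance table.
#' @param taxa Character vector of taxon ids, or a tibble with a `taxon_id`
#'   column such as the output of [select_taxa()].
#' @return Abundance table tibble restricted to `taxa`, rows closed.
#' @export
subset_and_reclose <- function(table, taxa) {
  if (is.data.frame(taxa)) {
    if (!"taxon_id" %in% names(taxa)) stop("taxa data frame needs a taxon_id column")
    taxa <- taxa$taxon_id
  }
  taxa <- as.character(taxa)
  m <- abundance_matrix(table)
  missing <- setdiff(taxa, colnames(m))
  if (length(missing)) {
    stop("taxa not present in table: ", paste(missing, collapse = ", "))
  }
  sub <- m[, taxa, drop = FALSE]
  zero <- rowSums(sub) <= 0
  if (any(zero)) {
    stop("sample(s) with no abundance on the selected taxa: ",
         paste(rownames(sub)[zero], collapse = ", "))
  }
  matrix_to_abundance(sub / rowSums(sub))
}
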