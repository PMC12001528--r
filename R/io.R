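#' Read a taxa abundance table
#'
#' Reads a TSV or CSV file (dialect inferred from the extension, `.csv` means
#' comma) whose first column holds sample identifiers and whose remaining
#' columns hold non-negative taxa abundances, counts or proportions, one
#' sample per row — the genus-level layout produced by exporting a
#' DADA2/QIIME2 feature table. Validates that identifiers are unique, values
#' are non-negative, and no sample has zero total.
#'
#' @param path Path to the table file (UTF-8, header required).
#' @return A tibble: `sample_id` plus one numeric column per taxon.
#' @export
read_abundance_table <- function(path) {
  tbl <- read_delim_auto(path)
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  invisible(abundance_matrix(tbl)) # validation side effect
  tbl
}

#' Write an abundance table
#'
#' Writes the wide `sample_id` + taxa layout back to TSV/CSV with numeric
#' cells at 9 significant digits, so repeated runs produce identical bytes.
#'
#' @param table Abundance table tibble.
#' @param path Output path; `.csv` writes comma-separated, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  out <- dplyr::mutate(table, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 9)))
  write_delim_auto(out, path)
}

#' Read sample metadata
#'
#' Reads per-sample study metadata with required columns `sample_id`,
#' `subject_id`, `condition`, `time_h` (hours since the perturbation started)
#' and `is_baseline` (true/false, case-insensitive). Checks that
#' `(subject_id, condition, time_h)` is unique.
#'
#' @param path Path to the metadata TSV/CSV.
#' @return A tibble with the five validated columns.
#' @export
read_sample_metadata <- function(path) {
  tbl <- read_delim_auto(path)
  validate_metadata(tbl)
}

#' @rdname read_sample_metadata
#' @param meta A data frame to validate in place of a file.
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "subject_id", "condition", "time_h", "is_baseline")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "))
  }
  meta <- tibble::as_tibble(meta)
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  meta$condition <- as.character(meta$condition)
  if (is.character(meta$is_baseline)) {
    low <- tolower(trimws(meta$is_baseline))
    if (!all(low %in% c("true", "false"))) {
      stop("is_baseline must be true/false; offending values: ",
           paste(unique(meta$is_baseline[!low %in% c("true", "false")]), collapse = ", "))
    }
    meta$is_baseline <- low == "true"
  }
  if (!is.logical(meta$is_baseline) || anyNA(meta$is_baseline)) {
    stop("is_baseline must be logical with no missing values")
  }
  meta$time_h <- suppressWarnings(as.numeric(meta$time_h))
  if (anyNA(meta$time_h) || any(meta$time_h < 0)) {
    stop("time_h must be non-negative numeric hours; offending sample(s): ",
         paste(meta$sample_id[is.na(meta$time_h) | meta$time_h < 0], collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  key <- paste(meta$subject_id, meta$condition, meta$time_h)
  if (anyDuplicated(key)) {
    stop("duplicated (subject_id, condition, time_h): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  meta[required]
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

write_delim_auto <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}
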