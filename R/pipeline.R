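#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end resilience analysis in
#' one validated object; see [run_pipeline()] for how each is used.
#'
#' @param zero_method Zero-replacement scheme, see [replace_zeros()].
#' @param delta Zero-replacement delta (`"auto"` or a positive number).
#' @param lra_threshold Cumulative variance share for taxon selection in
#'   `(0, 1]` (default 0.9).
#' @param baseline_mode,fixed_baseline,include_t0 See [build_trajectories()].
#' @param missing Missing-timepoint policy, see [complete_trajectories()].
#' @param K,fpca_weights See [fpca_fit()] (defaults 2 components, trapezoid
#'   quadrature).
#' @param bagplot_min_n Minimum number of trajectories for outlier flagging
#'   (default 10); with fewer, flags are reported as `NA`.
#' @param seed Optional integer seed recorded in the manifest (the pipeline
#'   itself is deterministic; the seed matters when the input study is
#'   generated).
#' @return A validated list of class `mbr_pipeline_config`.
#' @export
pipeline_config <- function(zero_method = "multiplicative", delta = "auto",
                            lra_threshold = 0.9,
                            baseline_mode = "per_condition",
                            fixed_baseline = NULL, include_t0 = TRUE,
                            missing = "drop",
                            K = 2, fpca_weights = "trapezoid",
                            bagplot_min_n = 10, seed = NULL) {
  cfg <- list(
    zero_method = match.arg(zero_method, c("multiplicative", "bayes_multiplicative")),
    delta = delta, lra_threshold = lra_threshold,
    baseline_mode = match.arg(baseline_mode, c("per_condition", "fixed_sample")),
    fixed_baseline = fixed_baseline, include_t0 = isTRUE(include_t0),
    missing = match.arg(missing, c("drop", "interpolate")),
    K = K, fpca_weights = match.arg(fpca_weights, c("trapezoid", "uniform")),
    bagplot_min_n = bagplot_min_n, seed = seed
  )
  if (!is.numeric(cfg$lra_threshold) || cfg$lra_threshold <= 0 || cfg$lra_threshold > 1) {
    stop("lra_threshold must be in (0, 1]")
  }
  if (!is.numeric(cfg$K) || cfg$K < 1) stop("K must be >= 1")
  structure(cfg, class = "mbr_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [pipeline_config()]; unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return An `mbr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full resilience analysis
#'
#' Executes the complete workflow on an abundance table and its metadata:
#' zero replacement, log-ratio analysis and taxon selection, restriction to
#' the selected subcomposition, Aitchison-distance trajectories from the
#' baseline, functional PCA with scores, score-distance correlations, and
#' bagplot outlier flagging, plus distance and score summaries. Any stage
#' failure is re-raised with the stage name. Given the same inputs and
#' configuration the output is identical, run to run.
#'
#' @param table Abundance table tibble, or a path readable by
#'   [read_abundance_table()].
#' @param meta Sample metadata tibble, or a path readable by
#'   [read_sample_metadata()].
#' @param config An [pipeline_config()] object.
#' @param out_dir Optional directory; when given, every artifact is written
#'   there via [write_pipeline()].
#' @return A list of class `mbr_pipeline`: `selected_taxa`, `lra`,
#'   `trajectories`, `fpca`, `scores`, `correlations`, `outlier_flags`,
#'   `group_means`, `score_summary`, `overall_distance`, `config`,
#'   `manifest`.
#' @export
run_pipeline <- function(table, meta, config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "mbr_pipeline_config")) stop("config must come from pipeline_config()")
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[mbresil] %-16s %6.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  if (is.character(table)) table <- stage("read_table", read_abundance_table(table))
  if (is.character(meta)) meta <- stage("read_metadata", read_sample_metadata(meta))
  meta <- validate_metadata(meta)

  positive <- stage("replace_zeros",
                    replace_zeros(table, method = config$zero_method, delta = config$delta))
  lra <- stage("lra_fit", lra_fit(positive))
  selected <- stage("select_taxa", select_taxa(lra, config$lra_threshold))
  reduced <- stage("subset_reclose", subset_and_reclose(positive, selected))
  traj <- stage("trajectories", {
    tr <- build_trajectories(reduced, meta,
                             baseline_mode = config$baseline_mode,
                             fixed_baseline = config$fixed_baseline,
                             include_t0 = config$include_t0)
    complete_trajectories(tr, missing = config$missing)
  })
  fpca <- stage("fpca", fpca_fit(traj, K = config$K, weights = config$fpca_weights))
  scores <- fpca$scores
  correlations <- stage("correlations", score_distance_correlation(scores, traj))
  flags <- stage("outliers", {
    if (nrow(scores) >= max(10, config$bagplot_min_n) && config$K >= 2) {
      flag_outlier_trajectories(scores)
    } else {
      dplyr::mutate(scores, depth = NA_integer_, outlier = NA)
    }
  })

  bundle <- structure(
    list(
      selected_taxa = selected, lra = lra, trajectories = traj,
      fpca = fpca, scores = scores, correlations = correlations,
      outlier_flags = flags,
      group_means = group_mean_se(traj),
      score_summary = score_group_summary(scores),
      overall_distance = overall_mean_distance(traj),
      config = config,
      manifest = list(
        package = "mbresil",
        version = as.character(utils::packageVersion("mbresil")),
        config = unclass(config),
        config_hash = rlang::hash(unclass(config)),
        seed = config$seed,
        n_samples = nrow(table), n_taxa = ncol(table) - 1,
        n_selected_taxa = nrow(selected),
        n_trajectories = nrow(scores),
        grid = fpca$grid
      )
    ),
    class = "mbr_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(bundle, out_dir)
  bundle
}

#' @export
print.mbr_pipeline <- function(x, ...) {
  cat("mbresil pipeline:", x$manifest$n_trajectories, "trajectories,",
      x$manifest$n_selected_taxa, "of", x$manifest$n_taxa, "taxa selected\n")
  cat("Explained variance:",
      paste(sprintf("FPCA%d %.1f%%", seq_len(x$fpca$K),
                    100 * x$fpca$explained_fraction), collapse = ", "), "\n")
  cat("Mean distance from baseline:",
      sprintf("%.3f +/- %.3f (n = %d)\n", x$overall_distance$mean_distance,
              x$overall_distance$se, x$overall_distance$n))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes every artifact of a pipeline run: selected taxa, long-format
#' trajectories, scores with outlier flags, score-distance correlations,
#' group mean curves, the FPCA model as JSON, a numeric summary, and a
#' manifest (package version, configuration and its hash, seed, record
#' counts). Numeric CSV cells are written at 9 significant digits so that
#' reruns with identical inputs produce byte-identical files.
#'
#' @param bundle An `mbr_pipeline` result.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 9)))
    readr::write_csv(df, file.path(out_dir, file), progress = FALSE)
  }
  w(bundle$selected_taxa, "selected_taxa.csv")
  w(bundle$trajectories, "trajectories.csv")
  w(bundle$outlier_flags, "scores.csv")
  w(bundle$correlations, "correlations.csv")
  w(bundle$group_means, "group_means.csv")
  w(bundle$score_summary, "score_summary.csv")
  write_fpca_model(bundle$fpca, file.path(out_dir, "fpca_model.json"))
  jsonlite::write_json(
    list(
      overall_mean_distance = signif(bundle$overall_distance$mean_distance, 9),
      overall_distance_se = signif(bundle$overall_distance$se, 9),
      explained_fraction = signif(bundle$fpca$explained_fraction, 9),
      n_selected_taxa = nrow(bundle$selected_taxa),
      n_outliers = sum(bundle$outlier_flags$outlier, na.rm = TRUE)
    ),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Serialize / read an FPCA model as JSON
#'
#' @param model An `mbr_fpca` fit.
#' @param path JSON file path.
#' @return `write_fpca_model()` returns `path` invisibly;
#'   `read_fpca_model()` returns the reconstructed `mbr_fpca` object
#'   (without fitting-set scores).
#' @export
write_fpca_model <- function(model, path) {
  stopifnot(inherits(model, "mbr_fpca"))
  jsonlite::write_json(
    list(
      grid = model$grid, mean_curve = model$mean_curve,
      phi = model$phi,
      lambda = model$lambda, lambda_total = model$lambda_total,
      explained_fraction = model$explained_fraction,
      weights = model$weights, weight_scheme = model$weight_scheme,
      K = model$K, n = model$n
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_fpca_model
#' @export
read_fpca_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      grid = as.numeric(x$grid), mean_curve = as.numeric(x$mean_curve),
      phi = matrix(as.numeric(if (is.list(x$phi)) unlist(x$phi) else x$phi),
                   ncol = x$K),
      lambda = as.numeric(x$lambda), lambda_total = x$lambda_total,
      explained_fraction = as.numeric(x$explained_fraction),
      weights = as.numeric(x$weights), weight_scheme = x$weight_scheme,
      K = as.integer(x$K), n = as.integer(x$n)
    ),
    class = "mbr_fpca"
  )
}
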