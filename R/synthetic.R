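#' Configuration for a synthetic perturbation-recovery study
#'
#' Describes a longitudinal compositional study with known ground truth,
#' emulating a typical exercise-challenge design: every subject undergoes
#' each condition, sampled at a pre-perturbation baseline and a handful of
#' post-perturbation timepoints. Each subject starts from a CLR-space
#' Gaussian baseline with heavy-tailed taxon loadings (a few dominant taxa,
#' many rare ones); each `(subject, condition)` trajectory receives a
#' CLR-space shock along a sparse taxon direction, rising linearly from zero
#' to its subject-specific magnitude at `peak_time_h` and decaying
#' exponentially with a subject-specific halflife. The shock direction is
#' centred and scaled to unit CLR norm, so a trajectory's true magnitude
#' equals its peak Aitchison distance from baseline. Optional multinomial
#' resampling emulates finite sequencing depth, and optional zeroing of
#' low-abundance cells emulates the heavy sparsity of real genus tables.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param conditions Character vector of condition labels (default three
#'   exercise bouts: `"wheel"`, `"atv"`, `"sled"`).
#' @param n_taxa Number of taxa (default 100).
#' @param times_h Sampling times in hours, must include 0 (the baseline;
#'   default `c(0, 0.5, 3, 6, 24, 48)`).
#' @param magnitude_mean,magnitude_sd Mean and sd of the per-trajectory
#'   shock magnitude, in CLR (Aitchison-distance) units (defaults 8 and 4;
#'   draws are folded to be non-negative).
#' @param recovery_halflife_mean,recovery_halflife_sd Mean and sd in hours
#'   of the exponential-recovery halflife (defaults 12 and 3; draws are
#'   truncated below at 0.5 h).
#' @param shock_direction_dim Number of taxa carrying the shock (default 10).
#' @param peak_time_h Time of maximal displacement (default 4.5 h, the
#'   centre of a 3-6 h peak window).
#' @param sequencing_depth Reads per sample for multinomial resampling, or
#'   `NULL` (default) for noise-free proportions.
#' @param sparsity_zeros_frac Target fraction of zero cells in `[0, 1)`
#'   (default 0.6); low-abundance cells are zeroed to reach it, never a
#'   row's largest cell.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A validated list of class `mbr_synth_config`.
#' @export
synth_config <- function(n_subjects = 15,
                         conditions = c("wheel", "atv", "sled"),
                         n_taxa = 100,
                         times_h = c(0, 0.5, 3, 6, 24, 48),
                         magnitude_mean = 8, magnitude_sd = 4,
                         recovery_halflife_mean = 12, recovery_halflife_sd = 3,
                         shock_direction_dim = 10,
                         peak_time_h = 4.5,
                         sequencing_depth = NULL,
                         sparsity_zeros_frac = 0.6,
                         seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, conditions = as.character(conditions),
    n_taxa = n_taxa, times_h = sort(unique(as.numeric(times_h))),
    magnitude_mean = magnitude_mean, magnitude_sd = magnitude_sd,
    recovery_halflife_mean = recovery_halflife_mean,
    recovery_halflife_sd = recovery_halflife_sd,
    shock_direction_dim = shock_direction_dim, peak_time_h = peak_time_h,
    sequencing_depth = sequencing_depth,
    sparsity_zeros_frac = sparsity_zeros_frac, seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1 || cfg$n_taxa < 3) stop("need n_subjects >= 1 and n_taxa >= 3")
  if (!length(cfg$conditions)) stop("at least one condition is required")
  if (!0 %in% cfg$times_h) stop("times_h must include the baseline time 0")
  if (length(cfg$times_h) < 2) stop("need at least one post-baseline timepoint")
  if (cfg$magnitude_sd < 0 || cfg$magnitude_mean < 0) stop("magnitude mean/sd must be non-negative")
  if (cfg$recovery_halflife_mean <= 0 || cfg$recovery_halflife_sd < 0) {
    stop("recovery halflife mean must be positive and sd non-negative")
  }
  if (cfg$shock_direction_dim < 1 || cfg$shock_direction_dim > cfg$n_taxa) {
    stop("shock_direction_dim must be in [1, n_taxa]")
  }
  if (cfg$peak_time_h <= 0) stop("peak_time_h must be positive")
  if (!is.null(cfg$sequencing_depth) &&
      (!is.numeric(cfg$sequencing_depth) || cfg$sequencing_depth < 1)) {
    stop("sequencing_depth must be NULL or a positive count")
  }
  if (cfg$sparsity_zeros_frac < 0 || cfg$sparsity_zeros_frac >= 1) {
    stop("sparsity_zeros_frac must be in [0, 1)")
  }
  structure(cfg, class = "mbr_synth_config")
}

# shock profile: 0 at t=0, 1 at the peak, exponential decay afterwards
shock_profile <- function(t, peak, halflife) {
  ifelse(t <= peak, t / peak, 2^(-(t - peak) / halflife))
}

#' Generate a synthetic longitudinal study
#'
#' Draws a complete study from a [synth_config()]: an abundance table, its
#' sample metadata (baseline flagged at time 0 per subject and condition),
#' and the ground-truth per-trajectory shock magnitudes and recovery
#' halflives that downstream score estimates can be validated against.
#' Identical configurations (including the seed) produce identical output.
#'
#' @param config An `mbr_synth_config`.
#' @return A list with elements `table` (abundance tibble; proportions, or
#'   counts when `sequencing_depth` is set), `metadata` (sample metadata
#'   tibble), and `truth` (tibble `subject_id`, `condition`, `magnitude`,
#'   `halflife`).
#' @examples
#' study <- generate_study(synth_config(n_subjects = 3, conditions = "run",
#'                                      n_taxa = 20, sparsity_zeros_frac = 0))
#' head(study$truth)
#' @export
generate_study <- function(config) {
  if (!inherits(config, "mbr_synth_config")) stop("config must come from synth_config()")
  withr::with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  subjects <- sprintf("subj_%02d", seq_len(cfg$n_subjects))
  # heavy-tailed community profile shared across subjects, plus subject offsets
  tau <- stats::rnorm(cfg$n_taxa, 0, 2)
  base_clr <- t(vapply(subjects, function(s) tau + stats::rnorm(cfg$n_taxa, 0, 0.5),
                       numeric(cfg$n_taxa)))

  # one sparse unit-CLR-norm shock direction per condition
  directions <- lapply(cfg$conditions, function(cond) {
    idx <- sample.int(cfg$n_taxa, cfg$shock_direction_dim)
    d <- numeric(cfg$n_taxa)
    d[idx] <- stats::rnorm(cfg$shock_direction_dim)
    d <- d - mean(d)
    d / sqrt(sum(d^2))
  })
  names(directions) <- cfg$conditions

  design <- expand.grid(condition = cfg$conditions, subject_id = subjects,
                        stringsAsFactors = FALSE)[, c("subject_id", "condition")]
  truth <- tibble::tibble(
    subject_id = design$subject_id,
    condition = design$condition,
    magnitude = abs(stats::rnorm(nrow(design), cfg$magnitude_mean, cfg$magnitude_sd)),
    halflife = pmax(0.5, stats::rnorm(nrow(design), cfg$recovery_halflife_mean,
                                      cfg$recovery_halflife_sd))
  )

  rows <- vector("list", nrow(truth) * length(cfg$times_h))
  meta <- vector("list", length(rows))
  r <- 0
  for (i in seq_len(nrow(truth))) {
    subj <- truth$subject_id[i]
    cond <- truth$condition[i]
    b <- base_clr[match(subj, subjects), ]
    d <- directions[[cond]]
    for (t in cfg$times_h) {
      s <- shock_profile(t, cfg$peak_time_h, truth$halflife[i])
      comp <- exp(b + truth$magnitude[i] * s * d)
      comp <- comp / sum(comp)
      r <- r + 1
      rows[[r]] <- comp
      meta[[r]] <- tibble::tibble(
        sample_id = sprintf("%s_%s_t%g", subj, cond, t),
        subject_id = subj, condition = cond, time_h = t, is_baseline = t == 0
      )
    }
  }
  m <- do.call(rbind, rows)
  metadata <- dplyr::bind_rows(meta)
  rownames(m) <- metadata$sample_id
  colnames(m) <- taxa

  if (!is.null(cfg$sequencing_depth)) {
    m <- t(apply(m, 1, function(p) {
      stats::rmultinom(1, size = cfg$sequencing_depth, prob = p)[, 1]
    }))
    colnames(m) <- taxa
  }
  if (cfg$sparsity_zeros_frac > 0) {
    m <- impose_sparsity(m, cfg$sparsity_zeros_frac)
  }
  list(table = matrix_to_abundance(m), metadata = metadata, truth = truth)
}

# zero the smallest cells (never a row maximum) until the target fraction of
# zero cells is reached
impose_sparsity <- function(m, frac) {
  target <- round(frac * length(m))
  zeros <- sum(m == 0)
  if (zeros >= target) return(m)
  row_max <- apply(m, 1, max)
  protect <- m == row_max[row(m)]
  candidates <- which(m > 0 & !protect)
  candidates <- candidates[order(m[candidates])]
  kill <- utils::head(candidates, target - zeros)
  m[kill] <- 0
  m
}

#' Rank agreement between ground truth and estimated scores
#'
#' Spearman rank correlations between the generator's true per-trajectory
#' parameters and the fitted scores: shock magnitude against the first
#' score and recovery halflife against the second. Signs are reported as-is;
#' a strong first correlation supports reading the first score as
#' perturbation impact.
#'
#' @param truth Truth tibble from [generate_study()].
#' @param scores Score tibble from [fpca_scores()], covering the same
#'   `(subject_id, condition)` pairs.
#' @return A tibble `parameter`, `score`, `spearman_rho`, `n`; `rho` is `NA`
#'   when either variable is constant.
#' @export
truth_recovery_report <- function(truth, scores) {
  key_t <- paste(truth$subject_id, truth$condition, sep = "\r")
  key_s <- paste(scores$subject_id, scores$condition, sep = "\r")
  if (!setequal(key_t, key_s) || nrow(truth) != nrow(scores)) {
    stop("truth and scores cover different (subject_id, condition) sets")
  }
  if (!"FPCA1" %in% names(scores)) stop("scores must have an FPCA1 column")
  joined <- dplyr::inner_join(truth, scores, by = c("subject_id", "condition"))
  spearman <- function(a, b) {
    if (is.null(b) || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }
  tibble::tibble(
    parameter = c("magnitude", "halflife"),
    score = c("FPCA1", "FPCA2"),
    spearman_rho = c(spearman(joined$magnitude, joined$FPCA1),
                     spearman(joined$halflife, joined$FPCA2)),
    n = nrow(joined)
  )
}
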