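#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults reproduce the
#' study conditions: genes are called differential when the log2 expression
#' ratio exceeds 0.8 (1.75-fold) at p < 0.05; fish are immature below
#' GSI 0.08% and pubertal at or above GSI 0.23%; a gene is gonad-specific when
#' its gonad expression is at least 8-fold the all-tissue average and it is
#' not expressed elsewhere.
#'
#' @param log2er_cutoff Log2 expression-ratio cutoff for HSA/LSA calls
#'   (strict inequality). Default 0.8.
#' @param alpha Significance level for all tests (strict inequality for
#'   classification). Must lie strictly between 0 and 1. Default 0.05.
#' @param gsi_immature_max GSI (percent) below which a fish is immature
#'   (strict). Default 0.08.
#' @param gsi_pubertal_min GSI (percent) at or above which a fish is pubertal
#'   (inclusive). Default 0.23. Must exceed `gsi_immature_max`.
#' @param gsg_fold_threshold Gonad-over-average fold at or above which a gene
#'   can be gonad-specific (inclusive). Default 8.
#' @param intensity_floor Linear-scale floor applied to non-positive or
#'   missing intensities before any log. Default 1.
#' @param absence_floor Absolute linear intensity below which a tissue is
#'   always considered unexpressed. Default 10.
#' @param absence_ratio A non-target tissue counts as expressed when its value
#'   reaches `max(absence_floor, absence_ratio * median(compendium))`.
#'   Default 2.
#' @param include_targets_in_average Whether the gonads themselves enter the
#'   all-tissue average of the specificity score. Default `TRUE`.
#' @param min_set_size Minimum number of scored genes for a functional group
#'   to be tested. Default 10.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#'   Default `FALSE` (Welch), appropriate for the unbalanced 14 vs 6 design.
#' @param p_adjust Multiple-testing adjustment method for per-gene and
#'   per-set p-values; `"none"` mirrors the raw criteria, `"BH"` applies
#'   Benjamini-Hochberg. Default `"none"`.
#' @param rng_seed Optional integer seed recorded alongside results.
#'
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(alpha = 0.01)
#' cfg$log2er_cutoff
#' @export
run_config <- function(log2er_cutoff = 0.8,
                       alpha = 0.05,
                       gsi_immature_max = 0.08,
                       gsi_pubertal_min = 0.23,
                       gsg_fold_threshold = 8,
                       intensity_floor = 1,
                       absence_floor = 10,
                       absence_ratio = 2,
                       include_targets_in_average = TRUE,
                       min_set_size = 10,
                       var_equal = FALSE,
                       p_adjust = c("none", "BH"),
                       rng_seed = NULL) {
  cfg <- list(
    log2er_cutoff = log2er_cutoff,
    alpha = alpha,
    gsi_immature_max = gsi_immature_max,
    gsi_pubertal_min = gsi_pubertal_min,
    gsg_fold_threshold = gsg_fold_threshold,
    intensity_floor = intensity_floor,
    absence_floor = absence_floor,
    absence_ratio = absence_ratio,
    include_targets_in_average = include_targets_in_average,
    min_set_size = min_set_size,
    var_equal = var_equal,
    p_adjust = match.arg(p_adjust),
    rng_seed = rng_seed
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  check_pos <- function(key) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 ||
        !is.finite(cfg[[key]]) || cfg[[key]] <= 0) {
      abort(sprintf("config key '%s' must be a single positive number", key))
    }
  }
  for (key in c("log2er_cutoff", "gsi_immature_max", "gsi_pubertal_min",
                "gsg_fold_threshold", "intensity_floor", "absence_floor",
                "absence_ratio", "min_set_size")) {
    check_pos(key)
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("config key 'alpha' must lie strictly between 0 and 1")
  }
  if (cfg$gsi_immature_max >= cfg$gsi_pubertal_min) {
    abort(paste0(
      "config key 'gsi_immature_max' (", cfg$gsi_immature_max,
      ") must be smaller than 'gsi_pubertal_min' (", cfg$gsi_pubertal_min, ")"
    ))
  }
  invisible(cfg)
}

#' Load an analysis configuration from a YAML or JSON file
#'
#' Keys absent from the file keep their [run_config()] defaults; unknown keys
#' raise an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) key-value file.
#' @return A `run_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) abort("config file must contain a key-value mapping")
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (key in setdiff(names(x), "rng_seed")) {
    cat(sprintf("  %-27s %s\n", key, format(x[[key]])))
  }
  if (!is.null(x$rng_seed)) cat(sprintf("  %-27s %s\n", "rng_seed", x$rng_seed))
  invisible(x)
}
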