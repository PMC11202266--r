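validate_compendium <- function(compendium) {
  if (!is.data.frame(compendium) || names(compendium)[1] != "gene_id") {
    abort("compendium must be a data frame with a leading 'gene_id' column")
  }
  tissues <- names(compendium)[-1]
  if (length(tissues) < 2) abort("compendium needs at least 2 tissues")
  if (anyDuplicated(tissues)) abort("tissue labels must be unique")
  if (anyDuplicated(compendium$gene_id)) abort("gene identifiers must be unique")
  vals <- as.matrix(compendium[, -1, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("compendium values must be finite and strictly positive; apply a floor first")
  }
  invisible(compendium)
}

#' Gonad-over-average specificity score
#'
#' Per gene, the maximum mean expression over the target (gonad) tissues
#' divided by the arithmetic mean over all tissues. By default the targets are
#' included in the average (configurable via
#' `include_targets`); with a single elevated tissue the score is therefore
#' bounded above by the number of tissues. The score is invariant to a global
#' rescaling of the compendium.
#'
#' @param compendium Tibble of per-tissue mean expression: `gene_id` plus one
#'   linear-scale column per tissue.
#' @param target_tissues Gonad tissue labels; those present in the compendium
#'   are used ("testes and/or ovaries" means the max over the pair). Default
#'   `c("testis", "ovary")`.
#' @param include_targets Whether target tissues enter the all-tissue average.
#'   Default `TRUE`.
#' @return Tibble with `gene_id` and `gonad_over_average_fold`.
#' @export
specificity_score <- function(compendium, target_tissues = c("testis", "ovary"),
                              include_targets = TRUE) {
  validate_compendium(compendium)
  tissues <- names(compendium)[-1]
  targets <- intersect(target_tissues, tissues)
  if (length(target_tissues) == 0 || length(targets) == 0) {
    abort("no target tissue present in the compendium")
  }
  mat <- as.matrix(compendium[, -1, drop = FALSE])
  target_max <- apply(mat[, targets, drop = FALSE], 1, max)
  denom_cols <- if (include_targets) tissues else setdiff(tissues, targets)
  if (length(denom_cols) == 0) abort("no tissues left to average over")
  tibble(
    gene_id = compendium$gene_id,
    gonad_over_average_fold = target_max /
      rowMeans(mat[, denom_cols, drop = FALSE])
  )
}

#' Call gonad-specific genes (GSG)
#'
#' A gene is gonad-specific when (a) its expression in testis and/or ovary is
#' at least `config$gsg_fold_threshold`-fold (inclusive) the average over all
#' tissues, and (b) it is not expressed in any other tissue. "Not expressed"
#' is operationalized with a single absence threshold per compendium:
#' `max(config$absence_floor, config$absence_ratio * median(compendium))`,
#' a robust background level; a non-target tissue at or above it counts as
#' expressed. Both constants are configurable.
#'
#' @inheritParams specificity_score
#' @param config A [run_config()]; uses `gsg_fold_threshold`, `absence_floor`,
#'   `absence_ratio`, and `include_targets_in_average`.
#' @param absence_threshold Optional explicit linear-scale threshold
#'   overriding the data-driven rule.
#' @return Tibble with `gene_id`, `gonad_over_average_fold`,
#'   `expressed_elsewhere`, `gonad_specific`.
#' @export
call_gonad_specific <- function(compendium, config = run_config(),
                                target_tissues = c("testis", "ovary"),
                                absence_threshold = NULL) {
  validate_compendium(compendium)
  score <- specificity_score(compendium, target_tissues,
                             include_targets = config$include_targets_in_average)
  tissues <- names(compendium)[-1]
  targets <- intersect(target_tissues, tissues)
  others <- setdiff(tissues, targets)
  mat <- as.matrix(compendium[, -1, drop = FALSE])
  thr <- absence_threshold %||%
    max(config$absence_floor, config$absence_ratio * median(mat))
  expressed_elsewhere <- if (length(others) > 0) {
    apply(mat[, others, drop = FALSE] >= thr, 1, any)
  } else {
    rep(FALSE, nrow(mat))
  }
  score |>
    mutate(
      expressed_elsewhere = expressed_elsewhere,
      gonad_specific = .data$gonad_over_average_fold >=
        config$gsg_fold_threshold & !expressed_elsewhere
    )
}

#' Average a replicate-level compendium to tissue means
#'
#' Collapses multiple columns per tissue to linear-scale tissue means, the
#' form consumed by [specificity_score()] and [call_gonad_specific()].
#'
#' @param expr Expression tibble whose columns are replicates.
#' @param tissue_of Named character vector mapping each replicate column to a
#'   tissue label, or a data frame with `sample_id` and `tissue` columns.
#' @return A compendium tibble (`gene_id` plus one column per tissue).
#' @export
compendium_from_replicates <- function(expr, tissue_of) {
  validate_expr(expr, require_positive = TRUE)
  if (is.data.frame(tissue_of)) {
    tissue_of <- setNames(as.character(tissue_of$tissue),
                          as.character(tissue_of$sample_id))
  }
  samples <- names(expr)[-1]
  if (!all(samples %in% names(tissue_of))) {
    abort("every replicate column needs a tissue label")
  }
  mat <- as_expr_matrix(expr)
  tissues <- unique(unname(tissue_of[samples]))
  means <- vapply(tissues, function(tt) {
    rowMeans(mat[, samples[tissue_of[samples] == tt], drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1) means <- matrix(means, nrow = 1, dimnames = list(NULL, tissues))
  bind_cols(tibble(gene_id = expr$gene_id),
            as_tibble(means, .name_repair = "minimal"))
}
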