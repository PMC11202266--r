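#' Spermatogenesis stage labels
#'
#' Ordered germ-cell stages used for histological staging of the testis:
#' spermatogonia A, spermatogonia B, spermatocytes, spermatids, spermatozoa.
#'
#' @return Character vector of stage labels, least to most advanced.
#' @export
stage_levels <- function() c("SPA", "SPB", "SPC", "SPT", "SZ")

stage_rank <- function(x) {
  r <- match(x, stage_levels())
  if (anyNA(r)) {
    abort(paste0("unknown stage label(s): ",
                 paste(unique(x[is.na(r)]), collapse = ", ")))
  }
  r
}

#' Gonadosomatic index (GSI)
#'
#' GSI (%) = gonad weight / body weight x 100. Both weights in grams.
#'
#' @param gonad_weight Gonad weight (g), non-negative.
#' @param body_weight Body weight (g), strictly positive.
#' @return GSI in percent; vectorized.
#' @examples
#' compute_gsi(0.5, 1000) # 0.05
#' @export
compute_gsi <- function(gonad_weight, body_weight) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0)) {
    abort("body_weight must be strictly positive")
  }
  if (any(!is.finite(gonad_weight)) || any(gonad_weight < 0)) {
    abort("gonad_weight must be non-negative")
  }
  gonad_weight / body_weight * 100
}

#' Fulton's condition factor (CF)
#'
#' CF = W / L^3 x 100 with W the body weight in grams and L the fork length
#' in centimetres.
#'
#' @param body_weight Body weight (g), strictly positive.
#' @param fork_length Fork length (cm), strictly positive.
#' @return Condition factor; vectorized.
#' @examples
#' compute_cf(1017, 41.3) # ~1.44
#' @export
compute_cf <- function(body_weight, fork_length) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0)) {
    abort("body_weight must be strictly positive")
  }
  if (any(!is.finite(fork_length)) || any(fork_length <= 0)) {
    abort("fork_length must be strictly positive")
  }
  body_weight / fork_length^3 * 100
}

#' Assign GSI-based maturity groups
#'
#' Fish with GSI strictly below `gsi_immature_max` are immature; fish with GSI
#' at or above `gsi_pubertal_min` are pubertal; the gap between the thresholds
#' is indeterminate. The three intervals partition `[0, Inf)` exactly.
#'
#' @param gsi GSI in percent (non-negative); vectorized.
#' @param config A [run_config()] supplying the two thresholds.
#' @return Character vector in `{"immature", "indeterminate", "pubertal"}`.
#' @examples
#' assign_maturity_group(c(0.05, 0.15, 0.23))
#' @export
assign_maturity_group <- function(gsi, config = run_config()) {
  if (any(!is.finite(gsi)) || any(gsi < 0)) abort("gsi must be non-negative")
  dplyr::case_when(
    gsi < config$gsi_immature_max ~ "immature",
    gsi >= config$gsi_pubertal_min ~ "pubertal",
    TRUE ~ "indeterminate"
  )
}

#' Add biometric indices and maturity group to a cohort table
#'
#' Computes `gsi` (if absent and weights are present), `cf` (if weights and
#' lengths are present), and `maturity_group`.
#'
#' @param cohort Data frame with per-fish `body_weight`, `fork_length`, and
#'   `gonad_weight` and/or `gsi` columns.
#' @param config A [run_config()].
#' @return The cohort as a tibble with `gsi`, `cf`, and `maturity_group`
#'   columns added where computable.
#' @export
add_biometrics <- function(cohort, config = run_config()) {
  out <- as_tibble(cohort)
  if (!"gsi" %in% names(out)) {
    if (!all(c("gonad_weight", "body_weight") %in% names(out))) {
      abort("cohort needs either a 'gsi' column or 'gonad_weight' and 'body_weight'")
    }
    out <- mutate(out, gsi = compute_gsi(.data$gonad_weight, .data$body_weight))
  }
  if (all(c("body_weight", "fork_length") %in% names(out))) {
    out <- mutate(out, cf = compute_cf(.data$body_weight, .data$fork_length))
  }
  mutate(out, maturity_group = assign_maturity_group(.data$gsi, config))
}

#' Filter a cohort by histology criteria
#'
#' Predicates mirror the questions asked of the histology table: fish whose
#' most advanced germ-cell type exceeds a stage, fish with a free-text
#' observation flag, and fish with a given dominating germ-cell type. Supplied
#' conditions are combined with AND; row order is preserved.
#'
#' @param records Cohort tibble with `most_advanced_stage`, `dominant_stage`,
#'   and `observations` columns as needed.
#' @param stage_above Keep fish with `most_advanced_stage` strictly more
#'   advanced than this stage label.
#' @param observation Keep fish whose `observations` text contains this flag
#'   (fixed substring match, e.g. `"oocytes"`).
#' @param dominant_stage Keep fish whose `dominant_stage` equals this label.
#' @return The matching subset (tibble); the count is `nrow()` of the result.
#' @examples
#' tbl <- tibble::tibble(
#'   fish_id = c("a", "b"),
#'   most_advanced_stage = c("SPA", "SPT"),
#'   dominant_stage = c("SPA", "SPC"),
#'   observations = c("oocytes", "")
#' )
#' filter_cohort(tbl, stage_above = "SPA")
#' @export
filter_cohort <- function(records, stage_above = NULL, observation = NULL,
                          dominant_stage = NULL) {
  out <- as_tibble(records)
  if (!is.null(stage_above)) {
    keep <- stage_rank(out$most_advanced_stage) > stage_rank(stage_above)
    out <- out[keep, , drop = FALSE]
  }
  if (!is.null(observation)) {
    obs <- out$observations
    obs[is.na(obs)] <- ""
    out <- out[grepl(observation, obs, fixed = TRUE), , drop = FALSE]
  }
  if (!is.null(dominant_stage)) {
    stage_rank(dominant_stage) # validate the label
    out <- out[stage_rank(out$dominant_stage) == stage_rank(dominant_stage), ,
               drop = FALSE]
  }
  out
}

normalize_index <- function(index, id_col = "fish_id") {
  if (is.data.frame(index)) {
    value_col <- setdiff(names(index), id_col)
    if (!id_col %in% names(index) || length(value_col) != 1) {
      abort(sprintf("index data frame must have columns '%s' and one value column", id_col))
    }
    setNames(index[[value_col]], index[[id_col]])
  } else if (is.numeric(index) && !is.null(names(index))) {
    index
  } else {
    abort("index must be a named numeric vector or a two-column data frame")
  }
}

#' Correlate serum analytes with a per-fish index
#'
#' Pearson product-moment correlation of each analyte's concentration with a
#' per-fish index (typically GSI). Analytes with fewer than 3 paired
#' observations or zero variance (in either variable) are reported with
#' `r = NA` and `undefined = TRUE` rather than raising an error.
#'
#' @param panel Long hormone tibble with columns `fish_id`, `analyte`,
#'   `concentration` (nmol/L).
#' @param index Per-fish index: a named numeric vector (names = fish ids) or a
#'   data frame with `fish_id` and one value column.
#' @param summary_analytes Optional character vector of analyte names; if
#'   given, the mean and SD of `r` across that subset are attached as the
#'   `"summary"` attribute (a one-row tibble) and returned by
#'   [summarize_correlations()].
#' @return Tibble with columns `analyte`, `n`, `r`, `undefined`.
#' @export
correlate_with_index <- function(panel, index, summary_analytes = NULL) {
  idx <- normalize_index(index)
  dat <- panel |>
    mutate(index_value = unname(idx[as.character(.data$fish_id)])) |>
    filter(!is.na(.data$index_value) & !is.na(.data$concentration))
  out <- dat |>
    group_by(.data$analyte) |>
    summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 3 && sd(.data$concentration) > 0 &&
              sd(.data$index_value) > 0) {
        cor(.data$concentration, .data$index_value)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(undefined = is.na(.data$r))
  if (!is.null(summary_analytes)) {
    attr(out, "summary") <- summarize_correlations(out, summary_analytes)
  }
  out
}

#' Mean and SD of correlation over an analyte subset
#'
#' @param correlations Output of [correlate_with_index()].
#' @param analytes Analyte names to aggregate over.
#' @return One-row tibble with `n_analytes`, `mean_r`, `sd_r`.
#' @export
summarize_correlations <- function(correlations, analytes) {
  sub <- filter(correlations, .data$analyte %in% analytes, !.data$undefined)
  tibble(n_analytes = nrow(sub), mean_r = mean(sub$r), sd_r = sd(sub$r))
}

normalize_groups <- function(groups, id_col = "fish_id") {
  if (is.data.frame(groups)) {
    if (!all(c(id_col, "group") %in% names(groups))) {
      abort(sprintf("groups data frame must have columns '%s' and 'group'", id_col))
    }
    g <- setNames(as.character(groups$group), as.character(groups[[id_col]]))
  } else if (is.character(groups) && !is.null(names(groups))) {
    g <- groups
  } else {
    abort("groups must be a named character vector or a data frame with id and 'group'")
  }
  list(
    immature = names(g)[g == "immature"],
    pubertal = names(g)[g == "pubertal"]
  )
}

#' Pubertal-over-immature fold change of serum analytes
#'
#' Ratio of the pubertal group mean to the immature group mean per analyte.
#' Indeterminate fish (those in neither group) are excluded. Means are taken
#' on the linear concentration scale by default, matching plain "x-fold"
#' reporting; geometric means are available for sensitivity analysis.
#'
#' @param panel Long hormone tibble (`fish_id`, `analyte`, `concentration`).
#' @param groups Per-fish maturity groups: data frame with `fish_id` and
#'   `group`, or a named character vector.
#' @param method `"arithmetic"` (default) or `"geometric"` group means.
#' @return Tibble with `analyte`, `mean_immature`, `mean_pubertal`, `fold`
#'   (`NA` when the immature mean is zero, or zero-valued observations make a
#'   geometric mean undefined).
#' @export
group_fold <- function(panel, groups, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  grp <- normalize_groups(groups)
  if (length(grp$immature) == 0 || length(grp$pubertal) == 0) {
    abort("both an immature and a pubertal group are required")
  }
  gmean <- function(x) {
    if (method == "arithmetic") return(mean(x))
    if (any(x <= 0)) return(NA_real_)
    2^mean(log2(x))
  }
  panel |>
    mutate(group = dplyr::case_when(
      as.character(.data$fish_id) %in% grp$immature ~ "immature",
      as.character(.data$fish_id) %in% grp$pubertal ~ "pubertal",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$group)) |>
    group_by(.data$analyte) |>
    summarise(
      mean_immature = gmean(.data$concentration[.data$group == "immature"]),
      mean_pubertal = gmean(.data$concentration[.data$group == "pubertal"]),
      .groups = "drop"
    ) |>
    mutate(fold = ifelse(
      !is.na(.data$mean_immature) & .data$mean_immature > 0,
      .data$mean_pubertal / .data$mean_immature, NA_real_
    ))
}

#' Two-sample test of analyte differences between maturity groups
#'
#' Per analyte, a two-sample t-test of concentrations between pubertal and
#' immature fish (Welch by default; pooled variance when
#' `config$var_equal = TRUE`). Analytes with fewer than 2 fish in either
#' group are reported as `NA`. When both groups are constant, p is 1 if the
#' group means are equal and 0 otherwise, so degenerate data never produce
#' NaN or spurious significance.
#'
#' @inheritParams group_fold
#' @param config A [run_config()]; `var_equal` selects the t-test variant.
#' @return Tibble with `analyte`, `n_immature`, `n_pubertal`, `p_value`.
#' @export
group_difference_test <- function(panel, groups, config = run_config()) {
  grp <- normalize_groups(groups)
  safe_t <- function(x, y) {
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (sd(x) == 0 && sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
    t.test(x, y, var.equal = config$var_equal)$p.value
  }
  panel |>
    group_by(.data$analyte) |>
    summarise(
      n_immature = sum(as.character(.data$fish_id) %in% grp$immature),
      n_pubertal = sum(as.character(.data$fish_id) %in% grp$pubertal),
      p_value = safe_t(
        .data$concentration[as.character(.data$fish_id) %in% grp$pubertal],
        .data$concentration[as.character(.data$fish_id) %in% grp$immature]
      ),
      .groups = "drop"
    )
}
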