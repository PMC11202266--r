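#' Run the full analysis pipeline
#'
#' Orchestrates the stages over one set of inputs: biometrics and maturity
#' grouping, per-gene HSA/LSA classification, gonad-specific gene calls,
#' the class-by-specificity summary, functional-group shift tests, and the
#' hormone statistics (per-analyte correlation with GSI, group folds, group
#' t-tests). Inputs may come from [simulate_study()] or be supplied as the
#' corresponding tibbles. The pipeline is a pure function of
#' `(inputs, config, seed)`; rerunning with the same arguments reproduces
#' every table.
#'
#' @param inputs A list with elements `cohort`, `metadata`, `expression`, and
#'   optionally `compendium`, `panel`, `annotation` (the shape returned by
#'   [simulate_study()]). When `NULL`, a synthetic study is generated from
#'   `sim_cfg` and `seed`.
#' @param config A [run_config()].
#' @param seed Integer seed used when `inputs` is `NULL` and recorded in the
#'   manifest.
#' @param sim_cfg A [sim_config()] used when `inputs` is `NULL`.
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV together with a JSON manifest (config, seed, package version, file
#'   list).
#' @return A `report_bundle` list with elements `cohort` (biometrics +
#'   maturity group), `specific_activity` (per-gene `sa_result`),
#'   `gsg_calls`, `specificity_summary`, `gene_sets`, `hormones` (list:
#'   `correlations`, `folds`, `tests`), and `manifest`.
#' @export
run_pipeline <- function(inputs = NULL, config = run_config(), seed = 1,
                         sim_cfg = sim_config(), out_dir = NULL) {
  if (is.null(inputs)) inputs <- simulate_study(sim_cfg, seed)
  for (needed in c("cohort", "metadata", "expression")) {
    if (is.null(inputs[[needed]])) {
      abort(paste0("missing pipeline input: ", needed))
    }
  }

  cohort <- add_biometrics(inputs$cohort, config)
  sample_groups <- inputs$metadata |>
    mutate(group = assign_maturity_group(.data$gsi, config)) |>
    select("sample_id", "group")
  fish_groups <- cohort |>
    transmute(fish_id = .data$fish_id, group = .data$maturity_group)

  expr <- apply_intensity_floor(inputs$expression, config$intensity_floor)
  sa <- diff_specific_activity(expr, sample_groups, config)

  gsg_calls <- NULL
  summary_tbl <- NULL
  if (!is.null(inputs$compendium)) {
    gsg_calls <- call_gonad_specific(inputs$compendium, config)
    shared <- intersect(sa$gene_id, gsg_calls$gene_id)
    if (length(shared) > 0) {
      summary_tbl <- summarize_by_specificity(
        filter(sa, .data$gene_id %in% shared),
        gsg_calls
      )
    }
  }

  gene_sets <- NULL
  if (!is.null(inputs$annotation)) {
    res_for_sets <- tidy(sa)
    if (!is.null(gsg_calls)) {
      res_for_sets <- left_join(res_for_sets,
                                select(gsg_calls, "gene_id", "gonad_specific"),
                                by = "gene_id") |>
        mutate(gonad_specific = !is.na(.data$gonad_specific) & .data$gonad_specific)
    }
    gene_sets <- set_shift_test(res_for_sets, inputs$annotation, config)
  }

  hormones <- NULL
  if (!is.null(inputs$panel)) {
    idx <- setNames(cohort$gsi, cohort$fish_id)
    hormones <- list(
      correlations = correlate_with_index(inputs$panel, idx),
      folds = group_fold(inputs$panel, fish_groups),
      tests = group_difference_test(inputs$panel, fish_groups, config)
    )
  }

  manifest <- list(
    package = "salmospec",
    version = as.character(utils::packageVersion("salmospec")),
    seed = seed,
    config = unclass(config),
    n_genes = nrow(expr),
    n_samples = ncol(expr) - 1,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  bundle <- structure(
    list(
      cohort = cohort,
      specific_activity = sa,
      gsg_calls = gsg_calls,
      specificity_summary = summary_tbl,
      gene_sets = gene_sets,
      hormones = hormones,
      manifest = manifest
    ),
    class = "report_bundle"
  )
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle to TSV files plus a JSON manifest
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (is.null(x)) return(NULL)
    readr::write_tsv(as_tibble(x), file.path(out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
    paste0(name, ".tsv")
  }
  files <- c(
    wr(bundle$cohort, "cohort"),
    wr(tidy(bundle$specific_activity), "specific_activity"),
    wr(bundle$gsg_calls, "gsg_calls"),
    wr(bundle$specificity_summary, "specificity_summary"),
    if (!is.null(bundle$gene_sets)) wr(tidy(bundle$gene_sets), "gene_sets"),
    if (!is.null(bundle$hormones)) c(
      wr(bundle$hormones$correlations, "hormone_correlations"),
      wr(bundle$hormones$folds, "hormone_folds"),
      wr(bundle$hormones$tests, "hormone_tests")
    )
  )
  manifest <- c(bundle$manifest, list(files = files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  g <- glance(x$specific_activity)
  cat(sprintf("  cohort: %d fish (%d immature / %d pubertal / %d indeterminate)\n",
              nrow(x$cohort),
              sum(x$cohort$maturity_group == "immature"),
              sum(x$cohort$maturity_group == "pubertal"),
              sum(x$cohort$maturity_group == "indeterminate")))
  cat(sprintf("  specific activity: %d genes, %d HSA / %d LSA / %d NS\n",
              g$n_genes, g$n_hsa, g$n_lsa, g$n_ns))
  if (!is.null(x$gsg_calls)) {
    cat(sprintf("  gonad-specific genes: %d of %d\n",
                sum(x$gsg_calls$gonad_specific), nrow(x$gsg_calls)))
  }
  if (!is.null(x$gene_sets)) {
    gs <- glance(x$gene_sets)
    cat(sprintf("  functional groups tested: %d (%d significant)\n",
                gs$n_groups, gs$n_significant))
  }
  if (!is.null(x$hormones)) {
    cat(sprintf("  hormone analytes: %d\n", nrow(x$hormones$correlations)))
  }
  invisible(x)
}

#' Heatmap of sample-centered log2 expression
#'
#' Draws the per-gene sample-centered log2 profile
#' ([center_to_sample_average()]) for a gene subset, samples ordered by a
#' per-sample index (typically GSI) when supplied.
#'
#' @param expr Linear-scale expression tibble.
#' @param genes Gene identifiers to show (default: first 50).
#' @param sample_order Optional character vector giving the sample display
#'   order.
#' @return A ggplot object.
#' @export
plot_centered_heatmap <- function(expr, genes = NULL, sample_order = NULL) {
  validate_expr(expr, require_positive = TRUE)
  log2_expr <- bind_cols(tibble(gene_id = expr$gene_id),
                         as_tibble(log2(as.matrix(expr[, -1, drop = FALSE])),
                                   .name_repair = "minimal"))
  centered <- center_to_sample_average(log2_expr)
  genes <- genes %||% utils::head(centered$gene_id, 50)
  dat <- centered |>
    filter(.data$gene_id %in% genes) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "centered_log2")
  if (!is.null(sample_order)) {
    dat$sample_id <- factor(dat$sample_id, levels = sample_order)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                    fill = .data$centered_log2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "centered\nlog2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}
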