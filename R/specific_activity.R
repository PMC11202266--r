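sample_groups_for_expr <- function(expr, groups, min_n = 1) {
  grp <- normalize_groups(groups, id_col = "sample_id")
  samples <- names(expr)[-1]
  grp$immature <- intersect(samples, grp$immature)
  grp$pubertal <- intersect(samples, grp$pubertal)
  if (length(grp$immature) == 0) abort("no immature samples found in the expression table")
  if (length(grp$pubertal) == 0) abort("no pubertal samples found in the expression table")
  if (length(grp$immature) < min_n || length(grp$pubertal) < min_n) {
    abort(sprintf("each group needs at least %d samples", min_n))
  }
  grp
}

#' Per-gene log2 expression ratio between maturity groups
#'
#' For each gene, the mean of log2 intensities over pubertal samples minus the
#' mean over immature samples (a log2 ratio of geometric group means).
#' Intensities must already be floored and strictly positive.
#'
#' @param expr Expression tibble (linear scale; see [read_expression_tsv()]).
#' @param groups Per-sample maturity groups: data frame with `sample_id` and
#'   `group` columns, or a named character vector. Samples labelled neither
#'   `"immature"` nor `"pubertal"` are ignored.
#' @return Tibble with `gene_id` and `log2_er`.
#' @export
log2_expression_ratio <- function(expr, groups) {
  validate_expr(expr, require_positive = TRUE)
  grp <- sample_groups_for_expr(expr, groups)
  mat <- log2(as_expr_matrix(expr))
  tibble(
    gene_id = expr$gene_id,
    log2_er = unname(rowMeans(mat[, grp$pubertal, drop = FALSE]) -
                       rowMeans(mat[, grp$immature, drop = FALSE]))
  )
}

row_var <- function(mat) {
  n <- ncol(mat)
  if (n < 2) return(rep(NA_real_, nrow(mat)))
  rowSums((mat - rowMeans(mat))^2) / (n - 1)
}

#' Per-gene t-test between maturity groups
#'
#' Two-sample t-test per gene on log2 intensities (Welch by default, pooled
#' when `config$var_equal = TRUE`). When both groups have zero variance, p is
#' 1 for equal means and 0 otherwise. With `config$p_adjust = "BH"`,
#' Benjamini-Hochberg adjusted p-values are returned (not part of the raw
#' classification criteria).
#'
#' @inheritParams log2_expression_ratio
#' @param config A [run_config()].
#' @return Tibble with `gene_id` and `p_value`.
#' @export
per_gene_test <- function(expr, groups, config = run_config()) {
  validate_expr(expr, require_positive = TRUE)
  grp <- sample_groups_for_expr(expr, groups, min_n = 2)
  mat <- log2(as_expr_matrix(expr))
  x <- mat[, grp$pubertal, drop = FALSE]
  y <- mat[, grp$immature, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- row_var(x); v2 <- row_var(y)
  if (config$var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  if (config$p_adjust != "none") p <- stats::p.adjust(p, method = config$p_adjust)
  tibble(gene_id = expr$gene_id, p_value = unname(p))
}

#' Classify genes as HSA, LSA, or NS
#'
#' High specific activity (HSA): log2-ER strictly above the cutoff with
#' p strictly below alpha. Low specific activity (LSA): log2-ER strictly below
#' the negated cutoff with p strictly below alpha. Everything else is NS.
#' Both inequalities are strict, so a gene sitting exactly on either boundary
#' is NS.
#'
#' @param log2_er Numeric vector of per-gene log2 expression ratios.
#' @param p_value Numeric vector of per-gene p-values (NA counts as NS).
#' @param config A [run_config()] supplying `log2er_cutoff` and `alpha`.
#' @return Character vector in `{"HSA", "LSA", "NS"}`.
#' @export
sa_classify <- function(log2_er, p_value, config = run_config()) {
  if (length(log2_er) != length(p_value)) {
    abort("log2_er and p_value must be aligned vectors of equal length")
  }
  sig <- !is.na(p_value) & p_value < config$alpha
  dplyr::case_when(
    sig & log2_er > config$log2er_cutoff ~ "HSA",
    sig & log2_er < -config$log2er_cutoff ~ "LSA",
    TRUE ~ "NS"
  )
}

#' Signed linear fold from a log2 ratio
#'
#' `2^m` for `m >= 0` and `-2^(-m)` for `m < 0`: magnitudes are symmetric
#' around 1 and the sign encodes direction, the usual convention of
#' fold-change tables (e.g. a log2 ratio of -3.036 prints as -8.2).
#'
#' @param log2_er Numeric vector of log2 ratios.
#' @return Signed folds; `signed_fold(0)` is 1.
#' @examples
#' signed_fold(c(0, 1, -1))
#' @export
signed_fold <- function(log2_er) {
  ifelse(log2_er >= 0, 2^log2_er, -(2^(-log2_er)))
}

#' Differential specific-activity analysis
#'
#' The core per-gene comparison of pubertal against immature testes: log2
#' expression ratio ([log2_expression_ratio()]), per-gene t-test
#' ([per_gene_test()]), HSA/LSA/NS class ([sa_classify()]), and signed fold.
#' "Specific activity" rather than regulation: with bulk testis RNA a class
#' call can reflect disproportional compartment growth as well as
#' transcriptional change.
#'
#' @inheritParams per_gene_test
#' @return An `sa_result` tibble with columns `gene_id`, `log2_er`,
#'   `p_value`, `class`, `fold`, carrying the config and group sizes as
#'   attributes. Methods: [tidy()], [glance()], [autoplot()].
#' @export
diff_specific_activity <- function(expr, groups, config = run_config()) {
  lfc <- log2_expression_ratio(expr, groups)
  p <- per_gene_test(expr, groups, config)
  grp <- sample_groups_for_expr(expr, groups)
  out <- lfc |>
    left_join(p, by = "gene_id") |>
    mutate(
      class = sa_classify(.data$log2_er, .data$p_value, config),
      fold = signed_fold(.data$log2_er)
    )
  structure(out,
    class = c("sa_result", class(out)),
    config = config,
    n_immature = length(grp$immature),
    n_pubertal = length(grp$pubertal)
  )
}

#' @method tidy sa_result
#' @export
tidy.sa_result <- function(x, ...) {
  as_tibble(unclass_sa(x))
}

#' @method glance sa_result
#' @export
glance.sa_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_genes = nrow(x),
    n_hsa = sum(x$class == "HSA"),
    n_lsa = sum(x$class == "LSA"),
    n_ns = sum(x$class == "NS"),
    n_immature = attr(x, "n_immature"),
    n_pubertal = attr(x, "n_pubertal"),
    log2er_cutoff = cfg$log2er_cutoff,
    alpha = cfg$alpha
  )
}

unclass_sa <- function(x) {
  class(x) <- setdiff(class(x), "sa_result")
  attr(x, "config") <- NULL
  attr(x, "n_immature") <- NULL
  attr(x, "n_pubertal") <- NULL
  x
}

#' Volcano plot of a specific-activity result
#'
#' @param object An `sa_result` from [diff_specific_activity()].
#' @param ... Unused.
#' @return A ggplot object: log2-ER against -log10 p, coloured by class, with
#'   the classification cutoffs drawn.
#' @method autoplot sa_result
#' @export
autoplot.sa_result <- function(object, ...) {
  cfg <- attr(object, "config")
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_er,
                                    y = -log10(pmax(.data$p_value, 1e-300)),
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * cfg$log2er_cutoff,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(HSA = "#c0392b", LSA = "#2980b9",
                                            NS = "grey70")) +
    ggplot2::labs(x = "log2 expression ratio (pubertal / immature)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Center a log2 expression table to the per-gene sample average
#'
#' Subtracts each gene's across-sample mean, so every row mean is zero: the
#' profile view used to compare individual fish against the cohort average.
#'
#' @param expr_log2 Expression tibble on the log2 scale.
#' @return The centered tibble (same shape).
#' @export
center_to_sample_average <- function(expr_log2) {
  if (names(expr_log2)[1] != "gene_id") {
    abort("first column must be 'gene_id'")
  }
  mat <- as.matrix(expr_log2[, -1, drop = FALSE])
  centered <- mat - rowMeans(mat)
  bind_cols(tibble(gene_id = expr_log2$gene_id),
            as_tibble(centered, .name_repair = "minimal"))
}

#' Summarize classified genes by gonad specificity
#'
#' The class-by-specificity contingency summary: per class (HSA, LSA) and in
#' total, the number of genes, the number that are gonad-specific, and the
#' gonad-specific percentage to one decimal. The ratio of the HSA to the LSA
#' gonad-specific proportion (one decimal) is attached as the
#' `"hsa_lsa_ratio"` attribute and reported by [glance()].
#'
#' @param results Data frame with `gene_id` and `class` columns (e.g. an
#'   `sa_result`).
#' @param gsg Gonad-specificity flags: a data frame with `gene_id` and
#'   `gonad_specific` (e.g. from [call_gonad_specific()]), or a logical vector
#'   aligned with `results`. Every classified (HSA/LSA) gene must be covered;
#'   an unflagged gene is a hard error.
#' @return A `specificity_summary` tibble with rows HSA, LSA, Total and
#'   columns `class`, `n_genes`, `n_gonad_specific`, `pct_gonad_specific`.
#' @examples
#' res <- tibble::tibble(
#'   gene_id = paste0("g", 1:4),
#'   class = c("HSA", "HSA", "LSA", "NS")
#' )
#' flags <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                         gonad_specific = c(TRUE, FALSE, FALSE, FALSE))
#' summarize_by_specificity(res, flags)
#' @export
summarize_by_specificity <- function(results, gsg) {
  if (is.logical(gsg)) {
    if (length(gsg) != nrow(results)) {
      abort("logical gsg flags must align with results rows")
    }
    flags <- tibble(gene_id = results$gene_id, gonad_specific = gsg)
  } else {
    if (!all(c("gene_id", "gonad_specific") %in% names(gsg))) {
      abort("gsg must have 'gene_id' and 'gonad_specific' columns")
    }
    flags <- as_tibble(gsg)[, c("gene_id", "gonad_specific")]
  }
  dat <- left_join(as_tibble(results)[, c("gene_id", "class")], flags,
                   by = "gene_id")
  missing_flag <- dat$gene_id[dat$class %in% c("HSA", "LSA") &
                                is.na(dat$gonad_specific)]
  if (length(missing_flag) > 0) {
    abort(paste0("gene(s) without a gonad-specificity flag: ",
                 paste(utils::head(missing_flag, 5), collapse = ", ")))
  }
  one_row <- function(label, sub) {
    n <- nrow(sub)
    ns <- sum(sub$gonad_specific)
    tibble(
      class = label, n_genes = n, n_gonad_specific = ns,
      pct_gonad_specific = if (n > 0) round(100 * ns / n, 1) else NA_real_
    )
  }
  hsa <- filter(dat, .data$class == "HSA")
  lsa <- filter(dat, .data$class == "LSA")
  out <- bind_rows(
    one_row("HSA", hsa),
    one_row("LSA", lsa),
    one_row("Total", bind_rows(hsa, lsa))
  )
  ratio <- if (nrow(hsa) > 0 && nrow(lsa) > 0 && sum(lsa$gonad_specific) > 0) {
    round((sum(hsa$gonad_specific) / nrow(hsa)) /
            (sum(lsa$gonad_specific) / nrow(lsa)), 1)
  } else {
    NA_real_
  }
  structure(out, class = c("specificity_summary", class(out)),
            hsa_lsa_ratio = ratio)
}

#' @method glance specificity_summary
#' @export
glance.specificity_summary <- function(x, ...) {
  tot <- x[x$class == "Total", ]
  tibble(
    n_genes = tot$n_genes,
    n_gonad_specific = tot$n_gonad_specific,
    pct_gonad_specific = tot$pct_gonad_specific,
    hsa_lsa_ratio = attr(x, "hsa_lsa_ratio")
  )
}

#' Trigger-candidate screen over explicit sample sets
#'
#' Finds genes elevated in every "include" sample and in no "exclude" sample,
#' relative to a baseline: a gene is selected when its log2 intensity exceeds
#' its baseline mean log2 intensity by more than `config$log2er_cutoff` in
#' all include samples and in none of the exclude samples. Used to screen for
#' genes that respond in endocrine-activated fish before histological change.
#'
#' @inheritParams log2_expression_ratio
#' @param include_samples Samples in which the gene must be elevated.
#' @param exclude_samples Samples in which it must not be elevated.
#' @param baseline_samples Samples defining the per-gene baseline mean.
#' @param config A [run_config()]; `log2er_cutoff` is the elevation threshold.
#' @return Tibble with the selected `gene_id`s and their minimum elevation
#'   over the include set (`min_include_log2_diff`).
#' @export
candidate_screen <- function(expr, include_samples, exclude_samples,
                             baseline_samples, config = run_config()) {
  validate_expr(expr, require_positive = TRUE)
  sets <- list(include = include_samples, exclude = exclude_samples,
               baseline = baseline_samples)
  if (length(include_samples) == 0 || length(baseline_samples) == 0) {
    abort("include and baseline sample sets must be non-empty")
  }
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0) {
        abort(sprintf("sample sets '%s' and '%s' overlap", names(sets)[i],
                      names(sets)[j]))
      }
    }
  }
  missing <- setdiff(unlist(sets), names(expr)[-1])
  if (length(missing) > 0) {
    abort(paste0("unknown sample id(s): ", paste(missing, collapse = ", ")))
  }
  mat <- log2(as_expr_matrix(expr))
  base_mean <- rowMeans(mat[, baseline_samples, drop = FALSE])
  elevated <- mat - base_mean > config$log2er_cutoff
  keep_inc <- rowSums(elevated[, include_samples, drop = FALSE]) ==
    length(include_samples)
  keep_exc <- if (length(exclude_samples) > 0) {
    rowSums(elevated[, exclude_samples, drop = FALSE]) == 0
  } else {
    TRUE
  }
  sel <- keep_inc & keep_exc
  tibble(
    gene_id = expr$gene_id[sel],
    min_include_log2_diff =
      apply((mat - base_mean)[sel, include_samples, drop = FALSE], 1, min)
  )
}
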