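#' Functional-group shift test
#'
#' Detects coordinated specific-activity change of annotated gene groups: per
#' group, the mean log2 expression ratio of its member genes, a test of
#' whether that mean deviates from zero, and the signed mean fold
#' ([signed_fold()] of the mean log2-ER, one decimal). Groups with fewer than
#' `config$min_set_size` scored genes are excluded; groups whose members all
#' share one identical log2-ER have an undefined p (reported as `NA`). When
#' the result table carries `class` and gonad-specificity flags, the counts of
#' gonad-specific genes among the LSA and HSA members are reported as well.
#'
#' The default test is a one-sample t-test of the member log2-ERs against
#' zero. Because inter-gene correlation inflates its type-I error on real
#' arrays, a gene-label permutation alternative is available
#' (`method = "permutation"`): the observed |mean| is compared with means of
#' `n_perm` random same-size gene sets drawn from the full log2-ER vector.
#'
#' @param results Data frame with `gene_id` and `log2_er`; optionally `class`
#'   (HSA/LSA/NS) and `gonad_specific` for the specificity counts.
#' @param annotation Data frame with `gene_id` and `functional_group`;
#'   multi-membership via repeated rows. Genes absent from `results` are
#'   ignored with an informational message.
#' @param config A [run_config()]; uses `min_set_size` and `p_adjust`.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param seed Optional seed for the permutation draw.
#' @return A `geneset_result` tibble: `functional_group`, `n_genes`,
#'   `gs_lsa`, `gs_hsa`, `mean_log2_er`, `p_value`, `mean_fold`.
#' @export
set_shift_test <- function(results, annotation, config = run_config(),
                           method = c("t", "permutation"), n_perm = 10000,
                           seed = NULL) {
  method <- match.arg(method)
  if (!all(c("gene_id", "log2_er") %in% names(results))) {
    abort("results must have 'gene_id' and 'log2_er' columns")
  }
  if (!all(c("gene_id", "functional_group") %in% names(annotation))) {
    abort("annotation must have 'gene_id' and 'functional_group' columns")
  }
  if (any(!nzchar(annotation$functional_group)) ||
      any(is.na(annotation$functional_group))) {
    abort("functional group labels must be non-empty strings")
  }
  res <- as_tibble(results)
  ann <- as_tibble(annotation)
  n_absent <- length(setdiff(unique(ann$gene_id), res$gene_id))
  if (n_absent > 0) {
    inform(sprintf("%d annotated gene(s) absent from the results were ignored",
                   n_absent))
  }
  has_class <- all(c("class", "gonad_specific") %in% names(res))
  dat <- inner_join(ann, res, by = "gene_id")

  one_sample_p <- function(x) {
    if (length(x) < 2 || sd(x) == 0) return(NA_real_)
    t.test(x, mu = 0)$p.value
  }
  perm_p <- function(x, pool) {
    obs <- abs(mean(x))
    perm <- replicate(n_perm, abs(mean(sample(pool, length(x)))))
    (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  if (method == "permutation" && !is.null(seed)) set.seed(seed)
  pool <- res$log2_er

  out <- dat |>
    group_by(.data$functional_group) |>
    summarise(
      n_genes = dplyr::n(),
      gs_lsa = if (has_class) {
        sum(.data$class == "LSA" & .data$gonad_specific)
      } else {
        NA_integer_
      },
      gs_hsa = if (has_class) {
        sum(.data$class == "HSA" & .data$gonad_specific)
      } else {
        NA_integer_
      },
      mean_log2_er = mean(.data$log2_er),
      p_value = if (method == "t") {
        one_sample_p(.data$log2_er)
      } else {
        perm_p(.data$log2_er, pool)
      },
      .groups = "drop"
    ) |>
    filter(.data$n_genes >= config$min_set_size) |>
    mutate(mean_fold = round(signed_fold(.data$mean_log2_er), 1))
  if (config$p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = config$p_adjust)
  }
  structure(out, class = c("geneset_result", class(out)), config = config)
}

#' Rank significant functional groups by fold magnitude
#'
#' Keeps the groups significant at `alpha` whose mean log2-ER has the
#' requested sign and orders them by decreasing |mean fold|; ties are broken
#' by group label so the order is stable.
#'
#' @param results A `geneset_result` from [set_shift_test()].
#' @param direction `"increased"` (mean log2-ER > 0) or `"decreased"` (< 0).
#' @param alpha Significance level; defaults to the config stored in
#'   `results`, else 0.05.
#' @return The ordered subset of `results`.
#' @export
rank_sets <- function(results, direction = c("increased", "decreased"),
                      alpha = NULL) {
  direction <- match.arg(direction)
  alpha <- alpha %||% attr(results, "config")$alpha %||% 0.05
  sgn <- if (direction == "increased") 1 else -1
  results |>
    filter(!is.na(.data$p_value), .data$p_value < alpha,
           sign(.data$mean_log2_er) == sgn) |>
    arrange(desc(abs(.data$mean_fold)), .data$functional_group)
}

#' @method glance geneset_result
#' @export
glance.geneset_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_groups = nrow(x),
    n_significant = sum(!is.na(x$p_value) & x$p_value < cfg$alpha),
    n_increased = sum(!is.na(x$p_value) & x$p_value < cfg$alpha &
                        x$mean_log2_er > 0),
    n_decreased = sum(!is.na(x$p_value) & x$p_value < cfg$alpha &
                        x$mean_log2_er < 0),
    min_set_size = cfg$min_set_size,
    alpha = cfg$alpha
  )
}

#' @method tidy geneset_result
#' @export
tidy.geneset_result <- function(x, ...) {
  y <- x
  class(y) <- setdiff(class(y), "geneset_result")
  attr(y, "config") <- NULL
  as_tibble(y)
}

#' Bar plot of functional-group mean folds
#'
#' @param object A `geneset_result` from [set_shift_test()].
#' @param alpha Significance level used to dim non-significant groups.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot geneset_result
#' @export
autoplot.geneset_result <- function(object, alpha = NULL, ...) {
  alpha <- alpha %||% attr(object, "config")$alpha
  dat <- tidy(object) |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$functional_group, .data$mean_fold),
    y = .data$mean_fold, fill = .data$mean_fold > 0,
    alpha = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "#2980b9"),
                               guide = "none") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "mean fold (pubertal / immature)") +
    ggplot2::theme_minimal()
}
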