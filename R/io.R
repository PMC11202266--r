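#' Expression tables
#'
#' Expression data travel as tibbles whose first column is `gene_id`
#' (character, unique) and whose remaining columns are samples holding
#' strictly positive linear-scale intensities. `as_expr_matrix()` converts to
#' a base matrix (genes in rows) for numeric work; `as_expr_tibble()` converts
#' back.
#'
#' @param expr An expression tibble.
#' @param x A numeric matrix with gene identifiers as row names.
#' @return `as_expr_matrix()` a numeric matrix; `as_expr_tibble()` a tibble.
#' @name expression-tables
NULL

#' @rdname expression-tables
#' @export
as_expr_matrix <- function(expr) {
  validate_expr(expr)
  mat <- as.matrix(expr[, -1, drop = FALSE])
  rownames(mat) <- expr$gene_id
  mat
}

#' @rdname expression-tables
#' @export
as_expr_tibble <- function(x) {
  if (is.null(rownames(x))) abort("matrix must carry gene identifiers as row names")
  bind_cols(tibble(gene_id = rownames(x)), as_tibble(x, .name_repair = "minimal"))
}

validate_expr <- function(expr, require_positive = FALSE) {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort("expression table must be a data frame with gene_id plus sample columns")
  }
  if (names(expr)[1] != "gene_id") {
    abort("first column of an expression table must be 'gene_id'")
  }
  dup_g <- expr$gene_id[duplicated(expr$gene_id)]
  if (length(dup_g) > 0) {
    abort(paste0("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", ")))
  }
  dup_s <- names(expr)[-1][duplicated(names(expr)[-1])]
  if (length(dup_s) > 0) {
    abort(paste0("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression values must be numeric")
  if (any(!is.finite(vals))) abort("expression values must all be finite")
  if (require_positive && any(vals <= 0)) {
    abort("expression values must be strictly positive; apply an intensity floor first")
  }
  invisible(expr)
}

#' Raise non-positive or missing intensities to a floor
#'
#' Background handling before any log2: intensities that are missing, not
#' finite, or not strictly positive are replaced by `floor` on the linear
#' scale, so that log2 is always defined.
#'
#' @param expr Expression tibble (see [as_expr_matrix()]).
#' @param floor Linear-scale replacement value. Default 1.
#' @return The floored expression tibble.
#' @export
apply_intensity_floor <- function(expr, floor = 1) {
  if (!is.numeric(floor) || floor <= 0) abort("intensity floor must be positive")
  mutate(expr, across(-"gene_id", function(v) {
    v[!is.finite(v) | v <= 0] <- floor
    v
  }))
}

#' Read an expression matrix from TSV
#'
#' Expects a header row and, by default, genes in rows: the first column holds
#' gene identifiers, the remaining columns one sample each. Duplicated
#' identifiers and non-numeric cells are hard errors (the offending
#' identifier, or the gene/sample coordinates, are named). Non-positive and
#' missing intensities are raised to `floor`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`
#'   (the table is transposed after reading).
#' @param floor Linear-scale intensity floor; see [apply_intensity_floor()].
#' @return An expression tibble (`gene_id` plus one column per sample).
#' @seealso [write_expression_tsv()], [read_geo_series_matrix()]
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_in_rows", "samples_in_rows"),
                                floor = 1) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression TSV needs an identifier column plus data columns")
  ids <- raw[[1]]
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(raw)[-1]))
  bad <- which(is.na(num) & !is.na(as.matrix(raw[-1])), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric value '%s' at row '%s', column '%s'",
      as.matrix(raw[-1])[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
      colnames(num)[bad[1, 2]]
    ))
  }
  expr <- bind_cols(tibble(gene_id = ids), as_tibble(num, .name_repair = "minimal"))
  if (orientation == "samples_in_rows") {
    mat <- t(as.matrix(expr[, -1, drop = FALSE]))
    colnames(mat) <- expr$gene_id
    expr <- bind_cols(tibble(gene_id = rownames(mat)),
                      as_tibble(mat, .name_repair = "minimal"))
  }
  expr <- apply_intensity_floor(expr, floor)
  validate_expr(expr, require_positive = TRUE)
  expr
}

#' Write an expression tibble to TSV
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expr(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort (histology + biometrics) TSV
#'
#' Reads a per-fish table with at least `fish_id`; recognized optional columns
#' are `body_weight`, `fork_length`, `gonad_weight`, `gsi`,
#' `most_advanced_stage`, `dominant_stage`, `compartment_size`,
#' `observations`. Stage labels are validated against [stage_levels()] and the
#' dominating germ-cell type may never be more advanced than the most advanced
#' one.
#'
#' @param path Path to a tab-separated cohort file with a header row.
#' @return A cohort tibble.
#' @export
read_cohort_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"fish_id" %in% names(out)) abort("cohort TSV needs a 'fish_id' column")
  out$fish_id <- as.character(out$fish_id)
  if (anyDuplicated(out$fish_id)) abort("duplicate fish_id in cohort TSV")
  for (col in c("body_weight", "fork_length", "gonad_weight")) {
    if (col %in% names(out) && any(out[[col]] <= 0, na.rm = TRUE)) {
      abort(paste0("column '", col, "' must be strictly positive"))
    }
  }
  if (all(c("most_advanced_stage", "dominant_stage") %in% names(out))) {
    if (any(stage_rank(out$dominant_stage) > stage_rank(out$most_advanced_stage))) {
      abort("dominant_stage may not be more advanced than most_advanced_stage")
    }
  }
  if ("observations" %in% names(out)) {
    out$observations[is.na(out$observations)] <- ""
  }
  out
}

#' Read a GEO Series Matrix file
#'
#' Convenience reader for the flat-text Series Matrix dialect: "!"-prefixed
#' key-value header lines followed by an expression table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Sample titles
#' and accessions are collected into a metadata tibble; quotes around fields
#' are stripped. The pipeline itself never requires this format; plain TSV is
#' the canonical interchange.
#'
#' @param path Path to a (decompressed) Series Matrix file.
#' @param floor Linear-scale intensity floor applied to the parsed table.
#' @return A list with elements `expression` (expression tibble) and
#'   `metadata` (tibble with `sample_id` and any `!Sample_*` header fields).
#' @export
read_geo_series_matrix <- function(path, floor = 1) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    abort("series matrix table markers not found (or empty table)")
  }
  unquote <- function(x) gsub('^"|"$', "", x)

  tab_lines <- lines[(begin + 1):(end - 1)]
  fields <- strsplit(tab_lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1]])
  widths <- lengths(fields)
  if (any(widths != n_col)) {
    abort(sprintf("malformed series matrix table: line %d has %d fields, expected %d",
                  which(widths != n_col)[1], widths[widths != n_col][1], n_col))
  }
  header <- unquote(fields[[1]])
  body <- fields[-1]
  ids <- unquote(vapply(body, `[[`, character(1), 1))
  num <- suppressWarnings(matrix(
    as.numeric(unquote(unlist(lapply(body, `[`, -1)))),
    nrow = length(body), byrow = TRUE,
    dimnames = list(NULL, header[-1])
  ))
  if (anyNA(num)) abort("non-numeric value inside the series matrix table")
  expr <- bind_cols(tibble(gene_id = ids), as_tibble(num, .name_repair = "minimal"))
  expr <- apply_intensity_floor(expr, floor)
  validate_expr(expr, require_positive = TRUE)

  hdr <- grep("^!Sample_", lines, value = TRUE)
  meta <- tibble(sample_id = header[-1])
  for (line in hdr) {
    parts <- unquote(strsplit(line, "\t", fixed = TRUE)[[1]])
    key <- sub("^!Sample_", "", parts[1])
    if (length(parts) - 1 == nrow(meta) && !key %in% names(meta)) {
      meta[[key]] <- parts[-1]
    }
  }
  list(expression = expr, metadata = meta)
}
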