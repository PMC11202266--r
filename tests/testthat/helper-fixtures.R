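# Small in-code fixtures shared across test files.

# expression tibble from a matrix-like spec: one named vector per sample
make_expr <- function(gene_ids, ...) {
  cols <- list(...)
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), tibble::as_tibble(cols))
}

# random positive expression tibble, genes x samples
random_expr <- function(n_genes, n_samples, seed = 1, prefix = "s") {
  set.seed(seed)
  mat <- matrix(2^stats::rnorm(n_genes * n_samples, 7, 1.5), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                paste0(prefix, seq_len(n_samples))))
  salmospec::as_expr_tibble(mat)
}

# standard 14 immature + 6 pubertal sample grouping for a 20-column table
default_groups <- function(expr) {
  samples <- names(expr)[-1]
  stopifnot(length(samples) == 20)
  tibble::tibble(
    sample_id = samples,
    group = c(rep("immature", 14), rep("pubertal", 6))
  )
}

table1_path <- function() {
  system.file("extdata", "cohort_table1.tsv", package = "salmospec")
}

androgen_names <- function() {
  names(sim_config()$hormone_folds)
}

# mean sample Pearson r between the androgen-like analytes and GSI,
# averaged over replicate simulated panels
mean_hormone_r <- function(n_reps, base_seed = 1, config = sim_config()) {
  rs <- vapply(seq_len(n_reps), function(i) {
    h <- generate_hormones(config, seed = base_seed + i - 1)
    idx <- stats::setNames(h$cohort$cohort$gsi, h$cohort$cohort$fish_id)
    cors <- correlate_with_index(h$panel, idx)
    mean(cors$r[cors$analyte %in% androgen_names()])
  }, numeric(1))
  mean(rs)
}
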