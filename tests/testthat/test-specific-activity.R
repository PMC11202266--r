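test_that("log2 expression ratio matches brute-force per-gene recomputation", {
  expr <- random_expr(100, 20, seed = 3)
  groups <- default_groups(expr)
  out <- log2_expression_ratio(expr, groups)
  # independent oracle: loop gene by gene over raw vectors
  mat <- as.matrix(expr[, -1])
  imm <- groups$sample_id[groups$group == "immature"]
  pub <- groups$sample_id[groups$group == "pubertal"]
  oracle <- vapply(seq_len(nrow(mat)), function(i) {
    mean(log2(mat[i, pub])) - mean(log2(mat[i, imm]))
  }, numeric(1))
  expect_equal(out$log2_er, oracle, tolerance = 1e-12)
})

test_that("log2 expression ratio has exact values on constructed cases", {
  expr <- make_expr(c("flat", "doubled"),
                    i1 = c(5, 3), i2 = c(5, 3), p1 = c(5, 6), p2 = c(5, 6))
  groups <- tibble::tibble(sample_id = c("i1", "i2", "p1", "p2"),
                           group = c("immature", "immature", "pubertal", "pubertal"))
  out <- log2_expression_ratio(expr, groups)
  expect_equal(out$log2_er[out$gene_id == "flat"], 0)
  expect_equal(out$log2_er[out$gene_id == "doubled"], 1)
  expect_error(
    log2_expression_ratio(expr, dplyr::mutate(groups, group = "immature")),
    "pubertal"
  )
})

test_that("per-gene Welch and pooled tests match t.test on small matrices", {
  expr <- random_expr(10, 20, seed = 4)
  groups <- default_groups(expr)
  mat <- log2(as.matrix(expr[, -1]))
  imm <- groups$sample_id[groups$group == "immature"]
  pub <- groups$sample_id[groups$group == "pubertal"]
  for (ve in c(FALSE, TRUE)) {
    cfg <- run_config(var_equal = ve)
    out <- per_gene_test(expr, groups, cfg)
    oracle <- vapply(seq_len(nrow(mat)), function(i) {
      stats::t.test(mat[i, pub], mat[i, imm], var.equal = ve)$p.value
    }, numeric(1))
    expect_equal(out$p_value, oracle, tolerance = 1e-10)
  }
})

test_that("per-gene test is calibrated under the null and powered under shift", {
  set.seed(21)
  n_genes <- 2000
  mat <- matrix(2^rnorm(n_genes * 20, 7, 1), nrow = n_genes,
                dimnames = list(sprintf("n%04d", 1:n_genes), paste0("s", 1:20)))
  expr <- as_expr_tibble(mat)
  groups <- default_groups(expr)
  p <- per_gene_test(expr, groups)$p_value
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)

  # planted shift of 2 pooled SDs in 100 genes
  shift <- mat
  shift[1:100, 15:20] <- shift[1:100, 15:20] * 2^2 # log2 sd is 1
  p2 <- per_gene_test(as_expr_tibble(shift), groups)$p_value
  expect_lt(median(p2[1:100]), 0.05)
})

test_that("zero-variance genes get the degenerate p-value rule", {
  expr <- make_expr(c("const", "split"),
                    i1 = c(4, 2), i2 = c(4, 2), p1 = c(4, 8), p2 = c(4, 8))
  groups <- tibble::tibble(sample_id = c("i1", "i2", "p1", "p2"),
                           group = c("immature", "immature", "pubertal", "pubertal"))
  p <- per_gene_test(expr, groups)
  expect_equal(p$p_value[p$gene_id == "const"], 1)
  expect_equal(p$p_value[p$gene_id == "split"], 0)
})

test_that("classification applies strict cutoffs on both axes", {
  cfg <- run_config()
  expect_identical(sa_classify(0.8, 0.01, cfg), "NS")   # boundary log2-ER
  expect_identical(sa_classify(1.0, 0.049, cfg), "HSA")
  expect_identical(sa_classify(-3.0, 0.001, cfg), "LSA")
  expect_identical(sa_classify(1.0, 0.05, cfg), "NS")   # boundary alpha
  expect_identical(sa_classify(-0.8, 0.001, cfg), "NS")
  expect_identical(sa_classify(2, NA_real_, cfg), "NS")
})

test_that("signed fold is symmetric and matches the printed convention", {
  expect_equal(signed_fold(0), 1)
  expect_equal(signed_fold(1), 2)
  expect_equal(signed_fold(-1), -2)
  expect_equal(signed_fold(3), -signed_fold(-3))
  expect_equal(round(signed_fold(-3.036), 1), -8.2)
  expect_equal(signed_fold(log2(25.3)), 25.3)
})

test_that("classification is antisymmetric under group swap", {
  expr <- random_expr(200, 20, seed = 8)
  groups <- default_groups(expr)
  swapped <- dplyr::mutate(groups, group = ifelse(group == "immature",
                                                  "pubertal", "immature"))
  a <- diff_specific_activity(expr, groups)
  b <- diff_specific_activity(expr, swapped)
  expect_equal(b$log2_er, -a$log2_er, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  map <- c(HSA = "LSA", LSA = "HSA", NS = "NS")
  expect_identical(b$class, unname(map[a$class]))
})

test_that("sample centering zeroes every gene mean", {
  expr <- make_expr(c("c", "r"), s1 = c(2, 1), s2 = c(2, 3))
  out <- center_to_sample_average(expr)
  expect_equal(unname(as.matrix(out[, -1])),
               matrix(c(0, -1, 0, 1), 2))
  big <- random_expr(100, 12, seed = 5)
  big_log2 <- dplyr::mutate(big, dplyr::across(-gene_id, log2))
  centered <- center_to_sample_average(big_log2)
  expect_true(all(abs(rowMeans(as.matrix(centered[, -1]))) < 1e-12))
})

test_that("specificity summary reproduces contingency arithmetic", {
  res <- tibble::tibble(
    gene_id = paste0("g", 1:10),
    class = c(rep("HSA", 10))
  )
  flags <- tibble::tibble(gene_id = paste0("g", 1:10),
                          gonad_specific = c(rep(TRUE, 5), rep(FALSE, 5)))
  out <- summarize_by_specificity(res, flags)
  expect_equal(out$pct_gonad_specific[out$class == "HSA"], 50.0)

  all_ns <- tibble::tibble(gene_id = "g1", class = "NS")
  empty <- summarize_by_specificity(all_ns, tibble::tibble(
    gene_id = "g1", gonad_specific = FALSE
  ))
  expect_equal(empty$n_genes, c(0L, 0L, 0L))
  expect_true(all(is.na(empty$pct_gonad_specific)))

  expect_error(
    summarize_by_specificity(res, flags[1:3, ]),
    "without a gonad-specificity flag"
  )
})

test_that("candidate screen selects planted genes and honors the exclusion rule", {
  set.seed(6)
  n_genes <- 120
  samples <- c(paste0("inc", 1:7), "exc1", paste0("base", 1:6))
  mat <- matrix(2^rnorm(n_genes * length(samples), 7, 0.2), nrow = n_genes,
                dimnames = list(sprintf("g%03d", 1:n_genes), samples))
  planted <- sprintf("g%03d", 1:20)
  mat[planted, paste0("inc", 1:7)] <-
    mat[planted, paste0("inc", 1:7)] * 2^3 # far above the 0.8 cutoff
  decoy <- sprintf("g%03d", 21:25) # elevated in includes AND the exclude
  mat[decoy, c(paste0("inc", 1:7), "exc1")] <-
    mat[decoy, c(paste0("inc", 1:7), "exc1")] * 2^3
  expr <- as_expr_tibble(mat)

  hits <- candidate_screen(expr, include_samples = paste0("inc", 1:7),
                           exclude_samples = "exc1",
                           baseline_samples = paste0("base", 1:6))
  expect_setequal(hits$gene_id, planted)

  expect_error(
    candidate_screen(expr, paste0("inc", 1:7), "inc1", paste0("base", 1:6)),
    "overlap"
  )
})

test_that("tidy, glance, and autoplot work on a specific-activity result", {
  expr <- random_expr(50, 20, seed = 9)
  sa <- diff_specific_activity(expr, default_groups(expr))
  td <- tidy(sa)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "sa_result"))
  gl <- glance(sa)
  expect_equal(gl$n_genes, 50)
  expect_equal(gl$n_hsa + gl$n_lsa + gl$n_ns, 50)
  expect_equal(gl$n_immature, 14)
  expect_s3_class(autoplot(sa), "ggplot")
})
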