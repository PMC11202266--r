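test_that("generators are fully deterministic under a fixed seed", {
  a <- simulate_study(seed = 5)
  b <- simulate_study(seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$expression, b$expression)
  expect_identical(a$compendium, b$compendium)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(seed = 6)
  expect_false(identical(a$expression, c$expression))
})

test_that("cohort has the study's group structure and planted observations", {
  cfg <- sim_config()
  out <- generate_cohort(cfg, seed = 2)
  expect_equal(nrow(out$cohort), 20)
  expect_equal(sum(out$cohort$group == "immature"), 14)
  expect_equal(sum(out$cohort$group == "pubertal"), 6)
  imm <- out$cohort[out$cohort$group == "immature", ]
  pub <- out$cohort[out$cohort$group == "pubertal", ]
  expect_true(all(imm$gsi >= 0.01 & imm$gsi <= 0.08))
  expect_true(all(pub$gsi >= 0.23 & pub$gsi <= 0.60))
  expect_true(all(imm$most_advanced_stage == "SPA"))
  expect_true(all(pub$most_advanced_stage %in% c("SPC", "SPT", "SZ")))
  # dominant stage never exceeds the most advanced one
  lv <- function(x) match(x, stage_levels())
  expect_true(all(lv(out$cohort$dominant_stage) <=
                    lv(out$cohort$most_advanced_stage)))
  # oocytes only among immature fish; expected 3 of 14 over many seeds
  n_oo <- vapply(1:200, function(s) {
    co <- generate_cohort(cfg, seed = s)$cohort
    expect_true(all(co$group[co$observations == "oocytes"] == "immature"))
    sum(co$observations == "oocytes")
  }, numeric(1))
  expect_equal(mean(n_oo), 3, tolerance = 0.15)
  # GSI derived from the stored weights reproduces the stored GSI
  expect_equal(compute_gsi(out$cohort$gonad_weight, out$cohort$body_weight),
               out$cohort$gsi, tolerance = 1e-12)
})

test_that("noise-free mixture output matches the closed form to machine precision", {
  cfg <- sim_config(n_genes = 300, noise_sd = 0, pi_sd = 0,
                    regulated_fraction = 0)
  m <- generate_testis_matrix(cfg, seed = 3)
  lfc <- log2_expression_ratio(m$expression,
                               m$truth$samples[, c("sample_id", "group")])
  truth <- m$truth$genes
  expected <- log2((0.8 * truth$germinative_level + 0.2 * truth$interstitial_level) /
                     (0.3 * truth$germinative_level + 0.7 * truth$interstitial_level))
  expect_equal(lfc$log2_er, expected, tolerance = 1e-9)
  germ <- truth$type == "germinative"
  expect_equal(lfc$log2_er[germ], rep(log2(0.8 / 0.3), sum(germ)),
               tolerance = 1e-9)
  # a shared gene with equal compartment levels is exactly flat
  g <- truth$germinative_level[1]
  eq <- make_expr("eq",
                  a = 0.3 * g + 0.7 * g, b = 0.3 * g + 0.7 * g,
                  c = 0.8 * g + 0.2 * g, d = 0.8 * g + 0.2 * g)
  eq_groups <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                              group = c("immature", "immature",
                                        "pubertal", "pubertal"))
  expect_equal(log2_expression_ratio(eq, eq_groups)$log2_er, 0)
})

test_that("planted regulation is recovered end to end", {
  cfg <- sim_config(frac_shared = 1, frac_germinative = 0, frac_interstitial = 0,
                    pi_immature = 0.5, pi_pubertal = 0.5, pi_sd = 0,
                    regulated_fraction = 0.05, regulation_log2 = 2)
  m <- generate_testis_matrix(cfg, seed = 4)
  sa <- diff_specific_activity(m$expression,
                               m$truth$samples[, c("sample_id", "group")])
  reg <- m$truth$genes$regulated
  # regulation multiplies the germinative term; at pi = 0.5 and +2 log2 the
  # expected shift is log2((0.5*4 + 0.5) / 1) = log2(2.5)
  expect_equal(mean(sa$log2_er[reg]), log2(2.5), tolerance = 0.1)
  expect_gte(mean(sa$class[reg] == "HSA"), 0.95)
  expect_lte(mean(sa$class[!reg] != "NS"), 0.01)
})

test_that("planted compendium genes sit where the margin puts them", {
  cfg1 <- sim_config(gsg_margin = 1)
  comp1 <- generate_compendium(cfg1, seed = 5)
  calls1 <- call_gonad_specific(comp1$compendium)
  planted <- comp1$truth$planted_gsg
  # margin 1: exactly on the 8-fold boundary, and called (inclusive rule)
  expect_equal(calls1$gonad_over_average_fold[planted], rep(8, sum(planted)),
               tolerance = 1e-12)
  expect_true(all(calls1$gonad_specific[planted]))

  cfg2 <- sim_config(gsg_margin = 2)
  comp2 <- generate_compendium(cfg2, seed = 5)
  calls2 <- call_gonad_specific(comp2$compendium)
  expect_true(all(calls2$gonad_over_average_fold[comp2$truth$planted_gsg] > 8))
  # decoys stay uncalled
  leaky <- comp2$truth$decoy == "leaky"
  ubi <- comp2$truth$decoy == "ubiquitous"
  expect_false(any(calls2$gonad_specific[leaky | ubi]))
  expect_true(all(calls2$expressed_elsewhere[leaky]))
})

test_that("hormone panels realize planted folds exactly without noise", {
  cfg <- sim_config(noise_sd = 0)
  h <- generate_hormones(cfg, seed = 6)
  co <- h$cohort$cohort
  groups <- tibble::tibble(fish_id = co$fish_id, group = co$group)
  folds <- group_fold(h$panel, groups)
  planted <- cfg$hormone_folds
  got <- stats::setNames(folds$fold, folds$analyte)[names(planted)]
  # concentrations are censored at zero (detection limit), so the fold and the
  # correlation are exact wherever the linear signal stays positive over the
  # cohort's GSI range; steep analytes censored at the lowest GSI realize a
  # smaller fold
  g_i <- mean(co$gsi[co$group == "immature"])
  g_p <- mean(co$gsi[co$group == "pubertal"])
  mu <- cfg$hormone_immature_mean
  signal_min <- vapply(planted, function(fold) {
    b <- mu * (fold - 1) / (g_p - g_i)
    (mu - b * g_i) + b * min(co$gsi)
  }, numeric(1))
  uncensored <- signal_min >= 0
  expect_true(any(uncensored)) # the 7.5-fold analyte is always positive
  expect_equal(unname(got[uncensored]), unname(planted[uncensored]),
               tolerance = 1e-9)
  expect_true(all(got[!uncensored] <= planted[!uncensored]))
  # noise-free androgens are perfectly linear in GSI where uncensored
  idx <- stats::setNames(co$gsi, co$fish_id)
  cors <- correlate_with_index(h$panel, idx)
  r <- stats::setNames(cors$r, cors$analyte)[names(planted)]
  expect_equal(unname(r[uncensored]), rep(1, sum(uncensored)),
               tolerance = 1e-9)
  expect_true(all(r > 0.99))
})

test_that("planted hormone folds are recovered under noise over replicates", {
  target <- "4-androsten-11B-OL3" # planted fold 10
  folds <- vapply(1:200, function(s) {
    h <- generate_hormones(seed = 500 + s)
    groups <- tibble::tibble(fish_id = h$cohort$cohort$fish_id,
                             group = h$cohort$cohort$group)
    gf <- group_fold(h$panel, groups)
    gf$fold[gf$analyte == target]
  }, numeric(1))
  expect_lt(abs(mean(folds) - 10) / 10, 0.2)
})

test_that("GSI-independent analytes show no correlation on average", {
  cortisol_like <- setdiff(unique(generate_hormones(seed = 1)$panel$analyte),
                           androgen_names())
  rs <- vapply(1:300, function(s) {
    h <- generate_hormones(seed = s)
    idx <- stats::setNames(h$cohort$cohort$gsi, h$cohort$cohort$fish_id)
    cors <- correlate_with_index(h$panel, idx)
    mean(cors$r[cors$analyte %in% cortisol_like])
  }, numeric(1))
  expect_equal(mean(rs), 0, tolerance = 0.03)
})

test_that("requested correlations at |r| >= 1 are rejected", {
  expect_error(sim_config(hormone_r = 1), "hormone_r")
  expect_error(sim_config(hormone_r = -1.2), "hormone_r")
})

test_that("simulation config validates its partitions and ranges", {
  expect_error(sim_config(frac_germinative = 0.5, frac_interstitial = 0.6,
                          frac_shared = 0.2), "sum to 1")
  expect_error(sim_config(gsi_immature = c(0.1, 0.05)), "increasing")
  expect_error(sim_config(gsi_immature = c(0.01, 0.3),
                          gsi_pubertal = c(0.23, 0.6)), "overlap")
  expect_error(sim_config(pi_pubertal = 1.2), "proportions")
  expect_error(sim_config(regulated_fraction = 0.9, frac_shared = 0.6,
                          frac_germinative = 0.2, frac_interstitial = 0.2),
               "regulated_fraction")
})
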