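#' Simulation configuration
#'
#' Parameters of the synthetic study generators. The defaults reproduce the
#' study conditions: a 20-fish cohort with bimodal GSI (14 immature fish with
#' GSI drawn from 0.01-0.08%, 6 pubertal fish from 0.23-0.60%), a
#' two-compartment testis transcriptome whose germinative proportion rises
#' with maturity (mean 0.3 immature, 0.8 pubertal), a multi-tissue compendium
#' with planted gonad-specific genes, and androgen-like serum analytes whose
#' population correlation with GSI is 0.83 and whose pubertal-over-immature
#' folds span 7.5-17.5.
#'
#' @param n_genes Number of genes in the testis expression matrix.
#' @param n_immature,n_pubertal Group sizes (defaults 14 and 6).
#' @param gsi_immature,gsi_pubertal GSI (percent) uniform sampling ranges per
#'   group.
#' @param pi_immature,pi_pubertal Mean germinative-compartment proportion per
#'   group.
#' @param pi_sd Per-fish jitter SD of the germinative proportion (truncated to
#'   the open unit interval).
#' @param frac_germinative,frac_interstitial,frac_shared Fractions of genes
#'   expressed exclusively in the germinative compartment, exclusively in the
#'   interstitial compartment, or in both; must sum to 1.
#' @param regulated_fraction Fraction of genes given a transcriptional
#'   regulation multiplier in the pubertal group. Regulation acts on the
#'   germinative term of the mixture, so regulated genes are planted among the
#'   shared genes (where it is observable).
#' @param regulation_log2 Log2 effect size of the regulation multiplier.
#' @param noise_sd Log2-scale SD of the multiplicative log-normal intensity
#'   noise.
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale location and spread
#'   of the per-gene compartment baseline intensities.
#' @param compartment_bias_sd Log2-scale SD of the compartment bias of shared
#'   genes (germinative level = base x 2^bias, interstitial = base x 2^-bias);
#'   a shared gene with zero bias is expressed identically in both
#'   compartments.
#' @param tissues Tissue labels of the compendium; must include testis and
#'   ovary plus at least one other tissue.
#' @param n_compendium_background Number of unplanted background genes in the
#'   compendium.
#' @param n_gsg Number of planted gonad-specific genes.
#' @param gsg_margin Multiplier on the target-tissue intensity relative to the
#'   intensity that puts the gene exactly at the 8-fold-over-average boundary;
#'   margin 1 plants genes exactly on the boundary.
#' @param n_decoy_ubiquitous Decoy genes expressed highly in all tissues.
#' @param n_decoy_leaky Decoy genes as high in liver as in the gonad.
#' @param hormone_r Target population Pearson correlation between the
#'   androgen-like analytes and GSI (|r| < 1).
#' @param hormone_folds Pubertal-over-immature fold per androgen-like analyte.
#' @param hormone_immature_mean Immature-group mean concentration (nmol/L) of
#'   the androgen-like analytes.
#' @param cortisol_mean Mean concentration of the GSI-independent
#'   (cortisol-like) analytes.
#' @param cortisol_log_sd Log-scale SD of the cortisol-like analytes.
#' @param oocyte_rate Probability that an immature fish carries the "oocytes"
#'   observation flag.
#' @param tubule_rate Probability that an immature fish carries the
#'   "tubules, high cell division" flag.
#' @param body_weight_mean,body_weight_sd Cohort body-weight distribution (g).
#' @param cf_mean,cf_sd Cohort condition-factor distribution; fork length is
#'   derived from weight and CF.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_immature = 14,
                       n_pubertal = 6,
                       gsi_immature = c(0.01, 0.08),
                       gsi_pubertal = c(0.23, 0.60),
                       pi_immature = 0.3,
                       pi_pubertal = 0.8,
                       pi_sd = 0.05,
                       frac_germinative = 0.2,
                       frac_interstitial = 0.2,
                       frac_shared = 0.6,
                       regulated_fraction = 0.05,
                       regulation_log2 = 2,
                       noise_sd = 0.25,
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 1.5,
                       compartment_bias_sd = 0.25,
                       tissues = c("testis", "ovary", "liver", "muscle",
                                   "brain", "gill", "skin", "kidney",
                                   "spleen", "heart"),
                       n_compendium_background = 910,
                       n_gsg = 50,
                       gsg_margin = 2,
                       n_decoy_ubiquitous = 20,
                       n_decoy_leaky = 20,
                       hormone_r = 0.83,
                       hormone_folds = c(
                         androstenedione = 7.5,
                         `4-androsten-11B-OL3` = 10,
                         `4-androsten-17B-OL3` = 12.5,
                         `4-androsten-3-11-17-trione` = 15,
                         testosterone = 17.5
                       ),
                       hormone_immature_mean = 2,
                       cortisol_mean = 20,
                       cortisol_log_sd = 0.3,
                       oocyte_rate = 3 / 14,
                       tubule_rate = 2 / 14,
                       body_weight_mean = 1017,
                       body_weight_sd = 82,
                       cf_mean = 1.44,
                       cf_sd = 0.08) {
  cfg <- as.list(environment())
  fracs <- c(frac_germinative, frac_interstitial, frac_shared)
  if (any(fracs < 0) || any(fracs > 1) || abs(sum(fracs) - 1) > 1e-8) {
    abort("compartment gene fractions must lie in [0, 1] and sum to 1")
  }
  for (rng in list(gsi_immature, gsi_pubertal)) {
    if (length(rng) != 2 || any(rng < 0) || rng[1] >= rng[2]) {
      abort("GSI ranges must be increasing non-negative pairs")
    }
  }
  if (gsi_immature[2] > gsi_pubertal[1]) {
    abort("immature and pubertal GSI ranges must not overlap")
  }
  for (p in c(pi_immature, pi_pubertal)) {
    if (p <= 0 || p >= 1) abort("germinative proportions must lie in (0, 1)")
  }
  if (abs(hormone_r) >= 1) abort("requested |hormone_r| must be < 1")
  if (regulated_fraction < 0 || regulated_fraction > frac_shared) {
    abort("regulated_fraction must lie in [0, frac_shared]")
  }
  if (!all(c("testis", "ovary") %in% tissues) || length(tissues) < 3) {
    abort("tissues must include testis and ovary plus at least one other tissue")
  }
  structure(cfg, class = "sim_config")
}

# inverse-CDF truncated normal draw on (lo, hi); deterministic given the RNG
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 1) {
  eps <- .Machine$double.eps
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  u <- runif(n, pmin(plo + eps, 1), pmax(phi - eps, 0))
  mean + sd * qnorm(u)
}

#' Generate a synthetic cohort with histology records
#'
#' Draws `n_immature + n_pubertal` fish: GSI uniform within each group's
#' range, body weight and condition factor normal (fork length derived), and
#' histology labels assigned by maturity. Pubertal fish get an advanced
#' most-advanced cell type (SPC, SPT, or SZ) with a dominating type no more
#' advanced than it; immature fish stay at SPA. Oocyte observations are
#' planted only among immature fish, mirroring the intersex observations seen
#' exclusively at low GSI.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list with `cohort` (per-fish biometrics plus histology) and
#'   `metadata` (per-sample table: `sample_id`, `fish_id`, `tissue`, weights,
#'   `gsi`, `group`).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n_i <- config$n_immature
  n_p <- config$n_pubertal
  n <- n_i + n_p
  group <- c(rep("immature", n_i), rep("pubertal", n_p))
  gsi <- c(
    runif(n_i, config$gsi_immature[1], config$gsi_immature[2]),
    runif(n_p, config$gsi_pubertal[1], config$gsi_pubertal[2])
  )
  body_weight <- rtrunc_norm(n, config$body_weight_mean, config$body_weight_sd,
                             lo = 1, hi = Inf)
  cf <- rtrunc_norm(n, config$cf_mean, config$cf_sd, lo = 0.2, hi = Inf)
  fork_length <- (100 * body_weight / cf)^(1 / 3)
  gonad_weight <- gsi / 100 * body_weight

  most_advanced <- ifelse(group == "immature", "SPA",
                          sample(c("SPC", "SPT", "SZ"), n, replace = TRUE))
  dominant <- vapply(seq_len(n), function(i) {
    if (group[i] == "immature") return("SPA")
    cand <- c("SPB", "SPC")
    cand <- cand[stage_rank(cand) <= stage_rank(most_advanced[i])]
    sample(cand, 1)
  }, character(1))
  compartment_size <- dplyr::case_when(
    group == "pubertal" & most_advanced %in% c("SZ", "SPC") ~ "large",
    group == "pubertal" ~ "medium",
    TRUE ~ "small"
  )
  observations <- rep("", n)
  imm <- which(group == "immature")
  oo <- imm[runif(length(imm)) < config$oocyte_rate]
  tu <- setdiff(imm[runif(length(imm)) < config$tubule_rate], oo)
  observations[oo] <- "oocytes"
  observations[tu] <- "tubules, high cell division"
  compartment_size[tu] <- "medium"

  fish_id <- sprintf("fish_%02d", seq_len(n))
  cohort <- tibble(
    fish_id = fish_id,
    body_weight = body_weight,
    fork_length = fork_length,
    gonad_weight = gonad_weight,
    gsi = gsi,
    most_advanced_stage = most_advanced,
    dominant_stage = dominant,
    compartment_size = compartment_size,
    observations = observations,
    group = group
  )
  metadata <- tibble(
    sample_id = paste0("testis_", fish_id),
    fish_id = fish_id,
    tissue = "testis",
    body_weight = body_weight,
    fork_length = fork_length,
    gonad_weight = gonad_weight,
    gsi = gsi,
    group = group
  )
  list(cohort = cohort, metadata = metadata)
}

#' Generate a two-compartment synthetic testis expression matrix
#'
#' The generative model treats bulk testis expression as a mixture of two
#' compartments. For gene g in sample s:
#' \deqn{I_{gs} = [\pi_s G_g r_{g,grp(s)} + (1 - \pi_s) S_g] \cdot \epsilon}
#' where `pi_s` is the sample's germinative proportion (truncated normal
#' around the group mean), `G_g` and `S_g` are the gene's germinative and
#' interstitial baseline levels (log-normal; zero for exclusive genes),
#' `r` is the transcriptional regulation multiplier (`2^regulation_log2` for
#' regulated genes in pubertal samples, otherwise 1, acting on the germinative
#' term), and `epsilon` is multiplicative log-normal noise with log2-scale SD
#' `noise_sd`. With zero noise and no regulation the log2 expression ratio of
#' a germinative-exclusive gene equals `log2(pi_pubertal / pi_immature)`
#' exactly: the composition confound in closed form.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param cohort Optional output of [generate_cohort()] to reuse (so GSI
#'   values are shared with the hormone panel); when `NULL` a cohort is drawn
#'   from `seed` first.
#' @return A list with `expression` (linear-scale expression tibble),
#'   `metadata` (per-sample tibble), and `truth` (list of `genes`:
#'   per-gene compartment profile and regulation; `samples`: per-sample
#'   germinative proportion, GSI, group).
#' @export
generate_testis_matrix <- function(config = sim_config(), seed = 1,
                                   cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config, seed)
  set.seed(seed + 1)
  meta <- cohort$metadata
  n <- nrow(meta)
  ng <- config$n_genes

  n_germ <- round(config$frac_germinative * ng)
  n_int <- round(config$frac_interstitial * ng)
  n_shared <- ng - n_germ - n_int
  type <- c(rep("germinative", n_germ), rep("interstitial", n_int),
            rep("shared", n_shared))
  gene_id <- sprintf("gene_%05d", seq_len(ng))

  # exclusive genes: one compartment only; shared genes: a common base level
  # with a mild compartment bias, so both compartments express them at
  # comparable levels
  base <- 2^rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)
  bias <- rnorm(ng, 0, config$compartment_bias_sd)
  G <- dplyr::case_when(
    type == "interstitial" ~ 0,
    type == "germinative" ~ base,
    TRUE ~ base * 2^bias
  )
  S <- dplyr::case_when(
    type == "germinative" ~ 0,
    type == "interstitial" ~ base,
    TRUE ~ base * 2^(-bias)
  )

  n_reg <- round(config$regulated_fraction * ng)
  shared_idx <- which(type == "shared")
  if (n_reg > length(shared_idx)) {
    abort("not enough shared genes to host the regulated fraction")
  }
  regulated <- rep(FALSE, ng)
  regulated[sample(shared_idx, n_reg)] <- TRUE
  reg_mult <- ifelse(regulated, 2^config$regulation_log2, 1)

  pi_mean <- ifelse(meta$group == "immature", config$pi_immature,
                    config$pi_pubertal)
  pi_s <- if (config$pi_sd > 0) {
    rtrunc_norm(n, pi_mean, config$pi_sd, lo = 0, hi = 1)
  } else {
    pi_mean
  }

  pubertal <- as.numeric(meta$group == "pubertal")
  # r_eff(g, s) = 1 + (r_g - 1) * [sample s pubertal]
  expected <- outer(G, pi_s) * (1 + outer(reg_mult - 1, pubertal)) +
    outer(S, 1 - pi_s)
  noise <- if (config$noise_sd > 0) {
    matrix(2^rnorm(ng * n, 0, config$noise_sd), nrow = ng)
  } else {
    1
  }
  mat <- expected * noise
  colnames(mat) <- meta$sample_id
  rownames(mat) <- gene_id

  truth <- list(
    genes = tibble(
      gene_id = gene_id, type = type, germinative_level = G,
      interstitial_level = S, regulated = regulated,
      regulation_log2 = ifelse(regulated, config$regulation_log2, 0)
    ),
    samples = tibble(
      sample_id = meta$sample_id, fish_id = meta$fish_id,
      group = meta$group, gsi = meta$gsi, germinative_proportion = pi_s
    )
  )
  list(expression = as_expr_tibble(mat), metadata = meta, truth = truth)
}

#' Generate a multi-tissue compendium with planted gonad-specific genes
#'
#' Background genes get independent log-normal expression in every tissue.
#' Planted gonad-specific genes sit at a fixed low background `b` outside the
#' gonads and at `margin * x0` in their target tissue (testis or ovary,
#' alternating), where `x0` is the intensity that puts the
#' gonad-over-average score exactly at the `gsg_fold_threshold` boundary;
#' margin 1 therefore plants genes exactly on the boundary. Decoys violate the
#' rule in the two canonical ways: ubiquitously high genes (score near 1) and
#' "leaky" genes as high in liver as in the gonad (expressed elsewhere).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param gsg_fold_threshold The score boundary the planted genes are anchored
#'   to (default 8, matching [run_config()]).
#' @param gene_ids Optional gene identifiers to build the compendium over
#'   (e.g. the genes of a simulated testis matrix, as [simulate_study()]
#'   does); planted and decoy roles are then assigned to a random subset. When
#'   `NULL`, a standalone universe of
#'   `n_gsg + n_decoy_leaky + n_decoy_ubiquitous + n_compendium_background`
#'   genes is created.
#' @return A list with `compendium` (tibble: `gene_id` plus one column per
#'   tissue) and `truth` (tibble: `gene_id`, `planted_gsg`, `decoy`,
#'   `target_tissue`).
#' @export
generate_compendium <- function(config = sim_config(), seed = 1,
                                gsg_fold_threshold = 8, gene_ids = NULL) {
  set.seed(seed + 2)
  tissues <- config$tissues
  nt <- length(tissues)
  # a single elevated tissue caps the score at nt, so planting needs nt > threshold
  if (nt <= gsg_fold_threshold) {
    abort("need more tissues than the fold threshold to plant boundary genes")
  }
  b <- 8 # fixed low background of planted/decoy genes outside their targets
  x0 <- gsg_fold_threshold * (nt - 1) * b / (nt - gsg_fold_threshold)

  n_gsg <- config$n_gsg
  n_leaky <- config$n_decoy_leaky
  n_ubi <- config$n_decoy_ubiquitous
  n_special <- n_gsg + n_leaky + n_ubi
  if (is.null(gene_ids)) {
    n <- n_special + config$n_compendium_background
    gene_ids <- sprintf("cgene_%05d", seq_len(n))
  } else {
    if (anyDuplicated(gene_ids)) abort("gene_ids must be unique")
    n <- length(gene_ids)
    if (n < n_special) {
      abort("fewer gene_ids than planted and decoy genes to place")
    }
  }
  role <- rep("background", n)
  pick <- sample(n, n_special)
  role[pick[seq_len(n_gsg)]] <- "gsg"
  role[pick[n_gsg + seq_len(n_leaky)]] <- "leaky"
  role[pick[n_gsg + n_leaky + seq_len(n_ubi)]] <- "ubiquitous"

  mat <- matrix(2^rnorm(n * nt, config$baseline_log2_mean,
                        config$baseline_log2_sd), ncol = nt,
                dimnames = list(gene_ids, tissues))
  target_tissue <- rep(NA_character_, n)
  for (what in c("gsg", "leaky")) {
    rows <- which(role == what)
    targets <- rep(c("testis", "ovary"), length.out = length(rows))
    target_tissue[rows] <- targets
    mat[rows, ] <- b
    mat[cbind(rows, match(targets, tissues))] <- config$gsg_margin * x0
    if (what == "leaky") mat[rows, "liver"] <- config$gsg_margin * x0
  }
  ubi_rows <- which(role == "ubiquitous")
  mat[ubi_rows, ] <- 2^rnorm(length(ubi_rows) * nt,
                             config$baseline_log2_mean + 3, 0.2)

  truth <- tibble(
    gene_id = gene_ids,
    planted_gsg = role == "gsg",
    decoy = ifelse(role %in% c("leaky", "ubiquitous"), role, "none"),
    target_tissue = target_tissue
  )
  list(compendium = as_expr_tibble(mat), truth = truth)
}

# population mean and variance of the linear signal a + b * GSI over the
# configured GSI mixture (uniform within each group, weighted by group size)
signal_pop_moments <- function(a, b, config) {
  mom <- function(rng) {
    m <- mean(rng)
    v <- diff(rng)^2 / 12
    c(mean = m, second = v + m^2)
  }
  n <- config$n_immature + config$n_pubertal
  w <- c(config$n_immature, config$n_pubertal) / n
  mi <- mom(config$gsi_immature)
  mp <- mom(config$gsi_pubertal)
  g_mean <- w[1] * mi["mean"] + w[2] * mp["mean"]
  g_second <- w[1] * mi["second"] + w[2] * mp["second"]
  s_mean <- a + b * g_mean
  s_var <- b^2 * (g_second - g_mean^2)
  c(mean = unname(s_mean), var = unname(s_var))
}

#' Generate GSI-correlated serum hormone panels
#'
#' Androgen-like analytes are linear in GSI, anchored so the pubertal and
#' immature group means realize the configured fold exactly in the absence of
#' noise, plus signal-proportional (constant coefficient of variation)
#' Gaussian noise, censored at zero as at a detection limit (rare at the
#' default correlation). Proportional noise matches the roughly constant CV of
#' steroid measurements across their range, keeps concentrations positive, and
#' preserves group means so planted folds are recovered under noise. The CV is
#' solved per analyte from the variance decomposition
#' `r^2 = var(signal) / var(total)` using the population moments of the GSI
#' mixture, so the population Pearson correlation with GSI equals
#' `config$hormone_r`; nothing is tuned to a sample. Cortisol-like analytes
#' are generated independent of GSI (log-normal around `cortisol_mean`).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param cohort Optional output of [generate_cohort()] to reuse; when `NULL`
#'   a cohort is drawn from `seed`.
#' @return A list with `panel` (long tibble: `fish_id`, `analyte`,
#'   `concentration`), `cohort`, and `truth` (per-analyte tibble with the
#'   target correlation, planted fold, and solved noise CV).
#' @export
generate_hormones <- function(config = sim_config(), seed = 1, cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config, seed)
  set.seed(seed + 3)
  dat <- cohort$cohort
  gsi <- dat$gsi
  g_i <- mean(gsi[dat$group == "immature"])
  g_p <- mean(gsi[dat$group == "pubertal"])
  r <- config$hormone_r
  mu <- config$hormone_immature_mean

  folds <- config$hormone_folds
  if (is.null(names(folds))) names(folds) <- paste0("androgen_", seq_along(folds))
  androgens <- purrr::imap(folds, function(fold, analyte) {
    b <- mu * (fold - 1) / (g_p - g_i)
    a <- mu - b * g_i
    pm <- signal_pop_moments(a, b, config)
    # r^2 = var(s) / var(total) with var(total) = var(s)(1 + cv^2) + cv^2 E[s]^2
    cv <- if (r == 0) {
      1 # an r = 0 analyte would be pure noise; not used for the androgens
    } else {
      sqrt(pm["var"] * (1 / r^2 - 1) / (pm["var"] + pm["mean"]^2))
    }
    signal <- a + b * gsi
    conc <- if (config$noise_sd > 0) {
      pmax(signal * (1 + cv * rnorm(length(gsi))), 0)
    } else {
      pmax(signal, 0)
    }
    list(
      panel = tibble(fish_id = dat$fish_id, analyte = analyte,
                     concentration = conc),
      truth = tibble(analyte = analyte, true_r = r, planted_fold = fold,
                     noise_cv = if (config$noise_sd > 0) unname(cv) else 0,
                     gsi_dependent = TRUE)
    )
  })

  cortisol_names <- c("cortisol", "11-deoxycortisol", "21-deoxycortisol",
                      "corticosterone", "4-androsten-11B-17B-diol-3one")
  cortisols <- purrr::map(cortisol_names, function(analyte) {
    conc <- config$cortisol_mean *
      exp(rnorm(nrow(dat), -config$cortisol_log_sd^2 / 2, config$cortisol_log_sd))
    list(
      panel = tibble(fish_id = dat$fish_id, analyte = analyte,
                     concentration = conc),
      truth = tibble(analyte = analyte, true_r = 0, planted_fold = 1,
                     noise_cv = config$cortisol_log_sd, gsi_dependent = FALSE)
    )
  })

  all <- c(androgens, cortisols)
  list(
    panel = purrr::list_rbind(purrr::map(all, "panel")),
    cohort = cohort,
    truth = purrr::list_rbind(purrr::map(all, "truth"))
  )
}

#' Generate a complete synthetic study
#'
#' One seeded call producing every input the pipeline consumes, with a shared
#' cohort so GSI values agree across the expression matrix, the hormone panel,
#' and the biometrics table. The global seed fans out to the stage generators
#' by fixed offsets (cohort: seed, expression: seed + 1, compendium:
#' seed + 2, hormones: seed + 3).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; keep below `2^31 - 4`.
#' @return A list with `cohort`, `metadata`, `expression`, `compendium`
#'   (built over the same gene universe as the expression matrix, so
#'   gonad-specificity calls join onto the differential results), `panel`,
#'   `annotation` (a two-group functional annotation over the simulated genes:
#'   regulated genes and a random null group), and `truth` (per-generator
#'   ground-truth tables).
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  cohort <- generate_cohort(config, seed)
  expr <- generate_testis_matrix(config, seed, cohort = cohort)
  comp <- generate_compendium(config, seed,
                              gene_ids = expr$truth$genes$gene_id)
  horm <- generate_hormones(config, seed, cohort = cohort)

  set.seed(seed + 4)
  reg_genes <- expr$truth$genes$gene_id[expr$truth$genes$regulated]
  null_genes <- sample(
    expr$truth$genes$gene_id[!expr$truth$genes$regulated],
    min(50, sum(!expr$truth$genes$regulated))
  )
  annotation <- bind_rows(
    tibble(gene_id = reg_genes, functional_group = "planted regulated"),
    tibble(gene_id = null_genes, functional_group = "random background")
  )

  list(
    cohort = cohort$cohort,
    metadata = expr$metadata,
    expression = expr$expression,
    compendium = comp$compendium,
    panel = horm$panel,
    annotation = annotation,
    truth = list(
      genes = expr$truth$genes,
      samples = expr$truth$samples,
      compendium = comp$truth,
      hormones = horm$truth
    )
  )
}
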