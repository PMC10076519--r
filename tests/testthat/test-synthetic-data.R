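test_that("config validation rejects invalid and non-finite values", {
  expect_error(sim_config(seed = 1, noise_sd = 0), "noise_sd")
  expect_error(sim_config(seed = 1, n_tf_targets = 2000), "n_tf_targets")
  expect_error(sim_config(seed = 1, npm1_frac = 1.5), "npm1_frac")
  expect_error(sim_config(seed = 1, tf_effect = NaN), "non-finite")
  expect_error(sim_config(seed = 1, n_genes = 0), "positive integer")
  expect_error(sim_config(n_genes = 100), "seed")
})

test_that("cohort simulation is deterministic given the seed", {
  cfg <- small_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$responses, b$responses)
  expect_false(any(is.na(a$responses[cfg$drug_names])))
  expect_identical(colnames(a$expression), a$responses$sample_id)
})

test_that("no planted effect leaves target expression and AUC uncorrelated", {
  cfg <- sim_config(n_genes = 300, n_samples = 200, n_tf_targets = 30,
                    tf_effect = 0, auc_tf_slope = 0, seed = 11)
  co <- simulate_cohort(cfg)
  mt <- colMeans(co$expression[co$truth$tf_target_gene_ids, ])
  r <- cor(mt, co$responses[[cfg$drug_names[1]]])
  expect_lt(abs(r), 0.2)
})

test_that("AUC-vs-blasts correlation matches a Monte-Carlo oracle of the same model", {
  n <- 500
  # independent re-simulation of the response model (no package code)
  oracle_rho <- replicate(50, {
    act <- rnorm(n); bl <- runif(n, 5, 95); npm1 <- runif(n) < 0.41
    auc <- 80 + 8 * act - 0.25 * bl - 10 * npm1 + rnorm(n, sd = 6)
    cor(rank(auc), rank(bl))
  })
  pkg_rho <- vapply(1:50, function(s) {
    cfg <- sim_config(n_genes = 20, n_samples = n, n_tf_targets = 2, seed = s)
    co <- simulate_cohort(cfg)
    correlate_auc_covariate(co$responses, cfg$drug_names[1], "blasts_bm")$rho
  }, numeric(1))
  expect_true(all(pkg_rho < 0))
  expect_lt(abs(mean(pkg_rho) - mean(oracle_rho)), 0.05)
})

test_that("perturbation tables plant targets with the right signs and overlap", {
  cfg <- small_config(seed = 3)
  co <- simulate_cohort(cfg)
  targets <- co$truth$tf_target_gene_ids

  full <- simulate_perturbation_signatures(cfg, co$truth, overlap = 1)
  common <- Reduce(intersect, list(
    deg_direction_sets(full$oe, cfg$score_threshold)$up,
    deg_direction_sets(full$kd, cfg$score_threshold)$down,
    deg_direction_sets(full$p30, cfg$score_threshold)$down))
  expect_setequal(common, targets)

  none <- simulate_perturbation_signatures(cfg, co$truth, overlap = 0)
  common0 <- Reduce(intersect, list(
    deg_direction_sets(none$oe, cfg$score_threshold)$up,
    deg_direction_sets(none$kd, cfg$score_threshold)$down,
    deg_direction_sets(none$p30, cfg$score_threshold)$down))
  expect_length(common0, 0)
})

test_that("half-overlap intersection size matches a set-simulation oracle", {
  n_targets <- 100
  oracle <- replicate(100, {
    sum(runif(n_targets) < 0.5 & runif(n_targets) < 0.5 &
          runif(n_targets) < 0.5)
  })
  sizes <- vapply(1:100, function(s) {
    cfg <- sim_config(n_genes = 2000, n_samples = 10, n_tf_targets = n_targets,
                      seed = s)
    co <- simulate_cohort(cfg)
    tabs <- simulate_perturbation_signatures(cfg, co$truth, overlap = 0.5)
    length(Reduce(intersect, list(
      deg_direction_sets(tabs$oe, cfg$score_threshold)$up,
      deg_direction_sets(tabs$kd, cfg$score_threshold)$down,
      deg_direction_sets(tabs$p30, cfg$score_threshold)$down)))
  }, numeric(1))
  # both means estimate n_targets * overlap^3 = 12.5
  expect_lt(abs(mean(sizes) - mean(oracle)), 1.5)
})

test_that("compendium plants a perfect reverser and unbiased noise signatures", {
  cfg <- small_config(seed = 5, reverser_strength = 1)
  co <- simulate_cohort(cfg)
  comp <- simulate_reference_compendium(cfg, co$truth)
  rev_key <- paste(co$truth$reverser_perturbagen_id,
                   cfg$cell_line_names[1], sep = "|")
  sig <- comp$signatures[[rev_key]]
  n <- nrow(sig)
  k <- length(co$truth$tf_target_gene_ids)
  bottom <- sig$gene[(n - k + 1):n]
  expect_setequal(bottom, co$truth$tf_target_gene_ids)

  # a noise perturbagen: mean target rank within 2 SD of (N+1)/2 under
  # sampling-without-replacement
  noise_key <- paste("PERT0002", cfg$cell_line_names[1], sep = "|")
  nsig <- comp$signatures[[noise_key]]
  ranks <- match(co$truth$tf_target_gene_ids, nsig$gene)
  sd_mean <- sqrt((n + 1) * (n - k) / (12 * k))
  expect_lt(abs(mean(ranks) - (n + 1) / 2), 2 * sd_mean)

  # same perturbagen, two cell lines: independent signatures, linked metadata
  other <- comp$signatures[[paste("PERT0002", cfg$cell_line_names[2], sep = "|")]]
  expect_false(identical(nsig$gene, other$gene))
  expect_equal(sum(comp$meta$perturbagen_id == "PERT0002"), 2)

  small <- small_config(seed = 5)
  small$compendium_size <- 5
  expect_error(simulate_reference_compendium(small, co$truth),
               "compendium_size")
})

test_that("null cohorts yield a calibrated downstream DEG count", {
  counts <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 500, n_samples = 60, n_tf_targets = 10,
                      tf_effect = 0, auc_tf_slope = 0, npm1_auc_shift = 0,
                      seed = 100 + s)
    co <- simulate_cohort(cfg)
    sp <- tertile_split(co$responses, cfg$drug_names[1])
    deg <- differential_expression(co$expression, sp$resistant_ids,
                                   sp$sensitive_ids)
    sum(deg$pass)
  }, numeric(1))
  expect_lte(mean(counts), 0.05 * 500)
})

test_that("stronger TF effects raise the mean target signal-to-noise score", {
  mean_s2n <- function(effect) {
    mean(vapply(1:10, function(s) {
      cfg <- sim_config(n_genes = 300, n_samples = 60, n_tf_targets = 30,
                        tf_effect = effect, seed = 200 + s)
      co <- simulate_cohort(cfg)
      sp <- tertile_split(co$responses, cfg$drug_names[1])
      s2n <- signal_to_noise(co$expression, sp$resistant_ids, sp$sensitive_ids)
      mean(s2n[co$truth$tf_target_gene_ids])
    }, numeric(1)))
  }
  grid <- vapply(c(0.5, 1, 2), mean_s2n, numeric(1))
  expect_true(all(diff(grid) > 0))
})
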