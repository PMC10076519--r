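make_responses <- function(auc, ids = sprintf("P%02d", seq_along(auc))) {
  data.frame(sample_id = ids, drugA = auc, stringsAsFactors = FALSE)
}

test_that("tertile split follows the pinned remainder and tie rules", {
  r9 <- make_responses(seq(10, 90, 10))
  sp <- tertile_split(r9, "drugA")
  expect_identical(sp$sensitive_ids, r9$sample_id[1:3])
  expect_identical(sp$resistant_ids, r9$sample_id[7:9])

  # n = 10: |S| = ceiling(10/3) = 4, |R| = floor(10/3) = 3; oracle = direct sort
  set.seed(1)
  auc10 <- sample(100, 10)
  r10 <- make_responses(auc10)
  sp10 <- tertile_split(r10, "drugA")
  ord <- r10$sample_id[order(auc10)]
  expect_identical(sp10$sensitive_ids, ord[1:4])
  expect_identical(sp10$resistant_ids, ord[8:10])
  expect_setequal(c(sp10$sensitive_ids, sp10$middle_ids, sp10$resistant_ids),
                  r10$sample_id)

  # all-equal AUC: stable sample-id order, partition sizes unchanged
  req <- make_responses(rep(5, 9))
  speq <- tertile_split(req, "drugA")
  expect_identical(speq$sensitive_ids, sort(req$sample_id)[1:3])
  expect_identical(speq$resistant_ids, sort(req$sample_id)[7:9])

  expect_error(tertile_split(make_responses(1:5), "drugA"), ">= 6")
  expect_error(tertile_split(r9, "drugB"), "drugB")
})

test_that("tertile split is invariant to monotone AUC transforms and shifts", {
  set.seed(2)
  r <- make_responses(runif(20, 10, 90))
  base <- tertile_split(r, "drugA")
  for (f in list(function(x) x + 100, exp, function(x) x^3)) {
    r2 <- r; r2$drugA <- f(r$drugA)
    expect_identical(tertile_split(r2, "drugA"), base)
  }
})

test_that("non-resistant subdivision partitions MS and LS disjointly", {
  r9 <- make_responses(seq(10, 90, 10))
  # non-resistant set = bottom 6; MS = bottom 2, LS = top 2 of those
  sub9 <- subdivide_nonresistant(r9, "drugA")
  expect_identical(sub9$ms_ids, r9$sample_id[1:2])
  expect_identical(sub9$ls_ids, r9$sample_id[5:6])
  expect_length(intersect(sub9$ms_ids, sub9$ls_ids), 0)

  # 12-sample cohort: non-resistant = 8, MS = ceiling(8/3) = 3, LS = floor = 2
  set.seed(3)
  auc12 <- sample(1000, 12)
  r12 <- make_responses(auc12)
  sub12 <- subdivide_nonresistant(r12, "drugA")
  ord <- r12$sample_id[order(auc12)]
  expect_identical(sub12$ms_ids, ord[1:3])
  expect_identical(sub12$ls_ids, ord[7:8])
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  n <- 20
  set.seed(4)
  r <- make_responses(runif(n, 20, 80))
  r$blasts_bm <- runif(n, 5, 95)

  res <- correlate_auc_covariate(r, "drugA", "blasts_bm")
  # independent oracle: midranks from sorted positions, then Pearson formula
  midrank <- function(x) {
    sapply(x, function(v) mean(which(sort(x) == v)))
  }
  rx <- midrank(r$drugA); ry <- midrank(r$blasts_bm)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, rho_oracle, tolerance = 1e-12)

  # perfectly monotone pairs
  mono <- make_responses(1:10); mono$blasts_bm <- (1:10)^2
  expect_equal(correlate_auc_covariate(mono, "drugA", "blasts_bm")$rho, 1)
  mono$blasts_bm <- rev(mono$blasts_bm)
  expect_equal(correlate_auc_covariate(mono, "drugA", "blasts_bm")$rho, -1)

  flat <- make_responses(rep(1, 10)); flat$blasts_bm <- 1:10
  expect_error(correlate_auc_covariate(flat, "drugA", "blasts_bm"),
               "zero variance")
})

test_that("Wilcoxon comparison agrees with exhaustive permutation enumeration", {
  r <- make_responses(c(1, 2, 3, 4, 5, 6))
  r$MUT <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- compare_mutation_groups(r, "drugA", "MUT")
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$p, perm_wilcox_p(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)

  # label swap symmetry
  r$MUT <- !r$MUT
  expect_equal(compare_mutation_groups(r, "drugA", "MUT")$p, res$p)

  # identical groups: p = 1 within tolerance
  rid <- make_responses(rep(c(10, 20, 30), 2))
  rid$MUT <- rep(c(TRUE, FALSE), each = 3)
  expect_gt(compare_mutation_groups(rid, "drugA", "MUT")$p, 0.99)

  rempty <- make_responses(1:6); rempty$MUT <- rep(FALSE, 6)
  expect_error(compare_mutation_groups(rempty, "drugA", "MUT"), "empty")
})

test_that("constant AUC shifts change no assignment or statistic", {
  set.seed(5)
  r <- make_responses(runif(15, 10, 90))
  r$blasts_bm <- runif(15, 5, 95)
  r$MUT <- rep(c(TRUE, FALSE, FALSE), 5)
  r2 <- r; r2$drugA <- r$drugA + 1000
  expect_identical(tertile_split(r2, "drugA")$sensitive_ids,
                   tertile_split(r, "drugA")$sensitive_ids)
  expect_equal(correlate_auc_covariate(r2, "drugA", "blasts_bm")$rho,
               correlate_auc_covariate(r, "drugA", "blasts_bm")$rho)
  expect_equal(compare_mutation_groups(r2, "drugA", "MUT")$p,
               compare_mutation_groups(r, "drugA", "MUT")$p)
})

test_that("dose-viability AUC is the normalized log-dose trapezoid", {
  expect_equal(auc_from_viability(c(1, 10, 100), rep(100, 3)), 100)
  expect_equal(auc_from_viability(c(1, 10, 100), rep(0, 3)), 0)
  expect_equal(auc_from_viability(c(1, 10, 100), c(100, 50, 0)), 50)
  expect_error(auc_from_viability(c(0, 1, 10), c(1, 2, 3)), "positive")
  expect_error(auc_from_viability(c(1, 10), c(1, 2)), ">= 3")
  expect_error(auc_from_viability(c(1, 10, 5), c(1, 2, 3)), "increasing")
})
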