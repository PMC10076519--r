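test_that("WTCS follows the sign-gated average of the tail enrichments", {
  expect_equal(wtcs(0.8, -0.2), 0.5)
  expect_equal(wtcs(0.5, 0.3), 0)
  expect_equal(wtcs(-0.6, 0.4), -0.5)
  expect_equal(wtcs(-0.5, -0.1), 0)
  expect_equal(wtcs(0.7), 0.7)       # one-tailed mode
  expect_equal(wtcs(0.7, NA), 0.7)
})

test_that("two-tailed enrichment matches the core ES and swaps with the tails", {
  set.seed(20)
  ref <- random_signature(10)
  q <- list(q_up = ref$gene[1:2], q_down = ref$gene[9:10])
  res <- two_sided_es(q, ref)
  expect_gt(res$es_up, 0)
  expect_equal(res$es_up, enrichment_score(ref, q$q_up)$es, tolerance = 1e-12)
  expect_equal(res$es_down, enrichment_score(ref, q$q_down)$es,
               tolerance = 1e-12)
  swapped <- two_sided_es(list(q_up = q$q_down, q_down = q$q_up), ref)
  expect_equal(swapped$es_up, res$es_down)
  expect_equal(swapped$es_down, res$es_up)
  expect_error(two_sided_es(list(q_up = c("nope"), q_down = character(0)), ref),
               "outside")
})

test_that("exhaustive 2-gene placements obey the WTCS bound and sign gate", {
  set.seed(21)
  ref <- random_signature(10)
  pairs <- utils::combn(10, 2, simplify = FALSE)
  n_checked <- 0
  for (up in pairs) {
    for (down in pairs) {
      if (length(intersect(up, down)) > 0) next
      es <- two_sided_es(list(q_up = ref$gene[up], q_down = ref$gene[down]),
                         ref)
      w <- wtcs(es$es_up, es$es_down)
      expect_lte(abs(w), 1)
      if (sign(es$es_up) == sign(es$es_down) && es$es_up != 0 &&
            es$es_down != 0) {
        expect_identical(w, 0)
      } else if (sign(es$es_up) != sign(es$es_down)) {
        expect_equal(w, (es$es_up - es$es_down) / 2)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, choose(10, 2) * choose(8, 2))
})

test_that("NCS normalization matches the signed within-stratum means", {
  df <- data.frame(query = "q", perturbagen_id = c("p1", "p2", "p3"),
                   cell_line = "cl", class = "k",
                   wtcs = c(0.4, 0.2, -0.3), stringsAsFactors = FALSE)
  out <- normalize_ncs(df)
  expect_equal(out$ncs, c(4 / 3, 2 / 3, -1), tolerance = 1e-12)

  # single positive score in its stratum self-normalizes to 1
  one <- df[1, ]
  expect_equal(normalize_ncs(one)$ncs, 1)
  # equal positive scores all map to 1
  eqp <- df; eqp$wtcs <- 0.25
  expect_equal(normalize_ncs(eqp)$ncs, rep(1, 3))
  expect_error(normalize_ncs(df[0, ]), "empty")
})

test_that("tau is the signed percentile of |NCS| with the pinned conventions", {
  ref <- c(seq(0.05, 0.95, length.out = 19), 2)
  expect_equal(tau_score(-1, ref), -95)   # exceeds 19 of 20, negative sign
  expect_equal(tau_score(1, ref), 95)
  expect_equal(tau_score(3, ref), 100)    # exceeds all references
  expect_equal(tau_score(-3, ref), -100)
  expect_equal(tau_score(0.01, ref), 0)   # below every reference
  expect_error(tau_score(1, ref[1:5]), ">= 10")

  # monotone non-decreasing in |ncs| within a stratum
  set.seed(22)
  ref2 <- rnorm(50)
  qs <- sort(abs(rnorm(30)))
  taus <- tau_score(qs, ref2)
  expect_true(all(diff(taus) >= 0))
  expect_true(all(abs(taus) <= 100))
})

test_that("summary scores are medians with the midpoint convention", {
  tt <- data.frame(perturbagen_id = c(rep("p1", 5), rep("p2", 2)),
                   tau = c(-95, -92, -91, -90, -89, -96, -90),
                   stringsAsFactors = FALSE)
  s <- summarize_drug(tt)
  expect_equal(s$summary_tau[s$perturbagen_id == "p1"], -91)
  expect_equal(s$summary_tau[s$perturbagen_id == "p2"], -93)
  perm <- tt[sample(nrow(tt)), ]
  expect_equal(summarize_drug(perm), s)
})

test_that("hit classification thresholds and top-fraction composition", {
  s <- data.frame(perturbagen_id = sprintf("p%d", 1:5),
                  summary_tau = c(-95, -91, -89, 0, 92),
                  n_queries = 5,
                  class = c("a", "b", "a", "c", "d"),
                  stringsAsFactors = FALSE)
  s <- s[order(s$summary_tau), ]
  h <- classify_hits(s, threshold = -90, top_frac = 0.4)
  expect_setequal(h$reversers$perturbagen_id, c("p1", "p2"))
  expect_setequal(h$mimics$perturbagen_id, "p5")
  expect_equal(sum(h$top_composition$count), 2)
  empty <- classify_hits(s, top_frac = 0.001)
  expect_equal(nrow(empty$top_composition), 0)
})

test_that("negating the reference ranking flips the connectivity sign", {
  set.seed(23)
  ref <- random_signature(60)
  q <- list(q_up = sample(ref$gene, 8), q_down = character(0))
  w1 <- wtcs(two_sided_es(q, ref)$es_up, NA)
  neg <- rank_genes(stats::setNames(-ref$score, ref$gene))
  w2 <- wtcs(two_sided_es(q, neg)$es_up, NA)
  expect_equal(w2, -w1, tolerance = 1e-12)
})

test_that("the planted reverser is recovered end to end from the compendium", {
  cfg <- sim_config(n_genes = 500, n_samples = 60, n_tf_targets = 50,
                    compendium_size = 30, reverser_strength = 0.9, seed = 77)
  co <- simulate_cohort(cfg)
  comp <- simulate_reference_compendium(cfg, co$truth)
  pert <- simulate_perturbation_signatures(cfg, co$truth)
  queries <- build_signed_queries(
    deg_direction_sets(pert$oe, cfg$score_threshold)$up,
    deg_direction_sets(pert$kd, cfg$score_threshold)$down,
    deg_direction_sets(pert$p30, cfg$score_threshold)$down)
  scored <- score_connectivity(queries, comp)
  expect_true(all(abs(scored$scores$tau) <= 100, na.rm = TRUE))
  expect_equal(scored$summary$perturbagen_id[1],
               co$truth$reverser_perturbagen_id)
  expect_lte(scored$summary$summary_tau[1], -90)
})
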