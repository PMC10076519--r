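#' Simulation configuration for synthetic cohorts and compendia
#'
#' Bundles every tunable of the synthetic-data generator: cohort dimensions,
#' the strength of the latent transcription-factor (TF) activity program, the
#' linear model linking drug-response AUC to TF activity / blast percentage /
#' NPM1 status, and the reference-compendium layout with its planted reverser.
#'
#' Expression is simulated directly on the log2 scale:
#' \code{expr[g, s] = baseline_g + tf_effect * activity_s * [g in targets] + N(0, noise_sd)}
#' with \code{activity_s ~ N(0, 1)}. Per-drug AUC follows
#' \code{AUC[d, s] = intercept_d + auc_tf_slope * activity_s +
#' auc_blast_slope * blasts_s + npm1_auc_shift * [NPM1_s] + N(0, auc_noise_sd)}
#' so that higher TF activity confers resistance (higher AUC) while higher
#' blast counts and NPM1 mutation confer sensitivity.
#'
#' @param n_genes number of genes in the universe.
#' @param n_samples number of cohort samples.
#' @param n_tf_targets number of planted TF target genes (< \code{n_genes}).
#' @param tf_effect log2-expression shift in target genes per unit TF activity.
#' @param auc_tf_slope AUC units per unit TF activity (positive = resistance).
#' @param auc_blast_slope AUC units per blast percentage point (negative =
#'   high-blast samples are more sensitive).
#' @param noise_sd per-gene log2-expression noise SD (> 0).
#' @param n_drugs number of screened drugs (AUC columns).
#' @param npm1_frac fraction of samples carrying the NPM1 mutation flag.
#' @param npm1_auc_shift AUC shift for NPM1-mutant samples (negative =
#'   sensitizing).
#' @param compendium_size number of perturbagens in the reference compendium
#'   (>= 10, so that tau percentiles are meaningful).
#' @param n_cell_lines number of cell lines each perturbagen is profiled in.
#' @param reverser_strength blend weight in [0, 1] of the anti-correlated
#'   signal in the planted reverser's signature (1 = perfect reversal).
#' @param seed integer seed; all generator sub-streams are derived from it by
#'   fixed offsets so stages can be rerun independently.
#' @param auc_intercept baseline AUC level per drug.
#' @param auc_noise_sd per-drug AUC residual SD.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression.
#' @param target_score absolute planted score of responsive TF targets in the
#'   perturbation-experiment DEG tables.
#' @param pert_noise_sd score noise added to planted targets in those tables.
#' @param score_threshold |score| cutoff used to call up/down genes from a
#'   perturbation DEG table.
#' @param drug_names character vector of drug identifiers (length
#'   \code{n_drugs}).
#' @param cell_line_names character vector of cell-line identifiers.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples = 120,
                       n_tf_targets = 100,
                       tf_effect = 1.0,
                       auc_tf_slope = 8,
                       auc_blast_slope = -0.25,
                       noise_sd = 1.0,
                       n_drugs = 4,
                       npm1_frac = 0.41,
                       npm1_auc_shift = -10,
                       compendium_size = 100,
                       n_cell_lines = 2,
                       reverser_strength = 0.9,
                       seed,
                       auc_intercept = 80,
                       auc_noise_sd = 6,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       target_score = 4,
                       pert_noise_sd = 0.3,
                       score_threshold = 2.5,
                       drug_names = NULL,
                       cell_line_names = NULL) {
  if (missing(seed)) stop("sim_config: 'seed' is required (no silent default)")
  cfg <- list(
    n_genes = n_genes, n_samples = n_samples, n_tf_targets = n_tf_targets,
    tf_effect = tf_effect, auc_tf_slope = auc_tf_slope,
    auc_blast_slope = auc_blast_slope, noise_sd = noise_sd,
    n_drugs = n_drugs, npm1_frac = npm1_frac,
    npm1_auc_shift = npm1_auc_shift, compendium_size = compendium_size,
    n_cell_lines = n_cell_lines, reverser_strength = reverser_strength,
    seed = seed, auc_intercept = auc_intercept, auc_noise_sd = auc_noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    target_score = target_score, pert_noise_sd = pert_noise_sd,
    score_threshold = score_threshold
  )
  num <- unlist(cfg)
  if (!all(is.finite(num))) {
    bad <- names(num)[!is.finite(num)]
    stop("sim_config: non-finite values for: ", paste(bad, collapse = ", "))
  }
  counts <- c("n_genes", "n_samples", "n_tf_targets", "n_drugs",
              "compendium_size", "n_cell_lines")
  for (nm in counts) {
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]])) {
      stop("sim_config: '", nm, "' must be a positive integer count")
    }
  }
  if (cfg$n_tf_targets >= cfg$n_genes) {
    stop("sim_config: n_tf_targets must be smaller than n_genes")
  }
  if (cfg$npm1_frac < 0 || cfg$npm1_frac > 1) {
    stop("sim_config: npm1_frac must lie in [0, 1]")
  }
  if (cfg$reverser_strength < 0 || cfg$reverser_strength > 1) {
    stop("sim_config: reverser_strength must lie in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("sim_config: noise_sd must be > 0")
  if (abs(cfg$seed) >= 2^30) stop("sim_config: |seed| must be < 2^30")

  if (is.null(drug_names)) {
    base <- c("gilteritinib", "quizartinib", "midostaurin", "crenolanib")
    drug_names <- if (n_drugs <= length(base)) base[seq_len(n_drugs)] else
      c(base, sprintf("drug%02d", seq_len(n_drugs - length(base))))
  }
  if (length(drug_names) != n_drugs) {
    stop("sim_config: drug_names must have length n_drugs")
  }
  if (is.null(cell_line_names)) {
    cell_line_names <- sprintf("CL%02d", seq_len(n_cell_lines))
  }
  if (length(cell_line_names) != n_cell_lines) {
    stop("sim_config: cell_line_names must have length n_cell_lines")
  }
  cfg$drug_names <- drug_names
  cfg$cell_line_names <- cell_line_names
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  genes: %d (TF targets: %d), samples: %d, drugs: %d\n",
              x$n_genes, x$n_tf_targets, x$n_samples, x$n_drugs))
  cat(sprintf("  tf_effect: %g, auc_tf_slope: %g, auc_blast_slope: %g\n",
              x$tf_effect, x$auc_tf_slope, x$auc_blast_slope))
  cat(sprintf("  compendium: %d perturbagens x %d cell lines, reverser strength %g\n",
              x$compendium_size, x$n_cell_lines, x$reverser_strength))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Sub-stream seeds: fixed offsets from the global seed so that each generator
# stage can be rerun on its own and still reproduce the full-pipeline output.
.sub_seed <- function(cfg, stage) {
  offsets <- c(cohort = 0L, perturbation = 1000L, compendium = 2000L,
               tf_sets = 3000L, gsea = 4000L, queries = 5000L)
  if (!stage %in% names(offsets)) stop("unknown seed sub-stream: ", stage)
  as.integer(cfg$seed) + offsets[[stage]]
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
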