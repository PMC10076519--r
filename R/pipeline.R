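#' Pipeline configuration
#'
#' Couples a \code{\link{sim_config}} with the analysis thresholds used
#' downstream. The seed lives in the simulation config and is mandatory.
#'
#' @param sim a \code{\link{sim_config}}.
#' @param lfc_threshold,fdr_threshold DEG filter (two-fold change, FDR 0.05
#'   by default).
#' @param n_perm GSEA permutations.
#' @param q_gate TF-screen significance gate on \code{q_bh}.
#' @param tau_threshold reverser cutoff on the summary tau.
#' @param top_frac fraction of lowest-scoring perturbagens profiled by class.
#' @param n_tf_sets number of TF target sets screened (planted + decoys).
#' @param weight_p GSEA weighting exponent.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim,
                            lfc_threshold = 1,
                            fdr_threshold = 0.05,
                            n_perm = 499,
                            q_gate = 0.25,
                            tau_threshold = -90,
                            top_frac = 0.02,
                            n_tf_sets = 20,
                            weight_p = 1) {
  stopifnot(inherits(sim, "sim_config"))
  if (fdr_threshold <= 0 || fdr_threshold > 1) stop("invalid fdr_threshold")
  if (q_gate <= 0 || q_gate > 1) stop("invalid q_gate")
  if (top_frac < 0 || top_frac > 1) stop("invalid top_frac")
  if (abs(tau_threshold) > 100) stop("invalid tau_threshold")
  structure(list(sim = sim, lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold, n_perm = n_perm,
                 q_gate = q_gate, tau_threshold = tau_threshold,
                 top_frac = top_frac, n_tf_sets = n_tf_sets,
                 weight_p = weight_p),
            class = "pipeline_config")
}

#' Run the full discovery-and-repurposing pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation; per-drug AUC tertile
#' stratification with cohort-level statistics (Spearman AUC-vs-blasts,
#' Wilcoxon by NPM1 status); per-drug signal-to-noise resistance signatures
#' and the cross-drug average-rank signature; per-drug DEG tables; the TF
#' target screen; perturbation-experiment signatures and the signed queries;
#' and connectivity scoring against the reference compendium with hit
#' classification. In synthetic mode the report states whether the planted
#' TF and the planted reverser were recovered.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir optional directory; when given, every intermediate artifact
#'   is written there (TSV/CSV/GMT/JSON) and its md5 digest recorded.
#' @return list of class \code{"run_report"}; key fields:
#'   \code{recovered_tf}, \code{tf_recovered} (logical),
#'   \code{reverser_rank}, \code{reverser_summary_tau},
#'   \code{reverser_recovered}, \code{cohort_stats}, \code{deg_counts},
#'   \code{hits}, \code{digests}, \code{timings}, \code{config}.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  timings <- list()
  artifacts <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  cohort <- stage("simulate", simulate_cohort(cfg))

  strat <- stage("stratify", {
    lapply(stats::setNames(cfg$drug_names, cfg$drug_names), function(d) {
      list(split = tertile_split(cohort$responses, d),
           spearman_bm = correlate_auc_covariate(cohort$responses, d, "blasts_bm"),
           wilcox_npm1 = if (length(unique(cohort$responses$NPM1)) == 2) {
             compare_mutation_groups(cohort$responses, d, "NPM1")
           } else {
             NULL
           })
    })
  })

  sigs <- stage("signature", {
    per_drug <- lapply(strat, function(s) {
      rank_genes(signal_to_noise(cohort$expression,
                                 s$split$resistant_ids,
                                 s$split$sensitive_ids),
                 label = s$split$drug)
    })
    avg <- average_rank_combine(per_drug)
    degs <- lapply(strat, function(s) {
      differential_expression(cohort$expression,
                              s$split$resistant_ids, s$split$sensitive_ids,
                              lfc_threshold = config$lfc_threshold,
                              fdr_threshold = config$fdr_threshold)
    })
    list(per_drug = per_drug, average = avg, degs = degs)
  })

  enrich <- stage("enrich", {
    tf_sets <- simulate_tf_sets(cfg, cohort$truth, n_sets = config$n_tf_sets)
    screen <- tf_screen(sigs$per_drug, tf_sets,
                        n_perm = config$n_perm,
                        seed = .sub_seed(cfg, "gsea"),
                        weight_p = config$weight_p,
                        q_gate = config$q_gate)
    list(tf_sets = tf_sets, screen = screen)
  })

  connect <- stage("connect", {
    pert <- simulate_perturbation_signatures(cfg, cohort$truth)
    thr <- cfg$score_threshold
    oe <- deg_direction_sets(pert$oe, thr)
    kd <- deg_direction_sets(pert$kd, thr)
    p30 <- deg_direction_sets(pert$p30, thr)
    drug_up <- lapply(sigs$degs, function(d) d$gene[d$pass & d$log2fc > 0])
    queries <- build_signed_queries(oe$up, kd$down, p30$down, drug_up)
    compendium <- simulate_reference_compendium(cfg, cohort$truth)
    scored <- score_connectivity(queries, compendium,
                                 weight_p = config$weight_p)
    hits <- classify_hits(scored$summary, threshold = config$tau_threshold,
                          top_frac = config$top_frac)
    list(queries = queries, compendium = compendium, scored = scored,
         hits = hits)
  })

  truth <- cohort$truth
  summary <- connect$scored$summary
  rev_row <- which(summary$perturbagen_id == truth$reverser_perturbagen_id)
  report <- list(
    recovered_tf = enrich$screen$common_top,
    tf_recovered = identical(enrich$screen$common_top, "TF_PLANTED"),
    tf_table = enrich$screen$table,
    reverser_rank = rev_row,
    reverser_summary_tau = summary$summary_tau[rev_row],
    reverser_recovered = length(rev_row) == 1 && rev_row == 1 &&
      summary$summary_tau[rev_row] <= config$tau_threshold,
    cohort_stats = lapply(strat, function(s) {
      list(spearman_rho = s$spearman_bm$rho, spearman_p = s$spearman_bm$p,
           wilcox_npm1_p = if (is.null(s$wilcox_npm1)) NA_real_ else
             s$wilcox_npm1$p)
    }),
    deg_counts = vapply(sigs$degs, function(d) sum(d$pass), integer(1)),
    summary = summary,
    hits = connect$hits,
    queries = lapply(connect$queries, function(q) q$q_up),
    truth = truth,
    config = config
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_expression_matrix(cohort$expression,
                            file.path(outdir, "expression.tsv"))
    utils::write.csv(cohort$responses, file.path(outdir, "responses.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth[c("tf_target_gene_ids",
                                 "reverser_perturbagen_id")],
                         file.path(outdir, "truth.json"), auto_unbox = TRUE)
    write_ranked_signature(sigs$average,
                           file.path(outdir, "average_rank_signature.tsv"))
    for (d in names(sigs$degs)) {
      utils::write.csv(sigs$degs[[d]],
                       file.path(outdir, paste0("deg_", d, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(enrich$screen$table, file.path(outdir, "tf_screen.csv"),
                     row.names = FALSE)
    write_gmt(report$queries, file.path(outdir, "queries.gmt"))
    write_compendium(connect$compendium, file.path(outdir, "compendium"))
    utils::write.csv(connect$scored$scores,
                     file.path(outdir, "connectivity_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(outdir, "summary_scores.csv"),
                     row.names = FALSE)
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    report$digests <- stats::setNames(as.character(tools::md5sum(files)),
                                      basename(files))
  }
  report$timings <- timings
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  common-top TF: %s (planted TF recovered: %s)\n",
              x$recovered_tf, x$tf_recovered))
  cat(sprintf("  planted reverser: rank %d of %d, summary tau %.1f (recovered: %s)\n",
              x$reverser_rank, nrow(x$summary), x$reverser_summary_tau,
              x$reverser_recovered))
  cat(sprintf("  DEG counts: %s\n",
              paste(sprintf("%s=%d", names(x$deg_counts), x$deg_counts),
                    collapse = ", ")))
  invisible(x)
}
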