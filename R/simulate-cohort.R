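#' Simulate a drug-sensitivity-annotated expression cohort
#'
#' Generates a genes x samples log2 expression matrix, a per-sample drug
#' response table, and the planted ground truth. A latent per-sample TF
#' activity (standard normal) raises the expression of the planted target
#' genes and, through \code{auc_tf_slope}, the AUC of every drug, so samples
#' with an active TF program are more resistant. Blast percentage
#' (Uniform(5, 95)) and the NPM1 mutation flag push AUC the other way.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return A list of class \code{"synthetic_cohort"} with elements
#'   \describe{
#'     \item{expression}{numeric matrix, genes x samples, log2 scale.}
#'     \item{responses}{data.frame: \code{sample_id}, \code{blasts_bm},
#'       \code{blasts_pb}, logical \code{NPM1}, and one AUC column per drug
#'       named by the drug.}
#'     \item{truth}{list: \code{tf_target_gene_ids},
#'       \code{per_sample_tf_activity}, \code{reverser_perturbagen_id},
#'       \code{planted_de_gene_ids}.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  .with_seed(.sub_seed(cfg, "cohort"), {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    samples <- sprintf("S%04d", seq_len(cfg$n_samples))
    targets <- genes[seq_len(cfg$n_tf_targets)]

    activity <- stats::rnorm(cfg$n_samples)
    names(activity) <- samples
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)

    expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, sd = cfg$noise_sd),
                   nrow = cfg$n_genes, ncol = cfg$n_samples,
                   dimnames = list(genes, samples))
    expr <- expr + baseline
    is_target <- genes %in% targets
    expr[is_target, ] <- expr[is_target, ] +
      cfg$tf_effect * matrix(activity, nrow = sum(is_target),
                             ncol = cfg$n_samples, byrow = TRUE)

    blasts_bm <- stats::runif(cfg$n_samples, 5, 95)
    blasts_pb <- pmin(95, pmax(5, blasts_bm + stats::rnorm(cfg$n_samples, sd = 10)))
    npm1 <- stats::runif(cfg$n_samples) < cfg$npm1_frac

    responses <- data.frame(sample_id = samples,
                            blasts_bm = blasts_bm,
                            blasts_pb = blasts_pb,
                            NPM1 = npm1,
                            stringsAsFactors = FALSE)
    for (d in cfg$drug_names) {
      auc <- cfg$auc_intercept +
        cfg$auc_tf_slope * activity +
        cfg$auc_blast_slope * blasts_bm +
        cfg$npm1_auc_shift * as.numeric(npm1) +
        stats::rnorm(cfg$n_samples, sd = cfg$auc_noise_sd)
      responses[[d]] <- pmax(auc, 0)  # AUC is non-negative by construction
    }

    truth <- list(
      tf_target_gene_ids = targets,
      per_sample_tf_activity = activity,
      reverser_perturbagen_id = "PERT0001",
      planted_de_gene_ids = targets
    )
    structure(list(expression = expr, responses = responses, truth = truth,
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples, %d drugs, %d planted TF targets\n",
              nrow(x$expression), ncol(x$expression),
              length(x$config$drug_names),
              length(x$truth$tf_target_gene_ids)))
  invisible(x)
}
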