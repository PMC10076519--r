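#' Simulate perturbation-experiment DEG score tables
#'
#' Emulates the three cell-line perturbation contrasts used to nominate a
#' signed query: TF overexpression (targets up), TF knockdown (targets down)
#' and dominant-negative p30 overexpression (targets down). Each table assigns
#' every gene a score; planted targets receive \code{+/- target_score} plus
#' noise, all other genes standard-normal background. \code{overlap} is the
#' probability that any given target responds in any given experiment, so the
#' intersection of the three calls shrinks as overlap drops.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth ground-truth list from \code{\link{simulate_cohort}}.
#' @param overlap per-experiment inclusion probability of each target, in
#'   [0, 1].
#' @return A list of class \code{"perturbation_signatures"} with data.frames
#'   \code{oe}, \code{kd}, \code{p30} (columns \code{gene}, \code{score}).
#' @export
simulate_perturbation_signatures <- function(config, truth, overlap = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(overlap) || overlap < 0 || overlap > 1) {
    stop("simulate_perturbation_signatures: overlap must lie in [0, 1]")
  }
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  targets <- truth$tf_target_gene_ids
  if (!all(targets %in% genes)) {
    stop("simulate_perturbation_signatures: truth targets outside gene universe")
  }
  .with_seed(.sub_seed(cfg, "perturbation"), {
    one_table <- function(direction) {
      score <- stats::rnorm(cfg$n_genes)
      responsive <- targets[stats::runif(length(targets)) < overlap]
      idx <- match(responsive, genes)
      score[idx] <- direction * cfg$target_score +
        stats::rnorm(length(idx), sd = cfg$pert_noise_sd)
      data.frame(gene = genes, score = score, stringsAsFactors = FALSE)
    }
    structure(list(oe = one_table(+1),
                   kd = one_table(-1),
                   p30 = one_table(-1)),
              class = "perturbation_signatures")
  })
}

#' Call up/down gene sets from a perturbation DEG table
#'
#' @param table data.frame with \code{gene} and \code{score}.
#' @param threshold absolute score cutoff.
#' @return list with character vectors \code{up} and \code{down}.
#' @export
deg_direction_sets <- function(table, threshold = 2.5) {
  stopifnot(is.data.frame(table), all(c("gene", "score") %in% names(table)))
  list(up = table$gene[table$score >= threshold],
       down = table$gene[table$score <= -threshold])
}

#' Simulate a TF-target gene-set collection
#'
#' One set is the planted TF's true target genes; the remaining sets are
#' size-matched random draws from the universe, standing in for the target
#' sets of unrelated transcription factors.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth ground-truth list from \code{\link{simulate_cohort}}.
#' @param n_sets total number of TF sets (including the planted one).
#' @return named list of gene-id character vectors; the planted set is named
#'   \code{"TF_PLANTED"}.
#' @export
simulate_tf_sets <- function(config, truth, n_sets = 20) {
  stopifnot(inherits(config, "sim_config"), n_sets >= 1)
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  .with_seed(.sub_seed(cfg, "tf_sets"), {
    sets <- list(TF_PLANTED = truth$tf_target_gene_ids)
    size <- length(truth$tf_target_gene_ids)
    for (i in seq_len(n_sets - 1)) {
      sets[[sprintf("TF_DECOY%02d", i)]] <- sample(genes, size)
    }
    sets
  })
}

#' Simulate a reference compendium of perturbation signatures
#'
#' Builds \code{compendium_size} perturbagens, each profiled in
#' \code{n_cell_lines} cell lines, as full-universe ranked signatures. One
#' planted reverser (\code{truth$reverser_perturbagen_id}) carries a score
#' vector blending, at weight \code{reverser_strength}, the negated
#' target-direction signal (so the planted TF targets sink to the bottom of
#' its ranking) with permutation noise; every other perturbagen is a pure
#' permutation of a fixed symmetric score profile.
#'
#' @param config a \code{\link{sim_config}} with \code{compendium_size >= 10}.
#' @param truth ground-truth list from \code{\link{simulate_cohort}}.
#' @return A list of class \code{"compendium"}:
#'   \describe{
#'     \item{signatures}{named list (\code{"<pert>|<cell>"}) of ranked
#'       signature data.frames (\code{gene}, \code{score}, descending).}
#'     \item{meta}{data.frame: \code{perturbagen_id}, \code{cell_line},
#'       \code{class}.}
#'   }
#' @export
simulate_reference_compendium <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$compendium_size < 10) {
    stop("simulate_reference_compendium: compendium_size must be >= 10 ",
         "(tau percentiles are meaningless below that)")
  }
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  targets <- truth$tf_target_gene_ids
  perts <- sprintf("PERT%04d", seq_len(cfg$compendium_size))
  if (!truth$reverser_perturbagen_id %in% perts) {
    stop("simulate_reference_compendium: reverser id not in compendium")
  }
  classes <- c("adrenergic receptor agonist", "kinase inhibitor",
               "HDAC inhibitor", "topoisomerase inhibitor", "glucocorticoid",
               "HMGCR inhibitor", "dopamine receptor antagonist",
               "mTOR inhibitor", "EGFR inhibitor", "proteasome inhibitor")
  .with_seed(.sub_seed(cfg, "compendium"), {
    # symmetric base profile: permuting it gives exchangeable noise signatures
    profile <- stats::qnorm(stats::ppoints(cfg$n_genes))
    direction <- 2 * as.numeric(genes %in% targets)  # ~2 SD planted signal
    sigs <- list()
    meta <- data.frame(perturbagen_id = character(0), cell_line = character(0),
                       class = character(0), stringsAsFactors = FALSE)
    for (p in perts) {
      cls <- classes[1 + (match(p, perts) - 1) %% length(classes)]
      for (cl in cfg$cell_line_names) {
        noise <- sample(profile)
        score <- if (p == truth$reverser_perturbagen_id) {
          cfg$reverser_strength * (-direction) +
            (1 - cfg$reverser_strength) * noise
        } else {
          noise
        }
        ord <- order(-score, genes)
        sigs[[paste(p, cl, sep = "|")]] <-
          data.frame(gene = genes[ord], score = score[ord],
                     stringsAsFactors = FALSE)
        meta <- rbind(meta, data.frame(perturbagen_id = p, cell_line = cl,
                                       class = cls, stringsAsFactors = FALSE))
      }
    }
    structure(list(signatures = sigs, meta = meta), class = "compendium")
  })
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("Reference compendium: %d perturbagens x %d cell lines, %d genes\n",
              length(unique(x$meta$perturbagen_id)),
              length(unique(x$meta$cell_line)),
              nrow(x$signatures[[1]])))
  invisible(x)
}
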