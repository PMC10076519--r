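#' Signal-to-noise gene ranking metric
#'
#' Per-gene signal-to-noise score between a resistant and a sensitive sample
#' group: \code{(mean_R - mean_S) / (sd_R + sd_S)}, with each group SD floored
#' at \code{max(sd, 0.2 * |mean|, 0.2 * sd_floor_abs)} (the usual convention
#' for this metric) so low-variance genes cannot blow the ratio up.
#'
#' @param expr genes x samples log2 expression matrix with dimnames.
#' @param group_r,group_s sample ids of the resistant / sensitive groups
#'   (>= 3 each).
#' @param sd_floor_abs absolute floor scale; the SD floor is
#'   \code{0.2 * sd_floor_abs} even for genes with mean near zero.
#' @return named numeric vector of scores, one per gene.
#' @export
signal_to_noise <- function(expr, group_r, group_s, sd_floor_abs = 1) {
  .check_groups(expr, group_r, group_s)
  mr <- rowMeans(expr[, group_r, drop = FALSE])
  ms <- rowMeans(expr[, group_s, drop = FALSE])
  sr <- .row_sds(expr[, group_r, drop = FALSE])
  ss <- .row_sds(expr[, group_s, drop = FALSE])
  sr <- pmax(sr, 0.2 * abs(mr), 0.2 * sd_floor_abs)
  ss <- pmax(ss, 0.2 * abs(ms), 0.2 * sd_floor_abs)
  (mr - ms) / (sr + ss)
}

#' Order gene scores into a ranked signature
#'
#' Descending by score; ties broken by gene-id lexicographic order so the
#' ranking is fully deterministic.
#'
#' @param scores named numeric vector (no NaN).
#' @param label optional provenance label (drug or contrast name).
#' @return data.frame of class \code{"ranked_signature"} with columns
#'   \code{gene} and \code{score}, row 1 = rank 1 (highest score).
#' @export
rank_genes <- function(scores, label = NULL) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("rank_genes: scores must be named with unique gene ids")
  }
  if (any(is.na(scores))) stop("rank_genes: NaN/NA scores not allowed")
  ord <- order(-scores, names(scores))
  sig <- data.frame(gene = names(scores)[ord], score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  attr(sig, "label") <- label
  class(sig) <- c("ranked_signature", "data.frame")
  sig
}

#' Combine ranked signatures by average rank
#'
#' Per-gene mean of 1-based ranks across the input signatures; the combined
#' signature is ordered ascending by mean rank (low mean rank = consistently
#' high in the inputs), ties broken lexicographically. The stored score is the
#' negated mean rank, keeping scores non-increasing down the ranking.
#'
#' @param signatures list of >= 2 \code{\link{rank_genes}} outputs over the
#'   same gene universe.
#' @param label optional provenance label.
#' @return a \code{"ranked_signature"} data.frame with an extra
#'   \code{mean_rank} column.
#' @export
average_rank_combine <- function(signatures, label = "average-rank") {
  if (length(signatures) < 2) {
    stop("average_rank_combine: need >= 2 signatures")
  }
  universe <- sort(signatures[[1]]$gene)
  for (i in seq_along(signatures)) {
    gi <- sort(signatures[[i]]$gene)
    if (!identical(gi, universe)) {
      off <- c(setdiff(gi, universe), setdiff(universe, gi))
      stop("average_rank_combine: gene universe mismatch in signature ", i,
           "; offending genes: ", paste(utils::head(off, 10), collapse = ", "))
    }
  }
  ranks <- vapply(signatures, function(s) {
    r <- seq_len(nrow(s))
    r[match(universe, s$gene)]
  }, numeric(length(universe)))
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, universe)
  sig <- data.frame(gene = universe[ord], score = -mean_rank[ord],
                    mean_rank = mean_rank[ord], stringsAsFactors = FALSE)
  attr(sig, "label") <- label
  class(sig) <- c("ranked_signature", "data.frame")
  sig
}

#' Differential expression between two sample groups
#'
#' Per-gene Welch two-sample t-test on log2 expression with
#' Benjamini-Hochberg FDR. This is a deliberately simple Gaussian test on
#' log2 values: the pipeline only consumes the fold-change / FDR filter, and
#' the synthetic cohorts are Gaussian on that scale. A gene passes when
#' \code{|log2FC| >= lfc_threshold} and \code{FDR <= fdr_threshold}
#' (defaults: two-fold change, FDR 0.05).
#'
#' @param expr genes x samples log2 expression matrix.
#' @param group_a,group_b sample ids (>= 3 each); log2FC is A minus B.
#' @param lfc_threshold,fdr_threshold pass-flag cutoffs.
#' @return data.frame: \code{gene}, \code{log2fc}, \code{p}, \code{fdr},
#'   logical \code{pass}.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    lfc_threshold = 1, fdr_threshold = 0.05) {
  .check_groups(expr, group_a, group_b)
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  # variance floor keeps zero-variance genes finite rather than dividing by 0
  va <- pmax(.row_sds(a)^2, 1e-12)
  vb <- pmax(.row_sds(b)^2, 1e-12)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  fdr <- stats::p.adjust(p, method = "BH")
  log2fc <- ma - mb
  data.frame(gene = rownames(expr), log2fc = log2fc, p = p, fdr = fdr,
             pass = abs(log2fc) >= lfc_threshold & fdr <= fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the signed connectivity queries
#'
#' The common query is the intersection of genes up under TF overexpression
#' and down under both knockdown and dominant-negative p30 overexpression.
#' Each per-drug query augments the common set with that drug's
#' resistance-up genes restricted to the TF-regulated (overexpression-up)
#' set. All queries are one-tailed by default (\code{q_down} empty): the
#' screen looks for perturbagens that reverse an up-gene program.
#'
#' @param oe_up genes up in TF-overexpressing cells.
#' @param kd_down genes down in TF-knockdown cells.
#' @param p30_down genes down in p30-overexpressing cells.
#' @param drug_up named list of per-drug resistance-up gene sets (may be
#'   empty, in which case only the common query is returned).
#' @return named list of signed queries, each a list
#'   \code{(q_up, q_down, label, one_tailed)}.
#' @export
build_signed_queries <- function(oe_up, kd_down, p30_down, drug_up = list()) {
  step1 <- intersect(oe_up, kd_down)
  if (length(step1) == 0) {
    stop("build_signed_queries: empty intersection at stage 'oe_up & kd_down'")
  }
  common <- intersect(step1, p30_down)
  if (length(common) == 0) {
    stop("build_signed_queries: empty intersection at stage ",
         "'(oe_up & kd_down) & p30_down'")
  }
  mk <- function(q_up, label) {
    list(q_up = sort(q_up), q_down = character(0), label = label,
         one_tailed = TRUE)
  }
  queries <- list(common = mk(common, "common"))
  for (d in names(drug_up)) {
    queries[[d]] <- mk(union(common, intersect(drug_up[[d]], oe_up)), d)
  }
  queries
}

.check_groups <- function(expr, g1, g2) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  missing <- setdiff(c(g1, g2), colnames(expr))
  if (length(missing) > 0) {
    stop("sample ids not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (length(g1) < 3 || length(g2) < 3) {
    stop("both groups need >= 3 samples (got ", length(g1), " and ",
         length(g2), ")")
  }
  if (length(intersect(g1, g2)) > 0) stop("groups must be disjoint")
  invisible(TRUE)
}

.row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}
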