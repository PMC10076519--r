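#' Split a cohort into sensitive / middle / resistant AUC tertiles
#'
#' Samples with a finite AUC for \code{drug} are sorted ascending by AUC
#' (ties broken by stable sample-id order). The bottom \code{ceiling(n/3)}
#' form the sensitive (S) group, the top \code{floor(n/3)} the resistant (R)
#' group, and the remainder the middle group. Only the AUC ordering matters,
#' so any strictly monotone transform of AUC yields the same split.
#'
#' @param responses drug-response data.frame (see
#'   \code{\link{simulate_cohort}}): \code{sample_id} plus one AUC column per
#'   drug.
#' @param drug name of the AUC column to split on.
#' @return list of class \code{"group_assignment"}: \code{drug},
#'   \code{sensitive_ids}, \code{middle_ids}, \code{resistant_ids}.
#' @export
tertile_split <- function(responses, drug) {
  auc <- .drug_auc(responses, drug)
  n <- length(auc)
  if (n < 6) {
    stop("tertile_split: need >= 6 samples with finite AUC for '", drug,
         "' (got ", n, ")")
  }
  ord <- order(auc, names(auc))
  ids <- names(auc)[ord]
  n_s <- ceiling(n / 3)
  n_r <- floor(n / 3)
  structure(list(drug = drug,
                 sensitive_ids = ids[seq_len(n_s)],
                 middle_ids = if (n - n_s - n_r > 0)
                   ids[(n_s + 1):(n - n_r)] else character(0),
                 resistant_ids = ids[(n - n_r + 1):n]),
            class = "group_assignment")
}

#' Subdivide the non-resistant two-thirds into MS and LS subgroups
#'
#' Within the non-resistant set (sensitive + middle tertiles), the bottom
#' AUC third is the more-sensitive (MS) subgroup and the top third the
#' less-sensitive (LS) subgroup, under the same remainder rule as
#' \code{\link{tertile_split}}.
#'
#' @inheritParams tertile_split
#' @return list with \code{ms_ids} and \code{ls_ids}.
#' @export
subdivide_nonresistant <- function(responses, drug) {
  split <- tertile_split(responses, drug)
  keep <- c(split$sensitive_ids, split$middle_ids)
  sub <- responses[responses$sample_id %in% keep, , drop = FALSE]
  inner <- tertile_split(sub, drug)
  list(ms_ids = inner$sensitive_ids, ls_ids = inner$resistant_ids)
}

#' Spearman correlation between AUC and a clinical covariate
#'
#' Tie-corrected Spearman rank correlation (Pearson correlation of midranks)
#' with a two-sided p-value from the t approximation on n - 2 degrees of
#' freedom.
#'
#' @inheritParams tertile_split
#' @param covariate \code{"blasts_bm"} or \code{"blasts_pb"}.
#' @return list: \code{rho}, \code{p}, \code{n}.
#' @export
correlate_auc_covariate <- function(responses, drug,
                                    covariate = c("blasts_bm", "blasts_pb")) {
  covariate <- match.arg(covariate)
  auc <- .drug_auc(responses, drug, min_n = 0)
  cov <- responses[[covariate]][match(names(auc), responses$sample_id)]
  ok <- is.finite(cov)
  auc <- auc[ok]; cov <- cov[ok]
  n <- length(auc)
  if (n < 5) stop("correlate_auc_covariate: need >= 5 paired observations")
  if (stats::sd(auc) == 0 || stats::sd(cov) == 0) {
    stop("correlate_auc_covariate: zero variance in '",
         if (stats::sd(auc) == 0) drug else covariate,
         "'; rho is undefined")
  }
  rho <- stats::cor(rank(auc), rank(cov))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = min(p, 1), n = n)
}

#' Compare AUC between mutation groups by the Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test of the AUC of flag-positive
#' versus flag-negative samples. For tie-free groups of at most 8 each the
#' exact permutation distribution is used; otherwise the normal approximation
#' with midranks, tie correction, and continuity correction.
#'
#' @inheritParams tertile_split
#' @param flag name of a logical mutation-flag column (e.g. \code{"NPM1"}).
#' @return list: \code{statistic} (Mann-Whitney U of the flag-positive group),
#'   \code{p}, group sizes \code{n_pos}, \code{n_neg}.
#' @export
compare_mutation_groups <- function(responses, drug, flag) {
  auc <- .drug_auc(responses, drug, min_n = 0)
  fl <- responses[[flag]][match(names(auc), responses$sample_id)]
  if (is.null(fl)) stop("compare_mutation_groups: no flag column '", flag, "'")
  x <- auc[which(fl)]; y <- auc[which(!fl)]
  if (length(x) == 0 || length(y) == 0) {
    stop("compare_mutation_groups: one mutation group is empty for '", flag, "'")
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n_pos = length(x), n_neg = length(y))
}

#' Area under a dose-viability curve
#'
#' Trapezoidal area of percent viability over log10(dose), normalized by the
#' log-dose span, so a curve pinned at 100 percent viability scores 100 and a
#' fully lethal curve scores 0. Higher AUC therefore means more resistant.
#'
#' @param doses strictly increasing positive dose values.
#' @param viability percent-of-control viability at each dose.
#' @return scalar AUC on the viability scale (0-100 for viability in
#'   [0, 100]).
#' @export
auc_from_viability <- function(doses, viability) {
  if (length(doses) < 3) stop("auc_from_viability: need >= 3 dose points")
  if (length(doses) != length(viability)) {
    stop("auc_from_viability: doses and viability differ in length")
  }
  if (any(doses <= 0)) stop("auc_from_viability: doses must be positive")
  if (any(diff(doses) <= 0)) {
    stop("auc_from_viability: doses must be strictly increasing")
  }
  ld <- log10(doses)
  pracma::trapz(ld, viability) / (ld[length(ld)] - ld[1])
}

# Finite AUC values for one drug, named by sample id.
.drug_auc <- function(responses, drug, min_n = 6) {
  stopifnot(is.data.frame(responses), "sample_id" %in% names(responses))
  if (!drug %in% names(responses)) {
    stop("no AUC column for drug '", drug, "'")
  }
  auc <- responses[[drug]]
  names(auc) <- responses$sample_id
  auc[is.finite(auc)]
}
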