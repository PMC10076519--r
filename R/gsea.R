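#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum enrichment of a gene set in a ranked signature. At each rank,
#' member genes ("hits") add \code{|score|^weight_p} (normalized to total 1
#' over the hits) and non-members subtract \code{1 / (N - n_hits)}; the
#' enrichment score (ES) is the running-sum value of maximal absolute
#' deviation from zero. The sum returns to zero at the bottom of the list,
#' and \code{|ES| <= 1}. \code{weight_p = 0} reduces to the classic
#' unweighted KS statistic.
#'
#' Only the running-sum values at and just before hit positions are
#' materialized (the extremum must occur there), so scoring is O(hits), not
#' O(universe).
#'
#' @param sig a \code{\link{rank_genes}}-style data.frame (\code{gene},
#'   \code{score}, descending).
#' @param set character vector of gene ids; ids outside the universe are
#'   dropped (count reported via attribute \code{"n_dropped"}).
#' @param weight_p score-weighting exponent (>= 0), default 1.
#' @param profile if TRUE, also return the full running-sum profile.
#' @return list: \code{es}, \code{leading_edge} (hit genes at/before a
#'   positive extremum, at/after a negative one), \code{n_hits}, and
#'   optionally \code{running_sum} (length-N numeric).
#' @export
enrichment_score <- function(sig, set, weight_p = 1, profile = FALSE) {
  stopifnot(is.data.frame(sig), all(c("gene", "score") %in% names(sig)))
  if (weight_p < 0) stop("enrichment_score: weight_p must be >= 0")
  n <- nrow(sig)
  idx <- which(sig$gene %in% set)
  n_dropped <- length(unique(set)) - length(idx)
  if (length(idx) == 0) {
    stop("enrichment_score: gene set has no overlap with the signature universe")
  }
  if (length(idx) >= n) {
    stop("enrichment_score: set covers the whole universe (miss step undefined)")
  }
  es <- .es_core(sig$score, idx, weight_p)
  hits <- sig$gene[idx]
  le <- if (es$es >= 0) hits[idx <= es$at] else hits[idx >= es$at]
  out <- list(es = es$es, leading_edge = le, n_hits = length(idx))
  if (profile) {
    w <- .hit_weights(sig$score, idx, weight_p)
    rs <- numeric(n)
    rs[idx] <- w + 1 / (n - length(idx))
    rs <- cumsum(rs - 1 / (n - length(idx)))
    out$running_sum <- rs
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

# Weighted hit increments, normalized to sum 1. If all hit scores are zero
# (degenerate under weighting) fall back to equal weights.
.hit_weights <- function(scores, idx, weight_p) {
  w <- abs(scores[idx])^weight_p
  tot <- sum(w)
  if (tot == 0) rep(1 / length(idx), length(idx)) else w / tot
}

# ES from hit positions only: the maximum of the running sum is attained
# right after a hit, the minimum right before one. When the two deviations
# tie in magnitude the positive one is reported.
.es_core <- function(scores, idx, weight_p) {
  idx <- sort(idx)
  k <- length(idx)
  n <- length(scores)
  miss <- 1 / (n - k)
  cw <- cumsum(.hit_weights(scores, idx, weight_p))
  after <- cw - (idx - seq_len(k)) * miss
  before <- c(0, cw[-k]) - (idx - 1 - (seq_len(k) - 1)) * miss
  maxdev <- max(after, 0)
  mindev <- min(before, 0)
  # ties in magnitude (within fp noise) resolve to the positive deviation
  if (maxdev >= -mindev - 1e-9) {
    list(es = maxdev, at = idx[which.max(after)])
  } else {
    list(es = mindev, at = idx[which.min(before)])
  }
}

#' Permutation significance for gene-set enrichment
#'
#' Gene-set permutation null: for each set size, \code{n_perm} random sets of
#' that size are drawn from the universe and scored. NES is ES divided by the
#' mean |null ES| of matching sign; the nominal p-value is the two-sided
#' permutation fraction \code{(1 + #{|null| >= |ES|}) / (n_perm + 1)}; q is
#' the Benjamini-Hochberg adjustment of the nominal p across sets (labelled
#' \code{q_bh} to distinguish it from NES-binned FDR machinery).
#'
#' @param sig ranked signature data.frame.
#' @param sets named list of gene-id vectors.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param weight_p weighting exponent passed to
#'   \code{\link{enrichment_score}}.
#' @return data.frame: \code{set}, \code{n_hits}, \code{es}, \code{nes},
#'   \code{p}, \code{q_bh}.
#' @export
gsea_significance <- function(sig, sets, n_perm = 999, seed = 1,
                              weight_p = 1) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  if (n_perm < 100) stop("gsea_significance: n_perm must be >= 100")
  n <- nrow(sig)
  sizes <- vapply(sets, function(s) sum(sig$gene %in% s), integer(1))
  if (any(sizes == 0)) {
    stop("gsea_significance: sets with no universe overlap: ",
         paste(names(sets)[sizes == 0], collapse = ", "))
  }
  if (any(sizes > n / 2)) {
    warning("gsea_significance: sets larger than half the universe: ",
            paste(names(sets)[sizes > n / 2], collapse = ", "))
  }
  .with_seed(seed, {
    null_pool <- new.env(parent = emptyenv())
    null_for_size <- function(m) {
      key <- as.character(m)
      if (is.null(null_pool[[key]])) {
        null_pool[[key]] <- vapply(seq_len(n_perm), function(i) {
          .es_core(sig$score, sample.int(n, m), weight_p)$es
        }, numeric(1))
      }
      null_pool[[key]]
    }
    res <- lapply(names(sets), function(nm) {
      obs <- enrichment_score(sig, sets[[nm]], weight_p = weight_p)
      null <- null_for_size(obs$n_hits)
      same <- null[sign(null) == sign(obs$es)]
      denom <- if (length(same) > 0) mean(abs(same)) else mean(abs(null))
      nes <- if (obs$es == 0) 0 else obs$es / denom
      p <- (1 + sum(abs(null) >= abs(obs$es))) / (n_perm + 1)
      data.frame(set = nm, n_hits = obs$n_hits, es = obs$es, nes = nes,
                 p = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q_bh <- stats::p.adjust(res$p, method = "BH")
    res
  })
}

#' Screen TF target sets across per-drug resistance signatures
#'
#' Runs \code{\link{gsea_significance}} of every TF target set against each
#' per-drug ranked signature and nominates the "common top" TF: among TFs
#' significant (\code{q_bh <= q_gate}) in all drugs, the one with the best
#' (largest) median NES across drugs. The full per-drug table is returned for
#' audit even when no TF clears the gate.
#'
#' @param signatures named list of >= 2 per-drug ranked signatures.
#' @param tf_sets named list of TF target gene sets.
#' @param n_perm,seed,weight_p passed to \code{\link{gsea_significance}}
#'   (each drug uses an offset of \code{seed} so reruns are reproducible).
#' @param q_gate significance gate on \code{q_bh} (default 0.25, the
#'   conventional exploratory GSEA threshold).
#' @return list: \code{common_top} (TF name or NA), \code{table} (long
#'   data.frame with \code{drug} column), \code{median_nes} (named vector
#'   over gated TFs).
#' @export
tf_screen <- function(signatures, tf_sets, n_perm = 499, seed = 1,
                      weight_p = 1, q_gate = 0.25) {
  if (length(signatures) < 2) stop("tf_screen: need >= 2 drug signatures")
  if (is.null(names(signatures))) {
    names(signatures) <- sprintf("drug%d", seq_along(signatures))
  }
  tabs <- lapply(seq_along(signatures), function(i) {
    t <- gsea_significance(signatures[[i]], tf_sets, n_perm = n_perm,
                           seed = seed + i, weight_p = weight_p)
    t$drug <- names(signatures)[i]
    t
  })
  tab <- do.call(rbind, tabs)
  sig_all <- Reduce(intersect, lapply(tabs, function(t) t$set[t$q_bh <= q_gate]))
  median_nes <- vapply(sig_all, function(s) {
    stats::median(tab$nes[tab$set == s])
  }, numeric(1))
  common_top <- if (length(median_nes) > 0) {
    names(median_nes)[which.max(median_nes)]
  } else {
    NA_character_
  }
  list(common_top = common_top, table = tab, median_nes = median_nes)
}

#' Overrepresentation of a DEG list in a gene set
#'
#' One-sided hypergeometric (Fisher) upper-tail test of the overlap between a
#' DEG list and a gene set inside a declared universe, with a
#' Haldane-corrected odds ratio (0.5 added to every cell) when any margin
#' cell is zero.
#'
#' @param deg_ids DEG gene ids (subset of \code{universe}).
#' @param set gene set ids (subset of \code{universe}).
#' @param universe all assayed gene ids.
#' @return list: \code{overlap}, \code{odds_ratio}, \code{p}.
#' @export
overrepresentation <- function(deg_ids, set, universe) {
  if (length(universe) == 0) stop("overrepresentation: empty universe")
  deg_ids <- intersect(unique(deg_ids), universe)
  set <- intersect(unique(set), universe)
  a <- length(intersect(deg_ids, set))
  b <- length(deg_ids) - a
  c_ <- length(set) - a
  d <- length(universe) - a - b - c_
  p <- stats::phyper(a - 1, length(set), length(universe) - length(set),
                     length(deg_ids), lower.tail = FALSE)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(overlap = a, odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       p = p)
}
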