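#' Two-tailed enrichment of a signed query in a reference signature
#'
#' Enrichment of the up and down tails of a signed query in one reference
#' ranked signature, via \code{\link{enrichment_score}}. An empty
#' \code{q_down} switches the query to one-tailed mode (\code{es_down = NA}).
#'
#' @param query list with \code{q_up}, \code{q_down} (see
#'   \code{\link{build_signed_queries}}).
#' @param ref reference ranked signature data.frame.
#' @param weight_p weighting exponent.
#' @return list: \code{es_up}, \code{es_down} (NA in one-tailed mode).
#' @export
two_sided_es <- function(query, ref, weight_p = 1) {
  up_in <- intersect(query$q_up, ref$gene)
  if (length(up_in) == 0) {
    stop("two_sided_es: q_up entirely outside the reference universe (",
         length(query$q_up), " genes dropped)")
  }
  es_up <- enrichment_score(ref, query$q_up, weight_p = weight_p)$es
  es_down <- if (length(query$q_down) == 0) {
    NA_real_
  } else {
    down_in <- intersect(query$q_down, ref$gene)
    if (length(down_in) == 0) {
      stop("two_sided_es: q_down entirely outside the reference universe (",
           length(query$q_down), " genes dropped)")
    }
    enrichment_score(ref, query$q_down, weight_p = weight_p)$es
  }
  list(es_up = es_up, es_down = es_down)
}

#' Weighted two-tailed connectivity score (WTCS)
#'
#' \code{(es_up - es_down) / 2} when the two tail enrichments disagree in
#' sign, 0 otherwise; for one-tailed queries (\code{es_down} absent) the
#' score is \code{es_up} alone. Always in [-1, 1].
#'
#' @param es_up,es_down tail enrichment scores; \code{es_down = NA} selects
#'   one-tailed mode.
#' @return scalar connectivity score.
#' @export
wtcs <- function(es_up, es_down = NA_real_) {
  if (is.na(es_down)) return(es_up)
  if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
}

#' Normalize connectivity scores within (cell line, class) strata
#'
#' Within each stratum, positive scores are divided by the stratum mean of
#' the positive scores and negative scores by the absolute stratum mean of
#' the negative scores; zeros stay zero. The means include the score itself,
#' so a score that is alone of its sign in the stratum normalizes to
#' exactly +/-1.
#'
#' @param scores data.frame with columns \code{query}, \code{perturbagen_id},
#'   \code{cell_line}, \code{class}, \code{wtcs}.
#' @param group_cols columns defining a normalization stratum.
#' @return the input with an \code{ncs} column appended.
#' @export
normalize_ncs <- function(scores, group_cols = c("query", "cell_line", "class")) {
  if (nrow(scores) == 0) stop("normalize_ncs: empty score table")
  stopifnot(all(c(group_cols, "wtcs") %in% names(scores)))
  key <- interaction(scores[group_cols], drop = TRUE)
  w <- scores$wtcs
  ncs <- numeric(length(w))
  for (k in levels(key)) {
    i <- which(key == k)
    pos <- i[w[i] > 0]; neg <- i[w[i] < 0]
    if (length(pos) > 0) ncs[pos] <- w[pos] / mean(w[pos])
    if (length(neg) > 0) ncs[neg] <- w[neg] / abs(mean(w[neg]))
  }
  scores$ncs <- ncs
  scores
}

#' Signed percentile tau score
#'
#' Rank of a normalized connectivity score against a reference distribution:
#' \code{tau = sign(ncs) * 100 / N * #(|ncs_ref| < |ncs|)}. With this strict
#' inequality convention, a score whose magnitude exceeds 95 percent of the
#' reference lands exactly at +/-95, and tau is bounded by +/-100.
#'
#' @param query_ncs scalar (or vector) of normalized connectivity scores.
#' @param reference_ncs reference NCS values (>= 10).
#' @return tau in [-100, 100], same length as \code{query_ncs}.
#' @export
tau_score <- function(query_ncs, reference_ncs) {
  n <- length(reference_ncs)
  if (n < 10) stop("tau_score: reference distribution needs >= 10 values")
  aref <- abs(reference_ncs)
  vapply(query_ncs, function(q) {
    sign(q) * 100 / n * sum(aref < abs(q))
  }, numeric(1))
}

#' Median summary score per perturbagen
#'
#' Median of the tau scores a perturbagen obtained across query lists
#' (midpoint convention for even counts).
#'
#' @param tau_table data.frame with \code{perturbagen_id}, \code{tau}, and
#'   (optionally) \code{class}.
#' @return data.frame sorted ascending by \code{summary_tau}:
#'   \code{perturbagen_id}, \code{summary_tau}, \code{n_queries},
#'   \code{class}.
#' @export
summarize_drug <- function(tau_table) {
  stopifnot(all(c("perturbagen_id", "tau") %in% names(tau_table)))
  if (nrow(tau_table) == 0) stop("summarize_drug: empty tau table")
  sp <- split(tau_table, tau_table$perturbagen_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(perturbagen_id = d$perturbagen_id[1],
               summary_tau = stats::median(d$tau),
               n_queries = nrow(d),
               class = if ("class" %in% names(d)) d$class[1] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$summary_tau, out$perturbagen_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify reversers and mimics and profile the top fraction
#'
#' Reversers are perturbagens with summary tau at or below \code{threshold}
#' (default -90); mimics at or above \code{-threshold}. The class
#' composition of the \code{top_frac} lowest-scoring perturbagens is
#' tabulated (count and fraction per perturbagen class).
#'
#' @param summaries output of \code{\link{summarize_drug}}.
#' @param threshold reverser cutoff in tau units (default -90).
#' @param top_frac fraction of lowest-scoring perturbagens to profile
#'   (default 0.02).
#' @return list: \code{reversers}, \code{mimics} (summary rows),
#'   \code{top_composition} (data.frame \code{class}, \code{count},
#'   \code{fraction}; empty when \code{top_frac} selects no perturbagen).
#' @export
classify_hits <- function(summaries, threshold = -90, top_frac = 0.02) {
  if (nrow(summaries) == 0) stop("classify_hits: empty summary table")
  reversers <- summaries[summaries$summary_tau <= threshold, , drop = FALSE]
  mimics <- summaries[summaries$summary_tau >= -threshold, , drop = FALSE]
  n_top <- floor(nrow(summaries) * top_frac)
  top <- utils::head(summaries[order(summaries$summary_tau,
                                     summaries$perturbagen_id), ], n_top)
  comp <- if (n_top > 0) {
    tb <- table(top$class)
    data.frame(class = names(tb), count = as.integer(tb),
               fraction = as.numeric(tb) / n_top, stringsAsFactors = FALSE)
  } else {
    data.frame(class = character(0), count = integer(0),
               fraction = numeric(0), stringsAsFactors = FALSE)
  }
  list(reversers = reversers, mimics = mimics, top_composition = comp)
}

#' Score signed queries against a reference compendium
#'
#' Full connectivity pass: per (query, perturbagen, cell line) the two-tailed
#' enrichment and WTCS; NCS normalization within (query, cell line, class)
#' strata; tau within each cell line against the other perturbagens of that
#' cell line (self excluded); per (query, perturbagen) the tau of the cell
#' line with the largest |NCS|; and the median summary score per perturbagen
#' across queries.
#'
#' @param queries named list of signed queries.
#' @param compendium a \code{\link{simulate_reference_compendium}}-style list
#'   (\code{signatures}, \code{meta}).
#' @param weight_p weighting exponent.
#' @return list: \code{scores} (per query x perturbagen x cell line:
#'   \code{es_up}, \code{es_down}, \code{wtcs}, \code{ncs}, \code{tau}),
#'   \code{per_query} (best-cell rows), \code{summary}
#'   (\code{\link{summarize_drug}} output).
#' @export
score_connectivity <- function(queries, compendium, weight_p = 1) {
  meta <- compendium$meta
  if (nrow(meta) == 0) stop("score_connectivity: empty compendium")
  rows <- lapply(names(queries), function(qn) {
    q <- queries[[qn]]
    es <- lapply(seq_len(nrow(meta)), function(i) {
      key <- paste(meta$perturbagen_id[i], meta$cell_line[i], sep = "|")
      two_sided_es(q, compendium$signatures[[key]], weight_p = weight_p)
    })
    data.frame(query = qn,
               perturbagen_id = meta$perturbagen_id,
               cell_line = meta$cell_line,
               class = meta$class,
               es_up = vapply(es, `[[`, numeric(1), "es_up"),
               es_down = vapply(es, `[[`, numeric(1), "es_down"),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  scores$wtcs <- mapply(wtcs, scores$es_up, scores$es_down)
  scores <- normalize_ncs(scores)

  # tau within (query, cell line), reference = the other perturbagens there
  scores$tau <- NA_real_
  key <- interaction(scores$query, scores$cell_line, drop = TRUE)
  for (k in levels(key)) {
    i <- which(key == k)
    aref <- abs(scores$ncs[i])
    n_ref <- length(i) - 1
    if (n_ref < 10) stop("score_connectivity: < 11 perturbagens per cell line")
    scores$tau[i] <- vapply(seq_along(i), function(j) {
      sign(scores$ncs[i[j]]) * 100 / n_ref * sum(aref[-j] < aref[j])
    }, numeric(1))
  }

  # per (query, perturbagen): keep the cell line with the largest |NCS|
  qp <- interaction(scores$query, scores$perturbagen_id, drop = TRUE)
  best <- unlist(lapply(split(seq_len(nrow(scores)), qp), function(i) {
    i[which.max(abs(scores$ncs[i]))]
  }), use.names = FALSE)
  per_query <- scores[best, , drop = FALSE]
  rownames(per_query) <- NULL

  list(scores = scores,
       per_query = per_query,
       summary = summarize_drug(per_query))
}
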