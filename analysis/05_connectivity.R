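#!/usr/bin/env Rscript
# Stage 5: connectivity scoring of the signed queries against the compendium.
#
# Builds the five query lists (the common TF-program genes plus the four
# per-drug resistance-up augmentations), scores every query against the
# 100-perturbagen x 2-cell-line reference compendium (two-tailed ES -> WTCS
# -> NCS -> tau), summarizes each perturbagen by its median tau, and
# classifies reversers (summary tau <= -90). Writes results/connectivity/.

suppressPackageStartupMessages(library(sigconnect))

cfg <- sim_config(seed = jsonlite::read_json("results/cohort/config.json")$seed)
cohort <- simulate_cohort(cfg)

pert <- simulate_perturbation_signatures(cfg, cohort$truth)
oe <- deg_direction_sets(pert$oe, cfg$score_threshold)
kd <- deg_direction_sets(pert$kd, cfg$score_threshold)
p30 <- deg_direction_sets(pert$p30, cfg$score_threshold)
drug_up <- lapply(setNames(nm = cfg$drug_names), function(d) {
  sp <- tertile_split(cohort$responses, d)
  deg <- differential_expression(cohort$expression, sp$resistant_ids,
                                 sp$sensitive_ids)
  deg$gene[deg$pass & deg$log2fc > 0]
})
queries <- build_signed_queries(oe$up, kd$down, p30$down, drug_up)
compendium <- simulate_reference_compendium(cfg, cohort$truth)

scored <- score_connectivity(queries, compendium)
hits <- classify_hits(scored$summary)

dir.create("results/connectivity", showWarnings = FALSE, recursive = TRUE)
write_gmt(lapply(queries, `[[`, "q_up"), "results/connectivity/queries.gmt")
write_compendium(compendium, "results/connectivity/compendium")
write.csv(scored$scores, "results/connectivity/connectivity_scores.csv",
          row.names = FALSE)
write.csv(scored$summary, "results/connectivity/summary_scores.csv",
          row.names = FALSE)
write.csv(hits$top_composition, "results/connectivity/top2pct_classes.csv",
          row.names = FALSE)

rev_id <- cohort$truth$reverser_perturbagen_id
rev_row <- which(scored$summary$perturbagen_id == rev_id)
cat(sprintf("Query sizes: %s\n",
            paste(sprintf("%s=%d", names(queries),
                          sapply(queries, function(q) length(q$q_up))),
                  collapse = ", ")))
cat(sprintf("Reversers (summary tau <= -90): %d; planted reverser %s ranks %d/%d with summary tau %.1f\n",
            nrow(hits$reversers), rev_id, rev_row, nrow(scored$summary),
            scored$summary$summary_tau[rev_row]))
cat("Class composition of the lowest-scoring 2%:\n")
print(hits$top_composition, row.names = FALSE)
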