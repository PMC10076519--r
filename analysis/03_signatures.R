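#!/usr/bin/env Rscript
# Stage 3: derive resistance signatures and DEG tables.
#
# Per drug: signal-to-noise ranking of every gene between the resistant and
# sensitive tertiles; the four per-drug rankings are combined into the
# cross-drug average-rank signature. Per drug DEG tables use Welch t with BH
# FDR and the two-fold-change / FDR <= 0.05 filter. Writes results/signatures/.

suppressPackageStartupMessages(library(sigconnect))

cfg <- sim_config(seed = jsonlite::read_json("results/cohort/config.json")$seed)
cohort <- simulate_cohort(cfg)

dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)
per_drug <- lapply(setNames(nm = cfg$drug_names), function(d) {
  sp <- tertile_split(cohort$responses, d)
  sig <- rank_genes(signal_to_noise(cohort$expression, sp$resistant_ids,
                                    sp$sensitive_ids), label = d)
  write_ranked_signature(sig, sprintf("results/signatures/s2n_%s.tsv", d))
  deg <- differential_expression(cohort$expression, sp$resistant_ids,
                                 sp$sensitive_ids)
  write.csv(deg, sprintf("results/signatures/deg_%s.csv", d),
            row.names = FALSE)
  list(sig = sig, deg = deg)
})
avg <- average_rank_combine(lapply(per_drug, `[[`, "sig"))
write_ranked_signature(avg, "results/signatures/average_rank.tsv")

targets <- jsonlite::read_json("results/cohort/truth.json",
                               simplifyVector = TRUE)$tf_target_gene_ids
top_decile <- avg$gene[1:(nrow(avg) / 10)]
cat(sprintf("DEG counts (|log2FC| >= 1, FDR <= 0.05): %s\n",
            paste(sprintf("%s=%d", cfg$drug_names,
                          sapply(per_drug, function(x) sum(x$deg$pass))),
                  collapse = ", ")))
cat(sprintf("Planted TF targets in the top decile of the average-rank signature: %d/%d\n",
            sum(targets %in% top_decile), length(targets)))
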