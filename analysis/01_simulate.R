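#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# A 2,000-gene x 120-sample log2 expression matrix in which a latent TF
# activity drives a 100-gene target program, plus a 4-drug AUC response table
# where the same activity confers resistance while blast percentage and NPM1
# mutation confer sensitivity. Artifacts land under results/cohort/.

suppressPackageStartupMessages(library(sigconnect))
seed <- 101

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
write_expression_matrix(cohort$expression, "results/cohort/expression.tsv")
write.csv(cohort$responses, "results/cohort/responses.csv", row.names = FALSE)
jsonlite::write_json(cohort$truth[c("tf_target_gene_ids",
                                    "reverser_perturbagen_id")],
                     "results/cohort/truth.json", auto_unbox = TRUE)
jsonlite::write_json(list(seed = seed), "results/cohort/config.json",
                     auto_unbox = TRUE)

cat(sprintf("Simulated %d genes x %d samples; %d planted TF targets; drugs: %s\n",
            nrow(cohort$expression), ncol(cohort$expression),
            length(cohort$truth$tf_target_gene_ids),
            paste(cfg$drug_names, collapse = ", ")))
cat(sprintf("AUC ranges: %s\n",
            paste(sprintf("%s %.0f-%.0f", cfg$drug_names,
                          sapply(cohort$responses[cfg$drug_names], min),
                          sapply(cohort$responses[cfg$drug_names], max)),
                  collapse = "; ")))
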