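#!/usr/bin/env Rscript
# Generate the synthetic AFF exome cohort (12 cases, 4 BP-treated controls)
# with planted recurrent genes and filter-failure variants, and write the
# variant table plus its ground-truth sidecar.
source("analysis/00_common.R")
seed <- arg_seed()
out <- res_dir("cohort")

sim <- simulate_cohort(cohort_sim_config(seed = seed))
write_variant_table(sim$cohort$calls, file.path(out, "variants.tsv"))
writeLines(sim$cohort$cases, file.path(out, "cases.txt"))
writeLines(sim$cohort$controls, file.path(out, "controls.txt"))
write_gene_list(sim$truth$bone_list, file.path(out, "bone_list_planted.txt"))

truth <- sim$truth
truth$bone_list <- truth$bone_list$symbols
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("cohort: %d cases, %d controls, %d calls across %d genes\n",
            length(sim$cohort$cases), length(sim$cohort$controls),
            nrow(sim$cohort$calls), length(unique(sim$cohort$calls$gene))))
cat(sprintf("planted survivors of the full cascade: %d calls\n",
            length(truth$surviving_variant_keys)))
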