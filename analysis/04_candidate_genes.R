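#!/usr/bin/env Rscript
# Candidate-gene selection: intersect the published recurrence-table genes
# with the bone/AFF literature fixture (recovering the 12 published
# candidates), overlap with the prior 3-sisters study stand-in (9 genes,
# 4 damaging), intersect the simulated cohort's recurrent genes with its
# planted bone list, and run a hypergeometric enrichment of the candidates.
source("analysis/00_common.R")
out <- res_dir("candidates")

fx <- paper_fixtures()

candidates <- gs_intersect(fx$table2_genes, fx$bone_candidates)
candidates$name <- "bone_AFF_candidates"
write_gene_list(candidates, file.path(out, "candidate_genes.txt"))
cat("published-table candidates:", length(candidates), "genes:\n  ",
    paste(candidates$symbols, collapse = ", "), "\n")
stopifnot(identical(candidates$symbols, fx$table3_genes$symbols))

ov <- overlap_with_prior(fx$all_mutated, fx$prior_sisters, fx$damaging)
write_gene_list(ov$overlap, file.path(out, "prior_overlap.txt"))
write_gene_list(ov$damaging_overlap, file.path(out, "prior_overlap_damaging.txt"))
cat(sprintf("prior-study overlap: %d genes, %d with damaging variants (%s)\n",
            length(ov$overlap), length(ov$damaging_overlap),
            paste(ov$damaging_overlap$symbols, collapse = ", ")))

# cohort-simulation candidates (planted bone list)
recurrent <- read_gene_list("results/recurrence/recurrent_genes.txt")
bone <- read_gene_list("results/cohort/bone_list_planted.txt")
sim_cand <- gs_intersect(recurrent, bone)
sim_cand$name <- "cohort_candidates"
write_gene_list(sim_cand, file.path(out, "cohort_candidate_genes.txt"))
cat("simulated-cohort candidates:", paste(sim_cand$symbols, collapse = ", "), "\n")

# enrichment of the candidates for the bone term within the mutated universe
universe <- fx$all_mutated
term <- gs_intersect(fx$bone_candidates, universe)
term$name <- "bone_metabolism"
enr <- hypergeom_enrichment(candidates, list(term), universe)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("bone-term enrichment: k=%d K=%d n=%d N=%d p=%.3g (BH q=%.3g)\n",
            enr$k, enr$K, enr$n, enr$N, enr$p_value, enr$q_value))
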