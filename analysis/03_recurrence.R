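#!/usr/bin/env Rscript
# Aggregate surviving variants by gene across cases, classify recurrence
# (two cases/two variants; two cases/one shared variant; more than two
# cases; singletons) and emit the compact "gene n (carriers)" listing.
source("analysis/00_common.R")
out <- res_dir("recurrence")

survivors <- read_variant_table("results/filtering/survivors.tsv", "tsv")
cases <- readLines("results/cohort/cases.txt")
records <- aggregate_by_gene(survivors, cases)
rep <- recurrence_report(records)

write.table(records[c("gene", "n_variants", "n_carriers", "n_hom",
                      "shared_variant", "category")],
            file.path(out, "recurrence.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(rep$listing$line, file.path(out, "recurrence_listing.txt"))
write_gene_list(recurrent_genes(records, 2L),
                file.path(out, "recurrent_genes.txt"))

cat("genes with any surviving variant:", rep$totals$n_genes, "\n")
cat("surviving variants:", rep$totals$n_variants, "\n")
print(rep$totals)
cat("worked-example shapes present:\n")
print(rep$listing$line[records$n_variants != records$n_carriers |
                         records$n_hom > 0])
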