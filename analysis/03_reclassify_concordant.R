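#!/usr/bin/env Rscript
# Reassessment of the 29 uncertain-significance variants with concordant SGE
# functional results: integrate PS3/BS3 at the stronger of the two category
# levels, append it to each variant's evidence, and reclassify by points.
#
# Writes results/table2_reclassification.tsv.

suppressPackageStartupMessages(library(sgecurate))

t2 <- read_variant_table(system.file("extdata", "table2.tsv", package = "sgecurate"))
out <- run_pipeline(t2)
per <- out$per_variant

dir.create("results", showWarnings = FALSE)
write_results(per, "results/table2_reclassification.tsv")

cat("Concordant-SGE VUS cohort:", out$summary$vus_n, "variants\n")
cat("Assigned functional evidence:\n")
print(table(per$assigned_code))
cat("\nClass transitions (rows: before, columns: after):\n")
print(out$summary$transitions["VUS", , drop = FALSE])
cat(sprintf("\nReclassified: %d/%d (%.1f%%)\n", out$summary$n_reclassified,
            out$summary$vus_n, out$summary$vus_reclassified_pct))
cat("Wrote results/table2_reclassification.tsv\n")
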