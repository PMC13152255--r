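#!/usr/bin/env Rscript
# Major-error / minor-error / concordance rates of each SGE dataset against
# (a) the point-based clinical classification of the 13 discordant variants
# and (b) the IARC classes of the 5 variants whose combined likelihood ratio
# is informative (outside [0.5, 2]), plus the Bhapkar marginal-homogeneity
# comparison of the two datasets.
#
# Writes results/concordance_rates.tsv and results/bhapkar.json.

suppressPackageStartupMessages({
  library(sgecurate)
  library(jsonlite)
})

t1 <- read_variant_table(system.file("extdata", "table1.tsv", package = "sgecurate"))
cls <- vapply(lapply(t1$evidence, classify_variant), `[[`, character(1), "label")

score <- function(clinical, sge) {
  rate_summary(agreement_category(clinical, functional_call(sge)))
}
row_of <- function(reference, dataset, r) {
  data.frame(reference = reference, dataset = dataset, n = r$n,
             major_pct = r$major_pct, minor_pct = r$minor_pct,
             concordant_pct = r$concordant_pct)
}

acmg_h <- score(cls, t1$sge_hap1)
acmg_m <- score(cls, t1$sge_mes)

iarc_all <- iarc_class(ifelse(is.na(t1$posterior), 0, t1$posterior),
                       ifelse(is.na(t1$combined_lr), 1, t1$combined_lr))
sel <- !is.na(t1$posterior) & iarc_all != "not_assigned"
iarc <- iarc_class(t1$posterior[sel], t1$combined_lr[sel])
iarc_h <- score(iarc, t1$sge_hap1[sel])
iarc_m <- score(iarc, t1$sge_mes[sel])

rates <- rbind(row_of("ACMG_points", "HAP1", acmg_h),
               row_of("ACMG_points", "mES", acmg_m),
               row_of("IARC", "HAP1", iarc_h),
               row_of("IARC", "mES", iarc_m))
dir.create("results", showWarnings = FALSE)
write_results(rates, "results/concordance_rates.tsv")
print(rates)

# Bhapkar comparison of the paired per-variant agreement categories
pair <- function(clinical, h, m) {
  crosstab_agreement(agreement_category(clinical, functional_call(h)),
                     agreement_category(clinical, functional_call(m)))
}
b_acmg <- bhapkar_test(pair(cls, t1$sge_hap1, t1$sge_mes))
b_iarc <- bhapkar_test(pair(iarc, t1$sge_hap1[sel], t1$sge_mes[sel]))
cat("\nACMG-reference comparison: ")
print(b_acmg)
cat("IARC-reference comparison: ")
print(b_iarc)

report <- function(b) list(statistic = b$statistic, df = b$df,
                           p_value = b$p_value,
                           pair_table = unname(b$pair_table))
write_json(list(acmg = report(b_acmg), iarc = report(b_iarc)),
           "results/bhapkar.json", auto_unbox = TRUE, digits = NA)
cat("\nWrote results/concordance_rates.tsv and results/bhapkar.json\n")
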