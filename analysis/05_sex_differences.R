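#!/usr/bin/env Rscript

# Stage 5 — per-lipid sex differences.
#
# Mixed models log2(conc + 1) ~ sex * age with random intercepts (and,
# where estimable, random age slopes) per participant, REML; the sex
# contrast is evaluated at the cohort mean age, BH-adjusted across
# lipids, and converted to a percent difference (2^beta - 1) * 100.
# Also writes a circular-barplot-ready long table grouped by class.

suppressMessages(library(lipidcohort))

manifest <- read.delim("results/manifest.tsv")
corrected <- read_abundance_csv("results/concentrations_corrected.csv",
                                state = "concentration")
retention <- read.delim("results/retention.tsv")
registry <- read_registry("results/registry.tsv")
kept <- retention$lipid[retention$retained]

res <- fit_sex_model(corrected[, kept, drop = FALSE], manifest,
                     registry = registry)
write.table(res, "results/sex_differences.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sig <- res[!is.na(res$q) & res$q < 0.05, ]
cat(sprintf("%d/%d lipids with significant sex differences (q < 0.05)\n",
            nrow(sig), nrow(res)))
cat(sprintf("  higher in females: %d (median +%.0f%%), higher in males: %d (median %.0f%%)\n",
            sum(sig$direction == "higher-in-female"),
            median(sig$percent_difference[sig$direction == "higher-in-female"]),
            sum(sig$direction == "higher-in-male"),
            median(sig$percent_difference[sig$direction == "higher-in-male"])))

# class-level summary of the significant species, sorted for plotting
plot_tab <- sig[order(sig$class, -sig$percent_difference),
                c("class", "lipid", "percent_difference", "q", "direction")]
write.table(plot_tab, "results/sex_differences_by_class.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
by_class <- aggregate(list(n_sig = sig$lipid), by = list(class = sig$class),
                      length)
print(by_class[order(-by_class$n_sig), ], row.names = FALSE)
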