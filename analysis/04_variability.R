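#!/usr/bin/env Rscript

# Stage 4 — variability decomposition and individuality.
#
# Computes, per retained lipid, the between-batch (analytical), within-
# subject and between-subject CVs, the intraclass correlation from a
# sex-adjusted random-intercept model, and the distance-based
# individuality analysis on 20 randomly sampled participants (complete
# triplets, UV-scaled, Euclidean distances, average-linkage clustering).

suppressMessages(library(lipidcohort))

seed <- as.integer(Sys.getenv("LIPIDCOHORT_SEED", "20260918")) %% .Machine$integer.max
manifest <- read.delim("results/manifest.tsv")
corrected <- read_abundance_csv("results/concentrations_corrected.csv",
                                state = "concentration")
retention <- read.delim("results/retention.tsv")
kept <- retention$lipid[retention$retained]
X <- corrected[, kept, drop = FALSE]

cvs <- subject_cvs(X, manifest)
ic <- icc(X, manifest)
qcid <- manifest$injection_id[manifest$role == "QC"]
cv_qc <- qc_cv(corrected[qcid, kept, drop = FALSE])

report <- merge(cvs, ic[, c("lipid", "icc", "sigma2_b", "sigma2_w",
                            "converged")], by = "lipid", sort = FALSE)
report$qc_cv <- cv_qc[report$lipid]
write.table(report, "results/variability.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("median CVs: analytical %.1f%% < within-subject %.1f%% < between-subject %.1f%%\n",
            median(report$qc_cv, na.rm = TRUE),
            median(report$within_cv, na.rm = TRUE),
            median(report$between_cv, na.rm = TRUE)))
cat(sprintf("ordering holds for %.0f%% of lipids; median ICC %.2f (%.0f%% of lipids > 0.5)\n",
            100 * mean(report$qc_cv < report$within_cv &
                         report$within_cv < report$between_cv, na.rm = TRUE),
            median(report$icc, na.rm = TRUE),
            100 * mean(report$icc > 0.5, na.rm = TRUE)))

dists <- individuality_distances(X, manifest, n_sampled_participants = 20,
                                 seed = seed)
print(dists)
write_dendrogram(dists, "results/individuality_dendrogram.nwk")

pca <- pca_overview(X[manifest$injection_id[manifest$role == "study"], ,
                      drop = FALSE])
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$explained_variance[1], 100 * pca$explained_variance[2]))
write.table(data.frame(injection_id = rownames(pca$scores),
                       pca$scores[, 1:5]),
            "results/pca_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
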