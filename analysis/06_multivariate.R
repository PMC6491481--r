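#!/usr/bin/env Rscript
# Stage 6 — multivariate analysis of the genetic values.
#
# Genotypic correlation table, PCA and Ward clustering on the seven-trait
# BLUP matrix (c_volume, a_volume, STAR, I_PL, WDI, NDVI, MCARI2), followed
# by per-group summaries with one-way ANOVA and Tukey letters.

suppressMessages(library(orchardphen))

blups <- read.csv("results/blups.csv")
m <- as.matrix(blups[, c("c_volume", "a_volume", "STAR", "I_PL", "WDI",
                         "NDVI", "MCARI2")])
rownames(m) <- blups$genotype

cors <- correlation_table(m, level = "genotypic")
print(cors)
write.csv(cors$r_squared, "results/genotypic_r_squared.csv")

pca <- pca_genetic(m)
print(pca)
write.csv(data.frame(axis = seq_along(pca$pct_variance),
                     pct_variance = pca$pct_variance),
          "results/pca_variance.csv", row.names = FALSE)

cl <- hac_ward(m, k = 6)
print(cl)
write.csv(data.frame(genotype = names(cl$labels),
                     group = unname(cl$labels)),
          "results/cluster_assignment.csv", row.names = FALSE)

grp <- group_summary(cl, m)
print(grp)
write.csv(data.frame(group = rownames(grp$means), size = grp$sizes,
                     grp$means, row.names = NULL),
          "results/group_means.csv", row.names = FALSE)
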