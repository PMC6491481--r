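#!/usr/bin/env Rscript
# Stage 5 — mixed models, BLUPs and broad-sense heritability per trait.
#
# Assembles the long-format phenotype table from stages 2-4, fits the
# genotype mixed model per trait (fixed scenario effect, BIC-checked against
# an intercept-only fixed part), and derives H2 = sigmaG2 / (sigmaG2 +
# sigmaR2 / n) plus the BLUP matrix used by stage 6.

suppressMessages(library(orchardphen))

trees <- read.csv("results/simdata/trees.csv")
geom <- read.csv("results/geometry_metrics.csv")
imag <- read.csv("results/tree_summary.csv")
ipl <- read.csv("results/ipl_predictions.csv")

tab <- data.frame(trees[, c("tree_id", "genotype", "scenario", "replicate")],
                  c_volume = geom$c_volume, a_volume = geom$a_volume,
                  c_i = geom$c_i, STAR = geom$STAR, NDVI = imag$NDVI,
                  MCARI2 = imag$MCARI2, WDI = imag$WDI,
                  t_diff = imag$t_diff_mean, I_PL = ipl$I_PL)
trait_cols <- setdiff(names(tab), c("tree_id", "genotype", "scenario",
                                    "replicate"))

fits <- lapply(trait_cols, function(tr) {
  long <- data.frame(genotype = tab$genotype, scenario = tab$scenario,
                     value = tab[[tr]])
  select_model(long, candidates = list(~ 1, ~ scenario))$best
})
names(fits) <- trait_cols

herit <- data.frame(
  trait = trait_cols,
  sigma_g2 = sapply(fits, function(f) f$sigma_g2),
  sigma_r2 = sapply(fits, function(f) f$sigma_r2),
  H2 = sapply(fits, heritability_of),
  cv_g = sapply(fits, function(f)
    tryCatch(genotypic_cv(f$blups + f$intercept), error = function(e) NA)),
  row.names = NULL)
print(herit)
write.csv(herit, "results/heritability.csv", row.names = FALSE)

geno <- sort(unique(tab$genotype))
blups <- sapply(fits, function(f) unname(f$blups[geno]))
rownames(blups) <- geno
write.csv(data.frame(genotype = geno, blups, row.names = NULL),
          "results/blups.csv", row.names = FALSE)
cat(sprintf("wrote BLUPs for %d genotypes x %d traits\n", nrow(blups),
            ncol(blups)))
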