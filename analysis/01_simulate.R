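#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic orchard study.
#
# Generates every input family the downstream stages consume, with known
# ground truth: crown point clouds (PLY), multispectral + thermal rasters
# (ESRI ASCII grids), a gas-exchange calibration campaign (CSV) and the
# orchard layout table. 24 genotypes x 4 replicate trees (two well-watered
# and two water-deficit rows), the same structure as the pipeline demo.

suppressMessages(library(orchardphen))

seed <- 7
out <- "results/simdata"
dir.create(file.path(out, "clouds"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "rasters"), showWarnings = FALSE)

config <- pipeline_config(seed = seed)
n_g <- config$n_genotypes
n_r <- config$n_rep

geno <- sprintf("G%03d", seq_len(n_g))
eff <- withr::with_seed(orchardphen:::sub_seed(seed, 1), list(
  size = rnorm(n_g, sd = 0.20),
  temp = rnorm(n_g, sd = 0.30),
  photo = rnorm(n_g, sd = 15)))
trees <- expand.grid(genotype = geno, replicate = seq_len(n_r),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
trees <- trees[order(trees$replicate, trees$genotype), ]
trees$scenario <- ifelse(trees$replicate %% 2 == 1, "WW", "WD")
trees$tree_id <- sprintf("T%03d", seq_len(nrow(trees)))
gi <- match(trees$genotype, geno)

# crowns -> PLY + per-tree truth
tla <- numeric(nrow(trees))
for (i in seq_len(nrow(trees))) {
  shrink <- if (trees$scenario[i] == "WD") 0.95 else 1
  spec <- crown_spec(
    n_leaves = max(20, round(config$n_leaves_base * exp(eff$size[gi[i]]) *
                               shrink)),
    leaf_radius = config$leaf_radius,
    semi_axes = c(0.9, 0.9, 1.1) * exp(eff$size[gi[i]] / 3) * shrink,
    clumping = 0.3, points_per_leaf = config$points_per_leaf,
    seed = orchardphen:::sub_seed(seed, 100 + i))
  cr <- generate_crown(spec, tree_id = trees$tree_id[i])
  tla[i] <- cr$truth$TLA
  write_ply(cr$cloud, file.path(out, "clouds",
                                paste0(trees$tree_id[i], ".ply")))
}
trees$TLA_true <- tla

# rasters -> ASCII grids + imagery truth table
canopy_r <- pmin(0.62 * exp(eff$size[gi] / 3), 0.9)
t_air <- 27.5
t_canopy <- t_air + 1.2 + eff$temp[gi] +
  ifelse(trees$scenario == "WD", 2, 0)
design <- orchard_design(n_rows = n_r, trees_per_row = n_g,
                         spacing = c(5, 2), pixel_size = config$pixel_size,
                         canopy_radius = canopy_r,
                         tree_temperature = t_canopy,
                         air_temperature = t_air,
                         seed = orchardphen:::sub_seed(seed, 2))
img <- generate_orchard_images(design)
for (b in names(img$stack$bands))
  write_ascii_grid(phen_raster(img$stack$bands[[b]],
                               pixel_size = config$pixel_size),
                   file.path(out, "rasters", paste0("band_", b, ".asc")))
write_ascii_grid(img$thermal, file.path(out, "rasters", "thermal.asc"))
trees$x <- img$truth$x
trees$y <- img$truth$y
write.csv(img$truth, file.path(out, "imagery_truth.csv"), row.names = FALSE)

# gas-exchange calibration campaign
cal <- generate_gas_exchange(ipl_truth(), n_records = c(98, 132),
                             seed = orchardphen:::sub_seed(seed, 3))
write.csv(cal, file.path(out, "gas_exchange_calibration.csv"),
          row.names = FALSE)

write.csv(trees, file.path(out, "trees.csv"), row.names = FALSE)
jsonlite::write_json(list(seed = seed, air_temperature = t_air,
                          genotype_effects = eff),
                     file.path(out, "truth_manifest.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d trees (%d genotypes x %d reps), %d calibration records\n",
            nrow(trees), n_g, n_r, nrow(cal)))
cat(sprintf("true canopy temperature contrast (WD - WW): %.2f degC\n",
            mean(t_canopy[trees$scenario == "WD"]) -
              mean(t_canopy[trees$scenario == "WW"])))
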