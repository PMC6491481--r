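#' Configuration of an end-to-end pipeline run
#'
#' Gathers every tunable of the synthetic end-to-end analysis: study size,
#' geometry parameters (alpha, STAR directions), imagery parameters (buffer
#' radius, NDVI threshold, trapezoid mode), I_PL calibration split and
#' clustering k. One master seed fans out to per-stage sub-seeds.
#'
#' @param seed master integer seed
#' @param n_genotypes,n_rep study size (replicates split over WW/WD rows)
#' @param alpha alpha-shape parameter (m)
#' @param star_directions number of STAR viewing directions
#' @param buffer_radius imagery buffer radius (m)
#' @param ndvi_threshold vegetation classification threshold
#' @param trapezoid `"auto"` (fit from all pixels) or four manual vertex
#'   temperatures `c(t_sat_soil, t_ww_veg, t_dry_soil, t_ws_veg)`
#' @param split_fraction I_PL calibration fraction
#' @param model_candidates list of fixed-effect formulas for [select_model()]
#' @param k_clusters number of genotype groups
#' @param n_leaves_base,points_per_leaf,leaf_radius crown generation scale
#' @param pixel_size raster resolution (m)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, n_genotypes = 24, n_rep = 4,
                            alpha = 0.15, star_directions = 6,
                            buffer_radius = 0.70, ndvi_threshold = 0.3,
                            trapezoid = "auto", split_fraction = 2 / 3,
                            model_candidates = list(~ scenario),
                            k_clusters = 6, n_leaves_base = 220,
                            points_per_leaf = 3, leaf_radius = 0.04,
                            pixel_size = 0.12) {
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline halted at stage '%s': %s", name, conditionMessage(e))
  })
}

#' Run the full multi-scale phenotyping pipeline on synthetic data
#'
#' Executes the stages in dependency order: (1) simulate the orchard
#' (genotype effects on crown size, canopy temperature and photosynthesis;
#' WW/WD planting rows), (2) crown geometry (hull volumes, convexity, STAR),
#' (3) rasters and per-tree imagery summary (indices, Tsurf - Tair, WDI),
#' (4) I_PL calibration campaign and high-throughput prediction, (5) mixed
#' models per trait (BLUPs, heritability), (6) multivariate analysis
#' (genotypic correlations, PCA, Ward clustering, group summaries).
#' Re-running with the same config is bit-identical. When `out_dir` is given
#' all stage tables are written there as CSV plus a JSON manifest recording
#' the configuration, seed and package version.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory
#' @return list: `trees` (per-tree trait table), `phenotypes` (long format),
#'   `geometry`, `imagery`, `ipl_models`, `model_fits`, `heritability`,
#'   `blups`, `correlations`, `pca`, `clusters`, `groups`, `truth`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ## stage 1: study design and true genotype effects -------------------------
  study <- pipeline_stage("simulate", {
    n_g <- config$n_genotypes
    n_r <- config$n_rep
    geno <- sprintf("G%03d", seq_len(n_g))
    eff <- with_seed_opt(sub_seed(config$seed, 1), list(
      size = rnorm(n_g, sd = 0.20),   # log-scale crown size effect
      temp = rnorm(n_g, sd = 0.30),   # deg C canopy temperature effect
      photo = rnorm(n_g, sd = 15)))   # P_KO/KC-scale photosynthesis effect
    trees <- expand.grid(genotype = geno, replicate = seq_len(n_r),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    trees <- trees[order(trees$replicate, trees$genotype), ]
    trees$scenario <- ifelse(trees$replicate %% 2 == 1, "WW", "WD")
    trees$tree_id <- sprintf("T%03d", seq_len(nrow(trees)))
    gi <- match(trees$genotype, geno)
    trees$g_size <- eff$size[gi]
    trees$g_temp <- eff$temp[gi]
    trees$g_photo <- eff$photo[gi]
    rownames(trees) <- NULL
    list(trees = trees, effects = eff)
  })
  trees <- study$trees
  wd <- trees$scenario == "WD"

  ## stage 2: crown geometry -------------------------------------------------
  geometry <- pipeline_stage("geometry", {
    rows <- lapply(seq_len(nrow(trees)), function(i) {
      sc_shrink <- if (wd[i]) 0.95 else 1
      spec <- crown_spec(
        n_leaves = max(20, round(config$n_leaves_base *
                                   exp(trees$g_size[i]) * sc_shrink)),
        leaf_radius = config$leaf_radius,
        semi_axes = c(0.9, 0.9, 1.1) * exp(trees$g_size[i] / 3) *
          sc_shrink,
        clumping = 0.3, points_per_leaf = config$points_per_leaf,
        seed = sub_seed(config$seed, 100 + i))
      cr <- generate_crown(spec, tree_id = trees$tree_id[i])
      hm <- hull_metrics(cr$cloud, alpha = config$alpha)
      # equal-area rendering: each of the points_per_leaf returns of a leaf
      # carries 1/points_per_leaf of the leaf disk area
      st <- compute_star(cr$cloud, directions = config$star_directions,
                         leaf_radius = config$leaf_radius /
                           sqrt(config$points_per_leaf),
                         total_leaf_area = cr$truth$TLA)
      cbind(hm, STAR = st$star, TLA_true = cr$truth$TLA)
    })
    do.call(rbind, rows)
  })

  ## stage 3: rasters + imagery summary --------------------------------------
  imagery <- pipeline_stage("imagery", {
    canopy_r <- pmin(0.62 * exp(trees$g_size / 3), 0.9)
    t_air <- 27.5
    t_canopy <- t_air + 1.2 + trees$g_temp + ifelse(wd, 2, 0)
    design <- orchard_design(
      n_rows = config$n_rep, trees_per_row = config$n_genotypes,
      spacing = c(5, 2), pixel_size = config$pixel_size,
      canopy_radius = canopy_r, tree_temperature = t_canopy,
      air_temperature = t_air, seed = sub_seed(config$seed, 2))
    img <- generate_orchard_images(design)
    trap <- if (is.numeric(config$trapezoid))
      fit_trapezoid(vertices = config$trapezoid) else NULL
    centers <- data.frame(tree_id = trees$tree_id, x = img$truth$x,
                          y = img$truth$y)
    summ <- tree_summary(img$stack, img$thermal, centers,
                         t_air = img$air_temperature,
                         radius = config$buffer_radius,
                         ndvi_threshold = config$ndvi_threshold, trap = trap)
    list(summary = summ, truth = img$truth, air_temperature = t_air)
  })

  ## stage 4: I_PL calibration + high-throughput prediction ------------------
  ipl <- pipeline_stage("ipl", {
    truth <- ipl_truth()
    cal <- generate_gas_exchange(truth, n_records = c(98, 132),
                                 seed = sub_seed(config$seed, 3))
    models <- calibrate_ipl(cal, split_fraction = config$split_fraction,
                            seed = sub_seed(config$seed, 4))
    ht <- with_seed_opt(sub_seed(config$seed, 5), {
      n <- nrow(trees)
      p <- pmax(40, 150 + trees$g_photo + ifelse(wd, -45, 0) +
                  rnorm(n, sd = 10))
      dt <- 1 + 0.5 * trees$g_temp + ifelse(wd, 1.5, 0) + rnorm(n, sd = 0.5)
      dev <- rownames(truth$beta)[(seq_len(n) %% nrow(truth$beta)) + 1L]
      tleaf <- truth$tair + dt
      ratio <- ko_kc_ratio(tleaf)
      phi <- (p / ratio) / (truth$ppfd * 0.84 * 0.5)
      fm <- runif(n, 1200, 1800)
      data.frame(tree_id = trees$tree_id, device = dev, Fs = fm * (1 - phi),
                 Fm_prime = fm, PPFD = truth$ppfd, Tleaf = tleaf,
                 Tair = truth$tair, stringsAsFactors = FALSE)
    })
    ht$I_PL <- predict_ipl(models, ht)
    list(models = models, calibration_data = cal, ht = ht)
  })

  ## stage 5: trait table + mixed models -------------------------------------
  traits <- pipeline_stage("quantgen", {
    tab <- data.frame(trees[, c("tree_id", "genotype", "scenario",
                                "replicate")],
                      c_volume = geometry$c_volume,
                      a_volume = geometry$a_volume,
                      c_i = geometry$c_i, STAR = geometry$STAR,
                      NDVI = imagery$summary$NDVI,
                      GNDVI = imagery$summary$GNDVI,
                      MCARI2 = imagery$summary$MCARI2,
                      PRI = imagery$summary$PRI,
                      WDI = imagery$summary$WDI,
                      t_diff = imagery$summary$t_diff_mean,
                      pix_num = imagery$summary$pix_num,
                      I_PL = ipl$ht$I_PL)
    trait_cols <- c("c_volume", "a_volume", "c_i", "STAR", "NDVI", "GNDVI",
                    "MCARI2", "PRI", "WDI", "t_diff", "pix_num", "I_PL")
    long <- do.call(rbind, lapply(trait_cols, function(tr) {
      data.frame(genotype = tab$genotype, scenario = tab$scenario,
                 replicate = tab$replicate, trait = tr, value = tab[[tr]],
                 stringsAsFactors = FALSE)
    }))
    fits <- lapply(trait_cols, function(tr) {
      sel <- select_model(long[long$trait == tr, ],
                          candidates = config$model_candidates)
      sel$best
    })
    names(fits) <- trait_cols
    herit <- data.frame(
      trait = trait_cols,
      sigma_g2 = vapply(fits, function(f) f$sigma_g2, numeric(1)),
      sigma_r2 = vapply(fits, function(f) f$sigma_r2, numeric(1)),
      n_rep = vapply(fits, function(f) f$n_rep, numeric(1)),
      H2 = vapply(fits, heritability_of, numeric(1)),
      bic = vapply(fits, function(f) f$bic, numeric(1)),
      row.names = NULL)
    geno <- sort(unique(tab$genotype))
    blups <- vapply(fits, function(f) unname(f$blups[geno]),
                    numeric(length(geno)))
    rownames(blups) <- geno
    list(table = tab, long = long, fits = fits, heritability = herit,
         blups = blups)
  })

  ## stage 6: multivariate ----------------------------------------------------
  multiv <- pipeline_stage("multivariate", {
    sel <- c("c_volume", "a_volume", "STAR", "I_PL", "WDI", "NDVI", "MCARI2")
    b <- traits$blups[, sel, drop = FALSE]
    cors <- correlation_table(b, level = "genotypic")
    pca <- pca_genetic(b)
    k <- min(config$k_clusters, nrow(b))
    cl <- hac_ward(b, k = k)
    grp <- group_summary(cl, b)
    list(correlations = cors, pca = pca, clusters = cl, groups = grp)
  })

  result <- list(trees = traits$table, phenotypes = traits$long,
                 geometry = geometry, imagery = imagery$summary,
                 ipl_models = ipl$models, model_fits = traits$fits,
                 heritability = traits$heritability, blups = traits$blups,
                 correlations = multiv$correlations, pca = multiv$pca,
                 clusters = multiv$clusters, groups = multiv$groups,
                 truth = list(effects = study$effects,
                              imagery = imagery$truth),
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(result$trees, "tree_metrics.csv")
  wr(result$heritability, "heritability.csv")
  wr(data.frame(genotype = rownames(result$blups), result$blups,
                row.names = NULL), "blups.csv")
  wr(data.frame(genotype = names(result$clusters$labels),
                group = unname(result$clusters$labels), row.names = NULL),
     "cluster_assignment.csv")
  wr(data.frame(group = rownames(result$groups$means), result$groups$means,
                row.names = NULL), "group_means.csv")
  manifest <- list(
    package = "orchardphen",
    version = as.character(utils::packageVersion("orchardphen")),
    seed = result$config$seed,
    config = result$config[setdiff(names(result$config),
                                   "model_candidates")],
    model_candidates = vapply(result$config$model_candidates,
                              function(f) paste(deparse(f), collapse = " "),
                              character(1)),
    outputs = c("tree_metrics.csv", "heritability.csv", "blups.csv",
                "cluster_assignment.csv", "group_means.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a long-format phenotype table from CSV
#'
#' Expects columns `genotype`, `scenario`, `trait`, `value` (plus any
#' covariates); reports non-numeric trait values with their line numbers.
#'
#' @param path CSV file with a header row
#' @return data frame of phenotype records
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "trait", "value")
  if (!all(need %in% names(df)))
    stopf("%s: missing column(s) %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  if (!is.numeric(df$value)) {
    suppressWarnings(num <- as.numeric(df$value))
    bad <- which(is.na(num) & !is.na(df$value) & df$value != "")
    if (length(bad))
      stopf("%s: non-numeric trait value at line(s) %s", path,
            paste(head(bad + 1L, 5), collapse = ", ")) # +1 for the header
    df$value <- num
  }
  df
}
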