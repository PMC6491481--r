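#' Pairwise correlation table with signed R-squared and significance stars
#'
#' Squared Pearson correlations between trait columns, with the sign of each
#' correlation reported separately and significance marked at the 0.08, 0.05,
#' 0.01 and 0.001 thresholds (`*`, `**`, `***`, `****`; `ns` otherwise). Used
#' both on individual phenotypic values and on genotypic values (BLUPs); the
#' `level` label records which.
#'
#' @param values numeric matrix or data frame (observations x traits)
#' @param level `"phenotypic"` or `"genotypic"` (metadata only)
#' @param min_pairs minimum complete pairs per cell (cells below are `NA`)
#' @return list of class `correlation_table`: `r_squared`, `sign`, `p_value`,
#'   `stars` (matrices), `level`, `n`
#' @export
correlation_table <- function(values, level = c("phenotypic", "genotypic"),
                              min_pairs = 3) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (ncol(values) < 2) stopf("need at least two traits")
  p <- ncol(values)
  nm <- colnames(values) %||% paste0("V", seq_len(p))
  r2 <- sgn <- pv <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      ok <- stats::complete.cases(values[, c(i, j)])
      x <- values[ok, i]; y <- values[ok, j]
      if (sum(ok) < min_pairs || sd(x) == 0 || sd(y) == 0) next
      ct <- suppressWarnings(cor.test(x, y))
      r2[i, j] <- unname(ct$estimate)^2
      sgn[i, j] <- sign(unname(ct$estimate))
      pv[i, j] <- ct$p.value
    }
  }
  stars <- matrix(ifelse(is.na(pv), NA,
                  ifelse(pv <= 0.001, "****",
                  ifelse(pv <= 0.01, "***",
                  ifelse(pv <= 0.05, "**",
                  ifelse(pv <= 0.08, "*", "ns"))))), p, p,
                  dimnames = list(nm, nm))
  structure(list(r_squared = r2, sign = sgn, p_value = pv, stars = stars,
                 level = level, n = nrow(values)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_table> %s level, n = %d\n", x$level, x$n))
  disp <- matrix(sprintf("(%s)%.*g%s",
                         ifelse(x$sign >= 0, "+", "-"), digits, x$r_squared,
                         ifelse(x$stars == "ns", " ns", x$stars)),
                 nrow(x$r_squared), dimnames = dimnames(x$r_squared))
  disp[is.na(x$r_squared)] <- "."
  print(disp, quote = FALSE)
  invisible(x)
}

#' PCA of genotypic values
#'
#' Principal component analysis of the genotype x trait matrix of genetic
#' values, on the correlation matrix (traits standardized, since units are
#' incommensurable). Loadings follow a deterministic sign convention: the
#' largest-magnitude loading of each axis is positive.
#'
#' @param blups numeric matrix or data frame (genotypes x traits), >= 3
#'   genotypes and >= 2 traits
#' @param scale standardize traits before decomposition (default TRUE)
#' @return list of class `genetic_pca`: `loadings`, `scores`,
#'   `pct_variance` (percent, sums to 100 over returned axes), `sdev`
#' @export
pca_genetic <- function(blups, scale = TRUE) {
  m <- as.matrix(blups)
  if (nrow(m) < 3 || ncol(m) < 2) stopf("need >= 3 genotypes and >= 2 traits")
  if (anyNA(m)) stopf("missing genetic values: impute or drop before PCA")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stopf("constant trait column(s): %s",
                           paste(colnames(m)[sds == 0], collapse = ", "))
  pc <- prcomp(m, center = TRUE, scale. = scale)
  keep <- pc$sdev > 1e-9 * pc$sdev[1]
  if (!all(keep))
    warnf("rank-deficient after standardization: %d axes retained", sum(keep))
  rot <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- pc$sdev[keep]^2
  structure(list(loadings = rot, scores = scores,
                 pct_variance = 100 * ev / sum(ev), sdev = pc$sdev[keep]),
            class = "genetic_pca")
}

#' @export
print.genetic_pca <- function(x, ...) {
  cat("<genetic_pca> % variance per axis:",
      paste(sprintf("%.1f", x$pct_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Ward hierarchical clustering of genotypes
#'
#' Agglomerative clustering of genotypes on their standardized genetic
#' values: Euclidean distances, Ward criterion (squared distances with the
#' Lance-Williams update, `hclust` method `ward.D2`), tree cut at `k` groups.
#'
#' @inheritParams pca_genetic
#' @param k number of groups (default 6, the group count retained in the
#'   study this package models); 1 <= k <= number of genotypes
#' @param scale standardize traits first (default TRUE)
#' @return list of class `cluster_result`: `labels` (named integer vector),
#'   `k`, `tree` (the `hclust` object), `traits`
#' @export
hac_ward <- function(blups, k = 6, scale = TRUE) {
  m <- as.matrix(blups)
  if (k < 1) stopf("'k' must be >= 1")
  if (k > nrow(m)) stopf("'k' (%d) exceeds the number of genotypes (%d)", k,
                         nrow(m))
  if (anyNA(m)) stopf("missing genetic values: impute or drop before clustering")
  ms <- if (scale) base::scale(m) else m
  tree <- hclust(dist(ms, method = "euclidean"), method = "ward.D2")
  labels <- cutree(tree, k = k)
  names(labels) <- rownames(m) %||% as.character(seq_len(nrow(m)))
  structure(list(labels = labels, k = as.integer(k), tree = tree,
                 traits = colnames(m)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d genotypes in %d groups (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Per-group trait summaries with ANOVA and Tukey letters
#'
#' Group means per trait, one-way ANOVA p-value for the group effect and a
#' compact letter display from all pairwise Tukey HSD comparisons at the 0.05
#' level (groups sharing no letter differ significantly). Singleton groups
#' are excluded from the Tukey comparisons with a warning.
#'
#' @param clusters a [hac_ward()] result (or named integer vector of labels)
#' @param blups genotype x trait matrix of genetic values (rows matched to
#'   labels by name when both are named)
#' @return list of class `group_summary`: `means` (group x trait), `sizes`,
#'   `anova_p` (per trait), `letters` (group x trait character matrix)
#' @export
group_summary <- function(clusters, blups) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels
            else clusters
  m <- as.matrix(blups)
  if (!is.null(names(labels)) && !is.null(rownames(m)))
    m <- m[names(labels), , drop = FALSE]
  if (length(labels) != nrow(m))
    stopf("labels (%d) and genotypes (%d) differ", length(labels), nrow(m))
  grp <- factor(labels)
  if (nlevels(grp) < 2) stopf("need at least 2 groups")
  sizes <- table(grp)
  singles <- names(sizes)[sizes < 2]
  if (length(singles))
    warnf("group(s) of size 1 excluded from Tukey comparisons: %s",
          paste(singles, collapse = ", "))
  keep <- !(as.character(grp) %in% singles)
  means <- apply(m, 2, function(v) tapply(v, grp, mean))
  anova_p <- numeric(ncol(m))
  letters <- matrix(NA_character_, nlevels(grp), ncol(m),
                    dimnames = list(levels(grp), colnames(m)))
  for (j in seq_len(ncol(m))) {
    d <- data.frame(y = m[keep, j], g = droplevels(grp[keep]))
    fit <- aov(y ~ g, data = d)
    anova_p[j] <- summary(fit)[[1]][["Pr(>F)"]][1]
    cld <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(
      g = "Tukey")), level = 0.05)
    letters[names(cld$mcletters$Letters), j] <- cld$mcletters$Letters
  }
  names(anova_p) <- colnames(m)
  structure(list(means = means, sizes = as.integer(sizes),
                 anova_p = anova_p, letters = letters),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat("<group_summary> group means (Tukey letters):\n")
  disp <- matrix(paste0(signif(x$means, digits),
                        ifelse(is.na(x$letters), "", paste0("^", x$letters))),
                 nrow(x$means), dimnames = dimnames(x$means))
  print(disp, quote = FALSE)
  cat("ANOVA p:", paste(sprintf("%s %.3g", names(x$anova_p), x$anova_p),
                        collapse = ", "), "\n")
  invisible(x)
}
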