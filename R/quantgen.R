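#' Fit the genotype mixed model for one trait
#'
#' Linear mixed model with a random genotypic effect and user-chosen fixed
#' effects (the watering scenario at minimum, in the design this package
#' models). Variance components are estimated by REML; BLUPs of the genotype
#' effects are the conditional means of the random effects; the BIC reported
#' for model comparison is computed from the maximum-likelihood refit of the
#' same structure (REML criteria are not comparable across fixed-effect
#' sets).
#'
#' @param records long-format data frame with at least `genotype` and `value`
#'   columns plus any fixed-effect covariates
#' @param fixed one-sided formula of fixed effects (e.g. `~ scenario`);
#'   `~ 1` for an intercept-only fixed part
#' @param response name of the response column
#' @param genotype name of the genotype column
#' @return object of class `mixed_fit`: `sigma_g2`, `sigma_r2`, `blups`
#'   (named vector), `bic`, `fixef`, `n_rep` (mean non-missing replicates per
#'   genotype, the Eq.-style n used for heritability), `boundary` (`TRUE`
#'   when the genetic variance is pinned at 0), `converged`, `fit` (the
#'   underlying lme4 object)
#' @export
fit_mixed <- function(records, fixed = ~ scenario, response = "value",
                      genotype = "genotype") {
  if (!all(c(response, genotype) %in% names(records)))
    stopf("records need '%s' and '%s' columns", response, genotype)
  vars <- all.vars(fixed)
  missing_vars <- setdiff(vars, names(records))
  if (length(missing_vars))
    stopf("fixed-effect columns not in records: %s",
          paste(missing_vars, collapse = ", "))
  records <- records[!is.na(records[[response]]), , drop = FALSE]
  if (length(unique(records[[genotype]])) < 2 || nrow(records) < 4)
    stopf("need >= 2 genotypes and >= 4 observations")
  fixed_rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  fml <- as.formula(sprintf("%s ~ %s + (1 | %s)", response, fixed_rhs,
                            genotype))
  fit <- suppressMessages(lme4::lmer(fml, data = records, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_g2 <- vc$vcov[vc$grp == genotype][1]
  sigma_r2 <- vc$vcov[vc$grp == "Residual"][1]
  conv <- length(fit@optinfo$conv$lme4) == 0
  boundary <- isTRUE(sigma_g2 < 1e-8 * max(sigma_r2, 1e-12))
  re <- lme4::ranef(fit)[[genotype]]
  blups <- setNames(re[["(Intercept)"]], rownames(re))
  n_rep <- mean(table(records[[genotype]]))
  fit_ml <- suppressMessages(lme4::refitML(fit))
  structure(list(sigma_g2 = sigma_g2, sigma_r2 = sigma_r2, blups = blups,
                 bic = BIC(fit_ml), fixef = lme4::fixef(fit),
                 intercept = unname(lme4::fixef(fit)["(Intercept)"]),
                 n_rep = n_rep, boundary = boundary, converged = conv,
                 formula = fml, fit = fit),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_fit> %s | sigmaG2 %.4g sigmaR2 %.4g | BIC(ML) %.1f | n %.2f%s\n",
    paste(deparse(x$formula), collapse = ""), x$sigma_g2, x$sigma_r2, x$bic,
    x$n_rep,
    if (x$boundary) " [sigmaG2 at boundary]" else ""))
  invisible(x)
}

#' Select the best mixed model by BIC
#'
#' Fits every candidate fixed-effect structure (each always alongside the
#' random genotype effect) and returns the fit with the lowest BIC, together
#' with the full BIC table.
#'
#' @inheritParams fit_mixed
#' @param candidates list of one-sided fixed-effect formulas
#' @return list `best` (a [fit_mixed()] result), `bic_table` (data frame of
#'   candidate vs BIC; failed candidates carry `NA`), `best_index`
#' @export
select_model <- function(records, candidates = list(~ scenario),
                         response = "value", genotype = "genotype") {
  if (length(candidates) < 1) stopf("need at least one candidate model")
  fits <- lapply(candidates, function(f) {
    tryCatch(fit_mixed(records, fixed = f, response = response,
                       genotype = genotype),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, character(1))
    stopf("all candidate models failed: %s", paste(unique(msgs),
                                                   collapse = " | "))
  }
  bics <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "mixed_fit")) f$bic else NA_real_, numeric(1)), NA_real_)
  tab <- data.frame(
    fixed = vapply(candidates, function(f)
      paste(deparse(f[[2]]), collapse = " "), character(1)),
    bic = bics, converged = ok)
  best <- which.min(bics)
  list(best = fits[[best]], bic_table = tab, best_index = best)
}

#' Broad-sense heritability of genotype means
#'
#' H2 = sigma_g2 / (sigma_g2 + sigma_r2 / n): the fraction of the variance of
#' genotype means (over n replicates) attributable to genetic variance.
#'
#' @param sigma_g2 genetic variance (>= 0)
#' @param sigma_r2 residual variance (>= 0; not both variances 0)
#' @param n replicates per genotype (>= 1; the mean number of non-missing
#'   replicates when the design is unbalanced)
#' @return H2 in \[0, 1\]
#' @export
heritability <- function(sigma_g2, sigma_r2, n) {
  chk_num(sigma_g2, "sigma_g2", lower = 0)
  chk_num(sigma_r2, "sigma_r2", lower = 0)
  chk_num(n, "n", lower = 1)
  if (sigma_g2 == 0 && sigma_r2 == 0)
    stopf("heritability undefined when both variance components are 0")
  sigma_g2 / (sigma_g2 + sigma_r2 / n)
}

#' @describeIn fit_mixed heritability of a fitted model via its variance
#'   components and mean replicate number
#' @param x a `mixed_fit`
#' @export
heritability_of <- function(x) {
  stopifnot(inherits(x, "mixed_fit"))
  heritability(x$sigma_g2, x$sigma_r2, x$n_rep)
}

#' Genotypic coefficient of variation
#'
#' Sample standard deviation of the genotypic values (BLUPs put back on the
#' trait scale by adding the model intercept / grand mean) divided by that
#' mean.
#'
#' @param genetic_values numeric vector of genotypic values on the trait
#'   scale (e.g. `blups + intercept`)
#' @param center the mean used as denominator; defaults to
#'   `mean(genetic_values)`; must be non-zero
#' @return coefficient of variation (dimensionless)
#' @export
genotypic_cv <- function(genetic_values, center = NULL) {
  if (is.null(center)) center <- mean(genetic_values)
  if (center == 0) stopf("zero mean: coefficient of variation undefined")
  sd(genetic_values) / center
}
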