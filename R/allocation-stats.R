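# Covariate-scaled storage allocation statistics and PLFA composition
# analysis. Storage and the structural-biomass covariate are modelled on the
# natural-log scale with a random intercept per sampling site; "allocation"
# is the storage predicted at the overall mean of the log covariate.

.build_mixed_frame <- function(dataset, response, covariate, term,
                               random_group, term_factor) {
  df <- if (inherits(dataset, "gradient_dataset")) dataset$samples else dataset
  for (nm in c(response, covariate, term, random_group)) {
    if (!nm %in% names(df)) stop("unknown field: ", nm, call. = FALSE)
  }
  keep <- stats::complete.cases(df[, c(response, covariate, term,
                                       random_group)])
  df <- df[keep, , drop = FALSE]
  if (any(df[[response]] <= 0) || any(df[[covariate]] <= 0)) {
    stop("validation error: response and covariate must be strictly ",
         "positive for log-scale analysis", call. = FALSE)
  }
  d <- data.frame(
    .ly = log(df[[response]]),
    .lx = log(df[[covariate]]),
    .site = factor(df[[random_group]])
  )
  if (term_factor) {
    d$.term <- factor(df[[term]])
    if (nlevels(d$.term) < 2L) {
      stop("degenerate-design error: grouping term has a single level",
           call. = FALSE)
    }
  } else {
    v <- df[[term]]
    if (!is.numeric(v)) stop("predictor must be numeric", call. = FALSE)
    if (stats::sd(v) == 0) {
      stop("degenerate-design error: constant predictor", call. = FALSE)
    }
    d$.term <- v
  }
  if (nlevels(d$.site) < 2L) {
    stop("validation error: need >= 2 sites for a random site intercept",
         call. = FALSE)
  }
  d
}

# Fit log(y) ~ log(x) + term + (1 | site) by ML, with a fixed-effects-only
# fallback when the mixed fit degenerates (e.g. zero residual variance in
# noise-free data). Returns the fit plus the nested-model likelihood-ratio
# test for the focal term.
.fit_lrt <- function(d) {
  singular <- FALSE
  fit <- tryCatch({
    f <- suppressMessages(lme4::lmer(
      .ly ~ .lx + .term + (1 | .site), data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    singular <- lme4::isSingular(f, tol = 1e-6)
    f
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- stats::lm(.ly ~ .lx + .term, data = d)
    singular <- TRUE
  }
  if (singular) {
    warning("singular fit: site variance estimated at (or near) zero",
            call. = FALSE)
  }
  if (inherits(fit, "lmerMod")) {
    reduced <- suppressMessages(stats::update(fit, . ~ . - .term))
    lrt <- stats::anova(reduced, fit)
    stat <- lrt$Chisq[2]
    df <- lrt$Df[2]
    p <- lrt$`Pr(>Chisq)`[2]
    # REML refit for variance components and coefficient SEs (ML variance
    # estimates are biased low at these sample sizes); the LRT above stays
    # on the ML pair.
    reml <- tryCatch(
      suppressMessages(stats::update(fit, REML = TRUE)),
      error = function(e) fit)
    vc <- as.data.frame(lme4::VarCorr(reml))
    site_var <- vc$vcov[vc$grp == ".site"][1]
    resid_var <- stats::sigma(reml)^2
    coefs <- summary(reml)$coefficients[, 1:2, drop = FALSE]
    # Satterthwaite per-coefficient df for interval construction
    # (cluster-level terms get close to the between-site df)
    coef_df <- tryCatch({
      lt <- lmerTest::as_lmerModLmerTest(reml)
      summary(lt)$coefficients[, "df"]
    }, error = function(e) rep(nrow(d) - nrow(coefs), nrow(coefs)))
    fit <- reml
  } else {
    reduced <- stats::lm(.ly ~ .lx, data = d)
    stat <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(reduced)))
    df <- length(stats::coef(fit)) - length(stats::coef(reduced))
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    site_var <- 0
    resid_var <- stats::sigma(fit)^2
    coefs <- summary(fit)$coefficients[, 1:2, drop = FALSE]
    coef_df <- rep(stats::df.residual(fit), nrow(coefs))
  }
  list(fit = fit, statistic = stat, df = df, p_value = p,
       site_variance = site_var, residual_variance = resid_var,
       coefficients = data.frame(term = rownames(coefs),
                                 estimate = coefs[, 1], se = coefs[, 2],
                                 df = pmax(as.numeric(coef_df), 1),
                                 row.names = NULL),
       df_resid = nrow(d) - nrow(coefs),
       singular = singular)
}

#' Fit a covariate-scaled storage allocation model
#'
#' Fits `log(response) ~ log(covariate) + group + (1 | site)` by maximum
#' likelihood. The covariate (total PLFA-C, or bacterial PLFA-C for PHB,
#' which is made only by prokaryotes) scales storage to structural biomass,
#' so the group contrasts measure allocation rather than abundance. The
#' group term is tested by a likelihood-ratio test against the nested model
#' without it; estimated marginal means are evaluated at the overall mean of
#' the log covariate.
#'
#' @param dataset replicate-level `gradient_dataset` or data frame.
#' @param response storage field name (strictly positive), e.g. `"nlfa_c"`.
#' @param covariate biomass covariate field, e.g. `"plfa_total"` (use
#'   `"plfa_bacterial"` for PHB).
#' @param group grouping field, e.g. `"soil_type"` or `"fertility_class"`.
#' @param random_group field holding the sampling-site identifier.
#' @return An `allocation_fit` list: fixed coefficients, variance
#'   components, `emm` (per-group estimated marginal mean on the log scale
#'   with 95% CI), `term_test` (LRT statistic, df, p), `n_obs`, `singular`.
#' @export
fit_allocation_model <- function(dataset, response, covariate, group,
                                 random_group = "site_id") {
  d <- .build_mixed_frame(dataset, response, covariate, group, random_group,
                          term_factor = TRUE)
  res <- .fit_lrt(d)
  em <- emmeans::emmeans(res$fit, ".term", at = list(.lx = mean(d$.lx)),
                         lmer.df = "asymptotic", data = d)
  es <- as.data.frame(em)
  ci_cols <- intersect(c("asymp.LCL", "lower.CL"), names(es))
  ci_cols2 <- intersect(c("asymp.UCL", "upper.CL"), names(es))
  emm <- data.frame(group = as.character(es$.term),
                    emmean = es$emmean, se = es$SE,
                    ci_low = es[[ci_cols[1]]], ci_high = es[[ci_cols2[1]]],
                    row.names = NULL)
  structure(list(
    response_name = response, covariate_name = covariate,
    group_name = group,
    fixed_coefficients = res$coefficients,
    site_variance = res$site_variance,
    residual_variance = res$residual_variance,
    emm = emm,
    term_test = list(statistic = res$statistic, df = res$df,
                     p_value = res$p_value),
    n_obs = nrow(d), df_resid = res$df_resid, singular = res$singular
  ), class = "allocation_fit")
}

#' Test a continuous predictor of storage allocation
#'
#' Same mixed model as [fit_allocation_model()] but with a continuous fixed
#' slope for the predictor (e.g. phosphodiesterase activity as an index of
#' belowground P demand, or the fungal:bacterial PLFA ratio as an index of
#' community composition). Returns the slope with a Wald 95% CI and the
#' likelihood-ratio p for the predictor term.
#'
#' @inheritParams fit_allocation_model
#' @param predictor numeric field used as the focal fixed effect.
#' @param log_predictor log-transform the predictor before fitting
#'   (default TRUE; activities and ratios are analysed on the log scale).
#' @return An `allocation_fit` list with `slope`, `slope_se`, `slope_ci`,
#'   and `term_test`.
#' @export
test_continuous_predictor <- function(dataset, response, covariate,
                                      predictor,
                                      random_group = "site_id",
                                      log_predictor = TRUE) {
  df <- if (inherits(dataset, "gradient_dataset")) dataset$samples else dataset
  if (log_predictor) {
    if (!predictor %in% names(df)) stop("unknown field: ", predictor,
                                        call. = FALSE)
    if (any(df[[predictor]] <= 0, na.rm = TRUE)) {
      stop("validation error: predictor must be positive for log transform",
           call. = FALSE)
    }
    df[[predictor]] <- log(df[[predictor]])
  }
  d <- .build_mixed_frame(df, response, covariate, predictor, random_group,
                          term_factor = FALSE)
  res <- .fit_lrt(d)
  co <- res$coefficients
  i <- match(".term", co$term)
  slope <- co$estimate[i]
  se <- co$se[i]
  tq <- stats::qt(0.975, co$df[i])
  structure(list(
    response_name = response, covariate_name = covariate,
    predictor_name = predictor,
    fixed_coefficients = co,
    site_variance = res$site_variance,
    residual_variance = res$residual_variance,
    slope = slope, slope_se = se,
    slope_ci = c(slope - tq * se, slope + tq * se),
    term_test = list(statistic = res$statistic, df = res$df,
                     p_value = res$p_value),
    n_obs = nrow(d), df_resid = res$df_resid, singular = res$singular
  ), class = "allocation_fit")
}

#' @export
print.allocation_fit <- function(x, ...) {
  cat("<allocation_fit> log(", x$response_name, ") ~ log(",
      x$covariate_name, ") + ",
      if (!is.null(x$group_name)) x$group_name else x$predictor_name,
      " + (1 | site), n = ", x$n_obs, "\n", sep = "")
  cat("  LRT: chisq = ", format(round(x$term_test$statistic, 3)),
      ", df = ", x$term_test$df,
      ", p = ", format.pval(x$term_test$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Relative log-transformed PLFA composition
#'
#' Converts marker amounts to relative molar quantities and applies the
#' `log_e(x + 1)` transform used before ordination/PERMANOVA. Markers are
#' ordered by sorted name so vectors from different samples align.
#'
#' @param amounts named numeric vector of marker amounts (nmol per g soil,
#'   non-negative, total > 0).
#' @return Named numeric vector `log(1 + amount / total)` in sorted-name
#'   order.
#' @export
relative_log_composition <- function(amounts) {
  if (is.null(names(amounts)) || any(!nzchar(names(amounts)))) {
    stop("validation error: marker amounts must be named", call. = FALSE)
  }
  if (any(is.na(amounts)) || any(amounts < 0)) {
    stop("validation error: marker amounts must be non-negative",
         call. = FALSE)
  }
  total <- sum(amounts)
  if (total <= 0) {
    stop("validation error: all-zero marker profile", call. = FALSE)
  }
  amounts <- amounts[order(names(amounts))]
  log1p(amounts / total)
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features; symmetric,
#' zero diagonal, entries in [0, 1].
#'
#' @param x numeric matrix (samples in rows) or list of equal-length
#'   non-negative vectors.
#' @return Full symmetric dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1L) {
      stop("validation error: vectors differ in length", call. = FALSE)
    }
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (any(x < 0)) stop("validation error: negative entries", call. = FALSE)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F on
#' among/within sums of squared dissimilarities) with free permutation of
#' sample labels. `p = (1 + #permuted F >= observed F) / (1 + n_permutations)`
#' and is bit-reproducible for a fixed seed.
#'
#' @param d dissimilarity matrix or `dist` object.
#' @param grouping group labels (>= 2 groups).
#' @param n_permutations number of permutations (>= 99; default 999).
#' @param seed integer seed (mandatory; the global RNG state is preserved).
#' @return A `permanova_result` list: `pseudo_f`, `r2`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, grouping, n_permutations = 999, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_permutations >= 99)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) {
    stop("degenerate-design error: a single group", call. = FALSE)
  }
  dd <- stats::as.dist(d)
  dat <- data.frame(.grp = grouping)
  fit <- withr::with_seed(seed,
    vegan::adonis2(dd ~ .grp, data = dat,
                   permutations = n_permutations, by = "terms"))
  structure(list(
    pseudo_f = fit$F[1],
    r2 = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_permutations = n_permutations,
    seed = seed
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("<permanova_result> pseudo-F = ", format(round(x$pseudo_f, 3)),
      ", R2 = ", format(round(x$r2, 3)),
      ", p = ", format(x$p_value), " (", x$n_permutations,
      " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
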