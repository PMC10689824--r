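# Seeded generators that emulate the statistical structure of the gradient
# (4 soil types x 2 sites x 3 replicates) and incubation (2 soils x 3
# treatments x 5 replicates) designs. All noise is lognormal on measured
# scales (normal on the log scale the analyses use), so generated
# concentrations are strictly positive by construction. Default magnitudes
# are calibrated to the packaged site-mean fixture.

#' Configuration for the synthetic gradient generator
#'
#' Defaults emulate the field design and the fixture's magnitudes: fertile
#' (basalt, shale) soils carry more structural biomass; infertile
#' (ironstone, sandstone) communities allocate 2.5-fold more C to NLFA and
#' PHB at a given biomass and have ~2.5-fold higher fungal:bacterial
#' ratios; phosphodiesterase activity predicts PHB allocation with slope
#' `phosphatase_link` on the log-log scale.
#'
#' @param seed integer root seed.
#' @param n_sites_per_type,n_reps_per_site design counts (default 2 and 3,
#'   giving 24 samples over 8 sites).
#' @param plfa_log_means named log-scale mean total PLFA (nmol/g) per soil
#'   type.
#' @param plfa_log_sd replicate SD of log total PLFA.
#' @param allocation_intercepts fertile-class log storage (ug C/g) at the
#'   grand-mean covariate, per compound.
#' @param allocation_contrast log-scale shift added for infertile classes,
#'   per compound (default log 2.5 for NLFA and PHB, 0 for trehalose).
#' @param covariate_slope slope of log storage on the log biomass covariate.
#' @param site_sd,residual_sd random site-intercept and residual SDs (log
#'   scale).
#' @param fungal_fraction per-class mean and sd of the fungal share of
#'   taxon-assigned PLFA.
#' @param phosphatase_link slope tying log PHB allocation to log
#'   phosphodiesterase activity.
#' @param phosphatase_log_mean,phosphatase_log_sd log-scale location and
#'   spread of phosphodiesterase activity (ug PNP/g/h).
#' @param chem_sdlog lognormal spread of the ancillary chemistry fields.
#' @param mbc_per_plfa,mbc_sdlog MBC as a multiple of total PLFA, with
#'   lognormal noise.
#' @param mbp_cp,mbp_sdlog per-class microbial C:P used to derive MBP.
#' @return A `gradient_config` list.
#' @export
gradient_config <- function(
    seed = 1L,
    n_sites_per_type = 2L,
    n_reps_per_site = 3L,
    plfa_log_means = c(basalt = log(55), shale = log(44),
                       ironstone = log(18), sandstone = log(20)),
    plfa_log_sd = 0.3,
    allocation_intercepts = c(nlfa_c = log(13), phb_c = log(20),
                              trehalose_c = log(4)),
    allocation_contrast = c(nlfa_c = log(2.5), phb_c = log(2.5),
                            trehalose_c = 0),
    covariate_slope = 1,
    site_sd = 0.1,
    residual_sd = 0.2,
    fungal_fraction = list(fertile = c(mean = 0.20, sd = 0.02),
                           infertile = c(mean = 0.38, sd = 0.03)),
    phosphatase_link = 0.8,
    phosphatase_log_mean = log(250),
    phosphatase_log_sd = 0.3,
    chem_sdlog = 0.2,
    mbc_per_plfa = 8.5,
    mbc_sdlog = 0.15,
    mbp_cp = c(fertile = 15, infertile = 60),
    mbp_sdlog = 0.3) {
  stopifnot(n_sites_per_type >= 1, n_reps_per_site >= 1,
            site_sd >= 0, residual_sd >= 0, plfa_log_sd >= 0,
            all(vapply(fungal_fraction, function(f)
              f[["mean"]] > 0 && f[["mean"]] < 1 && f[["sd"]] >= 0,
              logical(1))))
  structure(as.list(environment()), class = "gradient_config")
}

#' Zero every noise component of a synthetic configuration
#'
#' Sets all SD-type fields to zero, leaving the deterministic mean
#' structure; useful for exactness checks and as the noise-free limit.
#'
#' @param config a `gradient_config` or `incubation_config`.
#' @return The configuration with all SD fields set to 0.
#' @export
zero_noise <- function(config) {
  sd_fields <- intersect(
    c("plfa_log_sd", "site_sd", "residual_sd", "phosphatase_log_sd",
      "chem_sdlog", "mbc_sdlog", "mbp_sdlog",
      "noise_sdlog", "resp_day_sdlog"),
    names(config))
  for (f in sd_fields) config[[f]] <- 0
  if (!is.null(config$fungal_fraction)) {
    config$fungal_fraction <- lapply(config$fungal_fraction, function(f) {
      f[["sd"]] <- 0; f
    })
  }
  config
}

# Deterministic covariate centres implied by the configuration (not by any
# realised data), so the noise-free limit reproduces intercepts exactly.
.covariate_centres <- function(config) {
  lp <- mean(config$plfa_log_means)
  f_mean <- mean(vapply(config$fungal_fraction, `[[`, 0, "mean"))
  c(total = lp, bacterial = lp + log(0.85 * (1 - f_mean)))
}

# Ancillary chemistry means per fertility class, calibrated to the fixture.
.chem_means <- list(
  fertile = c(total_organic_c = 0.035, soluble_organic_c = 75,
              total_n = 2300, total_p = 300, mehlich_po4 = 1.6,
              glucosidase = 220),
  infertile = c(total_organic_c = 0.013, soluble_organic_c = 58,
                total_n = 890, total_p = 95, mehlich_po4 = 0.11,
                glucosidase = 100)
)

#' Generate a replicate-level synthetic gradient dataset
#'
#' Draws, in a documented fixed order under one root seed: (1) per-site
#' random intercepts per compound, (2) replicate log total PLFA around the
#' soil-type means, (3) fungal fractions, (4) log phosphodiesterase,
#' (5) per-compound residuals, then builds
#' `log storage = intercept(class) + slope * (log covariate - centre) +
#' site + residual`, with the PHB covariate being bacterial PLFA and a
#' `phosphatase_link * (log PD - centre)` term added for PHB. Ancillary
#' chemistry is lognormal around per-class means. Output is bit-identical
#' for identical (config, seed).
#'
#' @param config a `gradient_config`.
#' @param seed optional override of `config$seed`.
#' @return A `gradient_dataset` at replicate level.
#' @export
generate_gradient <- function(config = gradient_config(), seed = NULL) {
  stopifnot(inherits(config, "gradient_config"))
  seed <- if (is.null(seed)) config$seed else seed
  withr::with_seed(as.integer(seed), .generate_gradient_impl(config))
}

.generate_gradient_impl <- function(cf) {
  types <- names(cf$plfa_log_means)
  compounds <- names(cf$allocation_intercepts)
  design <- expand.grid(rep = seq_len(cf$n_reps_per_site),
                        site = seq_len(cf$n_sites_per_type),
                        soil_type = types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(match(design$soil_type, types), design$site,
                         design$rep), ]
  n <- nrow(design)
  site_id <- paste0(design$soil_type, "_site", design$site)
  sites <- unique(site_id)
  fclass <- ifelse(design$soil_type %in% .fertile_types,
                   "fertile", "infertile")

  # (1) site intercepts
  site_eff <- matrix(stats::rnorm(length(sites) * length(compounds),
                                  0, cf$site_sd),
                     nrow = length(sites),
                     dimnames = list(sites, compounds))
  # (2) log total PLFA
  lplfa <- stats::rnorm(n, cf$plfa_log_means[design$soil_type],
                        cf$plfa_log_sd)
  # (3) fungal fraction of taxon-assigned PLFA
  ff_mean <- vapply(cf$fungal_fraction[fclass], `[[`, 0, "mean")
  ff_sd <- vapply(cf$fungal_fraction[fclass], `[[`, 0, "sd")
  ffrac <- pmin(pmax(stats::rnorm(n, ff_mean, ff_sd), 0.02), 0.9)
  # (4) log phosphodiesterase
  lpd <- stats::rnorm(n, cf$phosphatase_log_mean, cf$phosphatase_log_sd)
  # (5) storage residuals
  resid <- matrix(stats::rnorm(n * length(compounds), 0, cf$residual_sd),
                  nrow = n, dimnames = list(NULL, compounds))

  plfa_total <- exp(lplfa)
  plfa_bacterial <- 0.85 * (1 - ffrac) * plfa_total
  plfa_fungal <- 0.85 * ffrac * plfa_total
  centres <- .covariate_centres(cf)

  storage <- sapply(compounds, function(cmp) {
    lcov <- if (cmp == "phb_c") log(plfa_bacterial) else lplfa
    centre <- if (cmp == "phb_c") centres[["bacterial"]] else
      centres[["total"]]
    ls <- cf$allocation_intercepts[[cmp]] +
      cf$allocation_contrast[[cmp]] * (fclass == "infertile") +
      cf$covariate_slope * (lcov - centre) +
      site_eff[site_id, cmp] + resid[, cmp]
    if (cmp == "phb_c") {
      ls <- ls + cf$phosphatase_link * (lpd - cf$phosphatase_log_mean)
    }
    exp(ls)
  })

  chem <- sapply(names(.chem_means$fertile), function(v) {
    mu <- vapply(.chem_means[fclass], `[[`, 0, v)
    mu * exp(stats::rnorm(n, 0, cf$chem_sdlog))
  })
  mbc <- cf$mbc_per_plfa * plfa_total * exp(stats::rnorm(n, 0, cf$mbc_sdlog))
  mbp <- mbc / (cf$mbp_cp[fclass] * exp(stats::rnorm(n, 0, cf$mbp_sdlog)))
  pmono <- 2.2 * exp(lpd) * exp(stats::rnorm(n, 0, cf$chem_sdlog))

  df <- data.frame(
    sample_id = paste0(site_id, "_r", design$rep),
    site_id = site_id,
    soil_type = design$soil_type,
    fertility_class = fclass,
    total_organic_c = pmin(chem[, "total_organic_c"], 0.6),
    soluble_organic_c = chem[, "soluble_organic_c"],
    total_n = chem[, "total_n"],
    total_p = chem[, "total_p"],
    mehlich_po4 = chem[, "mehlich_po4"],
    mbc = mbc,
    mbp = mbp,
    plfa_total = plfa_total,
    plfa_bacterial = plfa_bacterial,
    plfa_fungal = plfa_fungal,
    nlfa_c = storage[, "nlfa_c"],
    phb_c = storage[, "phb_c"],
    trehalose_c = storage[, "trehalose_c"],
    phosphomonoesterase = pmono,
    phosphodiesterase = exp(lpd),
    glucosidase = chem[, "glucosidase"],
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  gradient_dataset(df, level = "replicate")
}

#' Configuration for the synthetic incubation generator
#'
#' Defaults mirror the experimental design (2 soils x {control, +glucose-C,
#' +PO4-P} x 5 replicates; respiration measured at days 0, 1, 2, 3, 4, 8,
#' 10, day 0 pre-treatment) and its reported outcomes: control cumulative
#' respiration of 454 (basalt) and 201 (sandstone) ug CO2-C/g over 10 days;
#' glucose multiplies MBC x4, raises respiration, fungal PLFA, NLFA and PHB
#' in both soils; phosphate doubles respiration and raises bacterial PLFA
#' in the sandstone soil only, and leaves NLFA and PHB unchanged.
#'
#' @param seed integer root seed.
#' @param n_reps replicates per soil x treatment cell.
#' @param days measurement days (strictly increasing from 0).
#' @param control_respiration_total per-soil target cumulative control
#'   respiration, ug CO2-C/g over the incubation.
#' @param resp_shape relative respiration-rate profile over `days`
#'   (rescaled so the control integral hits its target).
#' @param control_pools per-soil control means of the day-10 pools
#'   (ug C/g soil).
#' @param effects `effects[[treatment]][[soil]][variable]` multiplicative
#'   treatment effects; `"respiration"` multiplies post-treatment rates.
#' @param noise_sdlog lognormal replicate noise on pools and jar-level
#'   respiration.
#' @param resp_day_sdlog extra lognormal per-day measurement noise on
#'   respiration rates.
#' @return An `incubation_config` list.
#' @export
incubation_config <- function(
    seed = 1L,
    n_reps = 5L,
    days = c(0, 1, 2, 3, 4, 8, 10),
    control_respiration_total = c(basalt = 454, sandstone = 201),
    resp_shape = c(1.2, 1.1, 1.05, 1, 1, 0.95, 0.9),
    control_pools = list(
      basalt = c(mbc = 553, plfa_total_c = 13.4, plfa_fungal_c = 1.9,
                 plfa_bacterial_c = 8.5, nlfa_c = 22.3, phb_c = 33.4),
      sandstone = c(mbc = 235, plfa_total_c = 4.8, plfa_fungal_c = 1.2,
                    plfa_bacterial_c = 1.9, nlfa_c = 20.5, phb_c = 41.0)),
    effects = list(
      glucose_c = list(
        basalt = c(respiration = 6, mbc = 4, plfa_total_c = 2.5,
                   plfa_fungal_c = 3, plfa_bacterial_c = 1,
                   nlfa_c = 2.5, phb_c = 2.5),
        sandstone = c(respiration = 6, mbc = 4, plfa_total_c = 2.5,
                      plfa_fungal_c = 3, plfa_bacterial_c = 1,
                      nlfa_c = 2.5, phb_c = 2.5)),
      po4_p = list(
        basalt = c(respiration = 1, mbc = 1, plfa_total_c = 1,
                   plfa_fungal_c = 1, plfa_bacterial_c = 1,
                   nlfa_c = 1, phb_c = 1),
        sandstone = c(respiration = 2, mbc = 1.1, plfa_total_c = 1.3,
                      plfa_fungal_c = 1, plfa_bacterial_c = 1.8,
                      nlfa_c = 1, phb_c = 1))),
    noise_sdlog = 0.12,
    resp_day_sdlog = 0.05) {
  stopifnot(n_reps >= 1, days[1] == 0, !is.unsorted(days, strictly = TRUE),
            length(resp_shape) == length(days),
            noise_sdlog >= 0, resp_day_sdlog >= 0)
  structure(as.list(environment()), class = "incubation_config")
}

#' Generate a synthetic incubation dataset
#'
#' For each jar (soil x treatment x replicate, in fixed order) draws one
#' lognormal jar factor, per-day respiration measurement noise, and one
#' lognormal draw per pool. Control respiration-rate profiles are scaled so
#' the expected cumulative control respiration equals the configured
#' per-soil target; treatment rate multipliers apply to days after day 0
#' (rates at day 0 are measured before treatment application).
#'
#' @param config an `incubation_config`.
#' @param seed optional override of `config$seed`.
#' @return An `incubation_dataset`: list with `respiration` (long data
#'   frame: soil, treatment, replicate, day, rate) and `pools` (one row per
#'   jar, one column per day-10 pool).
#' @export
generate_incubation <- function(config = incubation_config(), seed = NULL) {
  stopifnot(inherits(config, "incubation_config"))
  seed <- if (is.null(seed)) config$seed else seed
  withr::with_seed(as.integer(seed), .generate_incubation_impl(config))
}

.generate_incubation_impl <- function(cf) {
  soils <- names(cf$control_pools)
  treatments <- c("control", names(cf$effects))
  pool_vars <- names(cf$control_pools[[1]])
  resp_rows <- list(); pool_rows <- list()
  for (s in soils) {
    base_rate <- cf$resp_shape /
      pracma::trapz(cf$days, cf$resp_shape) *
      cf$control_respiration_total[[s]]
    for (tr in treatments) {
      eff <- if (tr == "control") {
        stats::setNames(rep(1, length(pool_vars) + 1L),
                        c("respiration", pool_vars))
      } else cf$effects[[tr]][[s]]
      for (r in seq_len(cf$n_reps)) {
        jar <- exp(stats::rnorm(1, 0, cf$noise_sdlog))
        day_noise <- exp(stats::rnorm(length(cf$days), 0,
                                      cf$resp_day_sdlog))
        mult <- ifelse(cf$days > 0, eff[["respiration"]], 1)
        rate <- base_rate * mult * jar * day_noise
        resp_rows[[length(resp_rows) + 1L]] <- data.frame(
          soil = s, treatment = tr, replicate = r,
          day = cf$days, rate = rate, stringsAsFactors = FALSE)
        pool_noise <- exp(stats::rnorm(length(pool_vars), 0,
                                       cf$noise_sdlog))
        vals <- cf$control_pools[[s]] * eff[pool_vars] * pool_noise
        pool_rows[[length(pool_rows) + 1L]] <- data.frame(
          soil = s, treatment = tr, replicate = r,
          as.list(stats::setNames(vals, pool_vars)),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(respiration = do.call(rbind, resp_rows),
                 pools = do.call(rbind, pool_rows)),
            class = "incubation_dataset")
}

#' @export
print.incubation_dataset <- function(x, ...) {
  cat("<incubation_dataset> ", nrow(x$pools), " jars, ",
      length(unique(x$respiration$day)), " respiration time points\n",
      sep = "")
  invisible(x)
}

#' Repeated generate-and-analyse recovery experiments
#'
#' Repeats a generate/analyse cycle with incremented seeds and summarises
#' estimator bias, CI coverage, and rejection (or type-I error) rate for
#' one analysis stage. Fully reproducible from (config seed, n_replicates).
#'
#' @param n_replicates number of seeded replicates (>= 50 recommended;
#'   smaller values allowed for smoke runs).
#' @param config a `gradient_config` (for `allocation_lrt`, `slope`,
#'   `permanova`) or `incubation_config` (for `rr_null_coverage`).
#' @param analysis one of:
#'   \describe{
#'     \item{`allocation_lrt`}{NLFA allocation contrast between fertility
#'       classes: LRT rejection rate, bias and coverage of the contrast.}
#'     \item{`slope`}{continuous phosphodiesterase predictor of PHB
#'       allocation: bias/coverage/rejection for the configured slope.}
#'     \item{`permanova`}{type-I error of PERMANOVA on structure-free
#'       composition profiles labelled by soil type.}
#'     \item{`rr_null_coverage`}{coverage of response-ratio CIs over the
#'       soil x treatment x variable cells whose configured multiplier
#'       is 1 (true null effects).}
#'   }
#' @param alpha nominal test level.
#' @param n_permutations permutations per PERMANOVA.
#' @return A list with `summary` (one-row data frame: analysis,
#'   n_replicates, rejection_rate, bias, coverage) and `estimates`
#'   (per-replicate values where applicable).
#' @export
recovery_experiment <- function(n_replicates, config,
                                analysis = c("allocation_lrt", "slope",
                                             "permanova",
                                             "rr_null_coverage"),
                                alpha = 0.05, n_permutations = 199) {
  analysis <- match.arg(analysis)
  stopifnot(n_replicates >= 1)
  seeds <- config$seed + seq_len(n_replicates)
  est <- rep(NA_real_, n_replicates)
  p <- rep(NA_real_, n_replicates)
  covered <- rep(NA, n_replicates)
  truth <- NA_real_

  if (analysis == "allocation_lrt") {
    truth <- config$allocation_contrast[["nlfa_c"]]
    for (i in seq_len(n_replicates)) {
      g <- generate_gradient(config, seed = seeds[i])
      fit <- suppressWarnings(fit_allocation_model(
        g, "nlfa_c", "plfa_total", "fertility_class"))
      co <- fit$fixed_coefficients
      j <- grep("^\\.term", co$term)
      est[i] <- co$estimate[j]
      tq <- stats::qt(0.975, co$df[j])
      ci <- est[i] + c(-tq, tq) * co$se[j]
      covered[i] <- ci[1] <= truth && truth <= ci[2]
      p[i] <- fit$term_test$p_value
    }
  } else if (analysis == "slope") {
    truth <- config$phosphatase_link
    for (i in seq_len(n_replicates)) {
      g <- generate_gradient(config, seed = seeds[i])
      fit <- suppressWarnings(test_continuous_predictor(
        g, "phb_c", "plfa_bacterial", "phosphodiesterase"))
      est[i] <- fit$slope
      covered[i] <- fit$slope_ci[1] <= truth && truth <= fit$slope_ci[2]
      p[i] <- fit$term_test$p_value
    }
  } else if (analysis == "permanova") {
    n <- length(config$plfa_log_means) * config$n_sites_per_type *
      config$n_reps_per_site
    groups <- rep(names(config$plfa_log_means),
                  each = config$n_sites_per_type * config$n_reps_per_site)
    for (i in seq_len(n_replicates)) {
      m <- withr::with_seed(seeds[i],
        matrix(stats::rlnorm(n * 12, 0, 0.5), nrow = n))
      comp <- t(apply(m, 1, function(v) {
        relative_log_composition(stats::setNames(v, sprintf("m%02d",
                                                            seq_along(v))))
      }))
      res <- permanova(bray_curtis_matrix(comp), groups,
                       n_permutations = n_permutations, seed = seeds[i])
      p[i] <- res$p_value
    }
  } else { # rr_null_coverage
    null_cells <- list()
    for (tr in names(config$effects)) {
      for (s in names(config$effects[[tr]])) {
        e <- config$effects[[tr]][[s]]
        for (v in names(e)) {
          if (e[[v]] == 1 && v != "respiration") {
            null_cells[[length(null_cells) + 1L]] <- c(s, tr, v)
          }
        }
      }
    }
    cov_counts <- 0L; tot <- 0L
    for (i in seq_len(n_replicates)) {
      inc <- generate_incubation(config, seed = seeds[i])
      eff <- incubation_effect_sizes(inc)
      for (cell in null_cells) {
        row <- eff[eff$soil == cell[1] & eff$treatment == cell[2] &
                     eff$variable == cell[3], ]
        cov_counts <- cov_counts + (row$ci_low <= 0 && 0 <= row$ci_high)
        tot <- tot + 1L
      }
    }
    return(list(summary = data.frame(
      analysis = analysis, n_replicates = n_replicates,
      rejection_rate = 1 - cov_counts / tot, bias = NA_real_,
      coverage = cov_counts / tot), estimates = NULL))
  }

  list(summary = data.frame(
    analysis = analysis,
    n_replicates = n_replicates,
    rejection_rate = mean(p < alpha, na.rm = TRUE),
    bias = if (all(is.na(est))) NA_real_ else mean(est) - truth,
    coverage = if (all(is.na(covered))) NA_real_ else mean(covered)
  ), estimates = data.frame(estimate = est, p_value = p,
                            covered = covered))
}

#' Write / read a synthetic configuration as YAML
#'
#' @param config a `gradient_config` or `incubation_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration with its class restored.
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become maps (yaml sequences drop names)
  listify <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else if (is.list(x)) lapply(x, listify)
    else x
  }
  obj <- listify(unclass(config))
  obj$.config_class <- class(config)[1]
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.config_class
  obj$.config_class <- NULL
  # yaml reads named numeric vectors back as lists; restore them
  restore <- function(x) {
    if (is.list(x) && length(x) > 0 &&
        all(vapply(x, function(e) is.numeric(e) && length(e) == 1L,
                   logical(1))) &&
        !is.null(names(x))) {
      unlist(x)
    } else if (is.list(x)) {
      lapply(x, restore)
    } else x
  }
  obj <- lapply(obj, restore)
  defaults <- if (identical(cls, "incubation_config")) {
    incubation_config()
  } else {
    gradient_config()
  }
  out <- utils::modifyList(unclass(defaults), obj)
  structure(out, class = cls)
}
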