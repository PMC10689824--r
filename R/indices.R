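# Derived indices used throughout the gradient analyses.

#' Microbial biomass C from a fumigation flush
#'
#' Converts a chloroform-fumigation C flush to microbial biomass C using the
#' standard vacuum-infiltration correction factor k = 2.64 (MBC = flush /
#' extractability, i.e. flush x 2.64 with the factor expressed as a
#' multiplier).
#'
#' @param flush_c C flush, ug C per g soil (non-negative).
#' @param k correction factor (default 2.64).
#' @return Microbial biomass C, ug C per g soil.
#' @export
mbc_from_flush <- function(flush_c, k = 2.64) {
  if (any(is.na(flush_c)) || any(flush_c < 0)) {
    stop("validation error: flush_c must be non-negative", call. = FALSE)
  }
  flush_c * k
}

#' Normalise a storage pool to soil organic C
#'
#' @param storage_c storage compound content, ug C per g soil.
#' @param total_organic_c total organic C as a fraction of dry mass (> 0).
#' @return Storage content per unit SOC, ug C per g SOC.
#' @export
per_soc_normalise <- function(storage_c, total_organic_c) {
  if (any(is.na(total_organic_c)) || any(total_organic_c <= 0)) {
    stop("validation error: total_organic_c must be > 0", call. = FALSE)
  }
  storage_c / total_organic_c
}

#' Convert a mass-basis C:P ratio to a molar basis
#'
#' Multiplies by M_P / M_C. Defaults use the integer atomic masses 31 (P) and
#' 12 (C), which match the published conversions within rounding; exact
#' masses can be supplied.
#'
#' @param cp_mass mass-basis C:P ratio (non-negative).
#' @param m_c,m_p atomic masses of C and P.
#' @return Molar-basis C:P ratio.
#' @export
cp_mass_to_molar <- function(cp_mass, m_c = 12, m_p = 31) {
  if (any(is.na(cp_mass)) || any(cp_mass < 0)) {
    stop("validation error: cp_mass must be non-negative", call. = FALSE)
  }
  cp_mass * (m_p / m_c)
}

#' Fungal to bacterial PLFA ratio
#'
#' Ratio of fungal to bacterial PLFA content; both inputs are molar
#' quantities (nmol per g soil) so the ratio is already on a molar basis.
#'
#' @param plfa_fungal,plfa_bacterial PLFA contents, nmol per g soil. May be
#'   vectors; alternatively pass a sample data frame via `sample`.
#' @param sample optional data frame (or `gradient_dataset` samples) with
#'   `plfa_fungal` and `plfa_bacterial` columns, used when the first two
#'   arguments are missing.
#' @return Dimensionless fungal:bacterial ratio.
#' @export
fungal_bacterial_ratio <- function(plfa_fungal, plfa_bacterial,
                                   sample = NULL) {
  if (!is.null(sample)) {
    if (inherits(sample, "gradient_dataset")) sample <- sample$samples
    plfa_fungal <- sample$plfa_fungal
    plfa_bacterial <- sample$plfa_bacterial
  }
  if (any(is.na(plfa_bacterial)) || any(plfa_bacterial <= 0)) {
    stop("validation error: plfa_bacterial must be > 0", call. = FALSE)
  }
  plfa_fungal / plfa_bacterial
}

#' Range statistics over a dataset field
#'
#' Returns the minimum, maximum, or mean of a field over non-missing values,
#' together with the sample id attaining it (ties broken by input order; the
#' mean reports no attaining id).
#'
#' @param dataset a `gradient_dataset` or sample data frame.
#' @param field column name.
#' @param statistic one of `"min"`, `"max"`, `"mean"`.
#' @return List with `value`, `sample_id` (`NA` for the mean), and `n` used.
#' @export
summarise_range <- function(dataset, field,
                            statistic = c("min", "max", "mean")) {
  statistic <- match.arg(statistic)
  df <- if (inherits(dataset, "gradient_dataset")) dataset$samples else dataset
  if (!field %in% names(df)) {
    stop("unknown field: ", field, call. = FALSE)
  }
  v <- df[[field]]
  keep <- !is.na(v)
  if (!any(keep)) stop("empty-data error: all values missing for ", field,
                       call. = FALSE)
  v <- v[keep]
  ids <- df$sample_id[keep]
  switch(statistic,
    min = {
      i <- which.min(v)
      list(value = v[i], sample_id = ids[i], n = length(v))
    },
    max = {
      i <- which.max(v)
      list(value = v[i], sample_id = ids[i], n = length(v))
    },
    mean = list(value = mean(v), sample_id = NA_character_, n = length(v))
  )
}

#' Total storage C as a fraction of microbial biomass C
#'
#' Sums the three storage pools (NLFA, PHB, trehalose; a missing trehalose
#' counts as zero) and divides by MBC.
#'
#' @param sample data frame (or `gradient_dataset`) with `nlfa_c`, `phb_c`,
#'   `trehalose_c` and `mbc` columns.
#' @return Fraction(s) of MBC held as storage C.
#' @export
storage_fraction_of_mbc <- function(sample) {
  if (inherits(sample, "gradient_dataset")) sample <- sample$samples
  if (any(is.na(sample$mbc)) || any(sample$mbc <= 0)) {
    stop("validation error: mbc must be > 0", call. = FALSE)
  }
  treh <- sample$trehalose_c
  if (is.null(treh)) treh <- rep(0, nrow(sample))
  treh[is.na(treh)] <- 0
  (sample$nlfa_c + sample$phb_c + treh) / sample$mbc
}
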