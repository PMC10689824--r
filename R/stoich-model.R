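# Storage-explicit stoichiometric model of microbial C-P growth.
#
# A homogeneous community takes up organic C and inorganic P in proportion to
# their availabilities, assimilates C into structural biomass with growth
# efficiency e, and partitions the remainder among growth-coupled
# respiration, intracellular storage, and overflow respiration. Three
# storage strategies are compared: "none" (no storage), "reserve"
# (a constitutive fraction f_res of acquired C goes to storage, traded off
# against growth), and "surplus" (C in excess of P-allowed growth is stored,
# up to a cap phi_max of uptake, instead of being lost to overflow).

#' Stoichiometric model parameters
#'
#' @param e growth efficiency: fraction of the C allocated to growth that
#'   becomes structural biomass, in (0, 1). Default 0.45.
#' @param r_b structural microbial biomass C:P ratio, mass basis (> 0).
#' @param f_res constitutive reserve fraction of C uptake, in [0, 1).
#'   Default 0.15.
#' @param phi_max cap on surplus storage as a fraction of C uptake, in
#'   (0, 1]. Default 1.
#' @param baseline_cp baseline substrate organic C : inorganic P ratio
#'   (mass basis) used to anchor gradient sweeps and the uptake affinities.
#' @return A `model_params` list.
#' @seealso [soil_params()] for the two study-soil parameterisations.
#' @export
model_params <- function(e = 0.45, r_b, f_res = 0.15, phi_max = 1,
                         baseline_cp) {
  stopifnot(e > 0, e < 1, r_b > 0, f_res >= 0, f_res < 1,
            phi_max > 0, phi_max <= 1, baseline_cp > 0)
  structure(list(e = e, r_b = r_b, f_res = f_res, phi_max = phi_max,
                 baseline_cp = baseline_cp),
            class = "model_params")
}

#' Default parameterisations for the two incubation soils
#'
#' The basalt soil uses the published site-mean microbial C:P (mass) of 29.4
#' and extractable substrate C:P of 59.6; the sandstone soil uses 78.7 and
#' 636. With the default growth efficiency e = 0.45 the basalt baseline sits
#' left of its threshold element ratio (C-limited) and the sandstone baseline
#' right of its TER (P-limited).
#'
#' @param soil `"basalt"` or `"sandstone"`.
#' @param ... overrides passed on to [model_params()].
#' @return A `model_params` list.
#' @export
soil_params <- function(soil = c("basalt", "sandstone"), ...) {
  soil <- match.arg(soil)
  defaults <- switch(soil,
    basalt = list(r_b = 29.4, baseline_cp = 59.6),
    sandstone = list(r_b = 78.7, baseline_cp = 636)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_params, args)
}

#' Threshold element ratio
#'
#' The substrate C:P at which growth switches between C- and P-limitation:
#' the structural biomass C:P divided by the growth efficiency, r_B / e.
#'
#' @param params a `model_params` object.
#' @return Dimensionless TER (mass basis).
#' @export
threshold_element_ratio <- function(params) {
  params$r_b / params$e
}

#' Classify growth limitation at a substrate C:P ratio
#'
#' P-limited iff the substrate C:P exceeds the TER; the boundary value is
#' classified C-limited (deterministic tie-break; all fluxes are continuous
#' there, so the label is cosmetic).
#'
#' @param cp_ratio substrate organic C : inorganic P ratio (> 0).
#' @param params a `model_params` object.
#' @return `"C_limited"` or `"P_limited"` (vectorised over `cp_ratio`).
#' @export
classify_limitation <- function(cp_ratio, params) {
  stopifnot(all(cp_ratio > 0))
  ifelse(cp_ratio > threshold_element_ratio(params),
         "P_limited", "C_limited")
}

#' Substrate availability state
#'
#' Relative availabilities of organic C and inorganic P. At `c_avail =
#' p_avail = 1` the uptake C:P equals the parameterisation's
#' `baseline_cp` (uptake is linear in availability with equal affinities,
#' scaled so baseline availabilities reproduce the baseline substrate C:P).
#'
#' @param c_avail,p_avail relative availabilities (> 0).
#' @return A `substrate_state` list.
#' @export
substrate_state <- function(c_avail = 1, p_avail = 1) {
  stopifnot(c_avail > 0, p_avail > 0)
  structure(list(c_avail = c_avail, p_avail = p_avail),
            class = "substrate_state")
}

#' Simulate the flux partitioning at one substrate state
#'
#' Computes C and P uptake, growth, respiration (growth-coupled plus
#' overflow), and net storage for one storage strategy:
#' \itemize{
#'   \item uptake: `u_c = c_avail`; `u_p = p_avail / baseline_cp`, so the
#'     uptake C:P is `baseline_cp * c_avail / p_avail`;
#'   \item growth-side C supply: `(1 - f_res) * u_c` under the reserve
#'     strategy, otherwise `u_c`;
#'   \item growth `G = min(e * supply, r_b * u_p)` (C-allowed vs P-allowed),
#'     with the limitation flag set accordingly (tie classified C-limited);
#'   \item storage: reserve `f_res * u_c`; surplus
#'     `min(u_c - G/e, phi_max * u_c)` when P-limited, else 0; none 0;
#'   \item overflow `= max(0, u_c - G/e - storage)`; respiration
#'     `= (1 - e)/e * G + overflow`.
#' }
#' C mass balance `u_c = G + respiration + storage` holds to machine
#' precision.
#'
#' @param mode `"none"`, `"reserve"`, or `"surplus"`.
#' @param params a `model_params` object.
#' @param substrate a `substrate_state` (or list with `c_avail`, `p_avail`).
#' @return A `model_fluxes` list: `u_c`, `u_p`, `growth`, `respiration`,
#'   `storage_net`, `overflow`, `limitation`, `mode`, `cp_ratio`.
#' @export
simulate_point <- function(mode = c("none", "reserve", "surplus"), params,
                           substrate = substrate_state()) {
  mode <- match.arg(mode)
  e <- params$e
  u_c <- substrate$c_avail
  u_p <- substrate$p_avail / params$baseline_cp
  cp <- u_c / u_p

  supply <- if (mode == "reserve") (1 - params$f_res) * u_c else u_c
  g_c <- e * supply
  g_p <- params$r_b * u_p
  growth <- min(g_c, g_p)
  limitation <- if (g_p < g_c) "P_limited" else "C_limited"

  storage_net <- switch(mode,
    none = 0,
    reserve = params$f_res * u_c,
    surplus = if (limitation == "P_limited") {
      min(u_c - growth / e, params$phi_max * u_c)
    } else 0
  )
  overflow <- max(0, u_c - growth / e - storage_net)
  respiration <- (1 - e) / e * growth + overflow

  fluxes <- list(u_c = u_c, u_p = u_p, growth = growth,
                 respiration = respiration, storage_net = storage_net,
                 overflow = overflow, limitation = limitation, mode = mode,
                 cp_ratio = cp)
  if (any(unlist(fluxes[c("growth", "respiration", "storage_net",
                          "overflow")]) < -1e-12)) {
    stop("model-consistency error: negative flux", call. = FALSE)
  }
  structure(fluxes, class = "model_fluxes")
}

#' Carbon use efficiency of a simulated point
#'
#' Fraction of C uptake retained in biomass: growth alone, or growth plus
#' net storage when storage counts as retained C.
#'
#' @param fluxes a `model_fluxes` object with `u_c > 0`.
#' @param count_storage logical; include `storage_net` in the numerator.
#' @return CUE as a fraction of C uptake.
#' @export
cue <- function(fluxes, count_storage = FALSE) {
  stopifnot(fluxes$u_c > 0)
  (fluxes$growth + if (count_storage) fluxes$storage_net else 0) / fluxes$u_c
}

#' Sweep the model across a substrate C:P gradient
#'
#' Emulates the experimental manipulation: ratios above the baseline are
#' reached by increasing organic C at fixed P (`c_avail = r / baseline_cp`,
#' `p_avail = 1`), ratios below it by increasing inorganic P at fixed C
#' (`c_avail = 1`, `p_avail = baseline_cp / r`). All fluxes are normalised
#' by the C uptake rate at the baseline point, which is always included in
#' the grid.
#'
#' @param mode storage strategy, or `"all"` for all three.
#' @param params a `model_params` object.
#' @param cp_min,cp_max sweep range; must bracket `baseline_cp`.
#' @param n_points number of grid points (>= 3); the grid is logarithmic in
#'   C:P (the gradient spans orders of magnitude).
#' @return A `gradient_sweep` list: `curves` (data frame with columns
#'   cp_ratio, mode, u_c, growth, respiration, storage_net, overflow,
#'   limitation; all rates normalised), `ter`, `baseline_cp`, `cp_ratios`.
#' @export
sweep_gradient <- function(mode = c("none", "reserve", "surplus", "all"),
                           params, cp_min, cp_max, n_points = 101) {
  mode <- match.arg(mode)
  if (!(cp_min < params$baseline_cp && params$baseline_cp < cp_max)) {
    stop("argument error: cp_min < baseline_cp < cp_max required",
         call. = FALSE)
  }
  stopifnot(n_points >= 3)
  modes <- if (mode == "all") c("none", "reserve", "surplus") else mode
  ratios <- sort(unique(c(
    exp(seq(log(cp_min), log(cp_max), length.out = n_points)),
    params$baseline_cp)))

  state_at <- function(r) {
    if (r >= params$baseline_cp) {
      substrate_state(c_avail = r / params$baseline_cp, p_avail = 1)
    } else {
      substrate_state(c_avail = 1, p_avail = params$baseline_cp / r)
    }
  }
  rows <- lapply(modes, function(m) {
    base <- simulate_point(m, params, state_at(params$baseline_cp))
    pts <- lapply(ratios, function(r) simulate_point(m, params, state_at(r)))
    data.frame(
      cp_ratio = ratios,
      mode = m,
      u_c = vapply(pts, `[[`, 0, "u_c") / base$u_c,
      growth = vapply(pts, `[[`, 0, "growth") / base$u_c,
      respiration = vapply(pts, `[[`, 0, "respiration") / base$u_c,
      storage_net = vapply(pts, `[[`, 0, "storage_net") / base$u_c,
      overflow = vapply(pts, `[[`, 0, "overflow") / base$u_c,
      limitation = vapply(pts, `[[`, "", "limitation"),
      stringsAsFactors = FALSE
    )
  })
  structure(list(curves = do.call(rbind, rows),
                 cp_ratios = ratios,
                 ter = threshold_element_ratio(params),
                 baseline_cp = params$baseline_cp,
                 params = params),
            class = "gradient_sweep")
}

#' @export
print.gradient_sweep <- function(x, ...) {
  cat("<gradient_sweep> C:P ", format(min(x$cp_ratios)), "-",
      format(max(x$cp_ratios)), ", baseline ", format(x$baseline_cp),
      ", TER ", format(round(x$ter, 2)), ", modes: ",
      paste(unique(x$curves$mode), collapse = ", "), "\n", sep = "")
  invisible(x)
}
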