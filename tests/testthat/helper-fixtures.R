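# Shared helpers: tiny in-code fixtures and independent oracles.

# Minimal valid two-sample table satisfying every sample invariant.
tiny_samples <- function() {
  data.frame(
    sample_id = c("a", "b"),
    site_id = c("s1", "s2"),
    soil_type = c("basalt", "sandstone"),
    fertility_class = c("fertile", "infertile"),
    total_organic_c = c(0.04, 0.015),
    soluble_organic_c = c(100, 60),
    total_n = c(2500, 900),
    total_p = c(600, 90),
    mehlich_po4 = c(2.0, 0.1),
    mbc = c(550, 160),
    mbp = c(38, 3),
    plfa_total = c(67, 15),
    plfa_bacterial = c(42, 6.5),
    plfa_fungal = c(9.5, 3.5),
    nlfa_c = c(22, 10),
    phb_c = c(33, 19),
    trehalose_c = c(0.9, 1.0),
    phosphomonoesterase = c(950, 630),
    phosphodiesterase = c(300, 245),
    glucosidase = c(205, 54),
    stringsAsFactors = FALSE
  )
}

# Independent brute-force allocator: grid-search the feasible (G, S)
# partition of C uptake that maximises growth (then storage, for the
# surplus strategy) subject to the C-allowed and P-allowed growth bounds,
# the mode's storage rule, and non-negative overflow.
brute_force_point <- function(mode, e, r_b, f_res, phi_max, u_c, u_p,
                              n_grid = 2001) {
  supply <- if (mode == "reserve") (1 - f_res) * u_c else u_c
  # candidate growth values: a grid over [0, u_c] plus the two analytic
  # bounds, filtered by feasibility (C-allowed and P-allowed)
  g_cand <- sort(unique(pmax(0, c(seq(0, u_c, length.out = n_grid),
                                  e * supply, r_b * u_p))))
  feasible <- g_cand <= e * supply + 1e-15 & g_cand <= r_b * u_p + 1e-15
  growth <- max(g_cand[feasible])
  p_limited <- r_b * u_p < e * supply
  storage <- switch(mode,
    none = 0,
    reserve = f_res * u_c,
    surplus = {
      if (p_limited) {
        s_cand <- sort(unique(pmax(0, c(seq(0, u_c, length.out = n_grid),
                                        phi_max * u_c,
                                        u_c - growth / e))))
        ok <- s_cand <= phi_max * u_c + 1e-15 &
          s_cand <= u_c - growth / e + 1e-15
        max(s_cand[ok])
      } else 0
    })
  overflow <- max(0, u_c - growth / e - storage)
  list(growth = growth,
       storage_net = storage,
       respiration = (1 - e) / e * growth + overflow,
       overflow = overflow)
}

# Naive double-loop Bray-Curtis oracle.
bray_curtis_naive <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  out
}
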