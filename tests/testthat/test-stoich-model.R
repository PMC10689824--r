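test_that("threshold element ratio is biomass C:P over growth efficiency", {
  expect_equal(threshold_element_ratio(model_params(e = 0.45, r_b = 29.4,
                                                    baseline_cp = 59.6)),
               29.4 / 0.45, tolerance = 1e-12)
  expect_equal(threshold_element_ratio(model_params(e = 0.45, r_b = 78.7,
                                                    baseline_cp = 636)),
               78.7 / 0.45, tolerance = 1e-12)
  # unit-efficiency limit: TER collapses to the biomass ratio
  expect_equal(threshold_element_ratio(model_params(e = 1 - 1e-12, r_b = 50,
                                                    baseline_cp = 100)),
               50, tolerance = 1e-9)
})

test_that("default parameterisations bracket their TERs as drawn", {
  pb <- soil_params("basalt")
  ps <- soil_params("sandstone")
  expect_identical(classify_limitation(pb$baseline_cp, pb), "C_limited")
  expect_identical(classify_limitation(ps$baseline_cp, ps), "P_limited")
  # boundary tie-break
  expect_identical(classify_limitation(threshold_element_ratio(pb), pb),
                   "C_limited")
})

test_that("simulate_point reproduces hand-computed flux partitions", {
  # surplus strategy, deep P limitation: all excess C is stored
  p <- model_params(e = 0.5, r_b = 50, f_res = 0, phi_max = 1,
                    baseline_cp = 200)
  f <- simulate_point("surplus", p, substrate_state(1, 1))
  expect_equal(f$u_p, 0.005)
  expect_equal(f$growth, 0.25)
  expect_equal(f$storage_net, 0.5)
  expect_equal(f$respiration, 0.25)
  expect_equal(f$overflow, 0)
  expect_identical(f$limitation, "P_limited")

  # no-storage community at exactly the TER: no overflow, G = e u_c
  p2 <- model_params(e = 0.4, r_b = 40, baseline_cp = 100)
  f2 <- simulate_point("none", p2,
                       substrate_state(threshold_element_ratio(p2) / 100, 1))
  expect_equal(f2$overflow, 0, tolerance = 1e-12)
  expect_equal(f2$storage_net, 0)
  expect_equal(f2$growth, p2$e * f2$u_c, tolerance = 1e-12)

  # reserve strategy under C limitation: constitutive split
  p3 <- model_params(e = 0.45, r_b = 30, f_res = 0.2, baseline_cp = 20)
  f3 <- simulate_point("reserve", p3, substrate_state(1, 1))
  expect_identical(f3$limitation, "C_limited")
  expect_equal(f3$storage_net, 0.2 * f3$u_c)
  expect_equal(f3$growth, 0.45 * 0.8 * f3$u_c)
})

test_that("C mass balance holds at every point of both default sweeps", {
  for (soil in c("basalt", "sandstone")) {
    p <- soil_params(soil)
    sw <- sweep_gradient("all", p, p$baseline_cp / 30, p$baseline_cp * 30,
                         n_points = 101)
    bal <- with(sw$curves, u_c - (growth + respiration + storage_net))
    expect_lt(max(abs(bal) / sw$curves$u_c), 1e-12)
    expect_true(all(sw$curves[, c("growth", "respiration", "storage_net",
                                  "overflow")] >= 0))
    # normalisation: baseline point has unit C uptake
    expect_equal(
      sw$curves$u_c[sw$curves$cp_ratio == p$baseline_cp],
      rep(1, 3), tolerance = 1e-12)
  }
})

test_that("fluxes are continuous in the C:P ratio at the TER", {
  p <- soil_params("basalt")
  ter <- threshold_element_ratio(p)
  for (m in c("none", "reserve", "surplus")) {
    for (h in 10^seq(-4, -9)) {
      lo <- simulate_point(m, p, substrate_state(ter * (1 - h) /
                                                   p$baseline_cp, 1))
      hi <- simulate_point(m, p, substrate_state(ter * (1 + h) /
                                                   p$baseline_cp, 1))
      for (fl in c("growth", "respiration", "storage_net")) {
        expect_lt(abs(hi[[fl]] - lo[[fl]]), 10 * h * max(1, hi[[fl]]))
      }
    }
  }
})

test_that("respiration slopes under P limitation separate the strategies", {
  # dR/du_c: ~1 without storage, ~(1 - f_res) for reserve, ~0 for surplus
  p <- model_params(e = 0.45, r_b = 30, f_res = 0.15, phi_max = 1,
                    baseline_cp = 30)
  ter <- threshold_element_ratio(p)
  u1 <- 3 * ter / p$baseline_cp  # deep in the P-limited regime
  h <- 1e-6
  slope <- function(m) {
    a <- simulate_point(m, p, substrate_state(u1, 1))
    b <- simulate_point(m, p, substrate_state(u1 + h, 1))
    (b$respiration - a$respiration) / h
  }
  expect_equal(slope("none"), 1, tolerance = 1e-6)
  expect_equal(slope("reserve"), 1 - p$f_res, tolerance = 1e-6)
  expect_equal(slope("surplus"), 0, tolerance = 1e-6)
  # growth is flat in C supply under P limitation for every strategy
  gslope <- function(m) {
    a <- simulate_point(m, p, substrate_state(u1, 1))
    b <- simulate_point(m, p, substrate_state(u1 + h, 1))
    (b$growth - a$growth) / h
  }
  for (m in c("none", "reserve", "surplus")) {
    expect_equal(gslope(m), 0, tolerance = 1e-9)
  }
})

test_that("storage rises fastest under the surplus strategy above the TER", {
  p <- soil_params("sandstone")
  sw <- sweep_gradient("all", p, p$baseline_cp / 10, p$baseline_cp * 10,
                       n_points = 81)
  above <- function(m) {
    cv <- sw$curves[sw$curves$mode == m &
                      sw$curves$cp_ratio >= sw$baseline_cp, ]
    cv[order(cv$cp_ratio), "storage_net"]
  }
  s_sur <- above("surplus"); s_res <- above("reserve")
  expect_true(all(diff(s_sur) > 0))
  expect_true(all(diff(s_sur) > diff(s_res) - 1e-12))
})

test_that("P addition is inert for the basalt parameterisation, and drains surplus storage for sandstone", {
  pb <- soil_params("basalt")
  swb <- sweep_gradient("all", pb, pb$baseline_cp / 20, pb$baseline_cp * 20,
                        n_points = 101)
  for (m in c("none", "reserve", "surplus")) {
    cv <- swb$curves[swb$curves$mode == m, ]
    b <- cv[cv$cp_ratio == pb$baseline_cp, ]
    left <- cv[cv$cp_ratio < pb$baseline_cp, ]
    expect_lt(max(abs(left$growth - b$growth),
                  abs(left$respiration - b$respiration),
                  abs(left$storage_net - b$storage_net)), 1e-9)
  }
  ps <- soil_params("sandstone")
  sws <- sweep_gradient("surplus", ps, ps$baseline_cp / 20,
                        ps$baseline_cp * 20, n_points = 201)
  cv <- sws$curves[order(sws$curves$cp_ratio), ]
  drain <- cv[cv$cp_ratio > sws$ter & cv$cp_ratio <= ps$baseline_cp, ]
  # moving toward lower C:P (P addition) storage declines until the TER
  expect_true(all(diff(drain$storage_net) > 0))
  left_of_ter <- cv[cv$cp_ratio < sws$ter, ]
  expect_true(all(left_of_ter$storage_net < 1e-12))
})

test_that("flux partition agrees with the brute-force allocation oracle", {
  set.seed(2024)
  for (i in 1:100) {
    e <- runif(1, 0.2, 0.8)
    r_b <- runif(1, 10, 120)
    f_res <- runif(1, 0, 0.4)
    phi_max <- runif(1, 0.3, 1)
    baseline_cp <- runif(1, 20, 800)
    c_avail <- exp(runif(1, -2, 2))
    p_avail <- exp(runif(1, -2, 2))
    p <- model_params(e, r_b, f_res, phi_max, baseline_cp)
    m <- sample(c("none", "reserve", "surplus"), 1)
    f <- simulate_point(m, p, substrate_state(c_avail, p_avail))
    o <- brute_force_point(m, e, r_b, f_res, phi_max, f$u_c, f$u_p)
    for (fl in c("growth", "respiration", "storage_net", "overflow")) {
      expect_equal(f[[fl]], o[[fl]], tolerance = 1e-9, label = fl)
    }
  }
})

test_that("carbon use efficiency responds to storage accounting as expected", {
  p <- model_params(e = 0.45, r_b = 30, f_res = 0.15, baseline_cp = 20)
  f <- simulate_point("reserve", p, substrate_state(1, 1)) # C-limited
  expect_equal(cue(f), p$e * (1 - p$f_res), tolerance = 1e-12)
  expect_equal(cue(f, count_storage = TRUE), cue(f) + p$f_res)
  fn <- simulate_point("none", p, substrate_state(1, 1))
  expect_equal(cue(fn), cue(fn, count_storage = TRUE))
  # storage-counting CUE under surplus beats the storage-free community
  # across a random P-limited grid
  set.seed(7)
  for (i in 1:50) {
    pp <- model_params(runif(1, 0.2, 0.8), runif(1, 20, 100), 0, 1,
                       baseline_cp = 50)
    r <- threshold_element_ratio(pp) * runif(1, 1.5, 10)
    st <- substrate_state(r / 50, 1)
    expect_gt(cue(simulate_point("surplus", pp, st), count_storage = TRUE),
              cue(simulate_point("none", pp, st), count_storage = TRUE))
  }
})

test_that("sweep argument validation rejects a baseline outside the range", {
  p <- soil_params("basalt")
  expect_error(sweep_gradient("none", p, 100, 1000), "baseline")
})
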