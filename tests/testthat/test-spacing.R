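test_that("consolidated fraction at t1 follows its closed form", {
  sp <- spacing_params(P1_t0 = 0.02, P_1S = 0.001, p_e0 = 0.01,
                       p_d0 = 2e-4, Peff1 = 0.3, t1 = 10)
  expect_equal(p1_at_t1(sp),
               0.02 * 0.999 * (1 - 2e-4)^10 + 0.001 * 0.3)
  # no initial consolidation: only the rehearsed tags contribute
  sp0 <- spacing_params(P1_t0 = 0, P_1S = 0.001, p_e0 = 0.01, p_d0 = 2e-4,
                        Peff1 = 0.3, t1 = 10)
  expect_equal(p1_at_t1(sp0), 0.001 * 0.3)
  # no deconsolidation: the initial pool survives intact
  spd <- spacing_params(P1_t0 = 0.02, P_1S = 0.001, p_e0 = 0.01, p_d0 = 0,
                        Peff1 = 0.3, t1 = 10)
  expect_equal(p1_at_t1(spd), 0.02 * 0.999 + 0.001 * 0.3)
})

test_that("gap formula obeys its algebraic limits", {
  sp <- spacing_params(p_e0 = 0.05, p_d0 = 1e-3, Peff1 = 0.25, t1 = 10)
  # zero-gap identity, exact
  expect_equal(peff_after_gap(sp, 0), 0.25, tolerance = 1e-14)
  # infinite-gap limit with p_d0 = 0
  spd <- spacing_params(p_e0 = 0.05, p_d0 = 0, Peff1 = 0.25, t1 = 10)
  P1t1 <- p1_at_t1(spd)
  lim <- (0.1 * 0.4 + (0.4 - 0.1) * 0.25 - 0.4 * P1t1) / (0.4 - P1t1)
  expect_equal(peff_after_gap(spd, 1e7), lim, tolerance = 1e-9)
  # retention only rescales the curve
  expect_equal(peff_at_test(sp, 5, 100),
               peff_after_gap(sp, 5) * (1 - 1e-3)^100)
  expect_equal(peff_at_test(spd, 5, 500), peff_after_gap(spd, 5))
})

test_that("gap formula approximates the macroscopic model-B protocol", {
  # two-session network benchmark: study 10 steps, gap, single re-study.
  # The closed form is an approximation summarizing the end-of-study state
  # by P_eff alone; against the full recursion it is accurate to a few
  # percent.
  cfg <- cepeda_params(p_e0 = 0.1, p_d0 = 0.005, model = "B")
  cfg$P_1S <- 0.1; cfg$P1_t0 <- 0
  st <- init_macro(cfg$P, cfg$P_pot, cfg$P1_t0, cfg$P_1S)
  for (t in 1:10) st <- step_macro(st, cfg$params, TRUE)
  sp <- spacing_params(P = 0.1, P_pot = 0.4, P1_t0 = 0, P_1S = 0.1,
                       p_e0 = 0.1, p_d0 = 0.005,
                       Peff1 = network_connectivities(st)$P_eff, t1 = 10)
  for (gap in c(5, 20, 50)) {
    s2 <- st
    for (t in seq_len(gap)) s2 <- step_macro(s2, cfg$params, FALSE)
    s2 <- step_macro(s2, cfg$params, TRUE)
    macro <- network_connectivities(s2)$P_eff
    expect_equal(peff_after_gap(sp, gap), macro, tolerance = 0.05)
  }
})

test_that("optimal gap solves the stationarity condition and maximizes the curve", {
  sp <- spacing_params_from_macro(p_e0 = 0.01, p_d0 = 2e-4)
  og <- optimal_gap(sp)
  # residual of the stationarity condition at the root
  P1t1 <- p1_at_t1(sp)
  resid <- (sp$Peff1 - P1t1) / (sp$P - P1t1) +
    (og$alpha - 1) * sp$Peff1 / sp$P_pot * og$x_opt^og$alpha -
    og$alpha * og$x_opt^(og$alpha - 1)
  expect_lt(abs(resid), 1e-10)
  # the root is the argmax of the gap curve on the integer grid
  dts <- 0:2000
  expect_lte(abs(dts[which.max(peff_after_gap(sp, dts))] - og$dt_opt), 1)
  expect_equal(og$alpha, log(1 - 0.01) / log(1 - 2e-4))
})

test_that("faster plasticity shortens the optimal gap", {
  base <- optimal_gap(spacing_params_from_macro(0.01, 2e-4))$dt_opt
  faster_turnover <- optimal_gap(spacing_params_from_macro(0.1, 2e-4))$dt_opt
  faster_decay <- optimal_gap(spacing_params_from_macro(0.01, 1e-3))$dt_opt
  expect_lt(faster_turnover, base)
  expect_lt(faster_decay, base)
})

test_that("gap curve is unimodal when turnover outpaces deconsolidation", {
  sp <- spacing_params_from_macro(0.01, 1e-3)
  pv <- peff_after_gap(sp, 0:3000)
  sgn <- sign(diff(pv))
  expect_equal(sum(diff(sgn[sgn != 0]) != 0), 1)  # one rise-fall change
})

test_that("protocol grids share their argmax across retention intervals", {
  cfg <- cepeda_params(p_e0 = 0.1, p_d0 = 1e-3, model = "B")
  grid <- run_cepeda_protocol(cfg, dt_grid = seq(0, 120, by = 10),
                              ri_grid = 24 * c(7, 35, 70), tr1 = 10, tr2 = 1)
  argmax <- tapply(seq_len(nrow(grid)), grid$ri, function(i)
    grid$dt[i][which.max(grid$peff3[i])])
  expect_true(all(argmax == argmax[1]))
  # forgetting curve: performance decreases with retention at fixed gap
  for (d in unique(grid$dt)) {
    sub <- grid[grid$dt == d, ]
    expect_true(all(diff(sub$peff3[order(sub$ri)]) < 0))
  }
})

test_that("synapse models A and B agree on the optimal gap location", {
  gridB <- run_cepeda_protocol(cepeda_params(0.1, 1e-3, "B"),
                               dt_grid = seq(0, 100, by = 5),
                               ri_grid = 24 * 7, tr1 = 10, tr2 = 1)
  gridA <- run_cepeda_protocol(cepeda_params(0.1, 1e-3, "A"),
                               dt_grid = seq(0, 100, by = 5),
                               ri_grid = 24 * 7, tr1 = 10, tr2 = 1)
  expect_lte(abs(gridB$dt[which.max(gridB$peff3)] -
                 gridA$dt[which.max(gridA$peff3)]), 5)
})
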