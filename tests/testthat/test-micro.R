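test_that("single-step transitions hit their deterministic limits", {
  pot <- matrix(1L, 10, 10)
  S <- matrix(1L, 10, 10)
  pop <- synapse_population(pot, S, P_init = 0.5, P1_init = 0, seed = 2)

  # certain consolidation of tagged silent synapses
  par1 <- plasticity_params("A", p_c = c(0, 1), p_e = c(0, 0),
                            p_d = c(0, 0), p_g = 0)
  p2 <- step_micro(pop, par1, rehearsing = TRUE)
  expect_equal(sum(p2$states == 2L), 50)
  expect_equal(sum(p2$states == 0L), 50)

  # all rates zero: identity
  par0 <- plasticity_params("A", p_c = c(0, 0), p_e = c(0, 0),
                            p_d = c(0, 0), p_g = 0)
  expect_identical(step_micro(pop, par0, rehearsing = TRUE)$states,
                   pop$states)

  # outside rehearsal, tags are inert: nothing consolidates
  p3 <- step_micro(pop, par1, rehearsing = FALSE)
  expect_equal(sum(p3$states == 2L), 0)

  expect_error(plasticity_params("A", p_c = c(0.8, 1), p_e = c(0.5, 0)),
               "exceed 1")
  expect_error(plasticity_params("A", p_c = c(0, 2)), "0, 1")
})

test_that("models A and B coincide when deconsolidation is off", {
  pot <- matrix(1L, 20, 20)
  set.seed(3)
  S <- matrix(as.integer(runif(400) < 0.2), 20, 20)
  mk <- function(model) plasticity_params(model, p_c = c(0, 0.5),
                                          p_e = c(0.3, 0), p_d = c(0, 0),
                                          p_g = 0.1)
  popA <- synapse_population(pot, S, P_init = 0.4, seed = 9)
  popB <- synapse_population(pot, S, P_init = 0.4, seed = 9)
  set.seed(77); a <- step_micro(popA, mk("A"), TRUE)
  set.seed(77); b <- step_micro(popB, mk("B"), TRUE)
  expect_identical(a$states, b$states)
})

test_that("state occupancy over many replicates follows the synchronous recursion", {
  # one tagged synapse, many independent replicates, fixed probabilistic rates
  par <- plasticity_params("A", p_c = c(0, 0.3), p_e = c(0.2, 0.05),
                           p_d = c(0, 0.1), p_g = 0.15)
  n_rep <- 10000L
  pot <- matrix(1L, 1, n_rep)   # n_rep independent tagged synapses
  S <- matrix(1L, 1, n_rep)
  pop <- synapse_population(pot, S, P_init = 1, P1_init = 0, seed = 5)
  # closed-form recursion of the state probabilities
  p <- c(pi = 0, s0 = 1, s1 = 0)
  set.seed(41)
  for (t in 1:10) {
    pop <- step_micro(pop, par, rehearsing = TRUE, apply_pg = TRUE)
    p <- c(pi = (1 - 0.15) * p["pi"] + 0.05 * p["s0"],
           s0 = (1 - 0.3 - 0.05) * p["s0"] + 0.1 * p["s1"] + 0.15 * p["pi"],
           s1 = (1 - 0.1) * p["s1"] + 0.3 * p["s0"])
    names(p) <- c("pi", "s0", "s1")
  }
  obs <- c(sum(pop$states == 0L), sum(pop$states == 1L),
           sum(pop$states == 2L))
  chi2 <- sum((obs - n_rep * p)^2 / (n_rep * p))
  expect_lt(chi2, qchisq(0.99, df = 2))
})

test_that("exact homeostasis conserves anatomical connectivity", {
  set.seed(6)
  ps <- generate_patterns(40, 40, 4, 4, 5, mode = "fixed")
  S <- consolidation_signal(ps)
  pot <- matrix(1L, 40, 40)
  pop <- synapse_population(pot, S, P_init = 22 / 56, seed = 10)
  par <- plasticity_params("A", p_c = c(0, 1), p_e = c(0.5, 0),
                           p_d = c(0, 0), p_g = "homeostatic")
  tr <- run_protocol_micro(pop, par, schedule = 0:99, t_end = 100, seed = 1)
  expect_true(all(abs(tr$P - tr$P[1]) < 1e-12))
  # with p_d = 0 and fixed tags, effectual connectivity never decreases
  expect_true(all(diff(tr$P_eff) >= -1e-12))

  # no regrowth requested: nothing changes
  expect_identical(homeostatic_generation(pop, 0)$states, pop$states)

  # depleted pi pool: warning flag, connectivity may drop
  full <- synapse_population(pot, S, P_init = 1, seed = 3)
  expect_warning(res <- homeostatic_generation(full, 5), "depleted")
  expect_true(res$depleted)
})

test_that("empty schedule leaves effectual connectivity at zero", {
  set.seed(30)
  ps <- generate_patterns(30, 30, 3, 3, 4, mode = "fixed")
  S <- consolidation_signal(ps)
  pop <- synapse_population(matrix(1L, 30, 30), S, P_init = 0.1,
                            P1_init = 0, seed = 2)
  par <- plasticity_params("A", p_c = c(0, 1), p_e = c(0.1, 0),
                           p_d = c(0, 0), p_g = "homeostatic")
  tr <- run_protocol_micro(pop, par, schedule = integer(0), t_end = 30,
                           seed = 4)
  expect_true(all(tr$P_eff == 0))
})

test_that("rehearsal schedules expand interval lists", {
  expect_identical(rehearsal_schedule(list(c(0, 2), c(10, 11))),
                   c(0L, 1L, 2L, 10L, 11L))
  expect_identical(rehearsal_schedule(c(5, 3, 3)), c(3L, 5L))
})
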