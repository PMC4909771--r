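test_that("pattern generation respects sizes, modes and seeds", {
  # saturated case: every unit active
  ps <- generate_patterns(4, 4, 4, 4, M = 1, mode = "fixed", seed = 1)
  expect_identical(ps$u[[1]], 0:3)
  expect_identical(ps$v[[1]], 0:3)

  # empty set stores to an all-zero weight matrix
  ps0 <- generate_patterns(10, 10, 3, 3, M = 0, seed = 1)
  expect_equal(sum(store_willshaw(ps0)$W), 0)

  # fixed-size mode: exactly k actives, all in range
  ps <- generate_patterns(100, 80, 7, 5, M = 25, mode = "fixed", seed = 2)
  expect_true(all(vapply(ps$u, length, 1L) == 7))
  expect_true(all(vapply(ps$v, length, 1L) == 5))
  expect_true(all(unlist(ps$u) >= 0 & unlist(ps$u) < 100))
  expect_true(all(unlist(ps$v) >= 0 & unlist(ps$v) < 80))

  # bernoulli mode: binomial moments of the activity counts
  ps <- generate_patterns(1000, 1000, 50, 50, M = 20, mode = "bernoulli",
                          seed = 1)
  mean_k <- mean(vapply(ps$u, length, 1L))
  expect_lt(abs(mean_k - 50), 3 * sqrt(50 * 0.95) / sqrt(20))

  # determinism given a seed
  a <- generate_patterns(50, 50, 5, 5, 10, seed = 99)
  b <- generate_patterns(50, 50, 5, 5, 10, seed = 99)
  expect_identical(a$u, b$u)

  expect_error(generate_patterns(10, 10, 0, 5, 1), "invalid")
  expect_error(generate_patterns(10, 10, 11, 5, 1), "invalid")
})

test_that("Willshaw storage places weights exactly at co-activations", {
  ps <- toy_pattern_set()
  W <- store_willshaw(ps)
  expected <- matrix(0L, 4, 4)
  expected[cbind(c(1, 1, 2, 2), c(1, 3, 1, 3))] <- 1L
  expect_identical(W$W, expected)

  # masked-out network stays silent
  W0 <- store_willshaw(ps, mask = matrix(0L, 4, 4))
  expect_equal(sum(W0$W), 0)

  # storing a superset of memories never clears a weight
  set.seed(5)
  ps1 <- generate_patterns(30, 30, 4, 4, 6, mode = "fixed", seed = 11)
  ps2 <- ps1
  ps2$u <- c(ps1$u, generate_patterns(30, 30, 4, 4, 4, seed = 12)$u)
  ps2$v <- c(ps1$v, generate_patterns(30, 30, 4, 4, 4, seed = 13)$v)
  ps2$M <- 10L
  expect_true(all(store_willshaw(ps1)$W <= store_willshaw(ps2)$W))
})

test_that("empirical 1-synapse fraction matches the closed form", {
  set.seed(21)
  m <- n <- 400; k <- l <- 20; M <- 30
  # entries of one matrix are correlated through shared patterns, so the
  # sampling error is estimated empirically across independent pattern sets
  p1_hat <- replicate(10, mean(store_willshaw(
    generate_patterns(m, n, k, l, M, mode = "bernoulli"))$W))
  p1 <- p1_expected(k, l, m, n, M)
  se <- sd(p1_hat) / sqrt(length(p1_hat))
  expect_lt(abs(mean(p1_hat) - p1), 3 * se)

  expect_equal(p1_expected(50, 50, 1000, 1000, 0), 0)
  expect_equal(p1_expected(50, 50, 1000, 1000, 1), 2500 / 1e6)
  # high-precision oracle value (arbitrary-precision evaluation)
  expect_equal(p1_expected(50, 50, 1e5, 1e5, 800000), 0.18126926739029012,
               tolerance = 1e-12)
})

test_that("zip-net storage realizes the target connectivity with fixed tie-breaks", {
  # M = 0: all potentials zero, ties resolved by index, exact per-column count
  ps0 <- generate_patterns(20, 20, 4, 4, M = 0, seed = 1)
  pot <- matrix(1L, 20, 20)
  W <- store_zipnet(ps0, pot, target_P1 = 0.3, rule = "covariance")
  expect_true(all(colSums(W$W) == ceiling(0.3 * 20)))
  expect_true(all(apply(W$W, 2, function(col) all(which(col == 1) == 1:6))))

  # degenerate quantile: every potential synapse realized
  set.seed(31)
  ps <- generate_patterns(20, 20, 4, 4, M = 5, mode = "fixed")
  pm <- matrix(as.integer(runif(400) < 0.6), 20, 20)
  Wall <- store_zipnet(ps, pm, target_P1 = mean(pm), rule = "covariance")
  expect_identical(Wall$W, pm)

  # realized fraction within per-column quantization of the target
  Wz <- store_zipnet(ps, pm, target_P1 = 0.2, rule = "homosynaptic")
  per_col <- colSums(Wz$W) / pmax(colSums(pm), 1)
  expect_true(all(abs(per_col - 0.2 / mean(pm)) <= 1 / pmax(colSums(pm), 1)))
  # weights only at potential locations
  expect_true(all(Wz$W <= pm))

  expect_error(store_zipnet(ps, pm, target_P1 = 0.99), "infeasible")
})

test_that("retrieval strategies implement their threshold contracts", {
  ps <- toy_pattern_set()
  W <- store_willshaw(ps)
  q <- bin_vec(ps$u[[1]], 4)

  # pattern-part on a full mask retrieves the stored content exactly
  r <- retrieve(W, q, strategy = "pattern-part")
  expect_identical(r$v_hat, bin_vec(ps$v[[1]], 4))

  # all-zero weights under a fixed threshold stay silent
  W0 <- store_willshaw(generate_patterns(4, 4, 2, 2, 0, seed = 1))
  expect_identical(retrieve(W0, q, strategy = "fixed", theta = 1)$v_hat,
                   rep(0L, 4))

  # l-winner picks the maximal threshold activating at least l units
  r <- retrieve(W, q, strategy = "l-winner", l = 2)
  expect_equal(r$theta_used, 2)
  expect_identical(r$v_hat, bin_vec(ps$v[[1]], 4))

  # empty query in l-winner mode: empty output with a warning flag
  expect_warning(r0 <- retrieve(W, rep(0L, 4), strategy = "l-winner", l = 2),
                 "all-zero")
  expect_true(r0$empty_output)
  expect_identical(r0$v_hat, rep(0L, 4))

  # noise draws are deterministic given the seed
  r1 <- retrieve(W, q, strategy = "fixed", theta = 1, noise_max = 1, seed = 4)
  r2 <- retrieve(W, q, strategy = "fixed", theta = 1, noise_max = 1, seed = 4)
  expect_identical(r1$noise, r2$noise)
})

test_that("pattern-part retrieval never misses on noiseless queries", {
  set.seed(17)
  for (rep in 1:5) {
    ps <- generate_patterns(60, 60, 6, 6, 8, mode = "fixed")
    mask <- matrix(as.integer(runif(3600) < runif(1, 0.2, 1)), 60, 60)
    W <- store_willshaw(ps, mask)
    for (mu in c(1, 4, 8)) {
      r <- retrieve(W, bin_vec(ps$u[[mu]], 60), strategy = "pattern-part")
      on <- output_noise(r$v_hat, bin_vec(ps$v[[mu]], 60), 6)
      expect_equal(on$q10_count, 0)
    }
  }
})

test_that("output noise counts Hamming errors normalized by assembly size", {
  v <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  expect_equal(output_noise(v, v, 3)$eps_hat, 0)
  vh <- v; vh[1] <- 0L; vh[4] <- 1L  # one miss + one add
  expect_equal(output_noise(vh, v, 3)$eps_hat, 2 / 3)
  expect_equal(output_noise(1L - v, v, 3)$eps_hat, 8 / 3)
  expect_error(output_noise(v, v, 0), "undefined")
})
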