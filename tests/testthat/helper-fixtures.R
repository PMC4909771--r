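# Shared fixtures and Monte-Carlo helpers built in code at test time.

bin_vec <- function(idx, len) {
  x <- integer(len)
  x[idx + 1L] <- 1L
  x
}

# The hand-checkable two-population example: one stored pair with address
# actives {0, 1} and content actives {0, 2} in a 4 x 4 net.
toy_pattern_set <- function() {
  ps <- generate_patterns(4, 4, 2, 2, M = 1, mode = "fixed", seed = 1)
  ps$u[[1]] <- c(0L, 1L)
  ps$v[[1]] <- c(0L, 2L)
  ps
}

# Pattern set with (M - 1) Bernoulli pairs plus one fixed-size target pair,
# so that analyses conditioning on exactly k active query units apply
# exactly. The target is stored at index M.
patterns_with_target <- function(m, n, k, l, M) {
  ps <- generate_patterns(m, n, k, l, M - 1, mode = "bernoulli")
  ps$u[[M]] <- sort(sample.int(m, k) - 1L)
  ps$v[[M]] <- sort(sample.int(n, l) - 1L)
  ps$M <- M
  ps
}

# Monte-Carlo estimate of Willshaw one-step component error rates at fixed
# threshold over independently drawn networks and dilution masks.
mc_willshaw_error_rates <- function(m, n, k, l, M, P_eff, theta, nets) {
  add <- 0; n_lo <- 0; miss <- 0; n_hi <- 0
  for (net in seq_len(nets)) {
    ps <- patterns_with_target(m, n, k, l, M)
    mask <- matrix(as.integer(runif(m * n) < P_eff), m, n)
    W <- store_willshaw(ps, mask)
    res <- retrieve(W, bin_vec(ps$u[[M]], m), strategy = "fixed",
                    theta = theta)
    v <- bin_vec(ps$v[[M]], n)
    add <- add + sum(res$v_hat == 1 & v == 0)
    n_lo <- n_lo + sum(v == 0)
    miss <- miss + sum(res$v_hat == 0 & v == 1)
    n_hi <- n_hi + sum(v == 1)
  }
  list(q01 = add / n_lo, q10 = miss / n_hi,
       se01 = sqrt(add / n_lo * (1 - add / n_lo) / n_lo),
       se10 = sqrt(miss / n_hi * (1 - miss / n_hi) / n_hi))
}

# Spacing parameter set whose performance level at t1 comes from the macro
# engine (initial study of tr1 rehearsal steps).
spacing_params_from_macro <- function(p_e0, p_d0, tr1 = 10, model = "B") {
  cfg <- cepeda_params(p_e0 = p_e0, p_d0 = p_d0, model = model)
  st <- init_macro(cfg$P, cfg$P_pot, cfg$P1_t0, cfg$P_1S)
  for (t in seq_len(tr1)) st <- step_macro(st, cfg$params, rehearsing = TRUE)
  spacing_params(P = cfg$P, P_pot = cfg$P_pot, P1_t0 = cfg$P1_t0,
                 P_1S = cfg$P_1S, p_e0 = p_e0, p_d0 = p_d0,
                 Peff1 = network_connectivities(st)$P_eff, t1 = tr1)
}
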