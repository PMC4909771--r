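# Deterministic group-level solver for the three-state synapse dynamics.
#
# Potential synapses are partitioned into groups by consolidation signal
# s (here s in {0, 1}). Per group the solver iterates the synchronous
# recursion of the synapse-state probabilities
#   p1(t) = (1 - p_d|s) p1(t-1) + p_c|s p0(t-1)
#   p0(t) = (1 - p_c|s - p_e|s) p0(t-1) + [A] p_d|s p1(t-1) + p_g ppi(t-1)
#   ppi(t) = 1 - p1(t) - p0(t)
# (model B routes the deconsolidation flux 1 -> pi instead of 1 -> 0).
# Pair-level connectivities follow from the synapse-count distribution p(n)
# per connected pair; with p(1) = 1 pair level and synapse level coincide.

#' Initialize a macroscopic connectivity state
#'
#' Splits the potential synapses into an untagged (s = 0) and a tagged
#' (s = 1) group. Tag placement is independent of potential-synapse
#' placement (random memory patterns are independent of anatomy), so the
#' group sizes are \code{P_pot * (1 - P_1S)} and \code{P_pot * P_1S}. Both
#' groups start with the same within-group state fractions
#' \code{p_1 = P1_init / P_pot}, \code{p_0 = (P - P1_init) / P_pot}.
#'
#' @param P initial anatomical connectivity.
#' @param P_pot potential connectivity.
#' @param P1_init initial consolidated fraction (of all pairs).
#' @param P_1S consolidation load of the memory set being tracked.
#' @param p_n synapse-count distribution per potentially connected pair:
#'   numeric vector with \code{p_n[i] = pr[n = i]}; default single synapse.
#' @return Object of class \code{"macro_state"}.
#' @export
init_macro <- function(P, P_pot, P1_init = 0, P_1S, p_n = 1) {
  if (!(P1_init <= P && P <= P_pot && P_pot <= 1))
    stop("need P1_init <= P <= P_pot <= 1")
  if (P_1S < 0 || P_1S > 1) stop("P_1S must lie in [0, 1]")
  if (abs(sum(p_n) - 1) > 1e-12 || any(p_n < 0))
    stop("p_n must be a probability distribution")
  w <- P_pot * c(`0` = 1 - P_1S, `1` = P_1S)
  p1 <- P1_init / P_pot
  p0 <- (P - P1_init) / P_pot
  p <- rbind(pi = rep(1 - p1 - p0, 2), `0` = rep(p0, 2), `1` = rep(p1, 2))
  colnames(p) <- c("0", "1")
  structure(list(w = w, p = p, s = c(0L, 1L), P_1S = P_1S,
                 P_pot = P_pot, p_n = p_n, depleted = FALSE),
            class = "macro_state")
}

#' @export
print.macro_state <- function(x, ...) {
  nc <- network_connectivities(x)
  cat(sprintf(
    "macro_state: P = %.4g, P_pot = %.4g, P_1 = %.4g, P_1S = %.4g, P_eff = %.4g\n",
    nc$P, nc$P_pot, nc$P_1, nc$P_1S, nc$P_eff))
  invisible(x)
}

# internal lean stepper on the 3 x G state matrix; returns the new matrix.
.step_groups <- function(p, w, params, rehearsing) {
  p_c <- if (rehearsing) params$p_c else c(0, 0)
  p_e <- params$p_e
  p_d <- params$p_d
  if (!rehearsing) {  # tags act only during rehearsal: s = 0 everywhere
    p_e <- rep(p_e[1], 2); p_d <- rep(p_d[1], 2)
  }
  modelB <- params$model == "B"
  if (params$homeostatic) {
    elim <- sum(w * p_e * p["0", ]) + if (modelB) sum(w * p_d * p["1", ]) else 0
    pool <- sum(w * p["pi", ])
    p_g <- if (pool > 0) min(1, elim / pool) else 0
  } else p_g <- params$p_g
  p1 <- (1 - p_d) * p["1", ] + p_c * p["0", ]
  p0 <- (1 - p_c - p_e) * p["0", ] + p_g * p["pi", ] +
    (if (modelB) 0 else p_d * p["1", ])
  ppi <- 1 - p1 - p0
  rbind(pi = ppi, `0` = p0, `1` = p1)
}

#' One deterministic macro step
#'
#' Applies the per-group three-state recursion. With homeostatic
#' synaptogenesis, \code{p_g} is recomputed from the pre-step state so that
#' generation balances elimination and total anatomical connectivity stays
#' constant. Outside rehearsal all groups evolve with the untagged (s = 0)
#' parameters and no consolidation.
#'
#' @param state a \code{macro_state}.
#' @param params a \code{plasticity_params}.
#' @param rehearsing logical.
#' @return Updated \code{macro_state}.
#' @export
step_macro <- function(state, params, rehearsing = TRUE) {
  pool <- sum(state$w * state$p["pi", ])
  pnew <- .step_groups(state$p, state$w, params, rehearsing)
  if (params$homeostatic && pool <= 0) {
    elim <- sum(state$w * params$p_e * state$p["0", ])
    if (elim > 0 && !state$depleted) {
      state$depleted <- TRUE
      warning("pi pool depleted: connectivity P can no longer be held constant")
    }
  }
  dimnames(pnew) <- dimnames(state$p)
  state$p <- pnew
  state
}

#' Network connectivities of a macro state
#'
#' Aggregates the group states into pair-level connectivity measures. For a
#' general synapse-count distribution, a pair is consolidated if at least one
#' of its \code{n} synapses is in state 1
#' (\eqn{P_1^{(s)} = P_{pot}^{(s)} \sum_n p(n) (1 - (1 - p_1^{(s)})^n)}),
#' and potential-only if all are unrealized.
#'
#' @param state a \code{macro_state}.
#' @return List \code{P_pi, P_0, P_1, P, P_pot, P_1S, P_eff}.
#' @export
network_connectivities <- function(state) {
  p_n <- state$p_n
  ns <- seq_along(p_n)
  pair_frac <- function(f) vapply(f, function(x)
    sum(p_n * (1 - (1 - x)^ns)), numeric(1))
  P1_s <- state$w * pair_frac(state$p["1", ])
  Ppi_s <- state$w * vapply(state$p["pi", ], function(x)
    sum(p_n * x^ns), numeric(1))
  P0_s <- state$w - P1_s - Ppi_s
  if (state$P_1S <= 0)
    stop("consolidation load P_1S = 0: P_eff is undefined")
  tagged <- state$s != 0
  list(P_pi = sum(Ppi_s), P_0 = sum(P0_s), P_1 = sum(P1_s),
       P = sum(P0_s) + sum(P1_s), P_pot = sum(state$w),
       P_1S = state$P_1S,
       P_eff = sum(P1_s[tagged]) / state$P_1S)
}

#' Simulate a rehearsal protocol at the macroscopic level
#'
#' Deterministic counterpart of \code{\link{run_protocol_micro}} with the
#' same trajectory schema.
#'
#' @param P,P_pot,P1_init,P_1S,p_n initial conditions, see
#'   \code{\link{init_macro}}.
#' @param params a \code{plasticity_params}.
#' @param schedule integer vector of 0-based rehearsal step times.
#' @param t_end number of steps.
#' @return \code{data.frame} with columns
#'   \code{t, P, P_pot, P_1, P_eff, rehearsing}; attribute \code{"state"}
#'   holds the final macro state.
#' @export
run_protocol_macro <- function(P, P_pot, P1_init = 0, P_1S, params,
                               schedule, t_end, p_n = 1) {
  state <- init_macro(P, P_pot, P1_init, P_1S, p_n)
  schedule <- as.integer(schedule)
  rows <- matrix(NA_real_, nrow = t_end + 1L, ncol = 4L)
  reh <- logical(t_end + 1L)
  nc <- network_connectivities(state)
  rows[1L, ] <- c(nc$P, nc$P_pot, nc$P_1, nc$P_eff)
  for (t in seq_len(t_end)) {
    r <- (t - 1L) %in% schedule
    state <- step_macro(state, params, rehearsing = r)
    nc <- network_connectivities(state)
    rows[t + 1L, ] <- c(nc$P, nc$P_pot, nc$P_1, nc$P_eff)
    reh[t + 1L] <- r
  }
  traj <- data.frame(t = 0:t_end, P = rows[, 1], P_pot = rows[, 2],
                     P_1 = rows[, 3], P_eff = rows[, 4], rehearsing = reh)
  attr(traj, "state") <- state
  traj
}
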