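# Stochastic per-potential-synapse simulation of structural plasticity.
#
# Each potential synapse is in one of three states:
#   pi (coded 0L) -- potential location, no synapse realized
#   0  (coded 1L) -- realized but unstable silent synapse
#   1  (coded 2L) -- potentiated and consolidated synapse
# Transitions per time step (synchronous, from the start-of-step snapshot):
#   model A: 0->1 w.p. p_c|s, 0->pi w.p. p_e|s, 1->0 w.p. p_d|s, pi->0 w.p. p_g
#   model B: as A but deconsolidation goes 1->pi.
# Outside rehearsal every synapse sees s = 0 and consolidation is off.

.ST_PI <- 0L
.ST_SILENT <- 1L
.ST_CONS <- 2L

#' Plasticity parameter set for the three-state synapse models
#'
#' Probabilities are given per consolidation-signal value: element 1 is the
#' untagged case (s = 0), element 2 the tagged case (s = 1). Tagged synapses
#' default to no elimination and no deconsolidation
#' (\code{p_e|1 = p_d|1 = 0}), the regime in which consolidated tagged
#' synapses escape further turnover.
#'
#' @param model \code{"A"} (deconsolidation 1 -> 0) or \code{"B"}
#'   (deconsolidation 1 -> pi).
#' @param p_c consolidation probabilities \code{c(p_c|0, p_c|1)}.
#' @param p_e elimination probabilities \code{c(p_e|0, p_e|1)}.
#' @param p_d deconsolidation probabilities \code{c(p_d|0, p_d|1)}.
#' @param p_g synaptogenesis probability, or \code{"homeostatic"} to balance
#'   generation against elimination each step.
#' @return Object of class \code{"plasticity_params"}.
#' @export
plasticity_params <- function(model = c("A", "B"),
                              p_c = c(0, 1), p_e = c(0.01, 0),
                              p_d = c(0, 0), p_g = "homeostatic") {
  model <- match.arg(model)
  chk <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, 2L)
    if (any(x < 0 | x > 1)) stop(nm, " must lie in [0, 1]")
    x
  }
  p_c <- chk(p_c, "p_c"); p_e <- chk(p_e, "p_e"); p_d <- chk(p_d, "p_d")
  if (any(p_c + p_e > 1))
    stop("per-state exit probabilities p_c|s + p_e|s must not exceed 1")
  homeostatic <- identical(p_g, "homeostatic")
  if (!homeostatic) {
    if (!is.numeric(p_g) || p_g < 0 || p_g > 1)
      stop("p_g must be a probability or \"homeostatic\"")
  } else p_g <- NA_real_
  structure(list(model = model, p_c = p_c, p_e = p_e, p_d = p_d,
                 p_g = p_g, homeostatic = homeostatic),
            class = "plasticity_params")
}

#' Initialize a population of potential synapses
#'
#' Places actual synapses uniformly at random among the potential locations
#' (independent of the consolidation tags), and consolidated synapses
#' uniformly among the actual ones, matching target anatomical connectivity
#' \code{P_init} and consolidated fraction \code{P1_init} (as fractions of
#' all \code{m*n} neuron pairs).
#'
#' @param potential_mask \code{m x n} 0/1 matrix of potential locations
#'   (at most one potential synapse per pair).
#' @param signal \code{m x n} consolidation-signal matrix.
#' @param P_init initial anatomical connectivity.
#' @param P1_init initial consolidated fraction (\code{<= P_init}).
#' @param seed optional seed.
#' @return Object of class \code{"synapse_population"}: parallel vectors of
#'   synapse states and signals over the potential locations, plus the
#'   pair-level bookkeeping needed by \code{\link{measure_connectivity}}.
#' @export
synapse_population <- function(potential_mask, signal, P_init, P1_init = 0,
                               seed = NULL) {
  mn <- length(potential_mask)
  if (length(signal) != mn) stop("signal and mask dimensions differ")
  pot_idx <- which(potential_mask != 0)
  n_pot <- length(pot_idx)
  n_act <- round(P_init * mn)
  n_cons <- round(P1_init * mn)
  if (n_cons > n_act || n_act > n_pot)
    stop("need P1_init <= P_init <= P_pot")
  .local_seed(seed)
  states <- rep(.ST_PI, n_pot)
  act <- sample.int(n_pot, n_act)
  states[act] <- .ST_SILENT
  if (n_cons > 0)
    states[act[sample.int(n_act, n_cons)]] <- .ST_CONS
  structure(list(states = states, signal = as.integer(signal[pot_idx] != 0),
                 pair_index = pot_idx, mn = mn,
                 n_tagged = sum(signal != 0),
                 depleted = FALSE),
            class = "synapse_population")
}

#' @export
print.synapse_population <- function(x, ...) {
  cat(sprintf(
    "synapse_population: %d potential synapses over %d pairs (P_pot = %.3g)\n",
    length(x$states), x$mn, length(x$states) / x$mn))
  cat(sprintf("  states: pi %d | silent %d | consolidated %d\n",
              sum(x$states == .ST_PI), sum(x$states == .ST_SILENT),
              sum(x$states == .ST_CONS)))
  invisible(x)
}

#' Connectivity summary of a synapse population
#'
#' @param pop a \code{synapse_population}.
#' @return List \code{P, P_pot, P_1, P_1S, P_eff} (pair-level fractions).
#' @export
population_connectivities <- function(pop) {
  mn <- pop$mn
  cons <- pop$states == .ST_CONS
  list(P = sum(pop$states != .ST_PI) / mn,
       P_pot = length(pop$states) / mn,
       P_1 = sum(cons) / mn,
       P_1S = pop$n_tagged / mn,
       P_eff = if (pop$n_tagged > 0) sum(cons & pop$signal != 0) / pop$n_tagged
               else NA_real_)
}

#' One synchronous update step of the microscopic synapse model
#'
#' All transitions are evaluated against the start-of-step state. Outside
#' rehearsal (\code{rehearsing = FALSE}) every synapse uses the untagged
#' (s = 0) parameters with consolidation switched off: tags act only while
#' the memory set is being rehearsed.
#'
#' @param pop a \code{synapse_population}.
#' @param params a \code{plasticity_params}.
#' @param rehearsing logical.
#' @param apply_pg logical; apply probabilistic synaptogenesis pi -> 0 with
#'   the fixed \code{params$p_g} (ignored for homeostatic parameter sets,
#'   where regrowth is handled by \code{\link{homeostatic_generation}}).
#' @return The updated population, with attribute \code{"eliminated"} giving
#'   the number of synapses removed in this step (0 -> pi, plus 1 -> pi for
#'   model B).
#' @export
step_micro <- function(pop, params, rehearsing = TRUE, apply_pg = !params$homeostatic) {
  st <- pop$states
  sig <- if (rehearsing) pop$signal else integer(length(st))
  p_c <- if (rehearsing) params$p_c else c(0, 0)
  p_e <- params$p_e
  p_d <- params$p_d
  idx0 <- which(st == .ST_SILENT)
  idx1 <- which(st == .ST_CONS)
  eliminated <- 0L
  if (length(idx0)) {
    s0 <- sig[idx0] + 1L
    r <- runif(length(idx0))
    up <- r < p_c[s0]
    out <- !up & r < p_c[s0] + p_e[s0]
    st[idx0[up]] <- .ST_CONS
    st[idx0[out]] <- .ST_PI
    eliminated <- eliminated + sum(out)
  }
  if (length(idx1)) {
    s1 <- sig[idx1] + 1L
    down <- runif(length(idx1)) < p_d[s1]
    if (params$model == "A") {
      st[idx1[down]] <- .ST_SILENT
    } else {
      st[idx1[down]] <- .ST_PI
      eliminated <- eliminated + sum(down)
    }
  }
  if (apply_pg && !params$homeostatic && params$p_g > 0) {
    idxp <- which(pop$states == .ST_PI)  # snapshot: not the newly eliminated
    if (length(idxp)) {
      grow <- runif(length(idxp)) < params$p_g
      st[idxp[grow]] <- pmax(st[idxp[grow]], .ST_SILENT)
    }
  }
  pop$states <- st
  attr(pop, "eliminated") <- eliminated
  pop
}

#' Homeostatic synaptogenesis
#'
#' Balances synapse elimination by regrowth at potential locations. In
#' \code{"exact"} mode exactly \code{min(eliminated, #pi)} new silent
#' synapses appear at uniformly chosen pi locations, keeping anatomical
#' connectivity constant until the pi pool depletes; \code{"probabilistic"}
#' mode instead grows each pi synapse independently with
#' \code{p_g = eliminated / #pi} (clipped to [0, 1]), balancing only in
#' expectation.
#'
#' @param pop a \code{synapse_population}.
#' @param eliminated number of synapses eliminated this step.
#' @param mode \code{"exact"} or \code{"probabilistic"}.
#' @param candidates optional index vector of pi locations eligible for
#'   regrowth (e.g. the start-of-step pi snapshot, so a synapse eliminated in
#'   this step cannot regrow immediately).
#' @return Updated population; \code{pop$depleted} is set if the pi pool ran
#'   out.
#' @export
homeostatic_generation <- function(pop, eliminated,
                                   mode = c("exact", "probabilistic"),
                                   candidates = NULL) {
  mode <- match.arg(mode)
  if (eliminated <= 0) return(pop)
  if (is.null(candidates)) candidates <- which(pop$states == .ST_PI)
  else candidates <- candidates[pop$states[candidates] == .ST_PI]
  n_pi <- length(candidates)
  if (n_pi == 0L) {
    pop$depleted <- TRUE
    warning("pi-synapse pool depleted: no regrowth possible")
    return(pop)
  }
  if (mode == "exact") {
    ngrow <- min(eliminated, n_pi)
    if (ngrow < eliminated) pop$depleted <- TRUE
    grow <- candidates[sample.int(n_pi, ngrow)]
  } else {
    p_g <- min(1, eliminated / n_pi)
    grow <- candidates[runif(n_pi) < p_g]
  }
  pop$states[grow] <- .ST_SILENT
  pop
}

#' Simulate a rehearsal protocol at the single-synapse level
#'
#' Iterates \code{\link{step_micro}} plus homeostatic regrowth over
#' \code{t = 1, .., t_end} and records the pair-level connectivity measures
#' after every step. Step \code{t} is a rehearsal step iff \code{t - 1} is in
#' \code{schedule} (0-based step times, as produced by
#' \code{\link{rehearsal_schedule}}).
#'
#' @param pop a \code{synapse_population}.
#' @param params a \code{plasticity_params}.
#' @param schedule integer vector of 0-based rehearsal step times.
#' @param t_end number of steps to simulate.
#' @param homeostasis \code{"exact"}, \code{"probabilistic"}, or
#'   \code{"none"} (use the fixed \code{params$p_g}).
#' @param seed optional seed for the whole trajectory.
#' @return \code{data.frame} with columns
#'   \code{t, P, P_pot, P_1, P_eff, rehearsing}; attribute
#'   \code{"population"} holds the final state.
#' @export
run_protocol_micro <- function(pop, params, schedule, t_end,
                               homeostasis = c("exact", "probabilistic", "none"),
                               seed = NULL) {
  homeostasis <- match.arg(homeostasis)
  .local_seed(seed)
  schedule <- as.integer(schedule)
  if (homeostasis == "none")
    return(.run_protocol_micro_generic(pop, params, schedule, t_end))
  # fast path: synchronous transitions with incremental bookkeeping of the
  # pi pool and the consolidated-tagged count (semantics identical to
  # step_micro + homeostatic_generation with start-of-step pi candidates)
  st <- pop$states
  sig <- pop$signal
  mn <- pop$mn
  modelB <- params$model == "B"
  pi_pool <- which(st == .ST_PI)
  n1 <- sum(st == .ST_CONS)
  n0 <- sum(st == .ST_SILENT)
  cons_tag <- sum(st == .ST_CONS & sig != 0)
  n_tag <- pop$n_tagged
  P_pot <- length(st) / mn
  Pv <- P1v <- Peffv <- numeric(t_end + 1L)
  rehv <- logical(t_end + 1L)
  Pv[1L] <- (n0 + n1) / mn; P1v[1L] <- n1 / mn
  Peffv[1L] <- if (n_tag > 0) cons_tag / n_tag else NA_real_
  depleted <- FALSE
  for (t in seq_len(t_end)) {
    reh <- (t - 1L) %in% schedule
    p_c <- if (reh) params$p_c else c(0, 0)
    p_e <- params$p_e; p_d <- params$p_d
    idx0 <- which(st == .ST_SILENT)
    idx1 <- which(st == .ST_CONS)
    elim_idx <- integer(0)
    if (length(idx0)) {
      s0 <- if (reh) sig[idx0] + 1L else rep(1L, length(idx0))
      r <- runif(length(idx0))
      up <- r < p_c[s0]
      out <- !up & r < p_c[s0] + p_e[s0]
      up_idx <- idx0[up]
      st[up_idx] <- .ST_CONS
      elim_idx <- idx0[out]
      st[elim_idx] <- .ST_PI
      n1 <- n1 + length(up_idx)
      n0 <- n0 - length(up_idx) - length(elim_idx)
      cons_tag <- cons_tag + sum(sig[up_idx])
    }
    if (length(idx1)) {
      s1 <- if (reh) sig[idx1] + 1L else rep(1L, length(idx1))
      down_idx <- idx1[runif(length(idx1)) < p_d[s1]]
      if (length(down_idx)) {
        n1 <- n1 - length(down_idx)
        cons_tag <- cons_tag - sum(sig[down_idx])
        if (modelB) {
          st[down_idx] <- .ST_PI
          elim_idx <- c(elim_idx, down_idx)
        } else {
          st[down_idx] <- .ST_SILENT
          n0 <- n0 + length(down_idx)
        }
      }
    }
    eliminated <- length(elim_idx)
    if (eliminated > 0L) {
      n_pi <- length(pi_pool)
      if (n_pi == 0L) {
        if (!depleted) warning("pi-synapse pool depleted: no regrowth possible")
        depleted <- TRUE
      } else if (homeostasis == "exact") {
        ngrow <- min(eliminated, n_pi)
        if (ngrow < eliminated) depleted <- TRUE
        pick <- sample.int(n_pi, ngrow)
        grow <- pi_pool[pick]
        st[grow] <- .ST_SILENT
        n0 <- n0 + ngrow
        pi_pool <- pi_pool[-pick]
      } else {
        p_g <- min(1, eliminated / n_pi)
        ngrow <- rbinom(1L, n_pi, p_g)
        if (ngrow > 0L) {
          pick <- sample.int(n_pi, ngrow)
          grow <- pi_pool[pick]
          st[grow] <- .ST_SILENT
          n0 <- n0 + ngrow
          pi_pool <- pi_pool[-pick]
        }
      }
    }
    if (eliminated > 0L) pi_pool <- c(pi_pool, elim_idx)
    Pv[t + 1L] <- (n0 + n1) / mn
    P1v[t + 1L] <- n1 / mn
    Peffv[t + 1L] <- if (n_tag > 0) cons_tag / n_tag else NA_real_
    rehv[t + 1L] <- reh
  }
  pop$states <- st
  pop$depleted <- depleted
  traj <- data.frame(t = 0:t_end, P = Pv, P_pot = P_pot, P_1 = P1v,
                     P_eff = Peffv, rehearsing = rehv)
  attr(traj, "population") <- pop
  traj
}

.run_protocol_micro_generic <- function(pop, params, schedule, t_end) {
  rec <- function(t, reh) {
    cc <- population_connectivities(pop)
    data.frame(t = t, P = cc$P, P_pot = cc$P_pot, P_1 = cc$P_1,
               P_eff = cc$P_eff, rehearsing = reh)
  }
  out <- vector("list", t_end + 1L)
  out[[1L]] <- rec(0L, FALSE)
  for (t in seq_len(t_end)) {
    reh <- (t - 1L) %in% schedule
    pop <- step_micro(pop, params, rehearsing = reh)
    out[[t + 1L]] <- rec(t, reh)
  }
  traj <- do.call(rbind, out)
  attr(traj, "population") <- pop
  traj
}

#' Expand rehearsal intervals into step times
#'
#' @param intervals list of \code{c(start, end)} inclusive 0-based step
#'   intervals, or a numeric vector of single step times.
#' @return Sorted integer vector of rehearsal step times.
#' @export
rehearsal_schedule <- function(intervals) {
  if (is.numeric(intervals)) return(sort(unique(as.integer(intervals))))
  sort(unique(unlist(lapply(intervals, function(iv)
    seq.int(iv[1], iv[length(iv)])))))
}
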