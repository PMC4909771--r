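# Closed-form spacing-effect theory (synapse model B with p_c|s = s and
# p_e|1 = p_d|1 = 0): effectual connectivity reached by a brief second
# rehearsal after a gap of length dt, and the optimal gap.

#' Parameter set for the spacing-effect theory
#'
#' Defaults are the physiologically motivated cortical values: potential
#' connectivity 0.4, anatomical connectivity 0.1, 20\% of synapses initially
#' consolidated, and a small consolidation load for a novel fact set that is
#' negligible against older memories. One time step corresponds to one hour
#' when comparing with behavioral protocols.
#'
#' @param P anatomical connectivity.
#' @param P_pot potential connectivity.
#' @param P1_t0 initial consolidated fraction at time 0.
#' @param P_1S consolidation load of the novel memory set.
#' @param p_e0 elimination probability of untagged silent synapses per step.
#' @param p_d0 deconsolidation probability of untagged synapses per step.
#' @param Peff1 performance level (effectual connectivity) reached at the end
#'   of the initial study session.
#' @param t1 duration of the initial study session (steps).
#' @return Object of class \code{"spacing_params"}; \code{alpha} is the
#'   turnover/deconsolidation rate ratio
#'   \eqn{\alpha = \ln(1-p_{e|0}) / \ln(1-p_{d|0})}.
#' @export
spacing_params <- function(P = 0.1, P_pot = 0.4, P1_t0 = 0.02, P_1S = 0.001,
                           p_e0 = 0.01, p_d0 = 2e-4, Peff1, t1 = 10) {
  if (!(P1_t0 <= P && P <= P_pot && P_pot <= 1))
    stop("need P1_t0 <= P <= P_pot <= 1")
  if (p_d0 < 0 || p_d0 >= 1 || p_e0 < 0 || p_e0 >= 1)
    stop("rates must lie in [0, 1)")
  alpha <- if (p_d0 > 0) log1p(-p_e0) / log1p(-p_d0) else NA_real_
  structure(list(P = P, P_pot = P_pot, P1_t0 = P1_t0, P_1S = P_1S,
                 p_e0 = p_e0, p_d0 = p_d0, Peff1 = Peff1, t1 = t1,
                 alpha = alpha),
            class = "spacing_params")
}

#' Consolidated fraction at the end of the initial study session
#'
#' \eqn{P_1(t_1) = P_1(t_0)(1-P_{1S})(1-p_{d|0})^{t_1} + P_{1S} P_{eff}^{(1)}}:
#' pre-existing consolidated synapses outside the new tag set decay by
#' deconsolidation, while the tagged pairs carry the performance level
#' reached during study.
#'
#' @param params a \code{spacing_params}.
#' @param t1 study duration (defaults to \code{params$t1}).
#' @export
p1_at_t1 <- function(params, t1 = params$t1) {
  params$P1_t0 * (1 - params$P_1S) * (1 - params$p_d0)^t1 +
    params$P_1S * params$Peff1
}

#' Effectual connectivity reached by a second rehearsal after a gap
#'
#' Closed-form model-B expression for the performance attained by a brief
#' re-study after a gap of \code{dt} steps during which untagged dynamics
#' (turnover \code{p_e0}, deconsolidation \code{p_d0}, homeostatic regrowth)
#' act on the network. With \eqn{x_d = (1-p_{d|0})^{\Delta t}},
#' \eqn{x_e = (1-p_{e|0})^{\Delta t}} and \eqn{P_1(t_1)} from
#' \code{\link{p1_at_t1}}:
#' \deqn{P_{eff}^{(2)} = \frac{P P_{pot} + [(P_{pot}-P) P_{eff}^{(1)} -
#'   P_{pot} P_1(t_1)] x_d - P_{pot} (P - P_1(t_1)) x_e}
#'   {P_{pot} - P_1(t_1) x_d - (P - P_1(t_1)) x_e}.}
#' At \code{dt = 0} this reduces identically to \eqn{P_{eff}^{(1)}}.
#'
#' @param params a \code{spacing_params}.
#' @param dt gap length in steps (vectorized).
#' @export
peff_after_gap <- function(params, dt) {
  P <- params$P; Ppot <- params$P_pot
  Peff1 <- params$Peff1
  P1t1 <- p1_at_t1(params)
  xd <- (1 - params$p_d0)^dt
  xe <- (1 - params$p_e0)^dt
  num <- P * Ppot + ((Ppot - P) * Peff1 - Ppot * P1t1) * xd -
    Ppot * (P - P1t1) * xe
  den <- Ppot - P1t1 * xd - (P - P1t1) * xe
  if (any(den <= 0))
    stop("vanishing denominator in the gap formula (P1(t1) = ", P1t1,
         ", dt = ", paste(dt[den <= 0], collapse = ", "), ")")
  num / den
}

#' Effectual connectivity at test time
#'
#' After the second rehearsal the tagged consolidated synapses decay
#' exponentially: \eqn{P_{eff}^{(3)} = P_{eff}^{(2)} (1-p_{d|0})^{RI}}. The
#' retention interval only scales the curve, so the optimal gap does not
#' depend on it.
#'
#' @param params a \code{spacing_params}.
#' @param dt gap length (steps).
#' @param RI retention interval (steps).
#' @export
peff_at_test <- function(params, dt, RI) {
  peff_after_gap(params, dt) * (1 - params$p_d0)^RI
}

#' Optimal rehearsal gap
#'
#' Solves the stationarity condition of the gap formula,
#' \deqn{\frac{P_{eff}^{(1)} - P_1(t_1)}{P - P_1(t_1)} +
#'   (\alpha - 1) \frac{P_{eff}^{(1)}}{P_{pot}} x^\alpha -
#'   \alpha x^{\alpha - 1} = 0,}
#' for \eqn{x = (1-p_{d|0})^{\Delta t} \in (0, 1)} by safeguarded Newton
#' iteration (bisection fallback, tolerance 1e-12), where
#' \eqn{\alpha = \ln(1-p_{e|0})/\ln(1-p_{d|0})}. A finite interior optimum
#' requires \eqn{\alpha > 1}, i.e. turnover faster than deconsolidation.
#'
#' @param params a \code{spacing_params}.
#' @return List with the root \code{x_opt}, \code{alpha}, the continuous
#'   optimum \code{dt_opt}, the best integer gap \code{dt_int} under
#'   \code{\link{peff_at_test}}, and \code{boundary} (\code{NA} for an
#'   interior root, otherwise \code{"0"} or \code{"Inf"} for monotone
#'   cases).
#' @export
optimal_gap <- function(params) {
  p_d0 <- params$p_d0; p_e0 <- params$p_e0
  if (p_d0 <= 0 || p_d0 >= 1 || p_e0 <= 0 || p_e0 >= 1)
    stop("optimal_gap needs 0 < p_d0 < 1 and 0 < p_e0 < 1")
  alpha <- log1p(-p_e0) / log1p(-p_d0)
  P1t1 <- p1_at_t1(params)
  cc <- (params$Peff1 - P1t1) / (params$P - P1t1)
  bb <- (alpha - 1) * params$Peff1 / params$P_pot
  g <- function(x) cc + bb * x^alpha - alpha * x^(alpha - 1)
  dg <- function(x) alpha * bb * x^(alpha - 1) - alpha * (alpha - 1) * x^(alpha - 2)
  # bracket a sign change on (0, 1)
  grid <- c(1e-12, 10^seq(-8, -0.0001, length.out = 400))
  gv <- g(grid)
  sw <- which(gv[-1] * gv[-length(gv)] <= 0)
  if (!length(sw)) {
    # g < 0 corresponds to P_eff^(2) rising with dt, g > 0 to falling:
    # all-positive means the gap never helps (optimum 0), all-negative means
    # it always helps (optimum at infinity)
    side <- if (all(gv > 0)) "0" else "Inf"
    dt_b <- if (side == "0") 0 else Inf
    return(list(x_opt = NA_real_, alpha = alpha, dt_opt = dt_b,
                dt_int = dt_b, boundary = side))
  }
  lo <- grid[sw[1]]; hi <- grid[sw[1] + 1]
  x <- (lo + hi) / 2
  for (it in 1:200) {
    gx <- g(x)
    if (gx > 0) lo <- x else hi <- x
    step <- gx / dg(x)
    xn <- x - step
    if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
    if (abs(xn - x) < 1e-12) { x <- xn; break }
    x <- xn
  }
  dt_opt <- log(x) / log1p(-p_d0)
  cand <- unique(pmax(0, c(floor(dt_opt), ceiling(dt_opt))))
  vals <- vapply(cand, function(d) peff_at_test(params, d, RI = 0), numeric(1))
  list(x_opt = x, alpha = alpha, dt_opt = dt_opt,
       dt_int = cand[which.max(vals)], boundary = NA_character_)
}

#' Default parameters for the two-session rehearsal protocol
#'
#' The named configuration used for the long-interval spacing experiments:
#' plasticity with \code{p_c|s = s}, no elimination or deconsolidation of
#' tagged synapses, homeostatic synaptogenesis, and network constants
#' \code{P_pot = 0.4}, \code{P = 0.1}, \code{P1(t0) = 0.02},
#' \code{P_1S = 0.001}. One time step represents one hour.
#'
#' @param p_e0,p_d0 untagged elimination / deconsolidation rates.
#' @param model synapse model variant.
#' @return List with \code{params} (a \code{plasticity_params}) and the
#'   network constants.
#' @export
cepeda_params <- function(p_e0 = 0.01, p_d0 = 2e-4, model = "B") {
  list(params = plasticity_params(model = model, p_c = c(0, 1),
                                  p_e = c(p_e0, 0), p_d = c(p_d0, 0),
                                  p_g = "homeostatic"),
       P = 0.1, P_pot = 0.4, P1_t0 = 0.02, P_1S = 0.001)
}

#' Simulate a two-session spacing protocol over gap and retention grids
#'
#' For every combination of gap and retention interval: an initial study of
#' \code{tr1} rehearsal steps, a gap of \code{dt} steps, a brief re-study of
#' \code{tr2} steps, then \code{RI} steps of decay; the final effectual
#' connectivity is recorded as the performance proxy. Run with the
#' macroscopic engine for either synapse model.
#'
#' @param cfg configuration as returned by \code{\link{cepeda_params}}.
#' @param dt_grid integer vector of gap lengths (steps).
#' @param ri_grid integer vector of retention intervals (steps; use 24 *
#'   days when one step is one hour).
#' @param tr1,tr2 rehearsal durations of the first and second session.
#' @return \code{data.frame} with columns
#'   \code{dt, ri, peff1, peff2, peff3}.
#' @export
run_cepeda_protocol <- function(cfg, dt_grid, ri_grid, tr1 = 10, tr2 = 1) {
  params <- cfg$params
  base <- init_macro(cfg$P, cfg$P_pot, cfg$P1_t0, cfg$P_1S)
  for (t in seq_len(tr1)) base <- step_macro(base, params, rehearsing = TRUE)
  peff1 <- network_connectivities(base)$P_eff
  out <- vector("list", length(dt_grid))
  for (di in seq_along(dt_grid)) {
    st <- base
    for (t in seq_len(dt_grid[di]))
      st <- step_macro(st, params, rehearsing = FALSE)
    for (t in seq_len(tr2))
      st <- step_macro(st, params, rehearsing = TRUE)
    peff2 <- network_connectivities(st)$P_eff
    # during retention the tagged consolidated fraction decays geometrically
    # with factor 1 - p_d|0 per step (both model variants), so P_eff does too
    peff3 <- peff2 * (1 - params$p_d[1])^ri_grid
    out[[di]] <- data.frame(dt = dt_grid[di], ri = ri_grid,
                            peff1 = peff1, peff2 = peff2, peff3 = peff3)
  }
  do.call(rbind, out)
}
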