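# Exact finite-size retrieval-error and storage-capacity analysis of the
# (diluted) Willshaw network under the i.i.d. component pattern model.

#' Binary entropy in bits
#'
#' \eqn{H_b(p) = -p \log_2 p - (1-p)\log_2(1-p)} with \eqn{0 \log 0 := 0}.
#' @param p probability (vectorized).
#' @export
binary_entropy <- function(p) {
  h <- function(x) ifelse(x <= 0 | x >= 1, 0, -x * log2(x))
  h(p) + h(1 - p)
}

#' Transinformation of one memory bit over a binary channel
#'
#' Mutual information (bits) between a stored component \eqn{v_j \sim
#' Bernoulli(q)} and its retrieved value under add-error probability
#' \code{q01} and miss-error probability \code{q10}: with output marginal
#' \eqn{\hat q = q(1-q_{10}) + (1-q) q_{01}},
#' \deqn{T = H_b(\hat q) - q H_b(q_{10}) - (1-q) H_b(q_{01}).}
#'
#' @param q activity of the content pattern components.
#' @param q01,q10 component error probabilities.
#' @export
transinfo_binary <- function(q, q01, q10) {
  qhat <- q * (1 - q10) + (1 - q) * q01
  binary_entropy(qhat) - q * binary_entropy(q10) - (1 - q) * binary_entropy(q01)
}

#' Exact component error rates of one-step Willshaw retrieval
#'
#' For a diluted Willshaw network (each required synapse present
#' independently with probability \code{P_eff}) storing \code{M} i.i.d.
#' random pattern pairs, queried with a noiseless address of \code{k} active
#' units and a fixed firing threshold \code{theta}:
#' \itemize{
#'   \item high units (\eqn{v_j = 1}): every member synapse is potentiated,
#'     so the dendritic potential is \eqn{X \sim Binom(k, P_{eff})} and the
#'     miss rate is \eqn{q_{10} = \Pr[X < \Theta]};
#'   \item low units: conditioned on the unit usage \eqn{B \sim
#'     Binom(M-1, q)} (number of other memories containing the unit), each
#'     active address unit is potentiated onto it with probability
#'     \eqn{\pi_1(B) = 1-(1-k/m)^B}, independently, so
#'     \eqn{X|B \sim Binom(k, P_{eff}\,\pi_1(B))} and
#'     \eqn{q_{01} = \sum_B \Pr[B] \Pr[X \ge \Theta | B]}.
#' }
#' The usage sum is truncated where the binomial tail mass falls below
#' 1e-14 and renormalized.
#'
#' @param M number of stored memories (>= 1).
#' @param k,l,m,n assembly sizes and population sizes.
#' @param P_eff effectual connectivity in (0, 1].
#' @param theta firing threshold(s) in \code{0..k}; vectorized.
#' @return List with vectors \code{q01}, \code{q10}, \code{eps_hat}
#'   (\eqn{\hat\epsilon = q_{10} + (1/q - 1) q_{01}}) and \code{theta}.
#' @export
error_rates_exact <- function(M, k, l, m, n, P_eff, theta) {
  if (P_eff <= 0 || P_eff > 1) stop("need 0 < P_eff <= 1")
  if (any(theta < 0 | theta > k)) stop("theta must lie in 0..k")
  q <- l / n
  q10 <- pbinom(theta - 1, k, P_eff)
  if (M < 1) stop("need M >= 1")
  B_lo <- qbinom(1e-14, M - 1, q)
  B_hi <- qbinom(1e-14, M - 1, q, lower.tail = FALSE)
  B <- B_lo:B_hi
  wB <- exp(dbinom(B, M - 1, q, log = TRUE))
  wB <- wB / sum(wB)
  pi1 <- -expm1(B * log1p(-k / m))
  p_hit <- P_eff * pi1
  q01 <- vapply(theta, function(th) {
    if (th == 0) return(1)
    sum(wB * pbinom(th - 1, k, p_hit, lower.tail = FALSE))
  }, numeric(1))
  list(theta = theta, q01 = q01, q10 = q10,
       eps_hat = q10 + (1 / q - 1) * q01)
}

#' Threshold-optimal error rates
#'
#' Scans all integer thresholds \code{0..k} and returns the rates minimizing
#' the output noise; ties go to the smallest threshold.
#'
#' @inheritParams error_rates_exact
#' @return List \code{theta, q01, q10, eps_hat} (scalars).
#' @export
min_noise_over_theta <- function(M, k, l, m, n, P_eff) {
  er <- error_rates_exact(M, k, l, m, n, P_eff, theta = 0:k)
  i <- which.min(er$eps_hat)
  list(theta = er$theta[i], q01 = er$q01[i], q10 = er$q10[i],
       eps_hat = er$eps_hat[i])
}

#' Pattern capacity and storage capacities of a finite Willshaw network
#'
#' Finds the maximal number of memories \eqn{M_\epsilon} whose
#' threshold-optimal output noise stays at or below \code{eps}, by
#' exponential bracketing followed by integer bisection (output noise is
#' non-decreasing in M; this is asserted on the evaluated points). From the
#' optimum it reports the 1-synapse fraction \eqn{p_1}, the minimal pruned
#' anatomical connectivity \eqn{P_1 = p_1 P_{eff}}, the absolute stored
#' information \eqn{C_{abs} = M n T(q, q_{01}, q_{10})}, the weight-plasticity
#' capacity per synapse \eqn{C^{wp} = C_{abs}/(P_{eff} m n)} and the total
#' capacity per non-silent synapse \eqn{C^{tot} = C_{abs}/(P_1 m n)}.
#'
#' @inheritParams error_rates_exact
#' @param eps target output-noise level (> 0), e.g. 0.01 for high fidelity.
#' @return Object of class \code{"capacity_result"}.
#' @export
pattern_capacity <- function(k, l, m, n, P_eff, eps) {
  if (eps <= 0) stop("eps must be positive")
  f <- function(M) min_noise_over_theta(M, k, l, m, n, P_eff)
  e1 <- f(1)
  if (e1$eps_hat > eps) {
    return(structure(list(M_eps = 0L, theta = NA_integer_, q01 = NA_real_,
                          q10 = NA_real_, eps_hat = NA_real_, p1 = 0,
                          P_1 = 0, C_abs = 0, C_wp = 0, C_tot = 0,
                          k = k, l = l, m = m, n = n, P_eff = P_eff,
                          eps = eps), class = "capacity_result"))
  }
  lo <- 1; e_lo <- e1
  hi <- 2
  repeat {
    e_hi <- f(hi)
    if (e_hi$eps_hat < e_lo$eps_hat - 1e-9)
      stop("output noise decreased with M: monotonicity assumption violated")
    if (e_hi$eps_hat > eps) break
    lo <- hi; e_lo <- e_hi
    hi <- hi * 2
    if (hi > 2^42) stop("capacity bracketing failed to terminate")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    e_mid <- f(mid)
    if (e_mid$eps_hat < e_lo$eps_hat - 1e-9 ||
        e_mid$eps_hat > e_hi$eps_hat + 1e-9)
      stop("output noise not monotone in M during bisection")
    if (e_mid$eps_hat <= eps) { lo <- mid; e_lo <- e_mid }
    else { hi <- mid; e_hi <- e_mid }
  }
  M_eps <- lo
  opt <- e_lo
  q <- l / n
  p1 <- p1_expected(k, l, m, n, M_eps)
  P_1 <- p1 * P_eff
  C_abs <- M_eps * n * transinfo_binary(q, opt$q01, opt$q10)
  structure(list(M_eps = M_eps, theta = opt$theta, q01 = opt$q01,
                 q10 = opt$q10, eps_hat = opt$eps_hat, p1 = p1, P_1 = P_1,
                 C_abs = C_abs,
                 C_wp = C_abs / (P_eff * m * n),
                 C_tot = C_abs / (P_1 * m * n),
                 k = k, l = l, m = m, n = n, P_eff = P_eff, eps = eps),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("capacity_result (k = %g, m = n = %g, P_eff = %g, eps = %g):\n",
              x$k, x$n, x$P_eff, x$eps))
  cat(sprintf("  M_eps = %d at theta = %s (q01 = %.3g, q10 = %.3g)\n",
              x$M_eps, format(x$theta), x$q01, x$q10))
  cat(sprintf("  p1 = %.4g, P_1 = %.4g, C_wp = %.4g, C_tot = %.4g bit/synapse\n",
              x$p1, x$P_1, x$C_wp, x$C_tot))
  invisible(x)
}

#' Asymptotic weight-plasticity capacity of the fully connected Willshaw net
#'
#' In the high-fidelity large-network limit the stored information per
#' synapse is \eqn{C^{wp}(p_1) = \log_2(p_1)\,\ln(1-p_1)} bit/synapse, a
#' symmetric function of the fraction \eqn{p_1} of potentiated synapses with
#' maximum \eqn{\ln 2 \approx 0.69} at \eqn{p_1 = 1/2}. With structural
#' plasticity (silent synapses pruned) the per-non-silent-synapse capacity is
#' \eqn{C^{tot}(p_1) = C^{wp}(p_1)/p_1}, which grows without bound as
#' \eqn{p_1 \to 0}.
#'
#' @return List with \code{C_max} (bit/synapse), the maximizing \code{p1_opt},
#'   and the curves as functions \code{cwp(p1)}, \code{ctot(p1)}.
#' @export
asymptotic_willshaw_capacity <- function() {
  cwp <- willshaw_cwp_asymptotic
  opt <- optimize(cwp, interval = c(1e-9, 1 - 1e-9), maximum = TRUE,
                  tol = 1e-12)
  list(C_max = opt$objective, p1_opt = opt$maximum,
       cwp = cwp, ctot = willshaw_ctot_asymptotic)
}

#' @rdname asymptotic_willshaw_capacity
#' @param p1 fraction of potentiated synapses in (0, 1); vectorized.
#' @export
willshaw_cwp_asymptotic <- function(p1) {
  ifelse(p1 <= 0 | p1 >= 1, 0, log2(p1) * log(1 - p1))
}

#' @rdname asymptotic_willshaw_capacity
#' @export
willshaw_ctot_asymptotic <- function(p1) {
  willshaw_cwp_asymptotic(p1) / p1
}
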