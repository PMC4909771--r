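# Gaussian signal-to-noise capacity theory for the optimal (covariance /
# Bayesian) associative network and for binary zip nets with structural
# plasticity.

#' Zip factor: capacity retention of binarized Gaussian weights
#'
#' Thresholding optimally learned (Gaussian-distributed) synaptic weights at
#' their \eqn{(1-p_1)}-quantile retains the squared signal-to-noise fraction
#' \deqn{\zeta(p_1) = \frac{\phi(\Phi^{-1}(1-p_1))^2}{p_1 (1-p_1)},}
#' with standard normal density \eqn{\phi} and cdf \eqn{\Phi}. \eqn{\zeta}
#' is symmetric around its maximum \eqn{2/\pi \approx 0.64} at
#' \eqn{p_1 = 1/2}; at the boundaries the retention vanishes.
#'
#' @param p1 fraction of potentiated (1-)synapses; vectorized.
#' @export
zip_factor <- function(p1) {
  out <- numeric(length(p1))
  inside <- p1 > 0 & p1 < 1
  z <- qnorm(1 - p1[inside])
  out[inside] <- dnorm(z)^2 / (p1[inside] * (1 - p1[inside]))
  out
}

# squared SNR of the covariance rule at M stored memories and connectivity P
.snr2_covariance <- function(M, k, l, m, n, P) {
  p <- k / m; q <- l / n
  m * P * (1 - p) / ((M - 1) * q * (1 - q))
}

# Gaussian error rates for SNR r with threshold split gamma in (0, 1):
# the firing threshold sits at fraction gamma of the signal separation above
# the low-unit mean.
.gaussian_rates <- function(r, gamma, q) {
  q10 <- pnorm(-(1 - gamma) * r)
  q01 <- pnorm(-gamma * r)
  list(q01 = q01, q10 = q10, eps_hat = q10 + (1 / q - 1) * q01)
}

.min_eps_over_gamma <- function(r, q) {
  opt <- optimize(function(g) .gaussian_rates(r, g, q)$eps_hat,
                  interval = c(1e-9, 1 - 1e-9), tol = 1e-10)
  c(.gaussian_rates(r, opt$minimum, q), gamma = opt$minimum)
}

#' Gaussian-theory capacity of the optimal associative network
#'
#' Signal-to-noise analysis of the covariance learning rule (which attains
#' the optimal Bayesian performance to leading order at sparse activity):
#' the squared SNR at \code{M} stored memories and anatomical connectivity
#' \code{P} is \eqn{r^2 = m P (1-p) / ((M-1) q (1-q))}; Gaussian error rates
#' \eqn{q_{10} = \Phi(-(1-\gamma) r)}, \eqn{q_{01} = \Phi(-\gamma r)} with
#' the threshold split \eqn{\gamma} optimized to minimize output noise. The
#' pattern capacity is the largest \code{M} keeping the minimal noise at or
#' below \code{eps}.
#'
#' @inheritParams pattern_capacity
#' @param P anatomical connectivity of the (structurally static) network.
#' @return Object of class \code{"gaussian_capacity_result"} with
#'   \code{M_eps}, the SNR \code{r}, threshold split \code{gamma}, error
#'   rates, \code{C_abs} and \code{C_wp}.
#' @export
bayesian_capacity <- function(k, l, m, n, P, eps) {
  q <- l / n
  f <- function(M) .min_eps_over_gamma(sqrt(.snr2_covariance(M, k, l, m, n, P)), q)
  e2 <- f(2)
  if (e2$eps_hat > eps)
    return(structure(list(M_eps = 0L, r = NA_real_, gamma = NA_real_,
                          q01 = NA_real_, q10 = NA_real_, eps_hat = NA_real_,
                          C_abs = 0, C_wp = 0, zeta = 1,
                          k = k, l = l, m = m, n = n, P = P, eps = eps),
                     class = "gaussian_capacity_result"))
  lo <- 2; e_lo <- e2; hi <- 4
  repeat {
    e_hi <- f(hi)
    if (e_hi$eps_hat < e_lo$eps_hat - 1e-12)
      stop("output noise decreased with M: SNR monotonicity violated")
    if (e_hi$eps_hat > eps) break
    lo <- hi; e_lo <- e_hi; hi <- hi * 2
    if (hi > 2^48) stop("capacity bracketing failed to terminate")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    e_mid <- f(mid)
    if (e_mid$eps_hat <= eps) { lo <- mid; e_lo <- e_mid }
    else { hi <- mid; e_hi <- e_mid }
  }
  M_eps <- lo
  C_abs <- M_eps * n * transinfo_binary(q, e_lo$q01, e_lo$q10)
  structure(list(M_eps = M_eps,
                 r = sqrt(.snr2_covariance(M_eps, k, l, m, n, P)),
                 gamma = e_lo$gamma, q01 = e_lo$q01, q10 = e_lo$q10,
                 eps_hat = e_lo$eps_hat, C_abs = C_abs,
                 C_wp = C_abs / (P * m * n), zeta = 1,
                 k = k, l = l, m = m, n = n, P = P, eps = eps),
            class = "gaussian_capacity_result")
}

#' Gaussian-theory capacity of a binary zip net with structural plasticity
#'
#' A zip net keeps a fixed fraction \eqn{p_1 = P_1/P_{pot}} of its potential
#' synapses potentiated (homeostatic synaptic thresholds) and uses structural
#' plasticity to place the \eqn{P_1 m n} 1-synapses at the most useful
#' potential locations. Binarization reduces the squared SNR of the
#' underlying Gaussian (covariance-rule) network at connectivity
#' \eqn{P_{pot}} by the zip factor \eqn{\zeta(p_1)}, so the pattern capacity
#' is \eqn{M_\epsilon \approx \zeta \cdot M_\epsilon^{Gauss}(P_{pot})};
#' error rates are re-evaluated at the reduced SNR and the total capacity is
#' counted per realized (non-silent) synapse,
#' \eqn{C^{tot} = C_{abs}/(P_1 m n)}.
#'
#' @inheritParams bayesian_capacity
#' @param P1 realized (anatomical = potentiated) connectivity of the zip net.
#' @param P_pot potential connectivity (\code{P1 <= P_pot}).
#' @return A \code{"gaussian_capacity_result"} with \code{C_tot} and
#'   \code{zeta}; \code{degenerate = TRUE} flags the boundary
#'   \code{P1 == P_pot} where the binarization retention vanishes.
#' @export
zipnet_capacity <- function(k, l, m, n, P1, P_pot, eps) {
  if (P1 > P_pot) stop("infeasible: P1 must not exceed P_pot")
  p1 <- P1 / P_pot
  zeta <- zip_factor(p1)
  if (zeta == 0) {
    res <- structure(list(M_eps = 0L, r = 0, gamma = NA_real_,
                          q01 = NA_real_, q10 = NA_real_, eps_hat = NA_real_,
                          C_abs = 0, C_wp = 0, C_tot = 0, zeta = zeta,
                          degenerate = TRUE,
                          k = k, l = l, m = m, n = n, P1 = P1,
                          P_pot = P_pot, eps = eps),
                     class = "gaussian_capacity_result")
    warning("zip factor is zero at p1 = ", p1, ": degenerate configuration")
    return(res)
  }
  q <- l / n
  bay <- bayesian_capacity(k, l, m, n, P = P_pot, eps = eps)
  M_zip <- max(0, round(zeta * as.numeric(bay$M_eps)))
  if (M_zip < 2) {
    C_abs <- if (M_zip >= 1) M_zip * n * binary_entropy(q) else 0
    r_zip <- NA_real_; rates <- list(q01 = 0, q10 = 0); gamma <- NA_real_
  } else {
    r_zip <- sqrt(zeta * .snr2_covariance(M_zip, k, l, m, n, P_pot))
    e <- .min_eps_over_gamma(r_zip, q)
    rates <- e; gamma <- e$gamma
    C_abs <- M_zip * n * transinfo_binary(q, e$q01, e$q10)
  }
  structure(list(M_eps = M_zip, r = r_zip, gamma = gamma,
                 q01 = rates$q01, q10 = rates$q10,
                 eps_hat = rates$q10 + (1 / q - 1) * rates$q01,
                 C_abs = C_abs, C_wp = C_abs / (P_pot * m * n),
                 C_tot = C_abs / (P1 * m * n), zeta = zeta,
                 degenerate = FALSE,
                 k = k, l = l, m = m, n = n, P1 = P1, P_pot = P_pot,
                 eps = eps),
            class = "gaussian_capacity_result")
}

#' @export
print.gaussian_capacity_result <- function(x, ...) {
  cat(sprintf("gaussian_capacity_result: M_eps = %.0f (zeta = %.4g)\n",
              x$M_eps, x$zeta))
  if (!is.null(x$C_tot))
    cat(sprintf("  C_tot = %.4g bit/synapse", x$C_tot))
  cat(sprintf("  C_wp = %.4g bit/synapse, r = %.3g, gamma = %.3g\n",
              x$C_wp, x$r, x$gamma))
  invisible(x)
}
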