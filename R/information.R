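# Transfer-entropy bounds for one-step retrieval viewed as a memory channel.
#
# Under the i.i.d.-component reduction, the transfer entropy per output unit
# between the address and content populations is bracketed by the normalized
# storage capacity CN = T(q, q01, q10) from below and the output entropy
# OE = H_b(qhat) from above; TE = OE for deterministic retrieval, TE = CN
# for non-deterministic retrieval with independent output noise.

#' Channel bounds on normalized transfer entropy
#'
#' @param q activity of the content patterns.
#' @param q01,q10 component error probabilities of retrieval.
#' @return List with \code{CN} (normalized capacity, bits/unit), \code{OE}
#'   (output entropy), and the output-noise coordinate
#'   \eqn{\hat\epsilon = q\,q_{10} + (1-q)\,q_{01}} used on the reporting
#'   axis.
#' @export
channel_bounds <- function(q, q01, q10) {
  CN <- transinfo_binary(q, q01, q10)
  qhat <- q * (1 - q10) + (1 - q) * q01
  list(CN = CN, OE = binary_entropy(qhat), q = q, q01 = q01, q10 = q10,
       eps_hat = q * q10 + (1 - q) * q01)
}

#' Empirical transfer-entropy estimate from simulated retrievals
#'
#' Runs repeated one-step retrievals of stored memories through a weight
#' matrix (with optional intrinsic uniform noise on the dendritic
#' potentials), counts component add/miss errors against the true content
#' patterns, and forms the plug-in estimate of transfer entropy per output
#' unit: for deterministic retrieval (\code{noise_max = 0}) the output
#' entropy of the empirical output marginal; for noisy retrieval the
#' empirical channel capacity CN (the two regimes in which the theoretical
#' bounds are attained). Estimation goes through the i.i.d.-bit reduction of
#' the channel, not through histograms over full output patterns.
#'
#' @param W a \code{"weight_matrix"}.
#' @param patterns the stored \code{pattern_set}.
#' @param trials number of retrievals (memories drawn with replacement).
#' @param noise_max intrinsic noise bound \eqn{N_j \sim U[0, N_{max}]}.
#' @param strategy,theta,l retrieval strategy passed to
#'   \code{\link{retrieve}}; default l-winner at the pattern activity.
#' @param seed optional seed.
#' @return A \code{channel_bounds} list extended with \code{TE_estimate} and
#'   the empirical error counts.
#' @export
estimate_te_retrieval <- function(W, patterns, trials, noise_max = 0,
                                  strategy = "l-winner", theta = NULL,
                                  l = patterns$l, seed = NULL) {
  if (trials < 1) stop("need at least one retrieval trial")
  .local_seed(seed)
  mus <- sample.int(patterns$M, trials, replace = TRUE)
  n <- patterns$n
  n_hi <- 0; n_lo <- 0; add <- 0; miss <- 0; ones_out <- 0
  for (mu in mus) {
    u <- .binary_vec(patterns$u[[mu]], patterns$m)
    v <- .binary_vec(patterns$v[[mu]], n)
    r <- retrieve(W, u, strategy = strategy, theta = theta, l = l,
                  noise_max = noise_max)
    hi <- v == 1
    n_hi <- n_hi + sum(hi); n_lo <- n_lo + sum(!hi)
    miss <- miss + sum(r$v_hat[hi] == 0)
    add <- add + sum(r$v_hat[!hi] == 1)
    ones_out <- ones_out + sum(r$v_hat)
  }
  q_emp <- n_hi / (n_hi + n_lo)
  q10_emp <- miss / n_hi
  q01_emp <- add / n_lo
  cb <- channel_bounds(q_emp, q01_emp, q10_emp)
  cb$TE_estimate <- if (noise_max == 0)
    binary_entropy(ones_out / (trials * n))
  else cb$CN
  cb$counts <- list(add = add, miss = miss, n_hi = n_hi, n_lo = n_lo,
                    trials = trials)
  cb$noise_max <- noise_max
  cb
}
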