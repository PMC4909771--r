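# Binary pattern sets and associative storage/retrieval for Willshaw-type
# and zip networks. Patterns are kept as sorted 0-based index lists of
# active units; dense matrices are materialized only for simulation-scale
# networks (see .check_dense_size).

.check_dense_size <- function(m, n) {
  if (as.double(m) * as.double(n) > 1e8)
    stop("dense matrix of ", m, " x ", n,
         " exceeds the supported simulation scale; ",
         "use the analytic capacity functions for macrocolumn-size networks")
  invisible(TRUE)
}

.local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  invisible(old)
}

#' Generate a random binary memory pattern set
#'
#' Draws \code{M} address/content pattern pairs \eqn{(u^\mu, v^\mu)} over
#' populations of \code{m} and \code{n} units. In \code{"fixed"} mode each
#' address (content) pattern has exactly \code{k} (\code{l}) active units
#' drawn uniformly without replacement; in \code{"bernoulli"} mode each unit
#' is activated independently with probability \eqn{p = k/m} (\eqn{q = l/n}),
#' the i.i.d. component model underlying the capacity analyses.
#'
#' @param m,n population sizes of the address and content layer.
#' @param k,l mean number of active units per address/content pattern
#'   (the cell assembly sizes).
#' @param M number of memory pairs.
#' @param mode \code{"fixed"} or \code{"bernoulli"}; a length-2 vector gives
#'   the address and content mode separately.
#' @param auto logical; auto-association (requires \code{m == n},
#'   \code{k == l}); content patterns are then identical to the addresses.
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return An object of class \code{"pattern_set"}: a list with the pattern
#'   index lists \code{u}, \code{v} (0-based, sorted) and the parameters
#'   \code{m, n, k, l, M, p, q}.
#' @export
generate_patterns <- function(m, n = m, k, l = k, M,
                              mode = c("fixed", "bernoulli"),
                              auto = FALSE, seed = NULL) {
  if (length(mode) == 1L) mode <- rep(mode, 2L)
  mode <- vapply(mode[1:2], function(x)
    match.arg(x, c("fixed", "bernoulli")), character(1))
  if (m < 1 || n < 1 || k <= 0 || k > m || l <= 0 || l > n || M < 0)
    stop("invalid pattern parameters: need 0 < k <= m, 0 < l <= n, M >= 0")
  if (auto && (m != n || k != l))
    stop("auto-association requires m == n and k == l")
  .local_seed(seed)
  draw <- function(size, act, how) {
    if (how == "fixed") sort(sample.int(size, act) - 1L)
    else (which(runif(size) < act / size) - 1L)
  }
  u <- vector("list", M)
  v <- vector("list", M)
  mu <- 0L
  while (mu < M) {
    mu <- mu + 1L
    u[[mu]] <- draw(m, k, mode[1])
    v[[mu]] <- if (auto) u[[mu]] else draw(n, l, mode[2])
  }
  structure(list(u = u, v = v, m = m, n = n, k = k, l = l, M = M,
                 p = k / m, q = l / n, mode = mode, auto = auto),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: M = %d pairs, m = %d (k = %g), n = %d (l = %g)%s\n",
              x$M, x$m, x$k, x$n, x$l,
              if (isTRUE(x$auto)) ", auto-associative" else ""))
  invisible(x)
}

#' Convert pattern index lists to a dense binary matrix
#'
#' @param patterns a \code{pattern_set}.
#' @param side \code{"u"} or \code{"v"}.
#' @return \code{M x m} (or \code{M x n}) 0/1 matrix, one pattern per row.
#' @export
patterns_to_matrix <- function(patterns, side = c("u", "v")) {
  side <- match.arg(side)
  len <- if (side == "u") patterns$m else patterns$n
  .check_dense_size(max(patterns$M, 1L), len)
  out <- matrix(0L, nrow = patterns$M, ncol = len)
  pl <- patterns[[side]]
  for (mu in seq_len(patterns$M))
    out[mu, pl[[mu]] + 1L] <- 1L
  out
}

.binary_vec <- function(idx, len) {
  x <- integer(len)
  x[idx + 1L] <- 1L
  x
}

.as_weight_matrix <- function(W, mask, potentials, theta) {
  structure(list(W = W, mask = mask, potentials = potentials, theta = theta),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: %d x %d, %d one-synapses (p1 = %.4g), mask fill %.4g\n",
              nrow(x$W), ncol(x$W), sum(x$W != 0),
              mean(x$W != 0), mean(x$mask != 0)))
  invisible(x)
}

#' Store a pattern set with clipped Hebbian (Willshaw) learning
#'
#' Synaptic potentials are the co-activation counts
#' \eqn{\omega_{ij} = \sum_\mu u_i^\mu v_j^\mu}; a binary weight is set
#' wherever \eqn{\omega_{ij} \ge 1} and the anatomical mask admits a synapse.
#'
#' @param patterns a \code{pattern_set}.
#' @param mask optional \code{m x n} 0/1 anatomical connectivity mask
#'   (default: fully connected).
#' @return A \code{"weight_matrix"}: list with binary weights \code{W}, the
#'   \code{mask}, the integer co-activation counts \code{potentials}
#'   (computed on the full graph, reusable as a consolidation signal), and
#'   the synaptic threshold \code{theta = 1}.
#' @export
store_willshaw <- function(patterns, mask = NULL) {
  m <- patterns$m; n <- patterns$n
  .check_dense_size(m, n)
  if (is.null(mask)) mask <- matrix(1L, m, n)
  if (!all(dim(mask) == c(m, n)))
    stop("mask dimensions do not match the pattern populations")
  omega <- matrix(0, m, n)
  for (mu in seq_len(patterns$M)) {
    ui <- patterns$u[[mu]] + 1L
    vj <- patterns$v[[mu]] + 1L
    if (length(ui) && length(vj))
      omega[ui, vj] <- omega[ui, vj] + 1
  }
  W <- (omega >= 1) * (mask != 0)
  storage.mode(W) <- "integer"
  .as_weight_matrix(W, mask, omega, theta = 1)
}

#' Store a pattern set in a binary zip net with structural plasticity
#'
#' Computes real-valued synaptic potentials on the potential graph with the
#' covariance rule \eqn{\omega_{ij} = \sum_\mu (u_i^\mu - p)(v_j^\mu - q)} or
#' the homosynaptic rule \eqn{\sum_\mu u_i^\mu (v_j^\mu - q)}, then sets, per
#' postsynaptic neuron, the synaptic threshold at the quantile that realizes
#' a fraction \code{target_P1 / P_pot} of its potential synapses as
#' 1-synapses (homeostatic control of the fraction of potentiated synapses).
#' Structural plasticity is implicit: the realized anatomical graph is
#' exactly the chosen 1-synapses.
#'
#' Ties are broken by (potential value descending, row index ascending), so
#' results are reproducible; each column realizes
#' \code{ceiling(target_P1/P_pot * n_potential_j)} synapses.
#'
#' @param patterns a \code{pattern_set}.
#' @param potential_mask \code{m x n} 0/1 potential-connectivity mask
#'   (default fully connected).
#' @param target_P1 desired fraction of 1-synapses among all \code{m*n} pairs;
#'   must not exceed the potential connectivity of the mask.
#' @param rule \code{"covariance"} or \code{"homosynaptic"}.
#' @return A \code{"weight_matrix"} whose \code{mask} equals the realized
#'   (pruned) anatomical graph \code{W}; \code{theta} holds the per-neuron
#'   synaptic thresholds.
#' @export
store_zipnet <- function(patterns, potential_mask = NULL, target_P1,
                         rule = c("covariance", "homosynaptic")) {
  rule <- match.arg(rule)
  m <- patterns$m; n <- patterns$n
  .check_dense_size(m, n)
  if (is.null(potential_mask)) potential_mask <- matrix(1L, m, n)
  P_pot <- mean(potential_mask != 0)
  if (target_P1 <= 0 || target_P1 > P_pot)
    stop("infeasible target_P1: need 0 < target_P1 <= P_pot = ", P_pot)
  if (patterns$M > 0L) {
    U <- patterns_to_matrix(patterns, "u")
    V <- patterns_to_matrix(patterns, "v")
    omega <- if (rule == "covariance")
      crossprod(U - patterns$p, V - patterns$q)
    else
      crossprod(U, V - patterns$q)
  } else {
    omega <- matrix(0, m, n)
  }
  frac <- target_P1 / P_pot
  W <- matrix(0L, m, n)
  theta <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    pot <- which(potential_mask[, j] != 0)
    if (!length(pot)) next
    n1 <- min(length(pot), ceiling(frac * length(pot)))
    ord <- pot[order(-omega[pot, j], pot)]
    chosen <- ord[seq_len(n1)]
    W[chosen, j] <- 1L
    theta[j] <- omega[chosen[n1], j]
  }
  .as_weight_matrix(W, mask = W, potentials = omega, theta = theta)
}

#' One-step retrieval in a binary associative network
#'
#' Dendritic potentials are \eqn{x_j = \sum_i \tilde u_i W_{ij}}; optional
#' intrinsic noise \eqn{N_j \sim U[0, N_{max}]} is added before thresholding.
#' Threshold strategies:
#' \describe{
#'   \item{fixed}{scalar firing threshold \code{theta}.}
#'   \item{l-winner}{the maximal integer threshold that activates at least
#'     \code{l} neurons (winner-take-all with inhibition control).}
#'   \item{pattern-part}{per-neuron threshold \eqn{\Theta_j = \sum_i
#'     \tilde u_i mask_{ij}}: all anatomically connected active inputs must
#'     be potentiated, which guarantees zero miss errors for noiseless
#'     queries.}
#' }
#'
#' @param W a \code{"weight_matrix"}.
#' @param query binary vector of length \code{m}.
#' @param strategy one of \code{"fixed"}, \code{"l-winner"},
#'   \code{"pattern-part"}.
#' @param theta scalar threshold (strategy \code{"fixed"}).
#' @param l target number of winners (strategy \code{"l-winner"}).
#' @param noise_max upper bound of the uniform intrinsic noise (0 = none).
#' @param seed optional seed for the noise draw.
#' @return List with binary output \code{v_hat}, potentials \code{x},
#'   \code{theta_used}, the noise draws, and \code{empty_output} flag (set
#'   when an all-zero-potential l-winner query is answered with the empty
#'   pattern rather than with all units tied at zero).
#' @export
retrieve <- function(W, query,
                     strategy = c("fixed", "l-winner", "pattern-part"),
                     theta = NULL, l = NULL, noise_max = 0, seed = NULL) {
  strategy <- match.arg(strategy)
  Wm <- W$W
  if (length(query) != nrow(Wm)) stop("query length must equal m")
  x <- as.numeric(query %*% Wm)
  n <- ncol(Wm)
  .local_seed(seed)
  N <- if (noise_max > 0) runif(n, 0, noise_max) else numeric(n)
  s <- x + N
  empty_output <- FALSE
  if (strategy == "fixed") {
    if (is.null(theta)) stop("strategy 'fixed' needs a scalar theta")
    theta_used <- theta
    v_hat <- as.integer(s >= theta)
  } else if (strategy == "l-winner") {
    if (is.null(l)) stop("strategy 'l-winner' needs l")
    if (max(s) <= 0) {
      # all potentials zero: returning every unit tied at 0 is meaningless
      v_hat <- integer(n)
      theta_used <- NA_real_
      empty_output <- TRUE
      warning("l-winner retrieval with all-zero potentials: empty output")
    } else {
      srt <- sort(s, decreasing = TRUE)
      theta_used <- floor(srt[min(l, n)])
      v_hat <- as.integer(s >= theta_used)
    }
  } else {
    theta_used <- as.numeric(query %*% (W$mask != 0))
    v_hat <- as.integer(s >= theta_used)
  }
  list(v_hat = v_hat, x = x, theta_used = theta_used, noise = N,
       empty_output = empty_output)
}

#' Output noise of a retrieval result
#'
#' \eqn{\hat\epsilon = \sum_j |\hat v_j - v_j| / l}: the Hamming distance
#' between retrieved and stored pattern normalized by the mean assembly size.
#'
#' @param v_hat,v_true binary vectors of equal length.
#' @param l mean number of active units per content pattern (> 0).
#' @return List with \code{eps_hat} and the add/miss counts
#'   \code{q01_count}, \code{q10_count}.
#' @export
output_noise <- function(v_hat, v_true, l) {
  if (length(v_hat) != length(v_true)) stop("length mismatch")
  if (l <= 0) stop("output noise is undefined for l = 0")
  add <- sum(v_hat == 1 & v_true == 0)
  miss <- sum(v_hat == 0 & v_true == 1)
  list(eps_hat = (add + miss) / l, q01_count = add, q10_count = miss)
}

#' Expected fraction of potentiated synapses in a Willshaw network
#'
#' Closed form \eqn{p_1 = 1 - (1 - kl/(mn))^M} for i.i.d. random patterns,
#' evaluated in log space so it is accurate for very large \code{M}.
#'
#' @inheritParams generate_patterns
#' @return The expected 1-synapse fraction.
#' @export
p1_expected <- function(k, l, m, n, M) {
  if (M == 0) return(0)
  -expm1(M * log1p(-(k / m) * (l / n)))
}
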