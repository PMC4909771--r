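# Anatomical, potential, effectual and target connectivity statistics.

#' Consolidation signal of a memory set
#'
#' The ensemble of "required" synapses for stable storage of a pattern set:
#' the binary matrix of synapses that would be potentiated in a fully
#' connected Willshaw network storing the same memories,
#' \eqn{S_{ij} = H(\omega_{ij} - \theta)}. \eqn{S_{ij} = 1} marks synapse
#' \eqn{ij} as tagged for consolidation.
#'
#' @param patterns a \code{pattern_set}.
#' @param theta synaptic threshold applied to the co-activation counts
#'   (default 1, the Willshaw convention).
#' @return \code{m x n} 0/1 integer matrix.
#' @export
consolidation_signal <- function(patterns, theta = 1) {
  full <- store_willshaw(patterns)
  S <- (full$potentials >= theta) * 1L
  storage.mode(S) <- "integer"
  S
}

#' The four connectivity measures of a structurally plastic network
#'
#' Given the anatomical mask, potential mask, realized weights \code{W} and
#' consolidation signal \code{S} (all \code{m x n}, possibly real-valued),
#' computes
#' \itemize{
#'   \item \code{P}: anatomical connectivity, fraction of neuron pairs with
#'     an actual synapse;
#'   \item \code{P_pot}: potential connectivity;
#'   \item \code{P_1S}: consolidation load, fraction of pairs with
#'     \eqn{S_{ij} \ne 0};
#'   \item \code{P_eff}: effectual connectivity, the fraction of required
#'     synapses already realized with nonzero weight,
#'     \eqn{\sum H(W_{ij} S_{ij}) / \sum H(S_{ij}^2)}.
#' }
#' Nonzero tests are exact (\code{!= 0}), as the measures are defined through
#' hard indicator functions; callers holding approximate real-valued signals
#' should quantize first.
#'
#' @param actual_mask,potential_mask,W,S matrices of identical dimension.
#' @return Named list \code{P, P_pot, P_eff, P_1S}.
#' @export
measure_connectivity <- function(actual_mask, potential_mask, W, S) {
  dm <- dim(actual_mask)
  if (!all(dim(potential_mask) == dm) || !all(dim(W) == dm) ||
      !all(dim(S) == dm))
    stop("all matrices must have identical dimensions")
  mn <- prod(dm)
  n_S <- sum(S != 0)
  if (n_S == 0)
    stop("consolidation signal is all-zero: effectual connectivity ",
         "P_eff is undefined (division by zero)")
  list(P = sum(actual_mask != 0) / mn,
       P_pot = sum(potential_mask != 0) / mn,
       P_eff = sum(W != 0 & S != 0) / n_S,
       P_1S = n_S / mn)
}

#' Expected consolidation load of a random memory set
#'
#' For M i.i.d. random pattern pairs the fraction of tagged neuron pairs is
#' \eqn{P_{1S} = 1 - (1 - kl/(mn))^M}, identical to the expected fraction of
#' potentiated synapses in a fully connected Willshaw network.
#'
#' @inheritParams p1_expected
#' @export
consolidation_load_expected <- function(k, l, m, n, M) {
  p1_expected(k, l, m, n, M)
}
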