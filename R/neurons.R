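#' Membrane potential of a conductance-driven unit
#'
#' Steady-state depolarization relative to rest of a neuron whose
#' excitatory and inhibitory synaptic conductances (relative to the leak
#' conductance) are `Ge` and `Gi`:
#' `V = Ge * E / (1 + Ge + Gi)`.
#'
#' @param Ge Total excitatory conductance (>= 0). Vectorized.
#' @param Gi Total inhibitory conductance (>= 0).
#' @param E Excitatory reversal potential (default 1, dimensionless).
#' @return Depolarization in `[0, E)`.
#' @examples
#' membrane_potential(1, 0)   # 0.5
#' membrane_potential(1, 1)   # 1/3
#' @export
membrane_potential <- function(Ge, Gi = 0, E = 1) {
  if (any(Ge < 0) || any(Gi < 0)) stop("conductances must be non-negative")
  Ge * E / (1 + Ge + Gi)
}

#' Linear sigmoid activation
#'
#' Activation is 0 at or below `thrsh`, 1 at or above `mxat`, and linear
#' in between. Used both for rate-coded neurons and for the evidence
#' gates on conditionability and fear expression.
#'
#' @param v Input (depolarization, or a weight of evidence). Vectorized.
#' @param thrsh Activation threshold.
#' @param mxat Saturation level; must exceed `thrsh`.
#' @return Activation in `[0, 1]`.
#' @export
linsig <- function(v, thrsh, mxat) {
  if (any(thrsh >= mxat)) stop("linsig requires thrsh < mxat")
  pmin(1, pmax(0, (v - thrsh) / (mxat - thrsh)))
}

#' K-winners-take-all selection
#'
#' Selects the most excited cells under inhibitory competition. Silent
#' cells (excitation exactly 0) can never win.
#'
#' With `keep_ties = FALSE`, independent uniform noise on
#' `(0, noise_eps)` is added to every nonzero excitation, after which the
#' `K` most excited cells with strictly positive excitation win (fewer if
#' fewer are positive) -- "at most, exactly K". The noise is drawn from
#' the current RNG state, so results are reproducible under `set.seed()`.
#'
#' With `keep_ties = TRUE` no noise is added; the K-th highest positive
#' excitation defines a cutoff and every cell at or above it wins, so
#' more than `K` cells may fire. This is the regime of the recurrent
#' iterations, where an exact evidence tie must propagate rather than be
#' broken arbitrarily.
#'
#' @param excitation Numeric vector of per-cell excitation, indexed by
#'   cell; names are ignored, winners are indices into this vector.
#' @param K Winner count (>= 1).
#' @param keep_ties Tie semantics, see above.
#' @param noise_eps Tie-breaking noise half-width; should be far below
#'   the smallest meaningful excitation difference.
#' @return Integer vector of winning cell indices (unordered).
#' @export
kwta <- function(excitation, K, keep_ties = FALSE, noise_eps = 1e-6) {
  if (K < 1) stop("K must be >= 1")
  pos <- which(excitation > 0)
  if (length(pos) == 0L) return(integer(0))
  exc <- excitation[pos]
  if (!keep_ties) {
    exc <- exc + stats::runif(length(exc), 0, noise_eps)
    if (length(pos) <= K) return(pos)
    ord <- order(exc, decreasing = TRUE)
    return(pos[ord[seq_len(K)]])
  }
  if (length(pos) <= K) return(pos)
  cutoff <- sort(exc, decreasing = TRUE)[K]
  pos[exc >= cutoff]
}
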