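#' Model parameters
#'
#' Builds the full parameter set of the automaton. Defaults are the
#' standard operating point used throughout the package: a universe of
#' `N_ctx` possible attributes of which each context expresses `N_A`,
#' `N_gen` of them common to every context; a hippocampal layer of
#' `N_hipp` dentate/CA3 dyads with `F` entorhinal afferents per cell and
#' `K`-winners-take-all firing; and the log10 evidence thresholds that
#' gate representation creation (`B_new`), creation-suppression (`B_pv`),
#' updating (`B_add`), and conditioning (`B_old`).
#'
#' @param N_ctx Number of possible attributes (entorhinal input/output cells).
#' @param N_hipp Number of dentate (and CA3) cells.
#' @param N_A Attributes per context.
#' @param N_gen Attributes common to all contexts.
#' @param F_aff Entorhinal afferents per dentate and per CA3 cell.
#' @param K Winner count of the hippocampal KWTA competitions.
#' @param K0 Minimum size of the pre-recurrent CA3 pattern for the
#'   recurrent collaterals to engage.
#' @param Z0 Minimum number of sampled attributes before a representation
#'   may be created.
#' @param thrsh_ctx Number of potentiated active CA3 inputs an entorhinal
#'   output cell needs in order to fire.
#' @param B_old,B_new,B_add,B_pv Evidence thresholds, log10 units.
#' @param alpha Amygdala learning rate.
#' @param dpf Direct-path factor: recall-mode strength of the direct
#'   entorhinal-to-CA3 route relative to the dentate route.
#' @param E_rev Excitatory reversal potential (dimensionless).
#' @param noise_eps Half-width of the uniform tie-breaking noise added to
#'   nonzero excitations in strict KWTA selection (excitation units).
#' @param n_recurrent_iters Recurrent cycles run to reach the final CA3
#'   pattern.
#' @param b_floor Finite stand-in for an infinitely negative weight of
#'   evidence; positive infinities clamp at `-b_floor`.
#' @param diff_model Observation model for the "different context"
#'   hypothesis of the weight of evidence: `"chance"` (different contexts
#'   share the `N_gen` general attributes plus whatever unique attributes
#'   collide by chance, exactly as the context generator draws them) or
#'   `"general"` (different contexts share exactly the general core).
#'   See the methods vignette for why `"chance"` is the default.
#'
#' @return An object of class `fear_params` (a validated named list).
#' @seealso [validate_params()]
#' @examples
#' p <- fear_params()
#' p$K
#' fear_params(dpf = 0.15)$dpf
#' @export
fear_params <- function(N_ctx = 1000L, N_hipp = 10000L, N_A = 100L,
                        N_gen = 50L, F_aff = 60L, K = 60L, K0 = 15L,
                        Z0 = 45L, thrsh_ctx = 42L,
                        B_old = 3, B_new = -3, B_add = 15, B_pv = 3,
                        alpha = 0.025, dpf = 0,
                        E_rev = 1, noise_eps = 1e-6,
                        n_recurrent_iters = 2L, b_floor = -50,
                        diff_model = c("chance", "general")) {
  p <- list(
    N_ctx = as.integer(N_ctx), N_hipp = as.integer(N_hipp),
    N_A = as.integer(N_A), N_gen = as.integer(N_gen),
    F_aff = as.integer(F_aff), K = as.integer(K), K0 = as.integer(K0),
    Z0 = as.integer(Z0), thrsh_ctx = as.integer(thrsh_ctx),
    B_old = B_old, B_new = B_new, B_add = B_add, B_pv = B_pv,
    alpha = alpha, dpf = dpf, E_rev = E_rev, noise_eps = noise_eps,
    n_recurrent_iters = as.integer(n_recurrent_iters), b_floor = b_floor,
    diff_model = match.arg(diff_model)
  )
  class(p) <- "fear_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set and returns it
#' unchanged, or stops with a message naming the violated relation.
#'
#' @param p A `fear_params` object (or a plain named list with the same
#'   fields).
#' @return `p`, invisibly unchanged, with class `fear_params`.
#' @export
validate_params <- function(p) {
  chk <- function(ok, what) if (!ok) stop("invalid parameters: ", what, call. = FALSE)
  chk(p$N_gen <= p$N_A, "N_gen <= N_A")
  chk(p$N_A <= p$N_ctx, "N_A <= N_ctx")
  chk(p$K0 <= p$K, "K0 <= K")
  chk(p$K <= p$N_hipp, "K <= N_hipp")
  chk(p$thrsh_ctx <= p$K, "thrsh_ctx <= K")
  chk(p$B_new < 0, "B_new < 0")
  chk(0 < p$B_old, "0 < B_old")
  chk(p$B_old <= p$B_pv, "B_old <= B_pv")
  chk(p$B_pv < p$B_add, "B_pv < B_add")
  chk(p$Z0 <= p$N_A, "Z0 <= N_A")
  chk(p$alpha > 0, "alpha > 0")
  chk(p$dpf >= 0, "dpf >= 0")
  chk(p$noise_eps > 0, "noise_eps > 0")
  chk(p$F_aff <= p$N_ctx, "F_aff <= N_ctx")
  chk(p$n_recurrent_iters >= 1, "n_recurrent_iters >= 1")
  class(p) <- "fear_params"
  p
}

#' @export
print.fear_params <- function(x, ...) {
  cat("<fear_params>\n")
  cat(sprintf("  world: N_ctx=%d N_A=%d N_gen=%d\n", x$N_ctx, x$N_A, x$N_gen))
  cat(sprintf("  hippocampus: N_hipp=%d F=%d K=%d K0=%d Z0=%d thrsh_ctx=%d dpf=%g\n",
              x$N_hipp, x$F_aff, x$K, x$K0, x$Z0, x$thrsh_ctx, x$dpf))
  cat(sprintf("  evidence (log10): B_new=%g B_old=%g B_pv=%g B_add=%g [%s diff model]\n",
              x$B_new, x$B_old, x$B_pv, x$B_add, x$diff_model))
  cat(sprintf("  amygdala: alpha=%g\n", x$alpha))
  invisible(x)
}
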