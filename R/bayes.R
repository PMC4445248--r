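#' Overlap probability under the matching-context hypothesis
#'
#' If the active representation really is that of the current context,
#' the `Z_cur` sampled attributes are a uniform subset of the context's
#' `N_A` attributes, of which `Z_rec` are recalled. The overlap `Z_com`
#' is then hypergeometric:
#' `P = C(Z_rec, Z_com) C(N_A - Z_rec, Z_cur - Z_com) / C(N_A, Z_cur)`.
#'
#' @param z_com Overlap count (vectorized).
#' @param z_cur Number of sampled attributes.
#' @param z_rec Number of recalled attributes.
#' @param N_A Attributes per context.
#' @return Probability (0 outside the support).
#' @export
p_same <- function(z_com, z_cur, z_rec, N_A) {
  stats::dhyper(z_com, z_rec, N_A - z_rec, z_cur)
}

#' Overlap probability under the different-context hypothesis
#'
#' If the active representation belongs to a *different* context, the
#' recalled attributes are a uniform `Z_rec`-subset of that context's
#' attributes, of which only `m` lie in the current context; the overlap
#' with the current sample is then hypergeometric given `m`, and `m` is
#' integrated out.
#'
#' Two observation models for `m` are provided (see the methods
#' vignette):
#' * `"chance"` (default): matches the context generator exactly --
#'   different contexts share the general core plus a chance number `u`
#'   of unique attributes, with
#'   `u ~ Hyp(N_A - N_gen, N_ctx - N_A, N_A - N_gen)` and
#'   `m ~ Hyp(N_gen + u, N_A - N_gen - u, Z_rec)` given `u`.
#' * `"general"`: different contexts share exactly the `N_gen` general
#'   attributes, so `m ~ Hyp(N_gen, N_A - N_gen, Z_rec)`; a simpler
#'   model under which any overlap beyond the general core is
#'   impossible.
#'
#' @inheritParams p_same
#' @param N_gen Number of general attributes.
#' @param N_ctx Number of possible attributes (used by `"chance"` only).
#' @param model `"general"` or `"chance"`.
#' @return Probability; sums to 1 over `z_com = 0..min(z_cur, z_rec)`.
#' @export
p_diff <- function(z_com, z_cur, z_rec, N_A, N_gen, N_ctx = NULL,
                   model = c("chance", "general")) {
  model <- match.arg(model)
  pm <- diff_m_pmf(z_rec, N_A, N_gen, N_ctx, model)   # P[m], m = 0..N_A
  m <- seq_along(pm) - 1L
  vapply(z_com, function(z)
    sum(pm * stats::dhyper(z, m, N_A - m, z_cur)), numeric(1))
}

# PMF of m = |recalled set ∩ current context| under the Diff hypothesis.
# Memoized on the full parameter tuple.
diff_m_pmf <- local({
  cache <- new.env(parent = emptyenv())
  function(z_rec, N_A, N_gen, N_ctx, model) {
    key <- paste(z_rec, N_A, N_gen, N_ctx %||% -1L, model, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- 0:N_A
    if (model == "general") {
      pm <- stats::dhyper(m, N_gen, N_A - N_gen, z_rec)
    } else {
      if (is.null(N_ctx)) stop("N_ctx is required for the 'chance' diff model")
      n_u <- N_A - N_gen
      pm <- numeric(N_A + 1L)
      for (u in 0:n_u) {
        pu <- stats::dhyper(u, n_u, N_ctx - N_A, n_u)
        if (pu < 1e-18) next
        pm <- pm + pu * stats::dhyper(m, N_gen + u, N_A - N_gen - u, z_rec)
      }
    }
    cache[[key]] <- pm
    pm
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian weight of evidence for the active representation
#'
#' The log10 odds that the active representation matches the current
#' context, given the observed counts:
#' `B = log10( P[Z_com | Same] / P[Z_com | Diff] )`.
#'
#' If the entorhinal output layer is silent (`ecout_silent = TRUE`,
#' which covers a pre-recurrent pattern below `K0` and suppression of a
#' tied final pattern), there is no active representation to evaluate
#' and the evidence is exactly 0. A zero matching-hypothesis probability
#' (e.g. when `Z_cur - Z_com + Z_rec > N_A`, which is impossible under a
#' valid representation) returns the finite floor `b_floor`; a zero
#' different-hypothesis probability with positive matching probability
#' clamps at `-b_floor`.
#'
#' @param z_cur,z_rec,z_com Observed counts; must satisfy
#'   `0 <= z_com <= min(z_cur, z_rec)` and `z_cur, z_rec <= N_A`.
#' @param p A [fear_params()] object.
#' @param ecout_silent If `TRUE` the evidence is 0 by definition.
#' @return Weight of evidence in log10 units.
#' @export
b_rep <- function(z_cur, z_rec, z_com, p, ecout_silent = FALSE) {
  if (ecout_silent) return(0)
  if (z_com < 0 || z_com > min(z_cur, z_rec) || z_cur > p$N_A)
    stop("invalid evidence query: need 0 <= z_com <= min(z_cur, z_rec), z_cur <= N_A")
  # a representation recalling more than N_A attributes cannot be the
  # representation of any single context
  if (z_rec > p$N_A) return(p$b_floor)
  ps <- p_same(z_com, z_cur, z_rec, p$N_A)
  pd <- p_diff(z_com, z_cur, z_rec, p$N_A, p$N_gen, p$N_ctx, p$diff_model)
  if (ps == 0) return(p$b_floor)
  if (pd == 0) return(-p$b_floor)
  b <- log10(ps / pd)
  min(max(b, p$b_floor), -p$b_floor)
}

#' Expected overlap count
#'
#' Mean of the hypergeometric overlap between a uniform `z_cur`-sample
#' and a fixed `z_rec`-subset of `N_A` attributes.
#'
#' @inheritParams p_same
#' @return `z_cur * z_rec / N_A` (real-valued).
#' @export
expected_z_com <- function(z_cur, z_rec, N_A) z_cur * z_rec / N_A

#' Expected weight of evidence
#'
#' The weight of evidence evaluated at the theoretically expected
#' overlap `Z_com = Z_cur * Z_rec / N_A`, by linear interpolation of
#' [b_rep()] between the two adjacent integer overlap counts. Used on
#' sessions where a representation has just been created (then with
#' `z_rec = z_cur`), and to draw the familiarization curves.
#'
#' @inheritParams b_rep
#' @return Weight of evidence in log10 units.
#' @export
expected_b_rep <- function(z_cur, z_rec, p) {
  zs <- expected_z_com(z_cur, z_rec, p$N_A)
  lo <- floor(zs)
  hi <- ceiling(zs)
  b_lo <- b_rep(z_cur, z_rec, lo, p)
  if (hi == lo) return(b_lo)
  b_hi <- b_rep(z_cur, z_rec, hi, p)
  b_lo + (zs - lo) * (b_hi - b_lo)
}

#' Tabulate the weight of evidence
#'
#' Convenience grid evaluation for plotting the evidence curve families.
#'
#' @param z_cur,z_rec Integer vectors.
#' @param p A [fear_params()] object.
#' @return A data frame with columns `z_cur`, `z_rec`, `z_com`, `b_rep`.
#' @export
b_rep_table <- function(z_cur, z_rec, p) {
  rows <- list()
  for (zc in z_cur) for (zr in z_rec) {
    z <- 0:min(zc, zr)
    rows[[length(rows) + 1L]] <- data.frame(
      z_cur = zc, z_rec = zr, z_com = z,
      b_rep = vapply(z, function(zz) b_rep(zc, zr, zz, p), numeric(1))
    )
  }
  do.call(rbind, rows)
}
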