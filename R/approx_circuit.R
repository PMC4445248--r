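#' Calibrate the rate-coded evidence-approximation circuit
#'
#' A small circuit of rate-coded neurons can approximate the exact
#' weight-of-evidence computation. Because the evidence is symmetric in
#' the sampled and recalled counts, the circuit works on
#' `Z_lo = min(Z_cur, Z_rec)` and `Z_hi = max(Z_cur, Z_rec)`. Its output
#' neuron receives:
#' * excitation proportional to a power function of the overlap,
#'   `Ge = c * Z_com^a`, tuned so that on the envelope
#'   (`Z_com = Z_lo = Z_hi`) the output follows the upper envelope of
#'   the exact evidence curves;
#' * divisive inhibition proportional to a power function of
#'   `Z_hi * (Z_lo - Z_com)`, which pulls the output down as the overlap
#'   falls short of `Z_lo`, the more steeply the larger `Z_hi`;
#' * a tonic bias conductance that elevates the baseline firing rate so
#'   the rate can move below baseline to signal an invalid
#'   representation;
#' * an impossibility gate that clamps the output at the evidence floor
#'   whenever `Z_lo + Z_hi - Z_com > N_A` (the observation is impossible
#'   under a valid representation).
#'
#' The output neuron's depolarization follows the membrane equation
#' `V = (Ge + Gb) E / (1 + Ge + Gb + Gi)` and the decoded evidence is
#' `scale * (V - V_baseline)`.
#'
#' Calibration first fits the envelope gain and exponent against the
#' exact envelope values, then fits the inhibition gain and exponent by
#' least squares against the exact evidence on the grid
#' `Z_lo, Z_hi in seq(30, 100, by = 10)`, `Z_com in 0..Z_lo`,
#' excluding the impossibility region. The achieved RMSE is recorded in
#' the returned object as the calibration's own reference residual.
#'
#' @param p A [fear_params()] object.
#' @param grid Values of `Z_lo`/`Z_hi` used for the fit.
#' @param zcom_step Stride through the overlap values of the fitting grid.
#' @return An object of class `approx_circuit` with the fitted
#'   parameters (`a`, `c`, `b`, `g`, `Gb`, `scale`), the fit `rmse`, and
#'   the parameter set.
#' @export
calibrate_approx_circuit <- function(p, grid = seq(30, 100, by = 10),
                                     zcom_step = 4L) {
  # envelope: exact evidence at Z_com = Z_lo = Z_hi. Beyond N_gen the
  # different-context hypothesis cannot produce the overlap at all and the
  # exact value sits at the clamp, so the power law is fitted below it.
  env_z <- seq(5L, min(max(grid), p$N_gen), by = 5L)
  env_b <- vapply(env_z, function(z) b_rep(z, z, z, p), numeric(1))
  env_fit <- stats::lm(log(env_b) ~ log(env_z))
  a <- unname(stats::coef(env_fit)[2])
  c_gain <- exp(unname(stats::coef(env_fit)[1]))

  # fitting grid for the inhibition branch
  pts <- list()
  for (zhi in grid) for (zlo in grid[grid <= zhi]) {
    zc <- unique(c(seq(0L, zlo, by = zcom_step), zlo))
    for (z in zc) {
      if (zlo + zhi - z > p$N_A) next   # neuron-I region, handled by the gate
      pts[[length(pts) + 1L]] <- c(zlo, zhi, z,
                                   b_rep(zhi, zlo, z, p))
    }
  }
  pts <- do.call(rbind, pts)
  colnames(pts) <- c("zlo", "zhi", "zcom", "b_exact")
  floor_ <- p$b_floor
  bex <- pmin(pmax(pts[, "b_exact"], floor_), -floor_)
  # points pinned at the positive clamp (overlap impossible under the
  # different-context hypothesis) would dominate the least squares; the
  # circuit saturates there and they are left out of the fit
  keep <- bex < -floor_ - 1e-9
  pts <- pts[keep, , drop = FALSE]
  bex <- bex[keep]

  predict_raw <- function(theta, zlo, zhi, zcom) {
    g <- exp(theta[1]); b <- exp(theta[2]); Gb <- exp(theta[3]); sc <- exp(theta[4])
    Ge <- c_gain * zcom^a
    Gi <- g * (zhi * pmax(zlo - zcom, 0) / p$N_A^2)^b
    V <- (Ge + Gb) * p$E_rev / (1 + Ge + Gb + Gi)
    Vb <- Gb * p$E_rev / (1 + Gb)
    sc * (V - Vb)
  }
  obj <- function(theta) {
    pr <- predict_raw(theta, pts[, "zlo"], pts[, "zhi"], pts[, "zcom"])
    sqrt(mean((pr - bex)^2))
  }
  fit <- stats::optim(c(log(5), log(1), log(0.5), log(30)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    warning("approximation-circuit fit did not converge; residual RMSE = ",
            signif(fit$value, 4))
  out <- list(
    a = a, c = c_gain,
    g = exp(fit$par[1]), b = exp(fit$par[2]),
    Gb = exp(fit$par[3]), scale = exp(fit$par[4]),
    rmse = fit$value, params = p
  )
  class(out) <- "approx_circuit"
  out
}

#' Evaluate the calibrated approximation circuit
#'
#' @param z_cur,z_rec,z_com Observed counts (order of `z_cur`/`z_rec`
#'   does not matter; the circuit sorts them into `Z_lo`/`Z_hi`).
#' @param circuit An `approx_circuit` from [calibrate_approx_circuit()].
#' @return The decoded evidence (log10 units); the floor value when the
#'   impossibility gate fires.
#' @export
b_rep_approx <- function(z_cur, z_rec, z_com, circuit) {
  p <- circuit$params
  zlo <- min(z_cur, z_rec)
  zhi <- max(z_cur, z_rec)
  if (zlo + zhi - z_com > p$N_A) return(p$b_floor)
  Ge <- circuit$c * z_com^circuit$a
  Gi <- circuit$g * (zhi * max(zlo - z_com, 0) / p$N_A^2)^circuit$b
  V <- (Ge + circuit$Gb) * p$E_rev / (1 + Ge + circuit$Gb + Gi)
  Vb <- circuit$Gb * p$E_rev / (1 + circuit$Gb)
  circuit$scale * (V - Vb)
}

#' @export
print.approx_circuit <- function(x, ...) {
  cat("<approx_circuit>\n")
  cat(sprintf("  envelope: %.3g * Z_com^%.3g\n", x$c, x$a))
  cat(sprintf("  inhibition: %.3g * [Z_hi (Z_lo - Z_com) / N_A^2]^%.3g\n", x$g, x$b))
  cat(sprintf("  bias Gb=%.3g  decode scale=%.3g  fit RMSE=%.3g\n",
              x$Gb, x$scale, x$rmse))
  invisible(x)
}
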