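# Independent numerical oracles used to cross-check closed-form solutions.

# Explicit finite-difference solution of the 1-D diffusion equation on a
# slab of unit thickness (x in [0, 1], Fourier time tau = D t / L^2) with
# both faces held at the equilibrium moisture: theta = 1 in the interior
# initially, theta = 0 on both boundaries. Returns the mean residual
# moisture (trapezoidal integral of theta) at the requested Fourier
# numbers. Entirely independent of the series solution.
fd_slab_mr <- function(fourier, nx = 201L, safety = 0.4) {
  dx <- 1 / (nx - 1L)
  dtau <- safety * dx^2
  theta <- rep(1, nx)
  theta[c(1L, nx)] <- 0
  step <- function(th, dt) {
    th[2:(nx - 1L)] <- th[2:(nx - 1L)] +
      dt / dx^2 * diff(th, differences = 2L)
    th[c(1L, nx)] <- 0
    th
  }
  trap <- function(v) (sum(v) - (v[1L] + v[length(v)]) / 2) * dx
  out <- numeric(length(fourier))
  ord <- order(fourier)
  targets <- fourier[ord]
  tau <- 0
  for (k in seq_along(targets)) {
    while (tau + dtau <= targets[k] + 1e-15) {
      theta <- step(theta, dtau)
      tau <- tau + dtau
    }
    th <- theta
    rem <- targets[k] - tau          # fractional step onto the target time
    if (rem > 1e-15) th <- step(th, rem)
    out[ord[k]] <- trap(th)
  }
  out
}
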