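# shared fixtures, built in code

paper_foil <- function() {
  foil_params(a_sway = 0.01, a_yaw = 20 * pi / 180, f = 2, U = 0.3)
}

# a small grid spec for pressure tests
unit_grid <- function(h = 0.02) list(x = c(-1, 1), y = c(-1, 1), h = h)

# closed-form pressure of steady solid-body rotation about the origin
p_solid_rotation <- function(x, y, Omega, rho) {
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  0.5 * rho * Omega^2 * (X^2 + Y^2)
}

# pressure of a steady Lamb-Oseen vortex by integrating the radial momentum
# ODE dp/dr = rho v_theta(r)^2 / r inward from a far-field zero
p_lamb_oseen <- function(x, y, gamma, r_c, rho) {
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  R[R < 1e-12] <- 1e-12
  vth2_over_r <- function(s) rho * (gamma / (2 * pi * s) *
                                      (1 - exp(-s^2 / r_c^2)))^2 / s
  pr <- vapply(as.vector(R), function(ri) {
    -stats::integrate(vth2_over_r, ri, 50, rel.tol = 1e-10)$value
  }, numeric(1))
  matrix(pr, length(x), length(y))
}

# gauge-free RMS mismatch of two fields relative to the truth's range
rms_of_range <- function(p_hat, p_true) {
  e <- p_hat - p_true
  e <- e - mean(e)
  sqrt(mean(e^2)) / diff(range(p_true))
}

# recovery-sweep swimmer: uniform amplitude envelope (so the true overall
# phase lag is exactly 2*pi/lam) sampled densely enough for the spline
sweep_swimmer <- function(f, lam, noise_sd = 0, seed = NULL,
                          duration = 5 / f) {
  a <- if (lam < 0.8) 0.0095 else 0.019
  swimmer_spec(f = f, lam = lam, a_head = a, a_tail = a, n_markers = 33,
               duration = duration, noise_sd = noise_sd, seed = seed)
}
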