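# Shared oracles and fixtures, all built in code.

# 4th-order central finite differences: an oracle for derivatives that is
# independent of the package's polynomial calculus.
fd_d1 <- function(f, x, h = 1e-3) {
  (f(x - 2 * h) - 8 * f(x - h) + 8 * f(x + h) - f(x + 2 * h)) / (12 * h)
}
fd_d2 <- function(f, x, h = 1e-3) {
  (-f(x - 2 * h) + 16 * f(x - h) - 30 * f(x) + 16 * f(x + h) - f(x + 2 * h)) /
    (12 * h^2)
}

# brute-force wave-ODE residual of a front profile via finite differences
fd_wave_residual <- function(front, omega) {
  p <- front$params
  prof <- function(nm) function(om) evaluate_front(front, 0, om)[[nm]]
  ode <- reduce_to_wave_ode(p, wave_frame(front$mu))
  u <- prof("u"); v <- prof("v"); w <- prof("w")
  r <- ode(u(omega), fd_d1(u, omega), fd_d2(u, omega),
           v(omega), fd_d1(v, omega), fd_d2(v, omega),
           w(omega), fd_d1(w, omega), fd_d2(w, omega))
  max(abs(unlist(r)))
}

# fixed known-admissible free parameters per family (used where a test
# needs one concrete valid front rather than random draws)
known_front_params <- list(
  "1-general" = list(mu = 3/2, d1 = 2, d3 = 2, alpha2 = 5, alpha4 = 5),
  "1-fixed"   = list(beta1 = 30, alpha2 = 2, alpha3 = 40, alpha4 = 1, kappa2 = 0.2),
  "2"         = list(d1 = 0.25, alpha1 = 7, alpha2 = 1, alpha3 = 20, kappa2 = 0.5),
  "3"         = list(d1 = 0.25, alpha1 = 1.5, alpha3 = 28, alpha4 = 11.5))

build_known_front <- function(case) {
  do.call(build_front, c(list(case = case), known_front_params[[case]]))
}

# a generic valid dimensionless parameter set (no front attached)
generic_params <- function() {
  dimensionless_params(d1 = 2, d3 = 1.5, beta1 = 0.8, beta3 = 1.2,
                       alpha1 = 0.5, alpha2 = 0.3, alpha3 = 0.7, alpha4 = 0.2,
                       kappa1 = 1.1, kappa2 = 0.9)
}
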