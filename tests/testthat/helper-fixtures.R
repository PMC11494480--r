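# Shared fixtures: all synthetic, built in code.

table1 <- function(...) hopf_params(...)

# pure-tone complex trace z(t) = A * exp(i * (w * t + phase))
tone_trace <- function(A = 1, w = 2 * pi, t_end = 20, dt = 0.01, phase = 0) {
  t <- seq(0, t_end, by = dt)
  data.frame(t = t, x = A * cos(w * t + phase), y = A * sin(w * t + phase))
}

# Independent oracle for the steady entrained amplitude of the forced bundle
# equation pinned at the bifurcation (mu_c + mu = 0): the rotating-frame
# balance  A * sqrt((delta - b2*A^2)^2 + (b1*A^2)^2) = F,  delta = wp - w,
# solved by bisection.  Used to cross-check simulation + spectral estimates.
forced_amp_oracle <- function(F, delta = 0, b1 = -1, b2 = 0) {
  g <- function(A) A * sqrt((delta - b2 * A^2)^2 + (b1 * A^2)^2) - F
  stats::uniroot(g, c(1e-12, 10 + 10 * F^(1 / 3)), tol = 1e-12)$root
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
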