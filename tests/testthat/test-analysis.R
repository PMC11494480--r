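test_that("amplitude and phase extraction recovers analytic signals", {
  tt <- tone_trace(A = 1, w = 2 * pi)
  ap <- amplitude_phase(tt)
  expect_equal(ap$A, rep(1, nrow(tt)))
  expect_equal(mean(ap$phi_dot), 2 * pi, tolerance = 1e-6)
  # constant real signal: amplitude 2, zero frequency
  cst <- data.frame(t = 0:50, x = 2, y = 0)
  ap2 <- amplitude_phase(cst)
  expect_equal(ap2$A, rep(2, 51))
  expect_equal(ap2$phi_dot[2:50], rep(0, 49))
  # zero samples get flagged NA phase
  z0 <- data.frame(t = 0:2, x = c(1, 0, 1), y = 0)
  expect_true(is.na(amplitude_phase(z0)$phi[2]))
})

test_that("steady cycle statistics average the trailing n cycles exactly", {
  tt <- tone_trace(A = 3, w = 2 * pi, t_end = 80)
  st <- steady_cycle_stats(tt, 50)
  expect_equal(st$amplitude, 3, tolerance = 1e-9)
  expect_equal(st$frequency, 2 * pi, tolerance = 1e-9)
  expect_error(steady_cycle_stats(tone_trace(t_end = 10), 50), "fewer than")
})

test_that("cycle statistics on a fixed-mu simulation recover the closed forms", {
  p <- table1()
  cfg <- integration_config(mu0 = -15, hold_mu = TRUE)
  tr <- hopf_simulate(p, t_span = c(0, 100), config = cfg)
  st <- steady_cycle_stats(tr, 50)
  expect_rel(st$amplitude, sqrt(5), 0.005)
  expect_rel(st$frequency, 2 * pi - 2.5, 0.005)
})

test_that("vector strength separates locking from drift", {
  tt <- tone_trace(A = 2, w = 3, t_end = 40, phase = 0.7)
  expect_equal(vector_strength(tt, 3), 1, tolerance = 1e-9)
  # detuned reference: phase difference sweeps many circles, V collapses
  expect_lt(vector_strength(tt, 3.5), 0.2)
  expect_error(vector_strength(tone_trace(t_end = 1), 0.5), "forcing period")
})

test_that("vector strength and locked amplitude are phase-shift invariant", {
  for (ph in c(0, 1.1, 4)) {
    tt <- tone_trace(A = 1.5, w = 4, t_end = 30, phase = ph)
    expect_equal(vector_strength(tt, 4), 1, tolerance = 1e-9)
    expect_equal(phase_locked_amplitude(tt, 4), 1.5, tolerance = 1e-9)
  }
})

test_that("phase-locked amplitude is a normalised Fourier coefficient", {
  tt <- tone_trace(A = 3, w = 5, t_end = 60)
  expect_equal(phase_locked_amplitude(tt, 5), 3, tolerance = 1e-9)
  # orthogonality: far-off frequency contributes ~0
  expect_lt(phase_locked_amplitude(tt, 9.3), 0.05)
})

test_that("forced simulation at the bifurcation matches the balance oracle", {
  iso <- hopf_params(b_imag = 0)
  cfg <- integration_config(mu0 = -iso$mu_c, hold_mu = TRUE)
  sn <- additive_forcing("sinusoid", F = 1, omega_prime = iso$omega)
  tr <- hopf_simulate(iso, sn, t_span = c(0, 150), config = cfg)
  expect_rel(phase_locked_amplitude(tr, iso$omega),
             forced_amp_oracle(1), 0.005)         # = 1: one-third law at F=1
  # off-resonance, nonisochronous: same oracle with detuning and shear
  p <- table1()
  cfgp <- integration_config(mu0 = -p$mu_c, hold_mu = TRUE)
  sn2 <- additive_forcing("sinusoid", F = 0.5, omega_prime = p$omega + 1)
  tr2 <- hopf_simulate(p, sn2, t_span = c(0, 200), config = cfgp)
  expect_rel(phase_locked_amplitude(tr2, p$omega + 1),
             forced_amp_oracle(0.5, delta = 1, b1 = -1, b2 = -0.5), 0.01)
})

test_that("Bartlett PSD satisfies Parseval and localises tones", {
  dt <- 0.01
  x <- rep(2, 4096)
  ps <- bartlett_psd(x, dt, 1)
  expect_equal(ps$power[1] * ps$d_omega, 4, tolerance = 1e-9)
  expect_true(all(abs(ps$power[-1]) < 1e-12))
  # unit sinusoid at an exact bin: total power 1/2, single dominant bin pair
  L <- 4000
  t <- (0:(L - 1)) * dt
  f0 <- 10 / (L * dt)                       # exact bin frequency
  xs <- sin(2 * pi * f0 * t)
  ps1 <- bartlett_psd(xs, dt, 1)
  expect_equal(sum(ps1$power) * ps1$d_omega, mean(xs^2), tolerance = 1e-9)
  expect_equal(sum(ps1$power) * ps1$d_omega, 1 / 2, tolerance = 1e-9)
  peak <- ps1$omega[which.max(ps1$power)]
  expect_equal(peak, 2 * pi * f0, tolerance = 1e-9)
  # Bartlett averaging (8 segments) preserves the peak location
  xs8 <- sin(2 * pi * (80 / (L * dt)) * (0:(8 * L - 1)) * dt)
  ps8 <- bartlett_psd(xs8, dt, 8)
  expect_equal(ps8$omega[which.max(ps8$power)], 2 * pi * 80 / (L * dt),
               tolerance = 1e-9)
  expect_equal(sum(ps8$power) * ps8$d_omega, mean(xs8^2), tolerance = 1e-9)
  expect_error(bartlett_psd(1:10, 0.1, 20), "segments")
})

test_that("power ratio is the ratio of logarithms", {
  mk <- function(total) {
    # flat spectrum with the requested sum of density values
    structure(list(omega = 0:9, power = rep(total / 10, 10), d_omega = 1,
                   n_segments = 1, segment_length = 10),
              class = "hopf_psd")
  }
  expect_equal(power_ratio(mk(100), mk(100)), 1)
  expect_equal(power_ratio(mk(100), mk(10)), 2)
  expect_equal(power_ratio(mk(10), mk(100)), 0.5)
  expect_error(power_ratio(mk(10), mk(1)), "log is zero")
  bad <- mk(10); bad$omega <- bad$omega + 0.5
  expect_error(power_ratio(mk(10), bad), "grids")
})

test_that("half-width interpolates crossings and scales correctly", {
  # symmetric triangle, peak 1, slopes +-1: width 1
  om <- seq(-2, 2, by = 0.05)
  tri <- pmax(0, 1 - abs(om))
  expect_equal(half_width(om, tri), 1, tolerance = 1e-9)
  # Lorentzian 1/(1 + (om/w)^2): width 2w
  w <- 0.7
  lor <- 1 / (1 + (om / w)^2)
  expect_equal(half_width(om, lor), 2 * w, tolerance = 1e-3)
  # invariant under vertical scaling
  expect_equal(half_width(om, 37.5 * lor), half_width(om, lor))
  expect_error(half_width(om, om + 3), "boundary|half maximum")
})

test_that("recovery time finds the post-dip upward crossing", {
  # constructed amplitude profile: forced high, dip, recovery at t = 62.5
  t <- seq(0, 100, by = 0.1)
  A <- ifelse(t < 50, 5, ifelse(t < 62.5, 0.01, 2))
  tr <- data.frame(t = t, x = A, y = 0)
  tR <- recovery_time(tr, 50, reference_amplitude = 2)
  expect_equal(as.numeric(tR), 12.5, tolerance = 0.2)
  expect_true(attr(tR, "recovered"))
  # never quiescent: tR = 0
  busy <- data.frame(t = t, x = 5, y = 0)
  expect_equal(as.numeric(recovery_time(busy, 50, reference_amplitude = 2)), 0)
  # never recovered: NA with flag
  dead <- data.frame(t = t, x = ifelse(t < 50, 5, 1e-6), y = 0)
  tRd <- recovery_time(dead, 50, reference_amplitude = 2)
  expect_true(is.na(tRd))
  expect_false(attr(tRd, "recovered"))
  # monotone non-increasing in the threshold for a growing amplitude
  grow <- data.frame(t = t, x = ifelse(t < 50, 5, pmin(2, (t[t >= 50] - 50) * 0.05)),
                     y = 0)
  tRs <- sapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    as.numeric(recovery_time(grow, 50, th, reference_amplitude = 2)))
  expect_true(all(diff(tRs) >= 0))
})

test_that("fit_relation recovers generating coefficients exactly", {
  x <- 10^seq(0, 1, length.out = 12)
  f1 <- fit_relation(x, x^(1 / 3), "power_law")
  expect_equal(unname(coef(f1)["b"]), 1 / 3, tolerance = 1e-9)
  expect_equal(unname(coef(f1)["c"]), 1, tolerance = 1e-9)
  f2 <- fit_relation(x, -0.095 + x^(-0.54), "offset_power")
  expect_equal(unname(coef(f2)["c"]), -0.095, tolerance = 1e-6)
  expect_equal(unname(coef(f2)["d"]), -0.54, tolerance = 1e-6)
  f3 <- fit_relation(x, 1 - 0.019 * log10(x), "log10_linear")
  expect_equal(unname(coef(f3)["a"]), 1, tolerance = 1e-9)
  expect_equal(unname(coef(f3)["b"]), -0.019, tolerance = 1e-9)
  expect_error(fit_relation(c(-1, 1, 2), c(1, 2, 3), "power_law"),
               "non-positive")
})
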