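test_that("parameter validation enforces the supercritical regime", {
  p <- table1()
  expect_equal(p$mu_c, 20)
  expect_equal(p$omega, 2 * pi)
  expect_equal(p$b_real, -1)
  expect_equal(p$b_imag, -1 / 2)
  expect_equal(p$tau, 10)
  expect_equal(p$gamma, 10)
  expect_equal(p$alpha, 3)
  expect_error(hopf_params(b_real = 0.5), "b_real")
  expect_error(hopf_params(mu_c = -1), "mu_c")
  expect_error(hopf_params(tau = 0), "tau")
})

test_that("additive forcing is piecewise-exact with half-open windows", {
  bx <- additive_forcing("boxcar", F = 1000, t_start = 10, t_stop = 50)
  expect_equal(eval_additive_forcing(bx, 30), 1000 + 0i)
  expect_equal(eval_additive_forcing(bx, 60), 0 + 0i)
  expect_equal(eval_additive_forcing(bx, 10), 1000 + 0i)  # on at t_start
  expect_equal(eval_additive_forcing(bx, 50), 0 + 0i)     # off at t_stop
  sn <- additive_forcing("sinusoid", F = 1, omega_prime = 8 * pi / 5)
  expect_equal(eval_additive_forcing(sn, 0), 1 + 0i)
  tq <- 2 * pi / (8 * pi / 5) / 4                          # quarter period
  expect_equal(eval_additive_forcing(sn, tq), 0 + 1i, tolerance = 1e-12)
  expect_error(additive_forcing("boxcar", F = 1), "t_start")
})

test_that("parametric forcing value and activity follow window membership", {
  pf <- parametric_forcing("rectangular", mu_p = 1, mu_c = 20,
                           t_start = 0, t_stop = 10)
  expect_equal(eval_parametric_forcing(pf, 5), list(value = -19, active = TRUE))
  expect_equal(eval_parametric_forcing(pf, 15),
               list(value = 0, active = FALSE))
  none <- parametric_forcing("none")
  expect_equal(eval_parametric_forcing(none, 3),
               list(value = 0, active = FALSE))
  # mu_p == mu_c would make the active forcing identically zero
  expect_error(parametric_forcing("rectangular", mu_p = 20, mu_c = 20,
                                  t_start = 0, t_stop = 1), "mu_p")
})

test_that("right-hand side matches hand-evaluated values", {
  p <- table1()
  r0 <- hopf_rhs(0 + 0i, 0, p)
  expect_equal(r0$dz, 0 + 0i)
  expect_equal(r0$dmu, -p$alpha / 2)
  r1 <- hopf_rhs(1 + 0i, -15, p)
  expect_equal(r1$dz, complex(real = 4, imaginary = 2 * pi - 0.5),
               tolerance = 1e-12)
  # active parametric forcing replaces mu: coefficient mu_c + Fp = mu_p
  r2 <- hopf_rhs(1 + 0i, 7, p, fp_value = -19, fp_active = TRUE)
  expect_equal(r2$dz, complex(real = 0, imaginary = 2 * pi - 0.5),
               tolerance = 1e-12)
  # mu dynamics are evaluated regardless of parametric activity
  expect_equal(r2$dmu, hopf_rhs(1 + 0i, 7, p)$dmu)
  expect_error(hopf_rhs(NaN + 0i, 0, p), "non-finite")
})

test_that("bundle equation is rotationally equivariant without additive forcing", {
  p <- table1()
  set.seed(11)
  for (i in 1:20) {
    z <- complex(real = rnorm(1), imaginary = rnorm(1))
    mu <- rnorm(1, -15, 5)
    th <- runif(1, 0, 2 * pi)
    a <- hopf_rhs(z * exp(1i * th), mu, p)$dz
    b <- hopf_rhs(z, mu, p)$dz * exp(1i * th)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("closed-form amplitude and frequency laws are mutually consistent", {
  p <- table1()
  expect_equal(steady_amplitude(p, -p$mu_c), 0)
  expect_equal(steady_amplitude(p, -15), sqrt(5))
  expect_equal(steady_amplitude(hopf_params(b_imag = 0), -19), 1)
  # quiescent side clamps to zero; oscillatory side strictly increasing
  mus <- seq(-30, 0, by = 1)
  A <- steady_amplitude(p, mus)
  expect_true(all(A[mus <= -20] == 0))
  expect_true(all(diff(A[mus >= -20]) > 0))
  # frequency law: omega + b2 * A^2, isochronous case flat
  expect_equal(steady_frequency(p, 0), p$omega)
  expect_equal(steady_frequency(p, sqrt(5)), 2 * pi - 2.5)
  iso <- hopf_params(b_imag = 0)
  expect_equal(steady_frequency(iso, 3), iso$omega)
  # cross-consistency on a mu grid
  on <- mus[mus > -20]
  expect_equal(steady_frequency(p, steady_amplitude(p, on)),
               p$omega + p$b_imag * (-(p$mu_c + on) / p$b_real))
})

test_that("one-third law and parametric steady predictions", {
  iso <- hopf_params(b_imag = 0)
  expect_equal(resonant_response_at_bifurcation(iso, 0), 0)
  expect_equal(resonant_response_at_bifurcation(iso, 1), 1)
  expect_equal(resonant_response_at_bifurcation(iso, 8), 2)
  p <- table1()
  ps0 <- parametric_steady_predictions(p, 0)
  expect_equal(ps0$amplitude, 0)
  expect_equal(ps0$frequency, p$omega)
  ps1 <- parametric_steady_predictions(p, 1)
  expect_equal(ps1$amplitude, 1)
  expect_equal(ps1$frequency, 2 * pi - 0.5)
  # consistency with the frequency law at the predicted amplitude
  for (mp in c(0.25, 1, 2.5, 5)) {
    ps <- parametric_steady_predictions(p, mp)
    expect_equal(steady_frequency(p, ps$amplitude), ps$frequency)
  }
  expect_equal(parametric_steady_predictions(hopf_params(b_imag = 0), 3)$frequency,
               2 * pi)
})

test_that("gating curve and self-tuning fixed point", {
  expect_equal(open_probability(10, 0), 0.5)
  expect_equal(open_probability(10, 100), 1)
  expect_equal(open_probability(10, -100), 0)
  p <- table1()
  expect_equal(selftuning_fixed_point(p, 0), -15)
  expect_equal(selftuning_fixed_point(p, 1e6), -30)
  expect_equal(selftuning_fixed_point(p, -1e6), 0)
  # the default operating point is self-tuned onto the oscillatory side
  expect_lt(p$mu_c, p$tau * p$alpha)
  expect_gt(-p$alpha * p$tau / 2, -p$mu_c)
})
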