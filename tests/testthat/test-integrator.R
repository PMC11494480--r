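test_that("timeline segmentation merges protocol discontinuities", {
  bx <- additive_forcing("boxcar", F = 1, t_start = 10, t_stop = 50)
  none_p <- parametric_forcing("none")
  expect_equal(segment_timeline(bx, none_p, c(0, 100)), c(0, 10, 50, 100))
  expect_equal(segment_timeline(additive_forcing("none"), none_p, c(0, 100)),
               c(0, 100))
  rp <- parametric_forcing("rectangular", mu_p = 1, mu_c = 20,
                           t_start = 50, t_stop = 80)
  expect_equal(segment_timeline(bx, rp, c(0, 100)), c(0, 10, 50, 80, 100))
  # edges outside the span are dropped
  expect_equal(segment_timeline(bx, rp, c(20, 45)), c(20, 45))
  expect_error(segment_timeline(bx, none_p, c(5, 5)), "empty")
})

test_that("nearly linear system reproduces the exponential closed form", {
  # b_real ~ 0 with a decaying coefficient: z(t) = z0 exp((mu_c+mu+i w) t)
  p <- hopf_params(mu_c = 20, b_real = -1e-12, b_imag = 0, alpha = 0)
  cfg <- integration_config(z0 = 1 + 0i, mu0 = -21, hold_mu = TRUE)
  tr <- hopf_simulate(p, t_span = c(0, 5), config = cfg)
  zhat <- exp((-1 + 1i * p$omega) * tr$t)
  expect_lt(max(Mod(complex(real = tr$x, imaginary = tr$y) - zhat)), 1e-6)
})

test_that("unforced run converges to the self-tuned limit cycle", {
  tr <- hopf_simulate(table1(), t_span = c(0, 150))
  st <- steady_cycle_stats(tr, 50)
  # attractor values; close to (but distinguishable from) sqrt(5), 2pi-2.5
  expect_rel(st$amplitude, 2.1874, 0.005)
  expect_rel(st$frequency, 3.8882, 0.005)
  expect_rel(mean(tr$mu[tr$t > 100]), -15.21, 0.01)
})

test_that("z = 0 is invariant while mu relaxes to its fixed point", {
  p <- table1()
  cfg <- integration_config(z0 = 0 + 0i, mu0 = 0)
  tr <- hopf_simulate(p, t_span = c(0, 80), config = cfg)
  expect_true(all(tr$x == 0 & tr$y == 0))
  # with x = 0 the mu equation is linear: mu(t) = mu* (1 - exp(-t/tau))
  mu_star <- -p$alpha * p$tau / 2
  expect_equal(tr$mu, mu_star * (1 - exp(-tr$t / p$tau)), tolerance = 1e-6)
})

test_that("runs are deterministic and continuous across segment boundaries", {
  p <- table1()
  bx <- additive_forcing("boxcar", F = 50, t_start = 5, t_stop = 12)
  t1 <- hopf_simulate(p, bx, t_span = c(0, 30))
  t2 <- hopf_simulate(p, bx, t_span = c(0, 30))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # no jump at the discontinuities: position is continuous through t = 5, 12
  for (edge in c(5, 12)) {
    i <- which.min(abs(t1$t - edge))
    expect_lt(abs(t1$x[i + 1] - t1$x[i]),
              10 * max(abs(diff(t1$x[(i - 5):(i + 5)]))))
  }
})

test_that("halving tolerances leaves steady amplitudes unchanged to 0.1%", {
  p <- table1()
  pf <- parametric_forcing("rectangular", mu_p = 1, mu_c = 20,
                           t_start = 20, t_stop = 60)
  co <- integration_config()
  fi <- integration_config(rtol = co$rtol / 2, atol = co$atol / 2)
  tc <- hopf_simulate(p, parametric = pf, t_span = c(0, 60), config = co)
  tf <- hopf_simulate(p, parametric = pf, t_span = c(0, 60), config = fi)
  win <- tc$t >= 20
  ac <- steady_cycle_stats(tc[win, ], 20)$amplitude
  af <- steady_cycle_stats(tf[win, ], 20)$amplitude
  expect_rel(ac, af, 1e-3)
  d <- refine_check(tc, tf)
  expect_lt(d["z"], 1e-4)
})

test_that("refine_check rejects mismatched protocols and is zero on identity", {
  p <- table1()
  tr <- hopf_simulate(p, t_span = c(0, 10))
  expect_equal(unname(refine_check(tr, tr)), c(0, 0))
  tr2 <- hopf_simulate(p, additive_forcing("boxcar", F = 1, t_start = 1,
                                           t_stop = 2), t_span = c(0, 10))
  expect_error(refine_check(tr, tr2), "protocol")
})

test_that("compiled and R-language right-hand sides integrate identically", {
  p <- table1()
  bx <- additive_forcing("sinusoid", F = 0.5, omega_prime = 5)
  tc <- hopf_simulate(p, bx, t_span = c(0, 15))
  tr <- hopf_simulate(p, bx, t_span = c(0, 15), use_compiled = FALSE)
  expect_lt(max(abs(tc$x - tr$x)), 1e-7)
  expect_lt(max(abs(tc$mu - tr$mu)), 1e-7)
})
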