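#' Recovery of spontaneous oscillation after strong boxcar forcing
#'
#' For each forcing duration, simulates a large constant (boxcar) force and
#' measures the recovery time of spontaneous oscillation after the force is
#' removed.  The self-tuning law drives the control parameter deep below the
#' bifurcation during forcing, producing a quiescent interval whose length
#' grows with the forcing duration (when the self-tuned steady state is on the
#' oscillatory side, \eqn{\alpha\tau/2 < \mu_c}).
#'
#' @param params A [hopf_params()] object.
#' @param F Boxcar force amplitude (default 1000).
#' @param tau Self-tuning time constant override (default 35).
#' @param durations Forcing durations (positive, sorted ascending).
#' @param t_start Forcing onset time (default 20, leaving a pre-stimulus
#'   steady-state stretch).
#' @param horizon_after Simulated time after forcing stops (default 200).
#' @param reference_amplitude Reference amplitude for [recovery_time()];
#'   `NULL` = closed form at the self-tuned steady state (must be oscillatory).
#' @param config An [integration_config()].
#' @return A data frame (class `hopf_sweep`) with one row per duration:
#'   `duration`, `t_R`, `recovered`, `mu_stop` (control parameter when forcing
#'   ends), `t_mu_cross`.
#' @export
run_recovery_study <- function(params = hopf_params(), F = 1000, tau = 35,
                               durations = c(40, 60, 80, 97.5),
                               t_start = 20, horizon_after = 200,
                               reference_amplitude = NULL,
                               config = integration_config()) {
  stopifnot(all(durations > 0), !is.unsorted(durations))
  if (!is.null(tau))
    params <- hopf_params(mu_c = params$mu_c, omega = params$omega,
                          b_real = params$b_real, b_imag = params$b_imag,
                          tau = tau, gamma = params$gamma, alpha = params$alpha)
  rows <- lapply(durations, function(d) {
    t_stop <- t_start + d
    ad <- additive_forcing("boxcar", F = F, t_start = t_start, t_stop = t_stop)
    tr <- hopf_simulate(params, ad, parametric_forcing("none", mu_c = params$mu_c),
                        t_span = c(0, t_stop + horizon_after), config = config)
    mu_stop <- stats::approx(tr$t, tr$mu, xout = t_stop)$y
    tR <- tryCatch(
      recovery_time(tr, t_stop, reference_amplitude = reference_amplitude),
      error = function(e) structure(NA_real_, recovered = NA,
                                    t_mu_cross = NA_real_,
                                    msg = conditionMessage(e)))
    data.frame(duration = d, t_R = as.numeric(tR),
               recovered = isTRUE(attr(tR, "recovered")),
               mu_stop = mu_stop,
               t_mu_cross = as.numeric(attr(tR, "t_mu_cross") %||% NA_real_))
  })
  out <- do.call(rbind, rows)
  structure(out, params = params, F = F,
            class = c("hopf_sweep", "data.frame"))
}

#' Parametric modulation of spontaneous oscillation
#'
#' Simulates rectangular parametric forcing at level `mu_p` on a window inside
#' an otherwise unforced, self-tuned run, and returns steady-cycle statistics
#' inside and outside the window.  While active, the forcing replaces the
#' control parameter, so the in-window oscillation should match the closed-form
#' predictions \eqn{\sqrt{-\mu_p/b'}} and \eqn{\omega - (b''/b')\mu_p}; the
#' out-of-window oscillation matches the self-tuned steady state.
#'
#' @param params A [hopf_params()] object.
#' @param mu_p Parametric forcing level (default 1).
#' @param window Length-2 forcing window (default `c(100, 180)`).
#' @param t_end End of simulation (default `window[2] + 40`).
#' @param n_cycles Cycles for the steady averages (default 50).
#' @param config An [integration_config()].
#' @return A list with elements `trace`, `stats_in`, `stats_out`, `predicted`
#'   (closed-form in-window values).
#' @export
run_parametric_spontaneous <- function(params = hopf_params(), mu_p = 1,
                                       window = c(100, 180), t_end = NULL,
                                       n_cycles = 50,
                                       config = integration_config()) {
  t_end <- t_end %||% (window[2] + 40)
  pf <- parametric_forcing("rectangular", mu_p = mu_p, mu_c = params$mu_c,
                           t_start = window[1], t_stop = window[2])
  tr <- hopf_simulate(params, additive_forcing("none"), pf,
                      t_span = c(0, t_end), config = config)
  inside <- tr$t >= window[1] & tr$t < window[2]
  before <- tr$t < window[1]
  stats_in <- steady_cycle_stats(tr[inside, , drop = FALSE], n_cycles)
  stats_out <- steady_cycle_stats(tr[before, , drop = FALSE], n_cycles)
  list(trace = tr, stats_in = stats_in, stats_out = stats_out,
       predicted = parametric_steady_predictions(params, mu_p))
}

.sim_forced <- function(params, F, omega_prime, mu_p, t_end, config) {
  ad <- additive_forcing("sinusoid", F = F, omega_prime = omega_prime)
  pf <- if (is.null(mu_p)) parametric_forcing("none", mu_c = params$mu_c)
        else parametric_forcing("constant", mu_p = mu_p, mu_c = params$mu_c)
  hopf_simulate(params, ad, pf, t_span = c(0, t_end), config = config)
}

#' Arnold-tongue sweep: locking versus forcing amplitude and frequency
#'
#' For every grid point `(F, omega_prime)`, simulates sinusoidal forcing --
#' with full self-tuning when `mu_p` is `NULL`, or under constant parametric
#' forcing at level `mu_p` -- and records the phase-locked amplitude and the
#' vector strength.  Failed cells are flagged, not fatal.
#'
#' @param params A [hopf_params()] object.
#' @param mu_p Constant parametric level, or `NULL` for the self-tuned case.
#' @param F_grid Forcing amplitudes.
#' @param omega_prime_grid Forcing angular frequencies (default 41 points on
#'   `[0.5, 1.5] * omega`).
#' @param t_end Simulation horizon per cell (default 150).
#' @param config An [integration_config()].
#' @return A `hopf_sweep` data frame with columns `F`, `omega_prime`, `A_lock`,
#'   `V`, `ok`.
#' @export
run_arnold_tongue <- function(params = hopf_params(), mu_p = NULL,
                              F_grid = 10^seq(-2, 1, length.out = 12),
                              omega_prime_grid =
                                seq(0.5, 1.5, length.out = 41) * params$omega,
                              t_end = 150,
                              config = integration_config()) {
  stopifnot(length(F_grid) >= 1, length(omega_prime_grid) >= 1)
  grid <- expand.grid(F = F_grid, omega_prime = omega_prime_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    Fi <- grid$F[i]; wi <- grid$omega_prime[i]
    out <- tryCatch({
      tr <- .sim_forced(params, Fi, wi, mu_p, t_end, config)
      c(A_lock = phase_locked_amplitude(tr, wi),
        V = vector_strength(tr, wi), ok = 1)
    }, error = function(e) c(A_lock = NA_real_, V = NA_real_, ok = 0))
    out
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, as.data.frame(res))
  out$ok <- out$ok == 1
  structure(out, params = params, mu_p = mu_p,
            class = c("hopf_sweep", "data.frame"))
}

#' Power-ratio scan: spectral suppression by moderate parametric forcing
#'
#' For each forcing amplitude `F`, simulates the response to resonant
#' sinusoidal forcing twice: the efferent-inactive condition (no parametric
#' forcing; full self-tuning) and the moderate condition (constant parametric
#' forcing at `mu_p_moderate`).  Bartlett spectra of the position signal after
#' burn-in give the ratio of total logarithmic powers
#' \eqn{R(F)}; the scan is summarised by the linear fit
#' \eqn{R = a + b \log_{10} F}.
#'
#' @param params A [hopf_params()] object.
#' @param F_grid Forcing amplitudes (log-spaced over at least a decade).
#' @param mu_p_moderate Moderate parametric level (default 5/2).
#' @param omega_prime Forcing frequency (default the characteristic `omega`).
#' @param burn_in Discarded initial time (default 50 natural periods).
#' @param record Record length analysed after burn-in (default 51200, i.e.
#'   8 segments of 6400 natural periods; the smallest power-of-two segment
#'   length at which doubling the record changes every `R` on the default
#'   grid by less than 1%).
#' @param n_segments Bartlett segments (default 8).
#' @param config An [integration_config()].
#' @return A `hopf_sweep` data frame (`F`, `P_inactive`, `P_moderate`, `R`)
#'   with the `hopf_fit` in attribute `fit`.
#' @export
run_power_ratio_scan <- function(params = hopf_params(),
                                 F_grid = 10^seq(-2, 1, length.out = 12),
                                 mu_p_moderate = 5 / 2,
                                 omega_prime = params$omega,
                                 burn_in = 50 * 2 * pi / params$omega,
                                 record = 51200, n_segments = 8,
                                 config = integration_config()) {
  stopifnot(all(F_grid > 0))
  t_end <- burn_in + record
  one <- function(F, mu_p) {
    tr <- .sim_forced(params, F, omega_prime, mu_p, t_end, config)
    keep <- tr$t > burn_in
    bartlett_psd(tr$x[keep], attr(tr, "dt_out"), n_segments)
  }
  rows <- lapply(F_grid, function(F) {
    ps_i <- one(F, NULL)
    ps_m <- one(F, mu_p_moderate)
    data.frame(F = F, P_inactive = sum(ps_i$power), P_moderate = sum(ps_m$power),
               R = power_ratio(ps_i, ps_m))
  })
  out <- do.call(rbind, rows)
  fit <- fit_relation(out$F, out$R, "log10_linear")
  structure(out, params = params, mu_p_moderate = mu_p_moderate, fit = fit,
            class = c("hopf_sweep", "data.frame"))
}

#' Off-resonance response versus parametric forcing level
#'
#' Phase-locked amplitude at a fixed off-resonance stimulus
#' (default `F = 1`, `omega_prime = 8 pi / 5`) as a function of the constant
#' parametric forcing level `mu_p`, spanning both sides of the bifurcation at
#' `mu_p = 0`.  The response is maximal at some `mu_p > 0`.
#'
#' @param params A [hopf_params()] object (use `b_imag = 0` for the
#'   isochronous case).
#' @param F Forcing amplitude (default 1).
#' @param omega_prime Forcing frequency (default `8 * pi / 5`).
#' @param mu_p_grid Parametric levels (default `seq(-2, 4, by = 0.25)`).
#' @param t_end Horizon per run (default 150).
#' @param config An [integration_config()].
#' @return A `hopf_sweep` data frame (`mu_p`, `A_lock`) with attribute
#'   `argmax_mu_p`.
#' @export
run_offresonance_parametric_scan <- function(params = hopf_params(),
                                             F = 1, omega_prime = 8 * pi / 5,
                                             mu_p_grid = seq(-2, 4, by = 0.25),
                                             t_end = 150,
                                             config = integration_config()) {
  rows <- lapply(mu_p_grid, function(mp) {
    tr <- .sim_forced(params, F, omega_prime, mp, t_end, config)
    data.frame(mu_p = mp, A_lock = phase_locked_amplitude(tr, omega_prime))
  })
  out <- do.call(rbind, rows)
  structure(out, params = params,
            argmax_mu_p = out$mu_p[which.max(out$A_lock)],
            class = c("hopf_sweep", "data.frame"))
}

#' Tuning width of the vector-strength curve versus parametric level
#'
#' For each parametric level `mu_p`, sweeps the stimulus frequency at fixed
#' amplitude `F`, computes the vector strength \eqn{V(\omega')} and its width
#' at half maximum, and fits the relation
#' \eqn{\Delta\omega = c + \mu_p^{\,d}} by nonlinear least squares.
#'
#' Widths are reported on the normalised frequency axis \eqn{\omega'/\omega}
#' (fractions of the characteristic frequency); tongues tilt towards low
#' frequency and widen as `mu_p` shrinks, so the default sweep is wide and
#' asymmetric.  A level whose vector-strength curve never falls below half
#' maximum inside the sweep (at strong forcing the tongue of a weak oscillator
#' reaches down to zero frequency) is flagged, not fatal, and excluded from
#' the fit.
#'
#' @param params A [hopf_params()] object.
#' @param F Forcing amplitude (default 1.5).
#' @param mu_p_grid Positive parametric levels (default
#'   `c(5/32, 0.5, 1, 2.5, 5)`).
#' @param omega_prime_grid Frequency sweep (default 50 points on
#'   `[0.05, 2.5] * omega`).
#' @param t_end Horizon per run (default 300; the smallest horizon at which
#'   doubling changes every measurable width by less than 1%).
#' @param config An [integration_config()].
#' @return A `hopf_sweep` data frame (`mu_p`, `width`, `ok`) with the
#'   `hopf_fit` in attribute `fit` (fitted on the successful rows).
#' @export
run_width_scan <- function(params = hopf_params(), F = 1.5,
                           mu_p_grid = c(5 / 32, 0.5, 1, 2.5, 5),
                           omega_prime_grid =
                             seq(0.05, 2.5, length.out = 50) * params$omega,
                           t_end = 300,
                           config = integration_config()) {
  stopifnot(all(mu_p_grid > 0))
  rows <- lapply(mu_p_grid, function(mp) {
    V <- vapply(omega_prime_grid, function(w) {
      tr <- .sim_forced(params, F, w, mp, t_end, config)
      vector_strength(tr, w)
    }, numeric(1))
    wd <- tryCatch(half_width(omega_prime_grid / params$omega, V),
                   error = function(e) NA_real_)
    data.frame(mu_p = mp, width = wd, ok = is.finite(wd))
  })
  out <- do.call(rbind, rows)
  fit <- if (sum(out$ok) >= 3)
    fit_relation(out$mu_p[out$ok], out$width[out$ok], "offset_power")
  else NULL
  structure(out, params = params, F = F, fit = fit,
            class = c("hopf_sweep", "data.frame"))
}

#' Half-width of the amplitude response versus forcing amplitude
#'
#' With the control parameter pinned at the bifurcation
#' (\eqn{\mu = -\mu_c}), sweeps the stimulus frequency around the
#' characteristic frequency for each forcing amplitude, computes the
#' phase-locked amplitude curve \eqn{A(\omega')} and its width at half
#' maximum, and fits the power law \eqn{\Delta\omega \propto F^{2/3}}.
#' The frequency sweep half-span scales as \eqn{F^{2/3}} so the feature is
#' resolved equally well at every amplitude.
#'
#' @param params A [hopf_params()] object.
#' @param F_grid Forcing amplitudes (default `c(0.05, 0.1, 0.2, 0.5, 1)`).
#' @param n_omega Points in the frequency sweep (default 41).
#' @param span_factor Sweep half-span = `span_factor * F^(2/3)` (default 4).
#' @param config Solver settings (the control parameter is held fixed).
#' @return A `hopf_sweep` data frame (`F`, `width`, `ok`) with the power-law
#'   `hopf_fit` in attribute `fit`.
#' @export
run_amplitude_width_scan <- function(params = hopf_params(),
                                     F_grid = c(0.05, 0.1, 0.2, 0.5, 1),
                                     n_omega = 41, span_factor = 4,
                                     config = NULL) {
  stopifnot(all(F_grid > 0))
  rows <- lapply(F_grid, function(F) {
    span <- span_factor * F^(2 / 3)
    wgrid <- seq(params$omega - span, params$omega + span,
                 length.out = n_omega)
    wgrid <- wgrid[wgrid > 0]
    t_end <- max(150, 60 * F^(-2 / 3))
    cfg <- config %||% integration_config(mu0 = -params$mu_c, hold_mu = TRUE)
    A <- vapply(wgrid, function(w) {
      tr <- .sim_forced(params, F, w, NULL, t_end, cfg)
      phase_locked_amplitude(tr, w)
    }, numeric(1))
    wd <- tryCatch(half_width(wgrid, A), error = function(e) NA_real_)
    data.frame(F = F, width = wd, ok = is.finite(wd))
  })
  out <- do.call(rbind, rows)
  fit <- if (sum(out$ok) >= 3)
    fit_relation(out$F[out$ok], out$width[out$ok], "power_law")
  else NULL
  structure(out, params = params, fit = fit,
            class = c("hopf_sweep", "data.frame"))
}

#' Resonant response scaling at the bifurcation point
#'
#' Simulates the forced bundle equation with the control parameter pinned at
#' the bifurcation (\eqn{\mu = -\mu_c}) under resonant forcing
#' (\eqn{\omega' = \omega}) for each amplitude in `F_grid`, and returns the
#' steady phase-locked amplitude.  Defaults to the isochronous oscillator
#' (\eqn{\beta = -1}), for which the one-third law
#' \eqn{A = (-b')^{-1/3} F^{1/3}} is exact at resonance.
#'
#' @param params A [hopf_params()] object; default isochronous (`b_imag = 0`).
#' @param F_grid Forcing amplitudes spanning at least a decade.
#' @param config Solver settings (control parameter held at the bifurcation).
#' @return A `hopf_sweep` data frame (`F`, `A`) with the log-log power-law
#'   `hopf_fit` in attribute `fit`.
#' @export
run_resonance_scaling <- function(params = hopf_params(b_imag = 0),
                                  F_grid = 10^seq(-3, 0, length.out = 8),
                                  config = NULL) {
  stopifnot(all(F_grid > 0))
  cfg <- config %||% integration_config(mu0 = -params$mu_c, hold_mu = TRUE)
  rows <- lapply(F_grid, function(F) {
    t_end <- max(150, 60 * F^(-2 / 3))
    tr <- .sim_forced(params, F, params$omega, NULL, t_end, cfg)
    data.frame(F = F, A = phase_locked_amplitude(tr, params$omega))
  })
  out <- do.call(rbind, rows)
  fit <- fit_relation(out$F, out$A, "power_law")
  structure(out, params = params, fit = fit,
            class = c("hopf_sweep", "data.frame"))
}

#' Efferent rescue of post-overstimulation quiescence
#'
#' Simulates a large additive boxcar force with parametric forcing applied
#' never (`"none"`), only during the additive window (`"during"`), or from the
#' end of the additive window until the end of the simulation (`"after"`), and
#' measures the recovery time of spontaneous oscillation.  Parametric forcing
#' after overstimulation abolishes the quiescent interval; applied only during
#' overstimulation it leaves the quiescent interval unchanged, because the
#' control parameter evolves independently of the parametric forcing.
#'
#' @param params A [hopf_params()] object.
#' @param F_a Additive force amplitude (default 50).
#' @param mu_p Parametric level (default 5).
#' @param timing One of `"none"`, `"during"`, `"after"`.
#' @param t_start_a,t_stop_a Additive forcing window (defaults 20 and 50).
#' @param t_end Simulation end (default `t_stop_a + 120`).
#' @param config An [integration_config()].
#' @return A list with `trace`, `t_R` (with attributes from
#'   [recovery_time()]), and `timing`.
#' @export
run_efferent_recovery <- function(params = hopf_params(), F_a = 50, mu_p = 5,
                                  timing = c("none", "during", "after"),
                                  t_start_a = 20, t_stop_a = 50, t_end = NULL,
                                  config = integration_config()) {
  timing <- match.arg(timing)
  t_end <- t_end %||% (t_stop_a + 120)
  ad <- additive_forcing("boxcar", F = F_a, t_start = t_start_a,
                         t_stop = t_stop_a)
  pf <- switch(timing,
    none = parametric_forcing("none", mu_c = params$mu_c),
    during = parametric_forcing("rectangular", mu_p = mu_p, mu_c = params$mu_c,
                                t_start = t_start_a, t_stop = t_stop_a),
    after = parametric_forcing("rectangular", mu_p = mu_p, mu_c = params$mu_c,
                               t_start = t_stop_a, t_stop = t_end))
  tr <- hopf_simulate(params, ad, pf, t_span = c(0, t_end), config = config)
  tR <- recovery_time(tr, t_stop_a)
  list(trace = tr, t_R = tR, timing = timing)
}

#' @export
print.hopf_sweep <- function(x, ...) {
  cat(sprintf("Sweep result: %d conditions\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  f <- attr(x, "fit")
  if (!is.null(f)) { cat("Attached fit:\n"); print(f) }
  invisible(x)
}
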