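#' Instantaneous amplitude and phase of a trace
#'
#' Computes \eqn{A(t) = |z(t)|}, the unwrapped argument \eqn{\phi(t)} of
#' \eqn{z}, and the instantaneous angular frequency \eqn{\dot\phi(t)} by
#' central differences of the unwrapped phase on the output grid.  Samples with
#' \eqn{|z| = 0} have undefined phase; they are returned as `NA` and excluded
#' from downstream frequency statistics.
#'
#' @param trace A `hopf_trace` or data frame with columns `t`, `x`, `y`.
#' @return A data frame with columns `t`, `A`, `phi`, `phi_dot`.
#' @export
amplitude_phase <- function(trace) {
  stopifnot(all(c("t", "x", "y") %in% names(trace)))
  A <- sqrt(trace$x^2 + trace$y^2)
  phi <- rep(NA_real_, length(A))
  ok <- A > 0
  phi[ok] <- unwrap_phase(atan2(trace$y[ok], trace$x[ok]))
  phi_dot <- .central_diff(phi, trace$t)
  data.frame(t = trace$t, A = A, phi = phi, phi_dot = phi_dot)
}

#' Unwrap a phase sequence
#'
#' Removes 2*pi jumps from a wrapped phase sequence (NA-tolerant; runs of NA
#' break and restart the unwrapping).
#'
#' @param phi Wrapped phase values (radians).
#' @return Unwrapped phase.
#' @export
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  d[is.na(d)] <- 0
  phi0 <- phi[1]
  if (is.na(phi0)) phi0 <- 0
  out <- phi0 + c(0, cumsum(d))
  out[is.na(phi)] <- NA_real_
  out
}

.central_diff <- function(v, t) {
  n <- length(v)
  if (n < 2L) return(rep(NA_real_, n))
  out <- rep(NA_real_, n)
  out[1] <- (v[2] - v[1]) / (t[2] - t[1])
  out[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  out
}

#' Average amplitude and frequency over the last steady-state cycles
#'
#' Averages the amplitude function and the angular frequency over exactly the
#' trailing `n_cycles` complete oscillation cycles.  Cycle boundaries come from
#' the unwrapped phase: the window is `[t*, t_end]` where \eqn{\phi(t^*)}
#' (linearly interpolated) lies `2 pi n_cycles` below \eqn{\phi(t_{end})}.  The
#' mean frequency is the exact phase advance over the window divided by its
#' duration; the mean amplitude is the trapezoidal time average.
#'
#' @param trace A `hopf_trace` or data frame with `t`, `x`, `y`.
#' @param n_cycles Number of trailing complete cycles (default 50).
#' @return A list with `amplitude` and `frequency`.
#' @export
steady_cycle_stats <- function(trace, n_cycles = 50) {
  ap <- amplitude_phase(trace)
  ok <- !is.na(ap$phi)
  if (!all(ok)) { ap <- ap[ok, , drop = FALSE] }
  n <- nrow(ap)
  if (n < 3L) stop("trace too short for cycle statistics")
  phi_end <- ap$phi[n]
  target <- phi_end - 2 * pi * n_cycles
  if (ap$phi[1] > target)
    stop(sprintf("trace contains fewer than %d complete cycles", n_cycles))
  i <- max(which(ap$phi <= target))
  # linear interpolation of the crossing time inside [i, i+1]
  t_star <- ap$t[i] + (target - ap$phi[i]) /
    (ap$phi[i + 1] - ap$phi[i]) * (ap$t[i + 1] - ap$t[i])
  A_star <- ap$A[i] + (t_star - ap$t[i]) /
    (ap$t[i + 1] - ap$t[i]) * (ap$A[i + 1] - ap$A[i])
  tt <- c(t_star, ap$t[(i + 1):n])
  AA <- c(A_star, ap$A[(i + 1):n])
  w <- diff(tt)
  amp <- sum(w * (AA[-1] + AA[-length(AA)]) / 2) / (tt[length(tt)] - tt[1])
  freq <- 2 * pi * n_cycles / (ap$t[n] - t_star)
  list(amplitude = amp, frequency = freq)
}

# analysis window: trailing fraction of the trace trimmed to an integer
# number of forcing periods (suppresses leakage and transients)
.locking_window <- function(trace, omega_prime, window_fraction = 0.6) {
  t0 <- trace$t[1]; t1 <- trace$t[nrow(trace)]
  span <- (t1 - t0) * window_fraction
  period <- 2 * pi / omega_prime
  n_per <- floor(span / period)
  if (n_per < 1L)
    stop("analysis window shorter than one forcing period")
  trace$t >= t1 - n_per * period
}

#' Vector strength of phase locking to a rotating stimulus
#'
#' \eqn{V = |\langle e^{i(\phi(t) - \omega' t)}\rangle|}, the modulus of the
#' circular mean of the phase difference between the oscillator and the
#' stimulus phase \eqn{\phi' = \omega' t}; 1 indicates perfect locking, 0 no
#' locking.  The average is taken over the trailing part of the trace trimmed
#' to an integer number of forcing periods.
#'
#' @param trace A `hopf_trace` or data frame with `t`, `x`, `y`.
#' @param omega_prime Stimulus angular frequency (> 0).
#' @param window_fraction Trailing fraction of the trace to analyse before
#'   trimming (default 0.6).
#' @return Vector strength in `[0, 1]`.
#' @export
vector_strength <- function(trace, omega_prime, window_fraction = 0.6) {
  stopifnot(omega_prime > 0)
  keep <- .locking_window(trace, omega_prime, window_fraction)
  z <- complex(real = trace$x[keep], imaginary = trace$y[keep])
  a <- Mod(z)
  use <- a > 0
  if (!any(use)) stop("trace has zero amplitude throughout the window")
  u <- z[use] / a[use] * exp(-1i * omega_prime * trace$t[keep][use])
  Mod(mean(u))
}

#' Phase-locked response amplitude
#'
#' Modulus of the Fourier coefficient of \eqn{z(t)} at the stimulus frequency,
#' over a trailing window trimmed to an integer number of forcing periods,
#' normalised so a pure tone \eqn{z = A e^{i\omega' t}} returns exactly `A`.
#'
#' @inheritParams vector_strength
#' @return Amplitude (>= 0).
#' @export
phase_locked_amplitude <- function(trace, omega_prime, window_fraction = 0.6) {
  stopifnot(omega_prime > 0)
  keep <- .locking_window(trace, omega_prime, window_fraction)
  z <- complex(real = trace$x[keep], imaginary = trace$y[keep])
  Mod(mean(z * exp(-1i * omega_prime * trace$t[keep])))
}

#' Bartlett power spectral density estimate
#'
#' Splits the record into `n_segments` equal non-overlapping segments
#' (truncating any remainder), computes the periodogram of each and averages.
#' The density is per unit angular frequency on the full FFT grid
#' \eqn{\omega_k = 2\pi k/(L\,\Delta t)}, so Parseval holds:
#' `sum(power) * d_omega` equals the mean square of the (truncated) signal.
#'
#' @param x_samples Real signal samples on a uniform grid.
#' @param sample_interval Sampling interval \eqn{\Delta t} (> 0).
#' @param n_segments Number of Bartlett segments (default 8).
#' @return An object of class `hopf_psd`: list with `omega` (angular frequency
#'   grid), `power`, `d_omega`, `n_segments`, `segment_length`.
#' @export
bartlett_psd <- function(x_samples, sample_interval, n_segments = 8) {
  stopifnot(sample_interval > 0, n_segments >= 1)
  n <- length(x_samples)
  if (n_segments > n)
    stop("more Bartlett segments than samples")
  L <- n %/% n_segments
  if (L < 2L) stop("segments too short")
  p <- numeric(L)
  for (s in seq_len(n_segments)) {
    seg <- x_samples[((s - 1) * L + 1):(s * L)]
    X <- stats::fft(seg)
    p <- p + Mod(X)^2 * sample_interval / L / (2 * pi)
  }
  p <- p / n_segments
  d_omega <- 2 * pi / (L * sample_interval)
  structure(list(omega = (seq_len(L) - 1) * d_omega, power = p,
                 d_omega = d_omega, n_segments = n_segments,
                 segment_length = L),
            class = "hopf_psd")
}

#' @export
print.hopf_psd <- function(x, ...) {
  cat(sprintf("Bartlett PSD: %d segments of %d samples, d_omega = %.4g\n",
              x$n_segments, x$segment_length, x$d_omega))
  cat(sprintf("  total power (sum P * d_omega) = %.6g\n",
              sum(x$power) * x$d_omega))
  invisible(x)
}

#' Ratio of total logarithmic spectral powers
#'
#' \eqn{R = \log_{10}\sum_{\omega'} P_\mathrm{inactive}(\omega') /
#' \log_{10}\sum_{\omega'} P_\mathrm{moderate}(\omega')} -- the ratio of the
#' logarithms of the summed spectral densities (not the logarithm of their
#' ratio).  Both spectra must share a grid.
#'
#' @param psd_inactive,psd_moderate `hopf_psd` objects on identical grids.
#' @return The scalar ratio `R`.
#' @export
power_ratio <- function(psd_inactive, psd_moderate) {
  stopifnot(inherits(psd_inactive, "hopf_psd"),
            inherits(psd_moderate, "hopf_psd"))
  if (length(psd_inactive$omega) != length(psd_moderate$omega) ||
      any(abs(psd_inactive$omega - psd_moderate$omega) > 1e-9))
    stop("spectra are not on identical frequency grids")
  num <- sum(psd_inactive$power)
  den <- sum(psd_moderate$power)
  if (num <= 0 || den <= 0) stop("non-positive total power")
  lden <- log10(den)
  if (lden == 0) stop("denominator total power equals 1: log is zero")
  log10(num) / lden
}

#' Width at half maximum of a sampled curve
#'
#' Locates the unique interior maximum of `value(omega)` and the two crossings
#' of `max/2` (linear interpolation between adjacent grid points) on either
#' side.  Errors if the curve does not fall below half maximum on both sides of
#' the peak within the sampled range.
#'
#' @param omega Strictly increasing abscissa (e.g. forcing frequency).
#' @param value Curve values (same length).
#' @return The width `Delta omega` (right crossing minus left crossing).
#' @export
half_width <- function(omega, value) {
  stopifnot(length(omega) == length(value), length(omega) >= 3,
            all(diff(omega) > 0))
  i_max <- which.max(value)
  if (i_max == 1L || i_max == length(value))
    stop("maximum lies on the boundary of the sampled range; widen the sweep")
  half <- value[i_max] / 2
  left <- NA_real_
  for (i in seq(i_max - 1L, 1L)) {
    if (value[i] <= half) {
      left <- omega[i] + (half - value[i]) / (value[i + 1] - value[i]) *
        (omega[i + 1] - omega[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(i_max + 1L, length(value))) {
    if (value[i] <= half) {
      right <- omega[i - 1] + (half - value[i - 1]) /
        (value[i] - value[i - 1]) * (omega[i] - omega[i - 1])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("curve does not cross half maximum on both sides; widen the sweep")
  right - left
}

#' Recovery time after cessation of strong forcing
#'
#' Time after `t_stop_a` at which the oscillation amplitude first reaches
#' `threshold_fraction` of a reference amplitude, measured from the first
#' upward crossing after the post-stimulus quiescent dip.  If the amplitude
#' never falls below the threshold after `t_stop_a` the bundle was never
#' quiescent and the recovery time is 0.  If it falls below and never
#' recovers within the simulated horizon the result is `NA` with attribute
#' `recovered = FALSE`.  The reference defaults to the closed-form steady
#' amplitude at the self-tuned operating point \eqn{\mu = -\alpha\tau/2} of
#' the trace's parameters.  The first time \eqn{\mu} re-crosses \eqn{-\mu_c}
#' is attached as attribute `t_mu_cross` (NA if it never does).
#'
#' @param trace A `hopf_trace` (needs `mu` and parameter provenance for the
#'   defaults; a plain data frame works if `reference_amplitude` is given).
#' @param t_stop_a End of the strong-forcing window.
#' @param threshold_fraction Fraction of the reference amplitude defining
#'   recovery (default 0.5).
#' @param reference_amplitude Reference amplitude; `NULL` = closed form at the
#'   self-tuned steady state.
#' @return Numeric recovery time `tR` (0 = never quiescent; `NA` = not
#'   recovered within the horizon), with attributes `recovered` and
#'   `t_mu_cross`.
#' @export
recovery_time <- function(trace, t_stop_a, threshold_fraction = 0.5,
                          reference_amplitude = NULL) {
  stopifnot(threshold_fraction > 0)
  if (is.null(reference_amplitude)) {
    p <- attr(trace, "params")
    if (is.null(p)) stop("no parameter provenance; supply reference_amplitude")
    reference_amplitude <- steady_amplitude(p, -p$alpha * p$tau / 2)
    if (reference_amplitude <= 0)
      stop("self-tuned steady state is quiescent: reference amplitude is 0; ",
           "supply reference_amplitude explicitly")
  }
  if (reference_amplitude <= 0) stop("reference_amplitude must be > 0")
  thr <- threshold_fraction * reference_amplitude
  post <- trace$t > t_stop_a
  if (!any(post)) stop("trace does not extend beyond t_stop_a")
  tt <- trace$t[post]
  A <- sqrt(trace$x[post]^2 + trace$y[post]^2)

  t_mu_cross <- NA_real_
  if (!is.null(trace$mu)) {
    p <- attr(trace, "params")
    if (!is.null(p)) {
      below <- trace$mu[post] < -p$mu_c
      if (below[1] && any(!below)) {
        i <- which(!below)[1]
        t_mu_cross <- tt[i - 1] + (-p$mu_c - trace$mu[post][i - 1]) /
          (trace$mu[post][i] - trace$mu[post][i - 1]) * (tt[i] - tt[i - 1])
      } else if (!below[1]) t_mu_cross <- t_stop_a
    }
  }

  res <- function(v, recovered) structure(v, recovered = recovered,
                                          t_mu_cross = t_mu_cross)
  below <- A < thr
  if (!any(below)) return(res(0, TRUE))        # never quiescent
  i_dip <- which(below)[1]
  after <- seq(i_dip, length(A))
  up <- which(A[after] >= thr)
  if (length(up) == 0L) return(res(NA_real_, FALSE))
  j <- after[up[1]]
  # interpolate the upward crossing
  t_rec <- if (j > 1 && A[j] > A[j - 1]) {
    tt[j - 1] + (thr - A[j - 1]) / (A[j] - A[j - 1]) * (tt[j] - tt[j - 1])
  } else tt[j]
  res(t_rec - t_stop_a, TRUE)
}

#' Least-squares fit of the relations used in the response scans
#'
#' Three functional forms:
#' \describe{
#'   \item{`"power_law"`}{\eqn{y = c\,x^b}, fitted as a linear regression of
#'     \eqn{\log y} on \eqn{\log x}; coefficients `c`, `b`.}
#'   \item{`"offset_power"`}{\eqn{y = c + x^d}, fitted by nonlinear least
#'     squares; coefficients `c`, `d`.}
#'   \item{`"log10_linear"`}{\eqn{y = a + b\,\log_{10} x}, fitted by linear
#'     regression; coefficients `a`, `b`.}
#' }
#' Unweighted least squares throughout.
#'
#' @param x_values,y_values Data (>= 3 points; `x` must be positive for all
#'   forms, `y` positive for `"power_law"`).
#' @param form One of `"power_law"`, `"offset_power"`, `"log10_linear"`.
#' @return An object of class `hopf_fit`: list with `form`, `coefficients`,
#'   `residual_norm`, `x_range`, `y_range`.
#' @examples
#' f <- fit_relation(1:10, (1:10)^(1/3), "power_law")
#' coef(f)["b"]   # 1/3
#' @export
fit_relation <- function(x_values, y_values,
                         form = c("power_law", "offset_power", "log10_linear")) {
  form <- match.arg(form)
  ok <- is.finite(x_values) & is.finite(y_values)
  x <- x_values[ok]; y <- y_values[ok]
  if (length(x) < 3L) stop("need at least 3 finite points")
  if (any(x <= 0)) stop("non-positive x under a logarithmic form")
  co <- switch(form,
    power_law = {
      if (any(y <= 0)) stop("non-positive y under a logarithmic form")
      fit <- stats::lm(log(y) ~ log(x))
      c(c = unname(exp(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
    },
    offset_power = {
      d0 <- tryCatch(unname(stats::coef(stats::lm(log(pmax(y - min(y) * 0.9,
        1e-12)) ~ log(x)))[2]), error = function(e) -0.5)
      if (!is.finite(d0)) d0 <- -0.5
      fit <- minpack.lm::nlsLM(y ~ cc + x^dd,
                               start = list(cc = 0, dd = d0),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(fit)
      c(c = unname(cf["cc"]), d = unname(cf["dd"]))
    },
    log10_linear = {
      fit <- stats::lm(y ~ log10(x))
      c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
    })
  pred <- switch(form,
    power_law = co["c"] * x^co["b"],
    offset_power = co["c"] + x^co["d"],
    log10_linear = co["a"] + co["b"] * log10(x))
  structure(list(form = form, coefficients = co,
                 residual_norm = sqrt(sum((y - pred)^2)),
                 x_range = range(x), y_range = range(y)),
            class = "hopf_fit")
}

#' @export
coef.hopf_fit <- function(object, ...) object$coefficients

#' @export
print.hopf_fit <- function(x, ...) {
  lab <- switch(x$form, power_law = "y = c * x^b",
                offset_power = "y = c + x^d",
                log10_linear = "y = a + b * log10(x)")
  cat(sprintf("Fit of %s\n", lab))
  print(round(x$coefficients, 6))
  cat(sprintf("  residual norm = %.4g on x in [%g, %g]\n",
              x$residual_norm, x$x_range[1], x$x_range[2]))
  invisible(x)
}
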