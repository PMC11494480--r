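#' Model parameters for the feedback-controlled Hopf oscillator
#'
#' Constructs and validates the parameter set of the Stuart-Landau hair-bundle
#' model with intrinsic self-tuning.  The bundle state is the complex variable
#' \eqn{z(t) = x(t) + i y(t)} whose real part is the bundle position; the control
#' parameter \eqn{\mu} measures displacement from the supercritical Hopf
#' bifurcation at \eqn{\mu = -\mu_c}.  The governing equations are
#' \deqn{dz/dt = (\mu_c + \mu \, 1_{F_p = 0} + F_p) z + i\omega z + \beta |z|^2 z + F_a,}
#' \deqn{d\mu/dt = -\mu/\tau - \alpha / (1 + e^{-\gamma x}),}
#' with \eqn{\beta = b' + i b''}.  Defaults are the reference parameter set
#' (\eqn{\mu_c = 20}, \eqn{\omega = 2\pi}, \eqn{\beta = -1 - i/2}, \eqn{\tau = 10},
#' \eqn{\gamma = 10}, \eqn{\alpha = 3}).
#'
#' @param mu_c Bifurcation point (dimensionless, > 0).
#' @param omega Characteristic angular frequency (rad per unit time).
#' @param b_real Real part of the cubic nonlinearity \eqn{\beta}; must be < 0
#'   (supercritical branch).
#' @param b_imag Imaginary part of \eqn{\beta}; couples amplitude to frequency
#'   (0 gives an isochronous oscillator).
#' @param tau Self-tuning relaxation time (> 0).
#' @param gamma Gating sensitivity of the transduction-channel open probability
#'   (inverse displacement, > 0).
#' @param alpha Self-tuning strength (control-parameter units per unit time,
#'   >= 0); proportional to the maximal calcium influx.
#'
#' @return An object of class `hopf_params` (a named list).
#' @examples
#' p <- hopf_params()
#' selftuning_fixed_point(p, 0)   # -alpha * tau / 2 = -15
#' @export
hopf_params <- function(mu_c = 20, omega = 2 * pi, b_real = -1, b_imag = -1 / 2,
                        tau = 10, gamma = 10, alpha = 3) {
  stopifnot(is.numeric(mu_c), is.numeric(omega), is.numeric(b_real),
            is.numeric(b_imag), is.numeric(tau), is.numeric(gamma),
            is.numeric(alpha))
  if (!is.finite(mu_c) || mu_c <= 0) stop("'mu_c' must be finite and > 0")
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be finite and > 0")
  if (!is.finite(b_real) || b_real >= 0)
    stop("'b_real' must be < 0 (supercritical Hopf branch)")
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be finite and > 0")
  if (!is.finite(alpha) || alpha < 0) stop("'alpha' must be finite and >= 0")
  if (!is.finite(omega)) stop("'omega' must be finite")
  structure(list(mu_c = mu_c, omega = omega, b_real = b_real, b_imag = b_imag,
                 tau = tau, gamma = gamma, alpha = alpha),
            class = "hopf_params")
}

#' @export
print.hopf_params <- function(x, ...) {
  cat("Hopf hair-bundle model parameters\n")
  cat(sprintf("  mu_c  = %g   (bifurcation point)\n", x$mu_c))
  cat(sprintf("  omega = %g   (characteristic angular frequency)\n", x$omega))
  cat(sprintf("  beta  = %g%+gi (nonlinearity b' + i b'')\n", x$b_real, x$b_imag))
  cat(sprintf("  tau   = %g   (self-tuning relaxation time)\n", x$tau))
  cat(sprintf("  gamma = %g   (gating sensitivity)\n", x$gamma))
  cat(sprintf("  alpha = %g   (self-tuning strength)\n", x$alpha))
  st <- -x$alpha * x$tau / 2
  cat(sprintf("  self-tuned <mu> = -alpha*tau/2 = %g (%s side of -mu_c = %g)\n",
              st, if (st > -x$mu_c) "oscillatory" else "quiescent", -x$mu_c))
  invisible(x)
}

#' Additive forcing protocols
#'
#' An additive force \eqn{F_a(t)} entering the bundle equation.  Three variants:
#' `"none"`, `"boxcar"` (a constant real force \eqn{F} on a window) and
#' `"sinusoid"` (the complex rotating force \eqn{F e^{i\omega' t}}, optionally
#' windowed).  Windows are half-open `[t_start, t_stop)`: the force applies at
#' `t_start` and is already off at `t_stop`, so the Heaviside difference
#' \eqn{\Theta(t - t_\mathrm{start}) - \Theta(t - t_\mathrm{stop})} is
#' single-valued at the discontinuities.
#'
#' @param variant One of `"none"`, `"boxcar"`, `"sinusoid"`.
#' @param F Force amplitude (>= 0).
#' @param t_start,t_stop Window endpoints (required for `"boxcar"`, optional for
#'   `"sinusoid"`; `t_start < t_stop`).
#' @param omega_prime Forcing angular frequency (> 0; `"sinusoid"` only).
#' @return An object of class `hopf_additive`.
#' @seealso [eval_additive_forcing()]
#' @export
additive_forcing <- function(variant = c("none", "boxcar", "sinusoid"),
                             F = 0, t_start = NULL, t_stop = NULL,
                             omega_prime = NULL) {
  variant <- match.arg(variant)
  if (variant != "none") {
    if (!is.numeric(F) || !is.finite(F) || F < 0)
      stop("'F' must be finite and >= 0")
  }
  if (variant == "boxcar") {
    if (is.null(t_start) || is.null(t_stop))
      stop("boxcar forcing requires 't_start' and 't_stop'")
  }
  if (variant == "sinusoid") {
    if (is.null(omega_prime) || !is.finite(omega_prime) || omega_prime <= 0)
      stop("sinusoid forcing requires 'omega_prime' > 0")
  }
  if (!is.null(t_start) || !is.null(t_stop)) {
    if (is.null(t_start) || is.null(t_stop) || t_start >= t_stop)
      stop("forcing window requires t_start < t_stop")
  }
  structure(list(variant = variant, F = if (variant == "none") 0 else F,
                 t_start = t_start, t_stop = t_stop,
                 omega_prime = omega_prime),
            class = "hopf_additive")
}

#' Parametric forcing protocols
#'
#' Efferent input is modelled as a parametric forcing function \eqn{F_p(t)}
#' that, while active, replaces the self-tuned control parameter in the bundle
#' equation: the linear coefficient becomes \eqn{\mu_c + F_p} with
#' \eqn{F_p = \mu_p - \mu_c}, so the effective displacement from the bifurcation
#' is exactly \eqn{\mu_p}.  Variants: `"none"`, `"rectangular"` (active on a
#' half-open window `[t_start, t_stop)`) and `"constant"` (active for the whole
#' simulation).  Activity is defined by window membership, not by comparing the
#' forcing value against zero; consequently `mu_p == mu_c` (which would make
#' \eqn{F_p \equiv 0} while nominally active) is rejected at construction.
#'
#' @param variant One of `"none"`, `"rectangular"`, `"constant"`.
#' @param mu_p Parametric forcing level, in control-parameter units.  The
#'   forcing strength of an active protocol is \eqn{S = 1/\mu_p} (defined for
#'   `mu_p > 0`).
#' @param mu_c Bifurcation point of the model the protocol will act on (needed
#'   to form \eqn{F_p = \mu_p - \mu_c}).
#' @param t_start,t_stop Window endpoints (`"rectangular"` only).
#' @return An object of class `hopf_parametric`.
#' @seealso [eval_parametric_forcing()]
#' @export
parametric_forcing <- function(variant = c("none", "rectangular", "constant"),
                               mu_p = NULL, mu_c = 20,
                               t_start = NULL, t_stop = NULL) {
  variant <- match.arg(variant)
  if (variant != "none") {
    if (is.null(mu_p) || !is.finite(mu_p)) stop("'mu_p' must be finite")
    if (mu_p == mu_c)
      stop("'mu_p' equal to 'mu_c' gives an identically zero active forcing; ",
           "use variant = \"none\" instead")
  }
  if (variant == "rectangular") {
    if (is.null(t_start) || is.null(t_stop) || t_start >= t_stop)
      stop("rectangular forcing requires t_start < t_stop")
  }
  structure(list(variant = variant, mu_p = mu_p, mu_c = mu_c,
                 t_start = t_start, t_stop = t_stop),
            class = "hopf_parametric")
}

#' Evaluate an additive forcing protocol at a time point
#'
#' Returns the (complex) force value.  Boxcar windows are half-open
#' `[t_start, t_stop)`.
#'
#' @param protocol A [additive_forcing()] object.
#' @param t Time (finite numeric, vectorised).
#' @return Complex vector of force values.
#' @export
eval_additive_forcing <- function(protocol, t) {
  stopifnot(inherits(protocol, "hopf_additive"), all(is.finite(t)))
  switch(protocol$variant,
    none = rep(0 + 0i, length(t)),
    boxcar = {
      inside <- t >= protocol$t_start & t < protocol$t_stop
      ifelse(inside, protocol$F + 0i, 0 + 0i)
    },
    sinusoid = {
      v <- protocol$F * exp(1i * protocol$omega_prime * t)
      if (!is.null(protocol$t_start)) {
        inside <- t >= protocol$t_start & t < protocol$t_stop
        v[!inside] <- 0 + 0i
      }
      v
    })
}

#' Evaluate a parametric forcing protocol at a time point
#'
#' @param protocol A [parametric_forcing()] object.
#' @param t Time (finite numeric, scalar).
#' @return A list with elements `value` (\eqn{\mu_p - \mu_c} inside the active
#'   window, 0 outside) and `active` (logical; window membership).
#' @export
eval_parametric_forcing <- function(protocol, t) {
  stopifnot(inherits(protocol, "hopf_parametric"), length(t) == 1L,
            is.finite(t))
  active <- switch(protocol$variant,
    none = FALSE,
    constant = TRUE,
    rectangular = t >= protocol$t_start && t < protocol$t_stop)
  list(value = if (active) protocol$mu_p - protocol$mu_c else 0,
       active = active)
}

#' Right-hand side of the coupled bundle/control-parameter system
#'
#' The instantaneous derivatives of the forced Stuart-Landau equation and of the
#' self-tuning law.  The control parameter always evolves by its own equation;
#' when parametric forcing is active it is merely excluded from the bundle
#' equation (the two are independent).
#'
#' @param z Complex bundle state.
#' @param mu Control parameter value.
#' @param params A [hopf_params()] object.
#' @param fa Complex additive force at this instant.
#' @param fp_value Parametric forcing value (\eqn{\mu_p - \mu_c} or 0).
#' @param fp_active Logical; is parametric forcing active?
#' @return A list with `dz` (complex) and `dmu` (real).
#' @examples
#' p <- hopf_params()
#' hopf_rhs(0 + 0i, 0, p)   # dz = 0 at the fixed point, dmu = -alpha/2
#' @export
hopf_rhs <- function(z, mu, params, fa = 0 + 0i, fp_value = 0,
                     fp_active = FALSE) {
  stopifnot(inherits(params, "hopf_params"))
  if (!all(is.finite(c(Re(z), Im(z), mu))))
    stop("non-finite state: integration blow-up")
  beta <- complex(real = params$b_real, imaginary = params$b_imag)
  coef <- params$mu_c + (if (fp_active) fp_value else mu)
  dz <- coef * z + 1i * params$omega * z + beta * abs(z)^2 * z + fa
  dmu <- -mu / params$tau - params$alpha / (1 + exp(-params$gamma * Re(z)))
  list(dz = dz, dmu = dmu)
}

#' Closed-form steady oscillation amplitude
#'
#' Limit-cycle amplitude \eqn{A = \sqrt{-(\mu_c + \mu)/b'}} on the oscillatory
#' side (\eqn{\mu > -\mu_c}); 0 on the quiescent side, where the stable solution
#' is the node at \eqn{z = 0}.
#'
#' @param params A [hopf_params()] object.
#' @param mu Control parameter value(s).
#' @return Amplitude(s), >= 0.
#' @export
steady_amplitude <- function(params, mu) {
  stopifnot(inherits(params, "hopf_params"))
  d <- params$mu_c + mu
  A <- numeric(length(d))
  on <- d > 0
  A[on] <- sqrt(-d[on] / params$b_real)
  A
}

#' Closed-form steady oscillation frequency
#'
#' Angular frequency of the limit cycle at amplitude `A`:
#' \eqn{\dot\phi = \omega + b'' A^2}.  For an isochronous oscillator
#' (\eqn{b'' = 0}) this is \eqn{\omega} at every amplitude.
#'
#' @param params A [hopf_params()] object.
#' @param A Oscillation amplitude(s) (>= 0).
#' @return Angular frequency(ies).
#' @export
steady_frequency <- function(params, A) {
  stopifnot(inherits(params, "hopf_params"), all(A >= 0))
  params$omega + params$b_imag * A^2
}

#' Resonant response amplitude at the bifurcation point
#'
#' One-third power law for a pure tone at the characteristic frequency applied
#' exactly at the bifurcation (\eqn{\mu_c + \mu = 0}):
#' \eqn{A = (-b')^{-1/3} F^{1/3}}.  Exact for the isochronous oscillator; for
#' \eqn{b'' \neq 0} the exponent is unchanged and the prefactor generalises to
#' \eqn{(b'^2 + b''^2)^{-1/6}}.
#'
#' @param params A [hopf_params()] object.
#' @param F Forcing amplitude(s) (>= 0).
#' @return Response amplitude(s).
#' @export
resonant_response_at_bifurcation <- function(params, F) {
  stopifnot(inherits(params, "hopf_params"), all(F >= 0))
  (-params$b_real)^(-1 / 3) * F^(1 / 3)
}

#' Steady amplitude and frequency under constant parametric forcing
#'
#' While parametric forcing at level \eqn{\mu_p} is active the effective
#' displacement from the bifurcation is \eqn{\mu_p}, so the limit cycle has
#' amplitude \eqn{\langle A\rangle = \sqrt{-\mu_p/b'}} and angular frequency
#' \eqn{\langle\dot\phi\rangle = \omega - (b''/b')\,\mu_p}.  For
#' \eqn{\mu_p \le 0} the amplitude branch is 0 and the frequency is \eqn{\omega}.
#'
#' @param params A [hopf_params()] object.
#' @param mu_p Parametric forcing level(s).
#' @return A list with `amplitude` and `frequency`.
#' @export
parametric_steady_predictions <- function(params, mu_p) {
  stopifnot(inherits(params, "hopf_params"))
  A <- numeric(length(mu_p))
  on <- mu_p > 0
  A[on] <- sqrt(-mu_p[on] / params$b_real)
  list(amplitude = A, frequency = steady_frequency(params, A))
}

#' Transduction-channel open probability
#'
#' Logistic gating curve \eqn{P_o(x) = 1/(1 + e^{-\gamma x})}.
#'
#' @param gamma Gating sensitivity.
#' @param x Bundle displacement(s).
#' @return Probability(ies) in (0, 1).
#' @export
open_probability <- function(gamma, x) 1 / (1 + exp(-gamma * x))

#' Self-tuning equilibrium at clamped displacement
#'
#' Fixed point of the control-parameter equation with the bundle held at
#' `x_held`: \eqn{\mu^* = -\tau\alpha\, P_o(\gamma, x_\mathrm{held})}.  At the
#' resting position (`x_held = 0`) this is the unforced steady state
#' \eqn{-\alpha\tau/2}.
#'
#' @param params A [hopf_params()] object.
#' @param x_held Clamped bundle displacement(s).
#' @return Equilibrium control-parameter value(s).
#' @export
selftuning_fixed_point <- function(params, x_held) {
  stopifnot(inherits(params, "hopf_params"))
  -params$tau * params$alpha * open_probability(params$gamma, x_held)
}
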