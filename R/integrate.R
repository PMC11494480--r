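#' Integration configuration
#'
#' Solver settings and initial state for [hopf_simulate()].  Defaults: a small
#' symmetry-breaking seed `z0 = 0.01` (the origin is an exact fixed point of the
#' deterministic model, so spontaneous oscillation needs a nonzero seed standing
#' in for the noise of the real system), initial control parameter at the
#' unforced self-tuned steady state \eqn{-\alpha\tau/2}, adaptive solver
#' tolerances `rtol = 1e-8`, `atol = 1e-10`, and an output sampling interval of
#' 1/50 of the natural period.
#'
#' @param z0 Initial complex bundle state.
#' @param mu0 Initial control parameter; `NULL` means \eqn{-\alpha\tau/2} of the
#'   model parameters in use.
#' @param rtol,atol Relative and absolute solver error tolerances (> 0).
#' @param dt_out Output sampling interval (> 0); `NULL` means period/50.
#' @param hold_mu Logical; if `TRUE` the control parameter is frozen at `mu0`
#'   (used to study the bundle equation at a fixed operating point, e.g. pinned
#'   exactly at the bifurcation).
#' @param max_step Maximum internal solver step (`Inf` = solver's choice).
#' @param method deSolve integration method (default `"lsoda"`).
#' @return An object of class `hopf_config`.
#' @export
integration_config <- function(z0 = 0.01 + 0i, mu0 = NULL,
                               rtol = 1e-8, atol = 1e-10, dt_out = NULL,
                               hold_mu = FALSE, max_step = Inf,
                               method = "lsoda") {
  stopifnot(rtol > 0, atol > 0, is.null(dt_out) || dt_out > 0)
  structure(list(z0 = as.complex(z0), mu0 = mu0, rtol = rtol, atol = atol,
                 dt_out = dt_out, hold_mu = isTRUE(hold_mu),
                 max_step = max_step, method = method),
            class = "hopf_config")
}

#' Breakpoints of a piecewise-constant forcing structure
#'
#' Returns the sorted unique times at which the forcing structure changes:
#' the span endpoints plus every protocol window edge falling inside the span.
#' Within each adjacent pair the forcing has a fixed functional form (constant
#' complex force or smooth rotating force; fixed parametric value and activity),
#' so an adaptive solver never steps across a discontinuity.
#'
#' @param additive A [additive_forcing()] object.
#' @param parametric A [parametric_forcing()] object.
#' @param t_span Numeric length-2, `t_span[1] < t_span[2]`.
#' @return Numeric vector of breakpoints (includes both span endpoints).
#' @export
segment_timeline <- function(additive, parametric, t_span) {
  stopifnot(inherits(additive, "hopf_additive"),
            inherits(parametric, "hopf_parametric"),
            length(t_span) == 2L)
  if (!(t_span[1] < t_span[2])) stop("empty time span")
  edges <- c(additive$t_start, additive$t_stop,
             parametric$t_start, parametric$t_stop)
  edges <- edges[!vapply(edges, is.null, logical(1))]
  edges <- unlist(edges)
  edges <- edges[edges > t_span[1] & edges < t_span[2]]
  sort(unique(c(t_span, edges)))
}

# parms vector for the compiled RHS over one segment; `tm` is any interior
# time of the segment (window membership is decided at the midpoint, which is
# robust to the half-open boundary convention).
.segment_parms <- function(params, config, additive, parametric, tm) {
  fa_type <- 0; fa_re <- 0; fa_im <- 0; F_amp <- 0; wp <- 0
  if (additive$variant == "boxcar") {
    inside <- is.null(additive$t_start) ||
      (tm >= additive$t_start && tm < additive$t_stop)
    if (inside) fa_re <- additive$F
  } else if (additive$variant == "sinusoid") {
    inside <- is.null(additive$t_start) ||
      (tm >= additive$t_start && tm < additive$t_stop)
    if (inside) { fa_type <- 1; F_amp <- additive$F; wp <- additive$omega_prime }
  }
  fp <- eval_parametric_forcing(parametric, tm)
  c(params$mu_c, params$omega, params$b_real, params$b_imag,
    params$tau, params$gamma, params$alpha,
    fa_type, fa_re, fa_im, F_amp, wp,
    fp$value, as.numeric(fp$active), as.numeric(config$hold_mu))
}

# R-language RHS mirroring src/hopfbundle.c (used when use_compiled = FALSE,
# and as an independent cross-check of the compiled code in the tests).
.rhs_r <- function(t, y, parms) {
  fa <- if (parms[8] > 0.5) {
    complex(real = parms[11] * cos(parms[12] * t),
            imaginary = parms[11] * sin(parms[12] * t))
  } else complex(real = parms[9], imaginary = parms[10])
  co <- parms[1] + (if (parms[14] > 0.5) parms[13] else y[3])
  r2 <- y[1]^2 + y[2]^2
  dx <- co * y[1] - parms[2] * y[2] + r2 * (parms[3] * y[1] - parms[4] * y[2]) + Re(fa)
  dy <- co * y[2] + parms[2] * y[1] + r2 * (parms[4] * y[1] + parms[3] * y[2]) + Im(fa)
  dmu <- if (parms[15] > 0.5) 0 else
    -y[3] / parms[5] - parms[7] / (1 + exp(-parms[6] * y[1]))
  list(c(dx, dy, dmu))
}

#' Simulate the feedback-controlled Hopf oscillator
#'
#' Integrates the coupled system (bundle equation plus self-tuning law) over
#' `t_span`, segment by segment between forcing discontinuities, carrying the
#' final state of each segment as the initial state of the next.  Output is
#' sampled on the uniform grid `seq(t_span[1], t_span[2], by = dt_out)`.
#' The run is deterministic: identical inputs give identical traces.
#'
#' @param params A [hopf_params()] object.
#' @param additive A [additive_forcing()] object (default none).
#' @param parametric A [parametric_forcing()] object (default none).  Its
#'   `mu_c` must agree with `params$mu_c`.
#' @param t_span Numeric length-2 time span.
#' @param config An [integration_config()] object.
#' @param use_compiled Integrate with the compiled right-hand side (default) or
#'   the equivalent R-language one.
#' @return A `hopf_trace`: a data frame with columns `t`, `x`, `y`, `mu` and
#'   attributes `params`, `additive`, `parametric`, `config` (provenance).
#' @examples
#' \donttest{
#' tr <- hopf_simulate(hopf_params(), t_span = c(0, 60))
#' summary(tr)
#' }
#' @export
hopf_simulate <- function(params = hopf_params(),
                          additive = additive_forcing("none"),
                          parametric = parametric_forcing("none"),
                          t_span = c(0, 100),
                          config = integration_config(),
                          use_compiled = TRUE) {
  stopifnot(inherits(params, "hopf_params"), inherits(config, "hopf_config"))
  if (parametric$variant != "none" && parametric$mu_c != params$mu_c)
    stop("parametric protocol was built for mu_c = ", parametric$mu_c,
         " but the model has mu_c = ", params$mu_c)
  dt_out <- config$dt_out %||% (2 * pi / params$omega) / 50
  mu0 <- config$mu0 %||% (-params$alpha * params$tau / 2)
  breaks <- segment_timeline(additive, parametric, t_span)
  grid <- seq(t_span[1], t_span[2], by = dt_out)

  state <- c(x = Re(config$z0), y = Im(config$z0), mu = mu0)
  out_t <- numeric(0); out_m <- NULL
  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1L]
    gseg <- grid[grid > a & grid <= b]
    times <- c(a, gseg)
    if (length(times) == 1L || times[length(times)] < b)
      times <- c(times, b)
    parms <- .segment_parms(params, config, additive, parametric, (a + b) / 2)
    sol <- if (use_compiled) {
      deSolve::ode(y = state, times = times, func = "hopf_derivs",
                   parms = parms, dllname = "hopfbundle",
                   initfunc = "hopf_init",
                   method = config$method, rtol = config$rtol,
                   atol = config$atol, hmax = config$max_step)
    } else {
      deSolve::ode(y = state, times = times, func = .rhs_r, parms = parms,
                   method = config$method, rtol = config$rtol,
                   atol = config$atol, hmax = config$max_step)
    }
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), ])))
      stop(sprintf("integration failed in segment [%g, %g] near t = %g",
                   a, b, sol[nrow(sol), 1]))
    state <- sol[nrow(sol), c("x", "y", "mu")]
    keep <- sol[, 1] %in% gseg
    if (k == 1L && grid[1] == a) {
      out_t <- c(out_t, a)
      out_m <- rbind(out_m, sol[1, c("x", "y", "mu"), drop = FALSE])
    }
    out_t <- c(out_t, sol[keep, 1])
    out_m <- rbind(out_m, sol[keep, c("x", "y", "mu"), drop = FALSE])
  }
  tr <- data.frame(t = out_t, x = out_m[, "x"], y = out_m[, "y"],
                   mu = out_m[, "mu"])
  rownames(tr) <- NULL
  structure(tr, params = params, additive = additive, parametric = parametric,
            config = config, dt_out = dt_out,
            class = c("hopf_trace", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum discrepancy between two traces of the same protocol
#'
#' Convergence diagnostic: compares two runs of the same protocol (e.g. default
#' versus halved solver tolerances) on their common time grid and returns the
#' largest discrepancy in `|z|` difference and in `mu`.
#'
#' @param trace_coarse,trace_fine `hopf_trace` objects from the same protocol.
#' @return Named numeric: `z` (max modulus of the complex state difference) and
#'   `mu` (max absolute control-parameter difference).
#' @export
refine_check <- function(trace_coarse, trace_fine) {
  stopifnot(inherits(trace_coarse, "hopf_trace"),
            inherits(trace_fine, "hopf_trace"))
  pa <- attr(trace_coarse, "additive"); pb <- attr(trace_fine, "additive")
  qa <- attr(trace_coarse, "parametric"); qb <- attr(trace_fine, "parametric")
  if (!identical(unclass(pa), unclass(pb)) ||
      !identical(unclass(qa), unclass(qb)))
    stop("traces come from different forcing protocols")
  common <- intersect(trace_coarse$t, trace_fine$t)
  if (length(common) == 0L) stop("traces share no common time samples")
  ic <- match(common, trace_coarse$t); jf <- match(common, trace_fine$t)
  dz <- sqrt((trace_coarse$x[ic] - trace_fine$x[jf])^2 +
               (trace_coarse$y[ic] - trace_fine$y[jf])^2)
  c(z = max(dz), mu = max(abs(trace_coarse$mu[ic] - trace_fine$mu[jf])))
}

#' @export
print.hopf_trace <- function(x, ...) {
  cat(sprintf("Hopf bundle trace: %d samples on [%g, %g] (dt_out = %g)\n",
              nrow(x), x$t[1], x$t[nrow(x)], attr(x, "dt_out")))
  ad <- attr(x, "additive"); pp <- attr(x, "parametric")
  cat(sprintf("  additive forcing:   %s\n", ad$variant))
  cat(sprintf("  parametric forcing: %s\n", pp$variant))
  cat(sprintf("  final state: x = %.4g, y = %.4g, mu = %.4g\n",
              x$x[nrow(x)], x$y[nrow(x)], x$mu[nrow(x)]))
  invisible(x)
}

#' @export
summary.hopf_trace <- function(object, n_cycles = 50, ...) {
  A <- sqrt(object$x^2 + object$y^2)
  res <- list(n = nrow(object), t_range = range(object$t),
              A_final = A[length(A)], mu_final = object$mu[nrow(object)],
              mu_mean_tail = mean(object$mu[object$t >=
                stats::quantile(object$t, 0.6)]))
  st <- try(steady_cycle_stats(object, n_cycles), silent = TRUE)
  if (!inherits(st, "try-error")) res <- c(res, st)
  class(res) <- "summary.hopf_trace"
  res
}

#' @export
print.summary.hopf_trace <- function(x, ...) {
  cat(sprintf("Trace on [%g, %g], %d samples\n", x$t_range[1], x$t_range[2], x$n))
  cat(sprintf("  final |z| = %.5g, final mu = %.5g (tail mean mu = %.5g)\n",
              x$A_final, x$mu_final, x$mu_mean_tail))
  if (!is.null(x$amplitude))
    cat(sprintf("  steady-cycle stats: <A> = %.5g, <phi-dot> = %.5g rad/time\n",
                x$amplitude, x$frequency))
  invisible(x)
}

#' Plot a simulated trace
#'
#' Bundle position and control parameter against time.
#'
#' @param x A `hopf_trace`.
#' @param which `"x"`, `"mu"`, or `"both"` (default).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hopf_trace <- function(x, which = c("both", "x", "mu"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "x"))
    graphics::plot(x$t, x$x, type = "l", xlab = "time", ylab = "position x", ...)
  if (which %in% c("both", "mu")) {
    graphics::plot(x$t, x$mu, type = "l", xlab = "time",
                   ylab = expression(mu), ...)
    graphics::abline(h = -attr(x, "params")$mu_c, lty = 2, col = "red")
  }
  invisible(x)
}
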