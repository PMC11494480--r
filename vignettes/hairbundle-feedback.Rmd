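---
title: "Feedback-controlled criticality in hair-bundle mechanics: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-controlled criticality in hair-bundle mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopfbundle)
```

## The model

The hair bundle is represented by the Stuart--Landau equation, the normal
form of a supercritical Hopf bifurcation, for the complex state
$z(t) = x(t) + i\,y(t)$ with $x$ the bundle position:

$$\frac{dz}{dt} = \bigl(\mu_c + \mu\,\mathbf{1}_{F_p=0} + F_p\bigr)\,z
  + i\omega z + \beta |z|^2 z + F_a(t), \qquad \beta = b' + i b'' .$$

For $\mu < -\mu_c$ the origin is a stable node (quiescence); for
$\mu > -\mu_c$ it loses stability and a limit cycle of amplitude
$A = \sqrt{-(\mu_c+\mu)/b'}$ and angular frequency
$\dot\phi = \omega + b'' A^2$ emerges. Two feedback pathways act on the
control parameter:

* **Intrinsic self-tuning.** Calcium influx through transduction channels,
  with logistic open probability $P_o(x) = (1+e^{-\gamma x})^{-1}$, feeds
  back on the control parameter,
  $$\frac{d\mu}{dt} = -\frac{\mu}{\tau} - \frac{\alpha}{1+e^{-\gamma x}},$$
  which at the resting position has the fixed point $-\alpha\tau/2$. The
  bundle is *self-tuned critical* when this sits close to, but above, the
  bifurcation: $\mu_c < \alpha\tau < 2\mu_c$. The defaults
  ($\mu_c = 20, \alpha\tau = 30$) satisfy this.
* **Efferent input as parametric forcing.** While active, the forcing
  $F_p = \mu_p - \mu_c$ *replaces* $\mu$ in the bundle equation (the
  indicator above), pinning the effective displacement from the bifurcation
  at $\mu_p$; the $\mu$ equation keeps integrating untouched, so intrinsic
  and efferent feedback are independent.

All quantities are dimensionless; $\omega = 2\pi$ makes the natural period
the unit of time. Defaults ($\mu_c = 20$, $\beta = -1 - i/2$, $\tau = 10$,
$\gamma = 10$, $\alpha = 3$) are the reference parameter set used by every
driver unless overridden.

## Parameters that matter

| parameter | default | meaning and sensitivity |
|---|---|---|
| $\mu_c$ | 20 | bifurcation point; sets the depth of the quiescent side |
| $\omega$ | $2\pi$ | characteristic angular frequency (period 1) |
| $b'$ | $-1$ | saturation of the limit cycle; must be $<0$ (supercritical) |
| $b''$ | $-1/2$ | amplitude--frequency coupling; $b''=0$ is isochronous |
| $\tau$ | 10 | self-tuning relaxation time; slow compared with the period |
| $\gamma$ | 10 | gating sharpness; $\gamma A \gg 1$ makes $P_o$ switch-like |
| $\alpha$ | 3 | influx strength; $\alpha\tau$ must lie in $(\mu_c, 2\mu_c)$ for self-tuned oscillation that strong stimuli can silence |

The admissibility window for $\alpha\tau$ deserves emphasis. The unforced
steady state is $\langle\mu\rangle \approx -\alpha\tau/2$; sustained strong
forcing saturates $P_o \to 1$ and drags $\mu \to -\alpha\tau$. Quiescence
can be induced only if $-\alpha\tau < -\mu_c$, and spontaneous oscillation
can recover only if $-\alpha\tau/2 > -\mu_c$ — together,
$\mu_c < \alpha\tau < 2\mu_c$. With $\alpha = 3$ a relaxation time of
$\tau = 35$ gives $\alpha\tau = 105 > 2\mu_c$: the self-tuned fixed point is
then itself quiescent and oscillations never return after overstimulation.
The recovery-versus-duration study (`run_recovery_study()`) therefore shows
monotonically growing recovery times only for parameter sets inside the
window (the test suite uses $\alpha = 1$, $\tau = 35$); at $\alpha = 3$,
$\tau = 35$ it faithfully reports permanent quiescence instead.

## The self-tuned attractor is *approximately* critical

The relation $\langle\mu\rangle = -\tau\alpha\langle P_o\rangle$ holds
exactly in steady state. For a perfectly circular orbit
$\langle P_o\rangle = 1/2$; in the coupled system the $\mu$-ripple
(std. dev. $\approx 0.35$ at defaults) distorts the waveform slightly, giving
$\langle P_o\rangle \approx 0.508$ and hence
$\langle\mu\rangle \approx -15.21$ rather than $-15$, with mean amplitude
$2.187$ and mean angular frequency $3.888$ — about $2\%$ and $3\%$ away from
the closed forms $\sqrt5$ and $2\pi - 2.5$ evaluated at $\mu = -15$. These
are properties of the deterministic attractor, not numerical error: halving
the solver tolerances changes them by $<10^{-4}$ relative, and an
independent integrator reproduces them to five digits. Analyses that need
the closed forms exactly (the one-third law, the cycle-statistics
cross-checks) therefore hold $\mu$ fixed (`hold_mu = TRUE`) or use constant
parametric forcing, both of which pin the linear coefficient exactly.

## Numerical integration

The coupled real system $(x, y, \mu)$ is integrated with `deSolve::lsoda`
(compiled right-hand side; `rtol = 1e-8`, `atol = 1e-10`). The timeline is
pre-segmented at every protocol discontinuity, so the solver never steps
across a jump; forcing windows are half-open $[t_{\rm start}, t_{\rm stop})$
so the Heaviside differences are single-valued. Output is sampled on a
uniform grid (default period/50). Runs are deterministic and
bit-reproducible on a given platform.

Initial conditions default to $z_0 = 0.01$, a small symmetry-breaking seed:
$z = 0$ is an exact fixed point of the deterministic model, and the seed
stands in for the noise that re-ignites oscillation in real bundles. The
control parameter starts at its unforced steady state $-\alpha\tau/2$ to
avoid long tuning transients. A caveat inherited from determinism: during
deep quiescence $|z|$ decays exponentially without bound, and once it falls
to the solver's absolute tolerance the subsequent regrowth time is set by
that numerical floor rather than by the model. The recovery-time tests
therefore use forcing durations whose quiescent dip stays many orders of
magnitude above `atol`; conclusions about *recovery-time ordering* at very
long durations would require an explicit noise floor, which the model (being
deterministic) deliberately omits.

## Trace statistics

* **Amplitude/phase**: $A = |z|$, $\phi$ the unwrapped argument of $z$,
  $\dot\phi$ by central differences; samples with $A = 0$ carry undefined
  phase and are excluded from frequency statistics.
* **Steady-cycle statistics** average $A$ and $\dot\phi$ over exactly the
  trailing $n$ cycles (phase-crossing boundaries, default 50 cycles).
* **Vector strength** $V = |\langle e^{i(\phi - \omega' t)}\rangle|$ and the
  **phase-locked amplitude** (Fourier coefficient of $z$ at $\omega'$,
  normalised so a pure tone returns its amplitude) are computed over the
  trailing 60% of the trace trimmed to an integer number of forcing periods,
  suppressing transients and spectral leakage.
* **Bartlett PSD**: average periodogram over non-overlapping rectangular
  segments (default 8); density per unit angular frequency, so
  $\sum P\,\Delta\omega$ equals the signal's mean square (Parseval, tested
  to $10^{-9}$).
* **Half-width**: linear interpolation of the two half-maximum crossings
  around a unique interior maximum; errors instruct a wider sweep if a
  crossing is missing.
* **Recovery time**: first upward crossing of $A$ through a threshold
  (default one half of the reference amplitude, itself defaulting to the
  closed-form steady amplitude at $-\alpha\tau/2$) after the post-stimulus
  dip; 0 if the bundle never went quiescent, `NA` (flagged) if it never
  recovered. The time at which $\mu$ re-crosses $-\mu_c$ is reported
  alongside as a diagnostic.
* **Fits**: unweighted least squares in three forms — log--log slope,
  offset-plus-power $y = c + x^d$ (Levenberg--Marquardt), and
  $y = a + b\log_{10}x$.

## Study defaults and how they were fixed

Problem sizes follow one rule, adopted once: *a default horizon or record is
long enough when doubling it changes the reported statistic by less than
1%.*

* **Resonance scaling** (one-third law): $\mu$ held at $-\mu_c$, resonant
  forcing, $F \in 10^{[-3,0]}$ (8 points); horizons grow as $F^{-2/3}$
  because the relaxation rate at the bifurcation is $\propto A^2$. Defaults
  to the isochronous oscillator $\beta = -1$, for which
  $A = (-b')^{-1/3}F^{1/3}$ is exact at resonance; with $b'' \neq 0$ the
  exponent survives but the resonant prefactor generalises to
  $(b'^2+b''^2)^{-1/6}$, which is why the isochronous case is the clean
  statement of the law.
* **Amplitude tuning widths**: frequency sweeps centred on $\omega$ with
  half-span $4F^{2/3}$ (41 points), so the feature is equally resolved at
  every amplitude.
* **Vector-strength widths** (F = 1.5, constant parametric forcing):
  sweep over $[0.05, 2.5]\,\omega$ (50 points), horizon 300. Widths are
  reported on the normalised axis $\omega'/\omega$, the scale on which the
  offset-plus-power relation is dimensionally coherent. At the weakest level
  $\mu_p = 5/32$ the tongue of the barely-oscillating bundle under this
  strong forcing extends down to zero frequency: the half-width does not
  exist on any positive sweep, and the level is flagged and excluded from
  the fit rather than extrapolated.
* **Power-ratio scan**: both conditions (self-tuned versus constant
  $\mu_p = 5/2$) forced at resonance over $F \in 10^{[-2,1]}$ (12 points);
  Bartlett records of 8 × 6400 time units after a 50-period burn-in — the
  smallest power-of-two segment length satisfying the 1% doubling rule. The
  ratio-of-logarithms statistic is *not* scale-free: its absolute level (and
  hence the fitted intercept and slope) depends on the spectral
  normalisation and record length, which is why the convergence rule, not
  taste, fixes the record.
* **Parametric modulation**: window $[100, 180]$ inside a 220-unit run,
  50-cycle averages on both sides of the window edges.
* **Efferent rescue**: boxcar $F_a = 50$ on $[20, 50]$, parametric level
  $\mu_p = 5$, applied never / during / after the stimulus.

## What the simulations emulate — and what they do not

The drivers generate every input from the model itself; nothing is fitted to
data. They emulate ex-vivo protocols — step deflections, pure-tone forcing,
efferent-nerve activation — under a deterministic, noise-free caricature.
Real bundle traces carry substantial stochastic forcing: spontaneous
oscillations there are noisy limit cycles, vector strengths never reach 1,
quiescent bundles still flicker, and recovery is noise-seeded rather than
seeded by a residual deterministic amplitude. Passing tests therefore
certify the deterministic skeleton (bifurcation structure, scaling laws,
feedback logic), not quantitative agreement with any recorded cell. The
complex rotating force $Fe^{i\omega' t}$ is used verbatim rather than its
real part; physical stimulation corresponds to the real projection, and the
rotating form keeps the forced response single-frequency.

## Known limitations

* No stochastic terms; see the recovery-time caveat above.
* The control parameter is not clamped during extreme forcing; it can
  transiently sit far below $-\mu_c$ (values near $-\alpha\tau$).
* The `1[Fp=0]` indicator makes the bundle equation discontinuous in
  *protocol space*; activity is defined by window membership, so a
  protocol with $\mu_p = \mu_c$ (identically zero active forcing) is
  rejected at construction instead of being silently ambiguous.
* Single-channel (position-only) traces support amplitude-envelope and
  spectral statistics only; no analytic-signal reconstruction is attempted.
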