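---
title: "Modelling coupled circadian redox oscillators: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coupled circadian redox oscillators: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Mitochondrial redox rhythms — circadian oscillations of hydrogen peroxide
controlled by the peroxiredoxin-3/sulfiredoxin system — are represented here
at the most phenomenological level that still captures their rhythmic
properties: a planar Poincaré (amplitude-phase) oscillator with *twist*,
subject to Gaussian white noise. In Cartesian coordinates, with
$r_i = \sqrt{x_i^2 + y_i^2}$,

$$
\begin{aligned}
dx_i &= \lambda x_i (A - r_i)\,dt
  - y_i\!\left[\tfrac{2\pi}{\tau_i} + \epsilon (A - r_i)\right] dt
  + K_c M\,dt + \sigma_x\,dW_1,\\
dy_i &= \lambda y_i (A - r_i)\,dt
  + x_i\!\left[\tfrac{2\pi}{\tau_i} + \epsilon (A - r_i)\right] dt
  + K_\mathrm{TTFL}\!\left(\tfrac{CB}{\overline{CB}} - 1\right) dt
  + \sigma_y\,dW_2 .
\end{aligned}
$$

The $x_i$ variable plays the role of cytosolic H$_2$O$_2$ released by
mitochondrion $i$. The parameters, with defaults and units:

| parameter | meaning | default | unit |
|---|---|---|---|
| $A$ | limit-cycle amplitude | 1 | signal |
| $\lambda$ | amplitude relaxation rate ("rigidity") | 0.05 | h$^{-1}$ |
| $\epsilon$ | twist: amplitude dependence of frequency | 0.05 | h$^{-1}$ |
| $\tau_i$ | intrinsic period, drawn per oscillator | $\mathcal N(24.23, 1.5^2)$ | h |
| $\sigma_x, \sigma_y$ | noise intensity in the velocity field | 0.05 | signal·h$^{-1/2}$ |
| $K_c$ | mean-field coupling strength | 0 | h$^{-1}$ |
| $K_\mathrm{TTFL}$ | TTFL forcing strength | 0 | h$^{-1}$ |

Twist couples amplitude to frequency: when the radius exceeds $A$ the
instantaneous frequency drops (positive twist, $\epsilon > 0$), so any
amplitude expansion — by noise, coupling resonance or forcing — lengthens
the period. This single term explains the headline phenomenology: coupled
ensembles of "plastic" oscillators (small $\lambda$) inflate their
amplitudes and slow down, while "rigid" ensembles ($\lambda \sim 1$)
keep both amplitude and pace.

Because cytosolic H$_2$O$_2$ diffuses fast relative to the circadian cycle,
inter-mitochondrial coupling is taken as all-to-all through the mean field
$M = N^{-1}\sum_i x_i$, entering the $x$ equations only. Forcing by the
canonical transcription–translation feedback loop (TTFL) enters the $y$
equations only, exactly as the model equations are printed; we implement
the coordinate placement as given and do not second-guess it.

The TTFL itself is the three-variable Goodwin-like negative feedback loop
(`simulate_goodwin()`): CLOCK:BMAL1 ($CB$) activates cytoplasmic PER:CRY
($PC_c$), which translocates to the nucleus ($PC_n$) and represses $CB$
with Hill coefficient 4 and Michaelis-type degradation. With the default
rate constants ($v_1 = v_3 = v_5 = 0.7$, $v_2 = v_4 = v_6 = 0.35$, all
thresholds 1) the limit cycle has a $\sim$23.6 h period and a
cycle-averaged $CB$ of $\sim$0.123. The forcing signal is
$CB/\overline{CB} - 1$, where $\overline{CB}$ is *computed* over an
integer number of detected cycles after the transient rather than
hard-coded, so that the drive always oscillates around zero even when a
user changes the Goodwin parameters; a warning fires when the computed
mean departs from the reference 0.123 by more than 5%.

## Numerical scheme

Stochastic trajectories use the Euler–Maruyama method:
$s \leftarrow s + f(s)\,dt + \sigma\sqrt{dt}\,\xi$ with independent
standard-normal $\xi$ per coordinate and step. The headline runs integrate
100 days at $dt = 0.01$ h, storing every 10th step (0.1 h resolution); the
first 20 days are discarded as transient. The ensemble loop is compiled
(Rcpp) and draws its noise from R's RNG in a fixed order — all $x$
increments, then all $y$ increments, one realization per seed — so the
compiled path and the generic R-level `integrate_sde()` agree to numerical
precision under the same seed, and every realization is reproducible from
its seed alone. We deliberately use one RNG stream per realization rather
than per-oscillator substreams: R's generator has no cheap substream API,
and a single documented draw order keeps the two implementations mutually
checkable.

A first-order scheme leaves first-order artefacts. The relevant one here is
the explicit-Euler rotation step, which inflates the radius by
$\mathcal O(\omega^2 dt)$ per unit time and balances the radial relaxation
at $r - A \approx \omega^2 dt / (2\lambda)$ (about 0.007 at the defaults).
This is invisible in the stochastic ensembles (noise dominates) but matters
for two analyses, which therefore use the adaptive deterministic solver
(`deSolve::lsoda`, relative tolerance $10^{-8}$, also the Goodwin solver):
noiseless oracle checks of the radial dynamics, and the
relaxation-rate estimation protocol below.

Deterministic ODE reference solutions and Euler–Maruyama with
$\sigma = 0$ are cross-checked in the tests (first-order convergence, and
the closed-form logistic solution of the radial equation
$\dot r = \lambda r (A - r)$).

## Rhythm analysis conventions

* **Phase and amplitude.** $\phi_i = \mathrm{atan2}(y_i, x_i)$ wrapped to
  $(-\pi, \pi]$, $r_i = \sqrt{x_i^2 + y_i^2}$. Phases are unwrapped only
  for dispersion/diffusion analyses; circular statistics always use
  wrapped phases. Origin points have undefined phase and are excluded from
  circular statistics with a logged count.
* **Zero-crossing periods.** Mean interval between successive downward
  zero crossings of the mean-removed signal, with crossings located by
  linear interpolation. On noisy series, jitter around zero creates
  spurious crossing pairs that bias the naive estimator low (by more than
  an hour at the default noise level), so crossings pass through a
  symmetric hysteresis band (Schmitt trigger): a crossing counts only on a
  descent from above $+0.3\,\mathrm{sd}$ of the series to below
  $-0.3\,\mathrm{sd}$, and the detector re-arms above the upper edge. Any
  constant within-cycle offset of the accepted crossing cancels in the
  intervals; the ensemble period statistics are flat over band widths of
  0.3–0.8 sd, and the band has no effect on noiseless signals.
* **Periodogram periods.** FFT periodogram of the mean-removed,
  transient-trimmed series, zero-padded at least 4-fold, with parabolic
  interpolation of log power around the maximal bin. Local peaks above 20%
  of the maximum are reported so that beating (coexisting ensemble and
  TTFL frequencies) is visible. A spectrum whose maximum is below 20 times
  the median power is flagged arrhythmic.
* **Synchronization.** Kuramoto order parameter
  $R_0 = |N^{-1}\sum_j e^{i\phi_j}|$. The printed defining formula omits
  the modulus; we implement the modulus of the complex mean, the standard
  order parameter, which statements like "$R_0 < 1$ despite period
  locking" require. Sweep summaries average $R_0$ over the last 8
  mean-field cycles, the same window used for the mean-field amplitude
  (half peak-to-trough per cycle, averaged over the last 8 cycles).
* **Phase dispersion.** Circular standard deviation
  $\sqrt{-2\ln \bar R}$ across the ensemble at each time, averaged across
  realizations. The power-law exponent of its growth is fitted log-log
  from $t = 12$ h until the mean dispersion first exceeds 1.5 rad,
  excluding the saturation plateau; an antipodal configuration
  ($\bar R = 0$) is reported as $+\infty$.
* **Entrainment.** An ensemble counts as entrained when the mean-field's
  dominant periodogram period is within 0.3 h of the 23.6 h forcing period
  *and* no secondary peak of at least half the maximal power lies outside
  that tolerance (which would indicate beating). The 0.3 h tolerance
  exceeds the $\approx 0.24$ h spectral resolution of an 80-day analysis
  window near 24 h.
* **Sweep summaries.** Scatter of per-realization metrics versus the swept
  parameter, smoothed by 100 Lowess fits to random 50% subsamples
  (span 0.4 of the subsample; plain local regression without robustness
  iterations, which degenerate on residual-free data and buy nothing on
  outlier-free simulated metrics), evaluated on a common grid with linear
  extrapolation beyond each subsample's range, reporting the pointwise
  mean and a 2.5–97.5% band.

## Parameter estimation

**Relaxation rate $\lambda$.** The oscillator is started on the cycle at a
uniformly random phase, its radius displaced instantaneously to
$A + \delta_0$, and the deterministic relaxation simulated with the
adaptive solver. The radial deviation $|r - A|$ is the perturbation
envelope; an exponential is fitted to it on the log scale over the window
where it decays to 1% of $|\delta_0|$, and the fitted rate is divided by
$A$ (the linearized decay rate is $\lambda A$), so the estimator remains
consistent for $A \ne 1$. The estimator carries a bias of order
$|\delta_0|/A$ — the radial equation is logistic, not exponential, at
finite perturbation size — which the tests verify to vanish as
$\delta_0 \to 0$ (5.6% at $\delta_0 = -0.3$, under 1% at $-0.05$). Runs
with no usable decay window are excluded with a warning; an all-excluded
protocol (e.g. $\delta_0 = 0$) errors.

**Twist $\epsilon$.** `estimate_twist()` regresses period on amplitude and
reports slope, correlation and p-value. A significantly positive slope
classifies positive twist; the mapping from the regression slope to a
numerical $\epsilon$ is left to the caller, because the underlying
identification (matching a kinetic model's amplitude–period correlation to
a representative $\epsilon$) is a judgement call, not a formula.

**The linearized phase-shift oracle.** While a radial perturbation
$\delta_0$ relaxes, twist accumulates extra phase
$\Delta\phi = -\epsilon \delta_0 / (\lambda A)$ to first order. This
closed form anchors the sign structure and magnitude of simulated
amplitude-to-phase conversion (simulation agrees within ~11% at
$\delta_0 = -0.2$, where second-order effects are visible).

## The simulator as synthetic-data generator

The package generates all of its own data; its defaults *are* the study
conditions: $N = 100$ oscillators, $\tau_i \sim \mathcal N(24.23, 1.5^2)$ h
(the heterogeneity scale measured in dispersed SCN neurons and U-2 OS
cells), $\sigma_x = \sigma_y = 0.05$, all oscillators starting at
$(A, 0)$ — a common on-cycle point; any other is equivalent up to
rotation. Only the period is heterogeneous across an ensemble; $A$,
$\lambda$, $\epsilon$ and $\sigma$ are shared, including inside the twist
term. Period draws at or below 1 h are redrawn — unreachable under the
default distribution, a guard for pathological user specifications.

What the generator emulates: desynchronization by intrinsic noise and
period heterogeneity, synchronization and amplitude resonance under
mean-field coupling, frequency pulling, period lengthening through twist,
and entrainment versus beating under TTFL forcing. What it does not:
radially asymmetric or relaxation-type waveforms, heterogeneity in
anything but period, stochastic TTFLs, redox-to-TTFL feedback, or any
spatial structure in the mitochondrial population. Passing tests therefore
certify the dynamics of this model class, not the biochemistry of any
particular tissue.

## Experiment sizes

The headline experiments use 100 days at $dt = 0.01$ h with a 20-day
transient and $N = 100$: the desynchronization experiment averages 50
realizations; coupling sweeps use 5 realizations per $K_c$; the
entrainment-versus-coupling sweep uses $K_c \in \{0.02, 0.04, \ldots,
0.20\}$ with 3 realizations per cell and a majority vote (the underlying
publication names only representative grid points and no realization
count, so the grids and the vote are our choices). The test suite
exercises the same code paths at reduced sizes — fewer oscillators,
realizations and days — chosen so each property remains comfortably
resolvable; e.g. the phase-diffusion exponents use 20 realizations of 50
identical oscillators over 30 days, where the rigid ensemble fits
$0.50 \pm 0.05$ and the plastic one sits clearly above the $\sqrt t$ law.

## Known limitations

* The entrainment boundary in $K_c$ sits near 0.08–0.10 on the default
  grid, at the lower edge of the expected 0.08–0.14 transition band; the
  boundary location is sensitive to the realization noise of a 3-vote
  majority and to the 0.02 grid pitch.
* The per-oscillator period SD of a single $N = 100$ ensemble inherits the
  sampling noise of the period draw itself (SE $\approx 0.11$ h), so
  individual realizations can stray outside a $\pm 0.3$ h band around the
  long-run value.
* First-order integration leaves $\mathcal O(dt)$ artefacts in noiseless
  trajectories (radius inflation $\approx 0.007$ at the defaults);
  analyses that need clean deterministic limits use the adaptive solver
  instead.
* `estimate_relaxation_rate()` is a deterministic protocol by design;
  estimating $\lambda$ or $\epsilon$ from noisy recordings is out of
  scope.
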