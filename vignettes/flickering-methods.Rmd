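---
title: "Membrane flickering spectroscopy: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane flickering spectroscopy: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(flickering)
```

## The observable and the model

A red blood cell held at its homeostatic state flickers: its equatorial
contour fluctuates by tens of nanometers around the mean discocyte radius.
The package analyses (and simulates) the displacement field
$\delta h_i(l_i, t) = R_i(t) - \bar R$ sampled at $N$ contour emplacements of
lateral size $L = 2\pi\bar R/N$, typically at 2 kHz for 5 s.

Two force classes drive the dynamics:

* **Passive thermal forces.** In the overdamped Langevin description the
  restoring force is harmonic, $f_i \approx -G_{\mathrm{eff}}(i)\,\delta h_i$,
  with contour modes $q_n = n/\bar R$ relaxing at the viscoelastic rate
  $\omega(q) = (\gamma q + \kappa q^3)/(4\eta)$ — tension ($\gamma$) at large
  scales, bending ($\kappa$) at small scales, against the membrane
  microviscosity $\eta$. The crossover
  $\omega_D \approx \gamma^{3/2}/(2\eta\kappa^{1/2})$ separates the two
  regimes.
* **Active kicking forces.** Following the Gov picture of cytoskeletal
  activity, a fraction $\phi$ of emplacements carries a dichotomous force
  $\pm f_0$ switching at rate $\omega_A$, pushing the membrane toward
  excursions of scale $\Lambda_0$. Activity raises the effective temperature,
  $T_{\mathrm{eff}}/T = 1 + \phi\,p_{on} f_0\Lambda_0/(k_B T)$, and adds a
  pink ($\sim 1/\omega$) component to the displacement spectrum in the
  window $(\omega_A, \omega_D)$ when the switching rates are distributed.

## Ring-mode normalization: the equatorial projection

The contour is a one-dimensional cut through a two-dimensional membrane, and
this matters for the spectrum. Projecting the 2D Helfrich spectrum onto the
equatorial line gives, per ring mode (one quadrature amplitude),

$$ s^2(q) \;=\; \frac{k_B T}{2\gamma q}
   \left(1 - \frac{x}{\sqrt{1 + x^2}}\right) \frac{1}{\pi \bar R},
   \qquad x = q\sqrt{\kappa/\gamma}, $$

with the limits $k_B T/(2\pi\bar R\,\gamma q)$ (tension) and
$k_B T/(4\pi\bar R\,\kappa q^3)$ (bending). Combined with the single-pole
relaxation $\omega(q)$ this is the only one-dimensional normalization that
reproduces, simultaneously,

* the pink $1/\omega$ tension spectrum below $\omega_D$,
* the Zilman–Granek $\omega^{-5/3}$ bending spectrum (point MSD
  $\propto \tau^{2/3}$) above $\omega_D$, and
* physically sensible parameters: with $\gamma = 4\times 10^{-5}$ N/m,
  $\kappa = 2\times10^{-19}$ J, $\eta = 1$ Pa·s, $\bar R = 3.6\ \mu$m and
  $T = 310.15$ K the basal amplitude is $\Sigma_0 \approx 8$ nm and
  $\omega_D \approx 300$ rad/s, the scales reported for rigidized and
  healthy erythrocytes.

A naive per-mode assignment $k_B T / (2\pi\bar R(\gamma q^2 + \kappa q^4))$
(the direct 2D form) yields $\omega^{-2}$ decay in both regimes and cannot
produce the observed exponents; we document this deliberately because the
choice is easy to get wrong and hard to notice downstream. Per-quadrature
variances are what `mode_variance()` returns, and per-mode equipartition
against exactly this quantity is enforced by the test suite (within four
standard errors of the OU variance estimator).

## The simulator

`simulate_passive_contour()` is a ring Fourier mode bank: each quadrature
amplitude is an exactly discretized Ornstein–Uhlenbeck process
($h \leftarrow h e^{-\omega(q)\Delta t} + \mathcal N(0, s^2(q)(1 -
e^{-2\omega(q)\Delta t}))$), started in its stationary law, so the series is
stationary at any $\Delta t$ and arbitrarily slow modes carry no burn-in
bias. Modes relaxing beyond the Nyquist rate appear as a white spectral
floor (the experimental instrument cutoff $\omega_C$ has the same
signature); a warning of class `flicker_aliasing` notes this.

`simulate_active_contour()` adds, at a random fraction $\phi$ of sites, a
telegraph force filtered through the local milieu friction
$\zeta_0 = 6\pi L \eta_0$ (relaxation corner
$\omega_r = f_0/(\zeta_0\Lambda_0)$). Two conventions deserve explanation:

* **Amplitude calibration.** "Excursions of scale $\Lambda_0$" and the Gov
  effective-temperature relation over-determine the process, so the active
  displacement is rescaled to a stationary added variance of exactly
  $p_{on} f_0\Lambda_0/G_0$ per active site, using the exact discrete-time
  variance of the AR(1)-filtered telegraph,
  $(1-a)^2\Lambda_0^2(1+a\rho)/((1-a^2)(1-a\rho))$ with
  $a = e^{-\omega_r\Delta t}$, $\rho = e^{-2\omega_A\Delta t}$. $G_0$ is the
  run's own passive stiffness $k_B T/\Sigma^2_{\mathrm{pass}}$ (analytic
  mode sum), or the explicit `G0` for athermal runs. With the default
  $f_0 = 2.5$ pN and $\Lambda_0 = 50$ nm ($f_0\Lambda_0 \approx 29\,k_BT$)
  and $\phi = 0.3$, the healthy ensemble amplitude comes out at
  $\Sigma \approx 25$ nm over the basal 8 nm — the observed scales.
* **Kicker friction.** The relaxation corner uses a separate milieu
  viscosity $\eta_0$ (default $10^{-3}$ Pa·s) rather than the membrane's
  effective $\eta$: the kicker pushes against the local fluid, and with the
  membrane-scale $\eta$ the corner would fall inside the kicking window and
  flatten the pink spectrum that defines it.

With `rate_mode = "log_uniform_ensemble"` (default) each kicker draws its
switching rate log-uniformly over `rate_span` (default 5–500 rad/s, the two
decades spanning $\omega_A$ to $\omega_D$); the superposition of equal-power
Lorentzians with log-uniform corners is analytically $\propto 1/\omega$
inside the band (slope $-0.975$ over the 30–250 rad/s fit window, by the
closed form). `single_rate` reproduces the single-Lorentzian alternative.
$p_{on}$ enters as a duty-cycle factor on the active power, so activity
scales with the product $\phi\,p_{on}$.

## The imaging chain

`render_contour_frames()` draws rings of Gaussian cross-section centered on
the instantaneous contour; `extract_contour()` inverts this by casting rays
from the cell center and refining the ring extremum to subpixel precision
(bicubic image sampling, cubic-spline upsampling, parabolic vertex).
Bilinear sampling was measurably insufficient here: its interpolation bias
is periodic in the subpixel position, which modulates with the moving ring
and distorts *per-site* variances even when the RMS error looks acceptable;
bicubic sampling brings the static error to ~0.03 px and per-site variance
recovery to within a few percent. Drift correction recenters each frame on
the contour barycenter (removing translation and, deliberately, the
translation-like first harmonic) and registers rotation against a running
mean reference profile. $\bar R$ is the global mean over frames and angles;
per-frame means are not subtracted, so the breathing mode is retained.

Missing rays (no detectable extremum) are tolerated up to 1% per frame and
filled by periodic interpolation; beyond that the frame is rejected.

## Spectral estimation and microrheology

`compute_psd()` is a Welch estimator (Hann window, 50% overlap, per-segment
demeaning), one-sided on an angular-frequency grid and normalized so the
spectral integral equals the series variance; Parseval holds to better than
2% whenever the segment length covers the correlation time (for slower
modes the missing near-DC power is real, not a normalization error). The
estimator also returns the ensemble mean-square displacement at log-spaced
lags, computed in the time domain by FFT autocovariance on a subsample of
(statistically equivalent) sites.

`gser_modulus()` converts fluctuations to a complex modulus with the Mason
local power-law estimator,
$$ |\tilde G(\omega)| = \frac{C_{\mathrm{cal}}\, k_B T}
   {\mathrm{MSD}(1/\omega)\,\Gamma[1+\beta(\omega)]},
   \qquad G' = |\tilde G|\cos(\pi\beta/2),\quad
   \eta_{\mathrm{eff}} = \frac{|\tilde G|\sin(\pi\beta/2)}{6\pi L\,\omega}, $$
with $\beta$ the local MSD exponent read off the (smooth) PSD log-slope,
clipped to $[0,1]$. The calibration constant $C_{\mathrm{cal}} = 2$ is fixed
once by the harmonic-trap identity (plateau MSD $= 2k_BT/G$) and never
refit; free diffusion against friction $6\pi L\eta$ then returns
$\eta_{\mathrm{eff}} = \eta$ identically. We use the *measured* time-domain
MSD rather than a quadrature of the estimated spectrum: the truncated
spectral integral is ballistic at lags below the Nyquist scale and biases
the upper frequency decade.

The fractional Maxwell models,
$$ G_{\mathrm{eff}}(\omega) = G_\gamma + G_\kappa
   \frac{(\omega\tau_D)^{2\alpha}}{1 + (\omega\tau_D)^{2\alpha}},
   \qquad
   \eta_{\mathrm{eff}}(\omega) = \eta_0 + H_0
   \frac{(\omega\tau_D)^{\alpha-1}}{1 + (\omega\tau_D)^{2\alpha}}
   + \eta_{\mathrm{kick}}, $$
are fitted in log space with a fixed multistart grid (deterministic given
the data), with bounds $0 \le \alpha \le 1$. $\alpha = 1/3$ is passive pure
bending ($G' \sim \omega^{2/3}$); active confinement pushes $\alpha$ toward
zero, and at $\alpha = 1/4$ the rising branch has exponent $1/2$. The
tension parameter is reported both as the plateau $G_\gamma$ (N/m) and as
$\gamma_{\mathrm{eff}} = G_\gamma \bar R/4$ (the Laplace-term convention);
because the plateau relates to the bare tension through the logarithmic
mode sum, round-trip tests invert the analytic $\gamma \mapsto
k_BT/\Sigma^2_{\mathrm{pass}}$ map rather than comparing plateau to tension
directly. At $\alpha = 1$, $\eta_{\mathrm{kick}} = 0$ the viscosity branch
reduces exactly to the Maxwell form $\eta_0 + G_0\omega_D/(\omega^2 +
\omega_D^2)$.

`viscoelastic_ratio_and_crossovers()` reports the pointwise ratio
$G'/(6\pi L\,\eta_{\mathrm{eff}})$, the Maxwell crossing $\omega_D$
(log-interpolated; a band edge with a flag when no crossing is in band) and
the noise-floor onset $\omega_C$ (the spectrum meeting twice the top-of-band
floor level, guarded by a local-slope flatness criterion). One subtlety is
worth stating plainly: in the Mason split the pointwise ratio equals
$\omega\cot(\pi\beta/2)$ — the modulus magnitude cancels — so *amplitude*
softening cannot lower it. The activity-induced drop of the viscoelastic
ratio is therefore assessed as the drop of the mean softness ratio
$\bar G_{\mathrm{eff}}/\eta$ at matched membrane microviscosity
($\bar G_{\mathrm{eff}} = k_BT/\Sigma^2$ falls roughly tenfold between
passive and fully active runs, with $\Delta\eta \approx 0$ by
construction), which is exactly the softening-at-constant-dissipation
statement the ratio figure expresses.

## Morphotyping

Principal radii come from exact polygon second moments (the
equivalent-ellipse semi-axes $2\sqrt{\lambda_{1,2}}$), robust to
spiculation since even-order lobes cancel. The classifier applies the
thresholds circularity $c = R_1/R_2 > 0.95$ (discocyte vs elliptocyte) and
relative contourness $\Delta = (D - 2\pi\bar R)/(2\pi\bar R) > 0.1$
(echinocyte), with precedence ghost → echinocyte → elliptocyte → discocyte:
contrast failure invalidates shape metrics, and spiculated cells can be
globally circular. $\bar R$ in $\Delta$ is each cell's own mean radius.
Population percentages exclude debris from the denominator and report it
separately.

## What the generator does and does not emulate

The synthetic data reproduce the statistical structure the analysis assumes:
stationary Gaussian passive modes with the stated dispersion, independent
telegraph kickers, ring images with Gaussian cross-section and additive
Gaussian noise, rigid drift. They do **not** emulate out-of-plane motion,
defocus or phase-contrast halo artifacts, intensity inhomogeneity,
neighbouring cells, or spatially correlated kicker clusters; passing tests
therefore validate the estimators under the model's assumptions, not the
imaging physics of a real microscope. Real-donor population values
($\Sigma = 25 \pm 4$ nm across donors, fitted $\phi$ per treatment group)
parameterize fixtures here; they are not reproducible outputs without
matched videomicroscopy recordings.

## Numerical choices and problem sizes

* Exact OU discretization and stationary initialization: no time-step bias,
  no burn-in.
* Spectral runs use $N = 512$ emplacements, $10^5$ frames at 0.5 ms
  (50 s), Welch segments of 8192 frames; slope windows are 100–2500 rad/s
  (bending) and 30–250 rad/s (kicking), chosen inside the respective
  scaling regimes by the closed-form mode sums before any simulation was
  run. Statistics runs use $N = 128$–256 with $2$–$3\times10^4$ frames.
  Imaging-chain tests render 400 frames of a 128-site contour at 20 nm/px.
* All fits are deterministic given data (fixed multistart grids); all
  simulations derive their randomness from one root seed via fixed stream
  offsets.
* Degenerate inputs fail loudly: zero restoring force, constant frames,
  contours that exit the frame, spectra spanning less than 2.5 decades,
  kicking amplitudes above $\bar R/2$.

## Known limitations

* The single-pole relaxation per projected ring mode is an approximation;
  the exact projected dynamics mixes rates across the transverse
  wavenumber. The spectral exponents are unaffected (they are reproduced to
  three decimals by the closed form), but mode-level line shapes are.
* The GSER assumes an equilibrium fluctuation–dissipation link evaluated at
  the bath temperature; applied to active runs it reports *apparent*
  softness and mobility, which is precisely the interpretive stance of the
  analysis, but absolute active moduli should be read with that caveat.
* The measured viscosity of strongly active runs is dominated by the
  kicker tail across the full band, so dissipation-side comparisons between
  active and passive runs are meaningful only at matched activity.
  Relatedly, the viscosity model's low-frequency slope is $\alpha - 1$
  (reaching the lubrication value $-1$ only as $\alpha \to 0$), so measured
  low-band viscosity slopes of passive mode-bank runs are shallower than
  $-1$.
* Contour content at the angular Nyquist mode ($n = N/2$) cannot survive
  angular resampling (drift correction, rotation registration), and its
  sine quadrature is not separately resolvable on the grid; analyses that
  resample should use spatially oversampled contours (modes well below
  $N/2$), as the imaging-chain tests do.
* The telegraph-force bandwidth is controlled by $f_0/(\zeta_0\Lambda_0)$;
  choosing a very viscous milieu moves the corner into the kicking window
  and suppresses the pink regime (this is physical, but defeats fits that
  assume the window exists).
```
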