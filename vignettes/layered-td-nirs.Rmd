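---
title: "Two-layer time-domain NIRS: models, inversion and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer time-domain NIRS: models, inversion and study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(layertof)
```

## The problem

Transabdominal monitoring of fetal tissue oxygenation must see through the
maternal abdominal wall: light injected at the surface samples a superficial
(maternal) layer before reaching the deep (fetal) tissue, and the maternal
contribution dominates the detected signal. Continuous-wave (CW) NIRS
measures only the total detected intensity and therefore struggles to
separate the two layers. Time-domain NIRS records the full distribution of
photon times of flight (DTOF): late-arriving photons have, on average,
penetrated deeper, so the arrival time axis encodes depth. `layertof`
implements the complete simulation and estimation pipeline for this
two-layer geometry: analytical forward models, a Monte Carlo oracle,
transient calibration, inverse fitting, hemoglobin unmixing to a tissue
oxygenation index (TOI), and time-gating analysis of pulsatile signals.

Units everywhere: lengths cm, absorption \(\mu_a\) and reduced scattering
\(\mu_s'\) in cm\(^{-1}\), time ns, wavelength nm, speed of light
\(c = 29.9792458\) cm/ns, \(v = c/n\).

## Forward models

### Semi-infinite closed form

For a homogeneous semi-infinite medium the package uses the standard
image-source solution of the time-dependent diffusion equation with an
extrapolated boundary: an isotropic point source at depth \(z_0 = 1/\mu_s'\)
and a negative image at \(-(z_0 + 2z_b)\), where \(z_b = 2AD\) and
\(D = 1/(3\mu_s')\). The surface fluence is

\[
\Phi(\rho, 0, t) = v\,(4\pi D v t)^{-3/2} e^{-\mu_a v t}
\left[e^{-(\rho^2+z_0^2)/(4Dvt)} - e^{-(\rho^2+(z_0+2z_b)^2)/(4Dvt)}\right],
\]

and reflectance is taken as \(R = \Phi/(2A)\), consistent with the
fluence-based layered solution below (a flux-based alternative exists in the
literature; the ratio is nearly time-independent and is absorbed by the
fitted amplitude, so the choice does not affect estimated coefficients).
The factor \(A\) is computed from the internal/ambient refractive-index
ratio by integrating the unpolarized Fresnel reflectance over the internal
hemisphere (fluence and flux moments); it is exactly 1 for matched indices
and about 2.95 for tissue (\(n = 1.4\)) against air.

### Two-layer kernel

For a finite top layer (thickness \(l\)) over a semi-infinite bottom layer
the diffusion equation is solved per layer after a spatial Hankel transform
(radial frequency \(s\)) and a temporal Fourier transform (angular
frequency \(\omega\)):

\[
\alpha_k^2 = s^2 + \frac{\mu_{a,k} + i\omega/v}{D_k}, \qquad k = 1, 2 .
\]

With the extrapolated boundary \(\phi(-z_b) = 0\), continuity of \(\phi\)
and \(D\,\partial_z \phi\) at \(z = l\), and decay at depth, the surface
Green's function is

\[
\phi(s, 0, \omega) = \frac{\sinh(\alpha_1 z_b)}{D_1 \alpha_1}\,
\frac{D_1\alpha_1\cosh(\alpha_1(l - z_0)) + D_2\alpha_2\sinh(\alpha_1(l - z_0))}
     {D_1\alpha_1\cosh(\alpha_1(l + z_b)) + D_2\alpha_2\sinh(\alpha_1(l + z_b))} .
\]

The implementation (C++ inner loop) rewrites this with only decaying
exponentials so it cannot overflow at large \(|\alpha_1|\). The inverse
Hankel transform is a fixed-order Gauss–Legendre quadrature on
\([0, s_{\max}]\) (defaults \(n = 256\) at \(\rho = 2\) cm for the
time-domain path, \(n = 512\) for CW where larger \(\rho\) means more
Bessel oscillations, \(s_{\max} = 300\) cm\(^{-1}\); the integrand decays
like \(e^{-s z_0}\)). Order doubling changes the result by less than
\(10^{-8}\) relative at these defaults; an optional `check = TRUE`
performs this doubling at run time and raises an error with diagnostics on
non-convergence. The time domain is synthesized by inverse FFT on an
internal grid whose step is the largest power-of-two fraction of the
requested bin width not exceeding 12.5 ps — bin centers then coincide with
internal samples, so the cubic-spline evaluation is exact there even on the
steep rising edge — with span \(\ge \max(2 t_{end}, 10)\) ns (padding keeps
aliasing of the decaying tail below \(10^{-6}\) of the peak for tissue-like
absorption). Values are computed at bin centers, not bin-integrated
(bin-integration differs by \(O(\Delta t^2)\) curvature terms, negligible
at \(\le 25\) ps bins). Negative transform ringing is clipped to zero; a
warning fires if the clipped mass ever exceeds \(10^{-3}\) of the total.

Two design choices deserve emphasis because the field is not unanimous:

* **Diffusion coefficient** \(D = 1/(3\mu_s')\), absorption-independent,
  matching the layered-solution literature this model follows; the
  alternative \(1/(3(\mu_a + \mu_s'))\) is available via `D_absorption`.
* **Refractive indices** default to \(n = 1.4\) for both tissue layers and
  1.0 ambient. The kernel assumes index-matched internal interfaces (equal
  \(n\) in both layers) and warns otherwise.

The CW solution is the \(\omega = 0\) limit of the same kernel, so CW
consistency with the time integral of the TD solution is structural, and is
verified to 2% in the tests (the residual is quadrature/FFT error, not
model error).

### Checks

The homogeneous limit (both layers identical) reproduces the closed form
within 1% wherever the signal exceeds \(10^{-4}\) of the peak; adding the
same \(\Delta\mu_a\) to both layers multiplies the solution by
\(e^{-v\Delta\mu_a t}\) per bin (exact for the absorption-independent
\(D\); numerically within 0.5%); increasing only the deep absorption
suppresses the late tail while leaving the rising edge essentially
unchanged — the depth-sensitivity mechanism the whole method rests on.

## Monte Carlo oracle

`run_layered_mc()` is an MCML-style layered photon transport code (pencil
beam, normal incidence): step lengths \(-\ln U/\mu_t\), implicit-capture
absorption (weight multiplied by the albedo \(\mu_s/\mu_t\) at each
interaction), Henyey–Greenstein scattering with \(g = 0.9\) by default
(\(\mu_s = \mu_s'/(1-g)\)), unpolarized Fresnel reflection/refraction at
the surface and at internal index mismatches, and Russian roulette below
weight \(10^{-4}\) with survival probability 0.1. Detection is an annulus
\([\rho - \Delta, \rho + \Delta]\) with \(\Delta = 0.05\) cm, accepting
all exit angles by default (a numerical-aperture cut is available).
Arrival time uses the optical pathlength \(\sum_i n_i L_i / c\), consistent
with \(v = c/n\) in the diffusion model. Per-photon counter-based RNG
substreams (splitmix64-seeded xoshiro256++) make results bit-reproducible
given the seed, independent of execution order.

For every detected photon the per-layer geometric pathlengths \(L_i\) are
accumulated per arrival bin. This enables Beer–Lambert perturbation
re-weighting: the DTOF at absorption \(\mu_a + \Delta\mu_a\) is predicted
from one baseline run as
\(\mathrm{DTOF}(t)\,e^{-\sum_i \Delta\mu_{a,i}\bar L_i(t)}\), where
\(\bar L_i(t)\) is the weighted mean pathlength in layer \(i\) for that
bin. This is exact up to the within-bin pathlength spread (a Jensen term of
order \(\Delta\mu_a^2 \mathrm{Var}(L)/2\), below \(10^{-3}\) relative for
the perturbations used here) and is validated against fresh transport runs
at the perturbed absorption within combined Monte Carlo error. It is what
makes minute-long pulsatile streams affordable: one transport run, then a
cheap re-weighting per frame.

## Calibration of measured transients

TCSPC electronics report arrival times relative to an arbitrary origin, and
the detection chain has an unknown efficiency. Both are estimated once per
session against a reference medium with known optical properties: a grid
search of the time shift at channel resolution (refined by parabolic
interpolation of the residual-norm profile) with the closed-form
least-squares amplitude at each shift. A constant dark level estimated from
pre-peak channels is subtracted first. The instrument response function is
treated as an ideal delta after the shift — the pipeline normalizes against
theory rather than deconvolving; an IRF convolution hook is the natural
extension point. Calibrated transients are resampled by bin-sum-preserving
rebinning, so total counts over the common support are conserved.

## Inversion

`tl_fit()` / `fit_two_layer_td()` estimate
\(\{\mu_{a1}, \mu_{s1}', \mu_{a2}, \mu_{s2}'\}\) (top thickness fixed —
in practice it comes from ultrasound or the phantom specification, and
fitting it would destroy identifiability) by Levenberg–Marquardt
(`minpack.lm`) on log-transformed parameters, which enforces positivity
without hard bounds. The default loss is weighted least squares with
per-bin Poisson variance weights \(1/\max(y, 1)\) on the counts scale
(noise-free model densities get the same *relative* weighting so the
information-bearing tail is not drowned by the peak); Poisson deviance and
log-domain least squares are available. The amplitude is profiled out in
closed form at every iteration, reducing the search to the four layer
coefficients. The fit window runs from the half-peak rising edge to the
last bin above 1% of peak: earlier bins are dominated by the instrument
response and the breakdown of the diffusion approximation, later bins by
noise.

Initialization fits a homogeneous semi-infinite model first and uses its
\((\mu_a, \mu_s')\) for both layers. From that start the noise-free fit
recovers the generating parameters to optimizer precision. The
least-squares surface does contain a shallow secondary valley in the
deep-layer scattering coefficient; from adversarial starts (50% off in the
wrong direction) a single LM run can stall there with \(\mu_{a2}\) still
within 1% but \(\mu_{s2}'\) badly determined. The deterministic
`multistart` option (the given start plus fixed multiplicative jitters,
lowest residual kept) resolves this without randomness. A covariance proxy
from a finite-difference Jacobian at the optimum is reported; its
deep-layer variance grows monotonically with top-layer thickness,
quantifying the loss of depth sensitivity.

The CW baseline (`fit_two_layer_cw`) fits log-intensities at \(\ge 4\)
distances with weights equal to the counts
(\(\mathrm{var}(\log y) \approx 1/y\)). Its amplitude is free by default,
as for an uncalibrated instrument; note that with four distances and four
layer coefficients a free amplitude makes the problem underdetermined, so
the CW-versus-TD study fixes the amplitude to the known simulated exposure
— the comparison is then four parameters against four observations for
both methods, which is the fairer reading of the accuracy claim being
tested.

## Hemoglobin unmixing and TOI

Absorption at wavelength \(\lambda\) is
\(\mu_a = \ln(10)(\epsilon_{HbO_2} c_{HbO_2} + \epsilon_{Hb} c_{Hb})\)
(decadic extinction convention, explicit \(\ln 10\)). Two wavelengths on
opposite sides of the isosbestic point (~800 nm) — 740 and 850 nm by
default — give a well-conditioned \(2\times 2\) system whose solution
yields relative concentrations and
\(\mathrm{TOI} = 100\,c_{HbO_2}/(c_{HbO_2}+c_{Hb})\). TOI is invariant to
total-hemoglobin scaling, so only relative concentrations matter and no
instrument calibration curve is needed. Negative solved concentrations
(possible under noise near the TOI extremes) are flagged and excluded from
TOI rather than clipped: clipping would bias the oxygenation estimate
silently. Water and lipid background absorption is ignored by default
(fixed offsets are supported) — appropriate for *relative* concentration
work, not for absolute chromophore quantification.

The bundled extinction table (`hb_extinction_synthetic.csv`) is a synthetic
compilation constructed to match the magnitude and shape of the standard
published NIR hemoglobin spectra, including the isosbestic crossing between
790 and 800 nm; it is versioned with the package and adequate for
simulation and TOI work, but is not a measured reference spectrum — users
with a preferred published table can load it through the same
`extinction_table(file)` interface.

## The synthetic-data generator and study conditions

All studies run on synthetic data from the package's own forward models;
the generator defaults *are* the study conditions:

* maternal layer \(\mu_a = 0.11\), \(\mu_s' = 11.19\) cm\(^{-1}\),
  thickness 9.6 mm; fetal layer \(\mu_s' = 9.551\) cm\(^{-1}\) with
  \(\mu_a\) from the five-condition TOI table (20–60%, `fetal_conditions()`);
* TD measurements at \(\rho = 2\) cm on a 0–5 ns grid with 20 ps bins,
  Poisson noise at \(10^6\) total counts (a 10 s acquisition at a typical
  TCSPC count rate); CW measurements at \(\rho = 1,2,3,4\) cm with the
  exposure anchored so the 2 cm detector also collects \(10^6\) counts;
* pulsatile study: sinusoidal absorption modulation at 1.3 Hz (maternal)
  and 2.1 Hz (fetal), amplitudes 2% of each layer's baseline absorption,
  20 Hz frame rate, 60 s duration, \(10^5\) counts per frame, late gate
  opening where the cumulative baseline DTOF reaches \(q = 0.7\);
* occlusion demonstration: piecewise-linear TOI trajectory (baseline 60%,
  ramp to 35% during a 3-minute occlusion starting after 2 minutes,
  overshoot to 70% within 20 s of release, recovery within 2 minutes),
  total hemoglobin anchored so the 850 nm fetal absorption at TOI 40%
  equals the corresponding table condition (~48 µM, a realistic tissue
  value).

What the generator emulates: two-layer diffuse transport, shot noise,
per-layer pulsatile absorption, known top thickness. What it does not:
instrument response functions and afterpulsing, motion artifacts,
physiological drift, curved anatomy, more than two layers, uncertainty in
the fetal depth. Passing tests therefore demonstrate the *method* under its
own assumptions — the simulation analog of a phantom experiment — not
clinical performance.

Problem sizes in the test suite are chosen to keep the full run at desk
scale: the Monte Carlo–diffusion equivalence uses \(10^7\) photons (about
ten minutes), the perturbation oracle re-runs transport at
\(2.5\times 10^6\) photons with the tolerance expressed in combined Monte
Carlo standard errors so the comparison stays calibrated at any photon
budget, the recovery study uses 5 seeds and the comparative studies 20
seeds; unit tests use smaller, cached transport runs.

## Numerical and degenerate-input policy

* Quadrature non-convergence (order doubling changes the result beyond
  tolerance) raises an error with diagnostics rather than returning a
  silently wrong transient.
* Kernel overflow during optimizer excursions returns a zero model, which
  the profiled-amplitude residual treats as infeasible (the step is
  rejected).
* If \(z_0 = 1/\mu_{s1}' \ge l\) (top layer thinner than one transport mean
  free path), the source depth is capped at \(0.9\,l\); the diffusion
  description is marginal there anyway.
* `mua > musp` triggers a diffusion-validity warning at construction.
* Transients must be nonnegative; counts must be integers; zero detected
  photons in a Monte Carlo run set an `empty` flag instead of erroring.
* Fits that hit the iteration cap or whose convergence code is abnormal
  are returned with `converged = FALSE`; studies record such frames as
  missing rather than imputing.

## Known limitations

* The layered kernel assumes index-matched internal interfaces; a full
  \(n_1 \ne n_2\) treatment would modify the interface conditions.
* No IRF convolution: calibrated data are assumed delta-like after time-zero
  correction.
* Single-distance TD fitting: joint multi-distance TD fitting (which would
  further constrain the superficial layer) is out of scope.
* The CW comparison fixes the amplitude to the known exposure; real CW
  instruments would need an absolute intensity calibration to reach even
  that baseline.
* TOI from two wavelengths resolves only the two hemoglobin species;
  additional chromophores (water, lipid, myoglobin) fold into the
  background term.
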