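# layertof

Two-layer time-domain near-infrared spectroscopy (TD-NIRS) modelling and
tissue oximetry in R.

## The problem

Monitoring the oxygenation of deep tissue through a superficial layer — the
motivating case is transabdominal monitoring of fetal tissue beneath the
maternal abdominal wall — requires separating the optical properties of the
two layers from surface measurements. Continuous-wave (CW) NIRS records only
total intensity and mixes the layers; time-domain NIRS records the full
distribution of photon times of flight (DTOF), and because late-arriving
photons have on average traveled deeper, the arrival-time axis encodes
depth.

`layertof` is for researchers in diffuse optics who want to simulate,
calibrate and invert such measurements. It implements:

- the closed-form time-resolved reflectance of a semi-infinite turbid
  medium and the analytical time-domain / steady-state reflectance of a
  two-layer medium (layered diffusion equation, extrapolated boundary,
  Hankel-space Gauss–Legendre quadrature, FFT time synthesis);
- an MCML-style layered time-resolved Monte Carlo simulator (compiled,
  per-photon counter-based RNG substreams) with per-layer partial-pathlength
  recording and Beer–Lambert perturbation re-weighting;
- TCSPC transient calibration (time zero + amplitude against a reference
  medium) and bin-conserving rebinning;
- Levenberg–Marquardt estimation of both layers' absorption and reduced
  scattering coefficients from a single-distance transient
  (`fit_two_layer_td`) or multi-distance CW intensities
  (`fit_two_layer_cw`), with the top-layer thickness fixed;
- two-wavelength hemoglobin unmixing to the tissue oxygenation index
  TOI = 100·[HbO₂]/([HbO₂]+[Hb]);
- photon time-of-flight gating analysis of pulsatile (heart-rate) signals;
- reproducible simulation studies: deep-layer absorption recovery,
  CW-versus-TD accuracy, gating benefit, and an occlusion-protocol TOI
  pipeline demonstration.

## The model in brief

For layer k with absorption μa_k, reduced scattering μs′_k (cm⁻¹), the
diffusion Green's function is solved per layer in Hankel (s) and temporal
frequency (ω) space with

    αₖ² = s² + (μa_k + iω/v)/Dₖ,   Dₖ = 1/(3 μs′_k),   v = c/n,

an extrapolated boundary at z = −2AD₁ (A from the Fresnel-integral
internal-reflection factor; A(1.4) ≈ 2.95), source depth z₀ = 1/μs′₁, and
continuity of fluence and flux at the interface. The surface fluence is
inverse-Hankel transformed by fixed-order quadrature and synthesized to the
time domain by inverse FFT. The inverse problem minimizes a Poisson-weighted
least-squares loss over a rising-edge-to-1%-tail window with log-parameter
positivity and a profiled amplitude; two wavelengths (740 and 850 nm,
straddling the ~800 nm isosbestic point) are fitted independently and
unmixed to TOI through a bundled extinction table.

## Worked example

Synthesize a noisy measurement of the standard two-layer medium (maternal
layer μa = 0.11, μs′ = 11.19 cm⁻¹, 9.6 mm thick; fetal layer
μa = 0.09333, μs′ = 9.551 cm⁻¹) and recover the deep-layer absorption:

```r
library(layertof)

med <- two_layer_medium(
  top    = optical_layer(0.11, 11.19, thickness = 0.96),
  bottom = optical_layer(0.09333, 9.551))

grid  <- time_grid(t_end = 5, n_bins = 250)          # 0-5 ns, 20 ps bins
model <- td_two_layer(med, rho = 2, grid = grid)      # forward model
obs   <- sample_counts(model, 1e6, seed = 42)         # 1e6-photon TCSPC shot noise

fit <- fit_two_layer_td(obs, top_thickness = 0.96)
summary(fit)
#> Two-layer diffuse optics fit (two_layer_td)
#>   90 data points, weighted RSS 71.75, 15 iterations, converged
#>   estimates:
#>         mua1        musp1         mua2        musp2    amplitude
#> 1.103756e-01 1.112989e+01 9.626858e-02 1.206709e+01 3.815599e+07
#>   approximate relative standard errors (from the log-scale
#>   covariance proxy of the free parameters):
#>    mua1   musp1    mua2   musp2
#> 0.28784 0.03950 0.01625 2.28573
```

The recovered deep-layer absorption `mua2 = 0.0963` is within 3.1% of the
generating value 0.09333 for this seed (note the standard-error pattern:
the deep absorption is well determined, the deep scattering is not — the
late tail constrains μa₂ strongly but μs′₂ only weakly).

Converting per-wavelength absorptions to oxygenation:

```r
tab <- extinction_table()
st  <- hemodynamic_state(4.8e-5 * 0.4, 4.8e-5 * 0.6)  # TOI 40%
u <- unmix_two_wavelengths(mua_from_state(st, tab, 740),
                           mua_from_state(st, tab, 850), tab)
u$toi
#> [1] 40
```

Study drivers reproduce the package's headline simulations end to end:

```r
rec <- run_recovery_study(seeds = 1:5)   # deep-layer mua recovery, 1e6 counts
rec$summary$median_rel_err_pct
#> [1] 1.160592
```

`run_cw_vs_td_study()`, `run_gating_study()` and `run_occlusion_demo()`
drive the CW-comparison, time-gating and occlusion-pipeline studies; each
returns a `study_report` whose per-seed table and summary can be written as
delimited text with `write_study_report()`. A thin command-line wrapper
over these functions is installed at `inst/cli/layertof.R`.

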