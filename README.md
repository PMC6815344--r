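# limbusflow

Quantifying episcleral blood-vessel morphology and regional aqueous-outflow
variation from fluorescence confocal laser endomicroscopy (CLE).

Aqueous humor leaves the eye through Schlemm's canal into episcleral veins,
and outflow is not uniform around the limbus — a question that matters for
where angle-based glaucoma surgery is placed. After an intracameral
fluorescein injection, a fiber-bundle confocal endomicroscope (423 × 423 μm
field of view, ~3.5 μm lateral resolution) images the episcleral
vasculature at 15° intervals around the limbal circumference. `limbusflow`
turns those frames into numbers: vessel midlines and diameters, ROI
fluorescence time courses with an optimal imaging time, and per-quadrant
statistics of fluorescence and vessel calibre. Because no real CLE frames
are publicly deposited, the package ships a first-class synthetic phantom
generator with known ground truth, and validates the entire chain against
it.

## The core algorithm

Vessels are modelled as tubes with a Gaussian cross-sectional intensity
profile, I(d) = A·exp(−d²/2σ₀²). The midline is extracted as a scale-space
ridge: at each scale σ of a logarithmic grid the frame is smoothed and the
γ-normalized bright-ridge strength

  R_σ = (σ²)^γ · max(−λ_min, 0)

is computed from the Hessian eigenvalue λ_min. On a Gaussian ridge the
response over t = σ² is R(t) ∝ t^γ σ₀ (σ₀² + t)^(−3/2), maximized at
t\* = γσ₀²/(3/2 − γ); with the default γ = 0.75 this gives σ\* = σ₀
exactly, so the scale of maximal response *is* the profile SD. Diameter is
reported as the PSF-deconvolved full width at half maximum,
2√(2 ln 2)·√(σ\*² − σ_psf²). Ridge points (non-maximum suppression,
sub-pixel localisation, noise-adaptive thresholds) are linked into ordered
midlines with per-point diameters; the inferior limbal quadrant
(225°–315°, endpoints inclusive; 7 of the 24 grid angles) is compared
against all other angles with a two-tailed two-sample t-test on per-angle
ROI totals, and the wash-in of fluorescence is fitted as
I(t) = B + I∞(1 − e^(−(t−t0)/τ)) with the optimal imaging time defined as
t0 + τ·ln 20 (95% of plateau).

## A worked example

```r
library(limbusflow)

# phantom: one vessel of 30 um FWHM at SNR 10 on a 256 px frame
sp <- frame_spec(fov_um = 250, grid_px = 256, background_au = 50,
                 noise_sd_au = 10, seed = 42)
v  <- vessel_truth(cbind(c(-20, 300), c(125, 120)), fwhm_to_sigma(30), 100)
fr <- generate_vessel_frame(sp, list(v))$frame

seg <- segment_vessels(fr, scale_space_params(),
                       psf_sigma_um = sp$psf_sigma_um)
seg
#> <vessel_segments> 1 segment(s), 251 ridge point(s)
#>   median diameter per segment (um): 30.0
summary(seg)
#>   segment_id n_points median_diameter_um mean_diameter_um ...
#> 1          1      251           30.03037         30.10002 ...
```

The 30 μm ground-truth diameter is recovered to 0.1% from a noisy frame;
`plot(seg)` draws the frame with the midline in red and the vessel borders
in blue. The wash-in fit recovers the human-preset plateau time:

```r
tc <- fit_washin(build_timecourse(
  generate_washin_series(sp, washin_preset("human"), list(v))))
tc
#> <timecourse> 61 samples, t = [0, 600] s
#>   wash-in fit: plateau 8.398e+05 au, tau 139.7 s, t0 -0.3071 s ...
#>   optimal imaging time (95% of plateau): 418.1 s
```

(the preset's true value is 420 s). A circumferential dataset with the
default quadrant effect (inferior 1742 ± 271 au vs other 1300 ± 316 au,
between-angle SDs) reproduces the inferior excess:

```r
ds <- generate_limbal_dataset(frame_spec(), limbal_effect_spec(), seed = 1)
compare_inferior_vs_rest(ds$truth)
#> <quadrant_comparison> inferior vs all other quadrants
#>   inferior: 1674 +/- 93.4 au (SEM), n = 14
#>   other:    1303 +/- 42.6 au (SEM), n = 34
#>   welch t-test: t = 3.618, df = 18.67, two-sided p = 0.001873 (significant)
#>   convention: inferior = 225-315 deg, endpoints inclusive
```

`run_pipeline()` ties everything together — simulate (or ingest), segment
every frame, measure background-corrected ROI totals, compare quadrants,
and compute angular cluster spans — writing CSV/JSON/PNG artifacts plus a
reproducibility manifest. A thin command-line wrapper lives at
`inst/cli/limbusflow.R` (`simulate | segment | timecourse | quadrants |
run`), and a demo configuration at `inst/extdata/demo_config.json`.

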