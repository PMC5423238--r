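# zerocross

Zero-crossing derivative spectrophotometry for two-component assays in R.

## The problem

Two drugs formulated in one tablet — here a buprenorphine-like major
component (validated 20–80 µg/mL) and a naloxone-like minor component
(5–20 µg/mL) — often have UV absorption spectra that overlap so heavily
across 200–350 nm that neither can be quantified from the raw absorbance
without a prior separation step. Derivative spectrophotometry sharpens the
overlapped band envelopes: the *n*th derivative of absorbance with respect
to wavelength, `Dⁿ(λ) = dⁿA/dλⁿ`, turns broad shoulders into oscillating
fine structure. The **zero-crossing technique** then measures one analyte's
derivative amplitude at a wavelength where the *other* analyte's derivative
is exactly zero. Because both the Beer–Lambert law
(`A(λ) = Σₖ cₖ aₖ(λ)`) and the derivative operator are linear, the
interferent contributes nothing at its own crossing, and the amplitude read
there is an affine function of the target concentration alone:

```
Dⁿ_mix(λ*) = c_target · dⁿa_target/dλⁿ(λ*)      where Dⁿ_interferent(λ*) = 0
```

A calibration line `Y = m·X + b` fitted at `λ*` (amplitude `Y` against
concentration `X`) is inverted to quantify unknowns, and the whole assay is
validated with the standard pharmaceutical battery: linearity (slope,
intercept, their standard errors, correlation coefficient), within-day and
between-day precision (CV %) and accuracy (Error %), standard-addition
recovery, and a method comparison against a reference method by the pooled
two-sample *t*-test and the variance-ratio *F*-test.

The package is aimed at analytical-method developers and teachers of
pharmaceutical analysis who want the full pipeline — spectra in, validated
report tables out — as tested, scriptable code, plus a synthetic-data
generator so every stage can be exercised and property-tested without an
instrument.

## What is in the package

| stage | functions |
|---|---|
| containers & I/O | `wl_grid()`, `spectrum()`, `read_spectrum_csv()`, `write_spectrum_csv()`, `read_spectrum_jcamp()`, `resample()` |
| synthetic spectra | `gaussian_band()`, `analyte_model()`, `default_analyte_models()`, `noise_model()`, `simulate_spectrum()`, `generate_calibration_set()`, `generate_tablet_sample()` |
| derivative transform | `derivative()` (iterated Δλ difference or Savitzky–Golay), `amplitude_at()` |
| wavelength selection | `find_zero_crossings()`, `screen_candidates()`, `select_working_pair()`, `optimize_settings()` |
| calibration | `fit_calibration()` → `"calcurve"` (print/summary/coef/predict/residuals/plot), `quantify()` |
| validation statistics | `accuracy_precision()`, `standard_addition_recovery()`, `two_sample_t()`, `paired_t()`, `variance_ratio_f()`, `t_critical()`, `f_critical()`, `method_comparison()` |
| study driver | `study_config()`, `read_study_config()`, `run_study()`, `report_tables()` |

`inst/scripts/run_study.R` is a thin Rscript wrapper
(`Rscript run_study.R --config study.yaml --seed 1 --out reports/`).

## Worked example

```r
library(zerocross)

## a noisy two-analyte mixture on the default 200-350 nm, 0.1 nm grid
m <- default_analyte_models()
s <- simulate_spectrum(m, c(50, 12.5), noise = noise_model(seed = 42),
                       label = "mix")
s
#> <spectrum> 'mix': 200-350 nm (1501 pts), A in [-0.007623, 2.219] AU
#>   meta: conc_bup_like=50, conc_nal_like=12.5, noise_sd_au=0.002, ...

## its third-derivative spectrum at delta-lambda = 28 nm
derivative(s, order = 3, delta_lambda_nm = 28)
#> <deriv_spectrum> order 3, delta-lambda 28 nm (diff) of 'mix': 242-308 nm

## the complete in-silico study under one master seed
st <- run_study(study_config(seed = 20170501))
st
#> <zc_study> zero-crossing derivative assay study
#>   settings: order 3, delta-lambda 28 nm (diff)
#>   working wavelengths: 255.9 nm (a), 246.7 nm (b)
#>   calibration r: 1.0000 (a), -1.0000 (b)
#>   max CV 0.76%, max |Error| 0.39% over 24 cells
#>   recovery: 100.24% (a), 100.44% (b)
#>   tablet t/F within critical values: TRUE (a), TRUE (b)

st$calibration$curve_a
#> <calcurve> [bup_like] Y = 2.727e-06 X - 2.188e-08
#>   r = 1.0000, n = 42, range 20-80 ug/mL
#>   measured at 255.9 nm (order 3, delta-lambda 28 nm)

report_tables(st, "reports")   # CSV + JSON report bundle
```

Reading the output: the screen selected 255.9 nm (a zero crossing of the
minor analyte) to measure the major one, and 246.7 nm (a crossing of the
major analyte) for the minor one. The 24 precision/accuracy cells are the
within-day (n = 3) and between-day (n = 9) determinations at three
concentration levels per analyte over three days; every CV stayed below
0.8 % and every accuracy error below 0.4 % in this run. Standard-addition
recoveries sit at 100.2–100.4 %, and the simulated tablet assay passes both
the *t*- and *F*-comparison against the simulated reference method
(critical values 2.776 at df = 4 and 19.0 at df = 2,2).

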