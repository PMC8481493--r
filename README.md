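# planteis

Electrical impedance spectroscopy (EIS) of plant-cell suspensions,
built around the unified Randles–Debye equivalent circuit: a Randles
electrode block (R_s, R_ct ∥ C_dl/CPE) in series with an extended Debye
suspension block (R_1 ∥ (R + C) ∥ C_1), valid over the ultra-wide
4 Hz–20 GHz band. The package is for experimenters and sensor designers
who want to differentiate and monitor suspended cell cultures (e.g.
tomato MSK8 vs tobacco BY2 cells, in MS nutrient medium vs phosphate
buffer) from features of the impedance spectrum rather than from raw
curves.

## The analysis in brief

With an ideal double layer the magnitude spectrum splits into seven
regions — four plateaus (R_s + R_ct + R_1, R_s + R_1, R_s + R_1‖R, R_s)
joined by −20 dB/decade roll-offs — and the phase shows bell-shaped
negative peaks, one per capacitor. Writing k = R/R_1 and p = R_s/R_1,
the two high-frequency peaks have closed forms independent of the
capacitances:

    φ4 = arctan√(k/(k+1)) − arctan√((k+1)/k)            (region 4, cells)
    φ6 = arctan√(p/(p+k/(k+1))) − arctan√((p+k/(k+1))/p) (region 6, medium)
    ω4 = (1/(C·R_1))·√(1/(k(k+1)))      ω6 = (1/(C_1·R_1))·√(1/(p(p+k/(k+1))))
    |Z|5 = R_1·(p + k/(k+1))            d = |Z|5,suspension / |Z|5,medium

φ4 is bounded below by ≈ −20° once R ≥ R_1 and tends to −90° as k → 0;
φ6 sits near −90° (≈ −74° at k = 1, p = 0.01) because the electrode
resistance is orders of magnitude below the solution's. These peaks,
their frequencies, and the region-5 deviation d are the detection
observables: deeper peaks mean more cells, φ4 is a cell-type signature,
d is larger in low-conductivity media.

The package provides: exact circuit evaluation (`evaluate_impedance`),
the pole/zero ladder and Bode skeleton (`corner_frequencies`,
`asymptotic_bode`), the closed forms above (`phi4`, `phi6`, `omega4`,
`omega6`, `z5_magnitude`), numeric peak detection (`find_phase_peaks`),
detection metrics and series comparison (`metrics_from_params`,
`delta_phi4`, `sensitivity_curve`), complex nonlinear least-squares
fitting with asymptote-driven initialization (`fit_spectrum`,
`initial_guess`), a seeded synthetic-suspension generator (`preset`,
`generate_series`), CSV spectrum I/O (`read_spectrum`,
`write_spectrum`), and a pipeline CLI (`run_cli`, installed as
`exec/planteis`).

## Worked example

```r
library(planteis)

cp <- circuit_params(R_s = 1, R_ct = 2e4, C_dl = 1e-6,
                     R = 150, R_1 = 100, C = 5e-10, C_1 = 2e-12)
metrics_from_params(cp, medium_reference = as_medium_params(cp))
#> <detection_metrics>
#>   k = 1.5, p = 0.01
#>   phi4 = -14.48 deg at f4 = 1.644e+06 Hz
#>   phi6 = -75.41 deg at f6 = 1.019e+10 Hz
#>   |Z|5 = 61 ohm, d = 0.604
```

k = 150/100 = 1.5 puts the cell peak at −14.5°, a bit above the
≈ −20° floor; the suspension's region-5 plateau sits at 60% of the
cell-free medium's. The numeric peaks of the exact spectrum agree with
the closed forms:

```r
sp <- evaluate_impedance(cp, log_freq_grid(points_per_decade = 20))
find_phase_peaks(sp)
#>         f_peak phi_min       f_grid phi_grid
#> 1 1.122600e+02  -81.89 1.127000e+02   -81.89   (electrode dispersion)
#> 2 1.639799e+06  -14.45 1.590250e+06   -14.44   (cells: f4, phi4)
#> 3 1.035871e+10  -75.41 1.002448e+10   -75.40   (water polarization: f6, phi6)

fit_spectrum(sp)$converged    # refit recovers all 7 parameters to ~1e-9
#> [1] TRUE
```

From a shell, the same pipeline runs as
`planteis simulate --config scenario.cfg --out-dir out/`, then
`planteis analyze --out metrics.csv out/*.csv`, with `fit`, `compare`
and `sensitivity` subcommands alongside (see `?run_cli`).

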