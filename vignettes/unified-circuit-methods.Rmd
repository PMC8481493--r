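---
title: "Methods: the unified Randles–Debye model and phase-peak detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the unified Randles-Debye model and phase-peak detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planteis)
```

## The model

A plant-cell suspension measured between two electrodes over an
ultra-wide band (4 Hz–20 GHz) is described by two blocks in series:

* a **Randles electrode block** — series access resistance $R_s$, and a
  charge-transfer resistance $R_{ct}$ shunted by the double-layer
  capacitance $C_{dl}$ (optionally a constant phase element
  $Z = 1/(C_{dl}(j\omega)^\alpha)$; $\alpha = 1$ is an ideal capacitor);
* an **extended Debye suspension block** — the solution resistance $R_1$
  in parallel with the cell branch $R + 1/(j\omega C)$ and with the
  water-polarization capacitance $C_1$.

The Warburg diffusion element of the full Randles model is omitted: it
only matters below the 4 Hz band edge. A cell-free medium is the same
circuit with the $R$–$C$ branch removed (`cell_branch = FALSE`); we
deliberately represent that by an explicit flag rather than sentinel
values like $R = \infty$ so validation can stay strict.

With $\alpha = 1$ the three capacitors produce three first-order
dispersions, hence three pole/zero pairs and a seven-region magnitude
skeleton: plateaus at $R_s + R_{ct} + R_1$, $R_s + R_1$,
$R_s + R_1 \| R$ and $R_s$, joined by $-20$ dB/decade roll-offs. Each
corner is where a capacitor's impedance matches the resistance it
shunts; `corner_frequencies()` returns the six corners and four
plateaus, and `asymptotic_bode()` the piecewise-linear skeleton.

## Phase peaks as observables

Each dispersion is a bilinear function
$(1 + j\omega/\omega_{zero})/(1 + j\omega/\omega_{pole})$ with
$\omega_{pole} < \omega_{zero}$. On a log axis its phase is
bell-shaped, with minimum
$\arctan\sqrt{\omega_{pole}/\omega_{zero}} -
\arctan\sqrt{\omega_{zero}/\omega_{pole}}$ at the geometric mean
$\sqrt{\omega_{pole}\,\omega_{zero}}$. Writing $k = R/R_1$ and
$p = R_s/R_1$, the two high-frequency peaks have closed forms that are
independent of the capacitances:

$$\varphi_4 = \arctan\sqrt{\tfrac{k}{k+1}} -
  \arctan\sqrt{\tfrac{k+1}{k}}, \qquad
  \omega_4 = \frac{1}{CR_1}\sqrt{\frac{1}{k(k+1)}},$$

$$\varphi_6 = \arctan\sqrt{\tfrac{p}{p + k/(k+1)}} -
  \arctan\sqrt{\tfrac{p + k/(k+1)}{p}}, \qquad
  \omega_6 = \frac{1}{C_1 R_1}\sqrt{\frac{1}{p\,(p + k/(k+1))}},$$

and the region-5 plateau is $|Z|_5 = R_1\,(p + k/(k+1))$. The deviation
of a suspension from its cell-free medium is
$d = |Z|_{5,\mathrm{susp}} / |Z|_{5,\mathrm{medium}}$.

```{r closed-forms}
phi4(1)        # ~ -19.5 deg: the practical floor once R >= R_1
phi6(1, 0.01)  # ~ -74 deg when the electrode is 100x below the solution
```

Two approximation caveats matter and are handled explicitly:

* $\omega_6$ above is the small-$p$ form of the exact geometric mean
  $\sqrt{\omega_{56}\omega_{67}}$; the exact form is exposed as
  `omega6_exact()` and used as the oracle in tests. At $p = 0.01$ the
  two differ by about 2%.
* $\varphi_4$ is likewise a $p \to 0$ limit — the exact region-4
  dispersion includes $R_s$, displacing the depth by roughly $40p$
  degrees. Both closed forms are therefore quoted (and tested) for the
  regime the method targets, $p \lesssim 0.02$, i.e. an electrode
  resistance orders of magnitude below the solution resistance.

**Well-separatedness.** The closed forms treat each dispersion in
isolation. `corner_frequencies()` reports a `well_separated` flag
requiring the *groups* to sit at least $10^{2.5}$ apart in frequency
(ratios $\omega_{34}/\omega_{23}$ and $\omega_{56}/\omega_{45}$). The
gap between the pole and zero of one dispersion is not part of the
criterion: it is fixed by resistance ratios (e.g.
$\omega_{45}/\omega_{34} = (k+1)/k$) and is necessarily small for
practical $k$ — which is precisely why the peaks are shallow, not a
sign of an invalid skeleton.

## Numeric peak detection

`find_phase_peaks()` takes grid-local minima of the phase and refines
each by a three-point parabola in $(\log_{10} f, \varphi)$, which is
accurate to well under a grid step at 10 points/decade. Minima
shallower than 1° (configurable) are suppressed as noise. For noisy
spectra, `initial_guess()` additionally smooths the phase with a
5-point moving average and keeps at most one peak per half decade
(deepest wins), since instrument jitter on the flank of a deep
dispersion otherwise fabricates minima.

## Fitting

`fit_spectrum()` minimizes the weighted squared real and imaginary
residuals with Levenberg–Marquardt (`minpack.lm`), with all resistances
and capacitances in log-space: positivity is enforced for free and the
ten-plus decades between $C_{dl}$ and $C_1$ become a well-scaled
problem. Default weighting is proportional ($1/|Z|$) so that the
ohm-scale region-5/7 plateaus are not drowned by the kilo-ohm region-1
plateau. Five seeded log-jittered starts (0.15 decades s.d.) guard
against local minima; the best weighted $\chi^2$ wins, ties broken by
the first start. Non-convergence is reported in the result
(`converged = FALSE`), not thrown.

The start point inverts the Bode skeleton: plateaus give resistances,
peak frequencies give capacitances through the geometric-mean
relations. $R_s$ is extrapolated from $\mathrm{Re}\,Z$ in $1/\omega^2$
over the top decade, because a 20 GHz band edge can sit below
$\omega_{67}$, where neither $|Z|$ nor $\mathrm{Re}\,Z$ has converged.
If the electrode dispersion is outside the recorded band (e.g. data
truncated below 1 kHz), $R_{ct}$ falls back to $R_1$ and $C_{dl}$ to a
value placing its zero a decade below the band edge, with `"flags"`
set on the returned object.

## The synthetic suspensions

No measured spectra ship with the package; `preset()` defines four
synthetic suspensions — tomato-like (MSK8) and tobacco-like (BY2)
cells in a nutrient-medium-like (MS) and a phosphate-buffer-like (PB)
background — that reproduce the qualitative phenomenology the method
exploits. The numbers are fixtures chosen once, not measurements:

* **Electrode and media.** $R_s = 1\ \Omega$, $R_{ct} = 20$ kΩ,
  $C_{dl} = 1\ \mu$F at both media; $R_1 = 100\ \Omega$ (MS) vs
  $300\ \Omega$ (PB). Fixing $R_s$ across media makes
  $p = R_s/R_1$ three times smaller in the buffer, which is what makes
  the deviation $d$ larger in the lower-conductivity medium.
* **Concentration response** (concentration $c \in [0,1]$, relative
  units of a stock — the study never states absolute units):
  $k(c) = g\,/\,(1/k_0 + b\,c)$ with $k_0 = 40$: cell loading adds
  conductance to the cell branch, so $k$ falls and $\varphi_4$ deepens.
  The rate $b$ is the cell-type signature (0.9 vs 1.6); $g$ is a small
  medium modulation (1.00 vs 1.06), so that $\varphi_4$ is primarily a
  cell property — same-cell pairs across media stay within ~1° while
  same-media pairs separate by ~8° at full concentration.
* **Solution displacement.** $R_1(c) = R_1(1 + 2c)$: cells displace
  conductive medium. This term is load-bearing: with $R_1$ fixed,
  decreasing $k$ would make $\varphi_6$ *shallower* with concentration,
  contradicting the observed joint deepening of both peaks; a growing
  $R_1$ (falling $p$) restores it.
* **Cell capacitance** $C(c) = 4\,\mathrm{nF}\cdot(0.05 + c)$ and
  $C_1 = 5$ pF, placing $f_4$ in the tens–hundreds of kHz and $f_6$ at
  a few GHz, inside the measured band with ~2.5-decade group
  separations.
* **Agglomeration and noise.** Clumping perturbs the effective cell
  capacitance, so agglomeration is mean-one lognormal jitter on $C$
  only (default CV 0.3): it randomizes $f_4$ while leaving
  $\varphi_4$ untouched. Instrument noise is multiplicative lognormal
  on the magnitude (default CV 2%) plus additive Gaussian phase jitter
  (0.3°). All randomness derives from one user seed via a fixed
  prime-stride splitting rule.

What the generator does **not** emulate: volume-fraction
(Maxwell–Wagner) physics linking concentration to parameters, electrode
geometry/cell constants, temperature effects, CPE behaviour
($\alpha < 1$) and low-frequency Warburg diffusion. Passing tests
therefore demonstrate the internal consistency of the analysis chain
and its robustness to the modelled noise — not parameter accuracy for
real MSK8/BY2 cultures.

```{r series}
pr <- preset("BY2", "PB")
pr$agglomeration_cv <- 0; pr$noise_mag_cv <- 0; pr$noise_phase_sd_deg <- 0
s <- generate_series(pr, c(0.25, 0.5, 1), seed = 1)
round(s$metrics[, c("k", "p", "phi4", "phi6", "d")], 3)
```

## Open choices made here

* The "mean deviation" $\Delta\varphi_4$ between series is the mean
  absolute per-concentration difference (unweighted mean over pairs);
  no formal definition exists to inherit.
* The denominator of $d$ defaults to the modelled cell-free plateau
  $R_s + R_1$ of the medium reference circuit; a measured plateau can
  be supplied via `medium_z5` (both readings of the reference are
  exposed because neither is canonical).
* Whether the CPE replaces or generalizes $C_{dl}$ is unspecified in
  the circuit's published form; here one element covers both,
  reducing exactly to the ideal capacitor at $\alpha = 1$, and all
  closed-form analysis is restricted to $\alpha = 1$ (fits may free
  $\alpha$).
* $f_4$ is reported but not used as a discrimination default, since
  agglomeration makes it erratic; $f_6$ and the phase depths carry the
  signal.

## Problem sizes and tolerances

The test and acceptance workloads use 10–40 points/decade grids over
4 Hz–20 GHz (≈100–560 points), 20 random circuits for the
analytic-vs-numeric peak oracle (1.5° / 15% agreement bands), 20 seeded
noisy refits for recovery statistics (median within 10%, $\varphi_4$
within 1°), and 100 Monte-Carlo draws for the agglomeration contrast —
sizes at which every statistic above is stable to well within its
tolerance while the full suite runs in seconds. Convergence tolerance
of the optimizer is $10^{-12}$ relative; peak refinement is local and
tie-breaks (equal-depth adjacent grid minima) resolve to the
lower-frequency point.

## Limitations

Closed forms degrade gracefully but measurably when dispersion groups
approach within ~2 decades; the `well_separated` flag should be heeded
before quoting analytic peaks. The fitted $R_{ct}$ absorbs any
unmodelled low-frequency diffusion if data below ~100 Hz are included.
Discrimination here is separability of known series, not
classification of unknowns.
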