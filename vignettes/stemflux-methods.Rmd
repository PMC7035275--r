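---
title: "Methods: chamber flux estimation, stem profiles and stand upscaling"
author: "stemflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber flux estimation, stem profiles and stand upscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemflux)
```

# The problem

Riparian and floodplain forests exchange methane and nitrous oxide with the
atmosphere through two coupled surfaces: the soil, and the tree stems that
vent gases taken up by the root system. Quantifying the stem pathway
requires (i) turning raw chamber headspace concentration time series into
areal fluxes with defensible quality control, (ii) describing how stem
emissions decline with height, and (iii) scaling per-stem-surface fluxes to
ground area so they can be compared with, and added to, soil fluxes.
`stemflux` implements this chain for the two chamber systems such
campaigns combine: manual static stem chambers sampled by syringe at
0/60/120/180 min and analysed by gas chromatography, and automated dynamic
soil chambers monitored by a cavity ring-down analyser at about 1.17 Hz
during 9-minute closures.

# Flux estimation

## Ideal-gas conversion

Mole fractions $x$ (ppm) are converted to mass concentrations before
fitting, at each closure's recorded air temperature $T$ and pressure $P$:

$$C \;=\; x \, \frac{M P}{R T} \quad [\mu g\, m^{-3}],$$

with $M$ the molar mass (CH$_4$ 16.043, N$_2$O 44.013, CO$_2$
44.010 g mol$^{-1}$) and $R = 8.31446$ J mol$^{-1}$ K$^{-1}$. Chamber
campaigns rarely log pressure; the default is 101325 Pa, overridable per
closure — at near-sea-level sites the error from this assumption is well
below instrument noise. Fluxes are reported as full-molecule mass
($\mu$g CH$_4$ m$^{-2}$ h$^{-1}$) by default; `unit_mode = "element"`
rescales to CH$_4$-C / N$_2$O-N for cross-study comparison, since both
conventions circulate in the literature.

## Windowed linear fit

The closed-chamber mass balance gives the flux from the initial
concentration slope:

$$F \;=\; \frac{dC}{dt} \cdot \frac{V}{A} \cdot 3600 \quad
  [\mu g\, m^{-2} h^{-1}],$$

where $V/A$ is the chamber's effective headspace height (0.110 m for the
paired stem chamber system of 0.00119 m$^3$ over 0.0108 m$^2$; 0.2 m for
the 0.032 m$^3$ / 0.16 m$^2$ soil chambers). $dC/dt$ is the ordinary
least-squares slope over a fitting window:

* **dynamic soil closures** — samples in the closed interval
  $[90, 240]$ s: a 90 s deadband discards the placement/stabilisation
  transient, then a 150 s window is fitted. Membership is decided by
  timestamp, so sampling jitter does not shift the window.
* **static stem closures** — all four GC samples (no deadband). With only
  four discrete samples there is no stabilisation period to discard, and
  dropping any sample would leave the fit fragile.

A constant series has zero total variance; its fit is defined as slope 0
with $R^2 = 0$ (no evidence of any flux). Two-point fits have $R^2$
identically 1 and are flagged `min-points`. The estimator is deliberately
linear: nonlinear (exponential/HMR-style) estimators are out of scope, and
the first-order headspace feedback model exists only in the synthetic
generator, to stress the quality gate.

## The CO$_2$-referenced quality gate

Automated soil systems co-measure CO$_2$, whose efflux is large and
reliably linear when the chamber seals well. A closure's CH$_4$ and N$_2$O
fits are therefore accepted exactly when the CO$_2$ fit's $R^2$ is
**strictly above 0.9**, regardless of their own $R^2$ — near-ambient CH$_4$
and N$_2$O slopes can be noisy yet unbiased, while a poor CO$_2$ fit
signals leakage or disturbed mixing that invalidates the whole closure.
The boundary $R^2 = 0.9$ rejects ("above" read strictly). Manual GC stem
closures measure no CO$_2$; the default fallback accepts them with a
`no-CO2-gate` flag, and a per-gas $R^2$ threshold is available in the QC
policy for users who prefer symmetric gating. Rejected estimates keep
their value with `qc_pass = FALSE`, so rejection rates stay auditable.

# Stem profiles

Stem fluxes measured at 0.10, 0.80 and 1.70 m are pooled per
plot $\times$ period $\times$ gas and fitted with an exponential decay

$$F(h) = F_0 e^{-kh},$$

by Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`,
maximum 200 iterations, relative sum-of-squares tolerance $10^{-10}$).
Starting values are $F_0$ = mean flux at the lowest height and $k$ from a
log-linear regression of $|F|$ on $h$ (fallback 1). The exponential family
is the standard description of the monotone decline of stem emissions with
height; the form is pluggable, and three degenerate situations degrade to
the constant profile $F(h) = F_0$ (with $k = 0$ and a `converged` flag):

* the optimiser fails;
* emission and uptake signs are mixed within one group (a magnitude-decay
  model is meaningless there);
* the fitted $k$ is not significantly different from zero (Wald test,
  $\alpha = 0.05$).

The significance fallback has a visible consequence worth knowing: when a
period pools days with very different emission levels (e.g. the flooding
response arriving mid-period), the between-day scatter inflates the
standard error of $k$ and the fit may fall back to constant even though
each day individually decays. The constant form then replaces the height
integral by the design-height mean, which overestimates the
height-averaged flux slightly when true decay is present. Homogeneous
periods resolve $k$ sharply. At the campaign's pooled design (six profile
trees, three heights) the bias of both estimators under 10% multiplicative
noise is below 1%; a minimal three-observation fit carries the usual
small-sample nonlinearity bias on $k$ (order 10%), which is why pooling
across trees is the default.

The height-averaged per-stem-surface flux over an integration band
$[0, H]$ is closed-form:

$$\bar F(H) = \frac{1}{H}\int_0^H F_0 e^{-kh}\,dh
            = F_0\,\frac{1 - e^{-kH}}{kH},$$

with a second-order series used for $|kH| < 10^{-8}$ to avoid
cancellation. $H$ defaults to 1.7 m — the highest measured chamber —
because extrapolating an exponential fitted on 0.1–1.7 m to a 19 m crown
is unsupported by data; full-height extrapolation is available and flagged
`extrapolated` in the outputs.

# Stand upscaling and partitioning

Stems are treated as cylinders of uniform diameter $D$ (diameter at
breast height, no taper), so a stand of density $\rho$ carries a stem
area index

$$\mathrm{SAI} = \pi D H \rho \quad [m^2\ \text{stem per}\ m^2\ \text{ground}],$$

and the ground-area stem flux is $\bar F(H) \cdot \mathrm{SAI}$. With the
default geometry (1500 trees ha$^{-1}$, $D = 0.17$ m, $H = 1.7$ m) the SAI
is 0.136. A per-height "soil-area-equivalent" transform
($F \cdot \pi D \Delta h \cdot \rho$ for a chamber's height band) supports
per-height comparison plots; for a uniform profile over the full band it
reproduces the SAI route exactly, which is tested to $10^{-12}$.

The stem contribution to the stem–soil continuum is
$100 \cdot F_{stem} / (F_{stem} + F_{soil})$ on the common ground-area
basis. When the compartments have opposite signs (one emits, the other
takes up) the percent-of-sum is undefined; absolute-magnitude shares are
reported with `mixed_sign_flag = TRUE`. Cumulative budgets accumulate
each sampled day's mean flux $\times$ 24 h, with no interpolation across
unsampled days. Box statistics use linear interpolation between closest
ranks (R quantile type 7), fixed so summaries are exactly reproducible.

# The synthetic campaign generator

No raw field data accompany this problem domain's campaigns, so the
generator is a first-class module producing a complete campaign with known
ground truth: a flooded (FP) and control (CP) plot, 14-day pre/experiment/
post periods, 9 FP and 4 CP tree–soil-chamber pairs of which 6 and 2 carry
the full three-height stem profile, 5/6/4 stem measurement days per
period, and daily automated soil closures.

The forward model per closure is
$C(t) = C_0 + S\,t$ (mass space, $S = F/3600 \cdot A/V$), or
$C(t) = C_0 + S\,(1 - e^{-\lambda t})/\lambda$ when the headspace feedback
rate $\lambda > 0$ is switched on to stress the QC gate; Gaussian
instrument noise is added in ppm space (GC: 0.03 ppm CH$_4$, 0.003 ppm
N$_2$O; CRDS: 0.0015, 0.0004, 0.8 ppm for CH$_4$/N$_2$O/CO$_2$).
Simulated mole fractions are clipped at zero — a chamber cannot hold
negative gas — so configured uptake fluxes must stay physical for the
chosen ambient concentrations.

True fluxes combine: a per-gas baseline; a flooding response (CH$_4$: a
persistent step $\times 100$ for stems and $\times 3$/$\times 12$
experiment/post for soil, arriving after a 4-day lag — flooded soil needs
days of anoxia before methanogenesis dominates; N$_2$O: an immediate
transient pulse, $\times 8$ for soil, 3-day e-folding, relaxing to a
suppressed floor of $0.3\times$ baseline as sustained anoxia pushes
denitrification past N$_2$O to N$_2$); an exponential height decay for
stems ($k$ = 1.5 m$^{-1}$ CH$_4$, 1.2 m$^{-1}$ N$_2$O); fixed lognormal
between-tree/between-chamber variability (sdlog 0.3); lognormal day
jitter (sdlog 0.1); and a soil-moisture coupling
$e^{2(\mathrm{SWC} - 0.30)}$ for CH$_4$. Covariates follow the flooding:
SWC ramps 0.30 $\to$ 0.55 over three days of flooding and drains with a
7-day e-folding; NO$_3^-$ is drawn down while NH$_4^+$ accumulates
(8-day rise), recovering partially after drainage. These choices make the
generated data reproduce the qualitative sign structure of flooded-forest
campaigns: CH$_4$ fluxes correlate positively with soil moisture, N$_2$O
negatively with ammonium.

The configured stem share — the generator's estimand — is computed from
the noise-free trajectories over exactly the days each source is
measured: stems on the 5/6/4 measurement days, soil on all days. That
matches what the pipeline can see, so estimate and estimand are
comparable. Magnitudes are order-of-magnitude plausible for a flooded
alder stand, not a reproduction of any particular field data set:
pre-period soil CH$_4$ of ~1 µg m$^{-2}$ h$^{-1}$ sits near the CRDS
detection scale on purpose, so low-signal QC behaviour is exercised.

What the generator does **not** emulate — and hence what green tests do
not certify about field data: diurnal flux cycles (true flux is constant
within a day), chamber artefacts other than first-order feedback
(pressure pulses, leaks, temperature transients), instrument drift and
spikes, spatial autocorrelation between neighbouring trees, and soil
heterogeneity beyond a lognormal chamber effect.

# Numerical and design choices

* Strict inequalities at QC boundaries ($R^2 = 0.9$ rejects).
* Constant series: slope 0, $R^2 = 0$; degenerate time grids error.
* $\bar F(H)$ switches to a series below $|kH| = 10^{-8}$.
* The batch estimator (`estimate_fluxes`) computes the grouped
  least-squares slopes in closed form for speed; a test asserts equality
  with the compositional per-closure path to $10^{-12}$, and the fit
  itself is checked against `stats::lm` to $10^{-10}$.
* Closure timestamps are ISO-8601 strings; within-closure time is seconds
  since closure start, keeping the arithmetic timezone-free.
* Determinism: one seed fixes the entire campaign; the pipeline rerun on
  the same configuration is byte-identical.

## Problem sizes used in the shipped checks

The package's own test ensemble runs the full campaign design with two
automated soil closures per chamber-day (instead of the field systems'
~12) and 20 replicate seeds for the end-to-end stem-share recovery; the
mechanical tests use a further-trimmed 6+6+6-day, 4+2-tree layout. These
sizes were chosen so the whole suite exercises every stage in a few
minutes while keeping the Monte-Carlo bands tight enough to be
informative; the statistical conclusions do not depend on the soil
closure count, which only narrows the (already small) soil-flux standard
errors.

# Known limitations

* The stem profile is fitted on 0.1–1.7 m; whole-tree emissions depend on
  an extrapolation the data cannot constrain. The default integration
  height therefore stops at 1.7 m, and the stem share should be read as
  "stems up to 1.7 m".
* The CO$_2$ gate is only as good as the assumption that CO$_2$ linearity
  proxies chamber integrity; processes that disturb CH$_4$/N$_2$O but not
  CO$_2$ (e.g. ebullition) pass the gate.
* Basal area is carried as a diagnostic only; upscaling uses mean DBH and
  density directly under the cylinder assumption.
* Uncertainty on the SAI (diameter and density variability) is not
  propagated into the contribution percentages.
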