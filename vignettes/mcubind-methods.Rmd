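---
title: "Models and methods behind mcubind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mcubind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcubind)
```

mcubind packages the quantitative analyses used to characterize the
interaction between the N-terminal domains (NTDs) of the mitochondrial
calcium uniporter MCU and its paralog MCUb: binding titrations in three
spectroscopies, circular-dichroism (CD) thermal melts, NMR titrations in
slow exchange, SEC-MALS molecular weights, and cell-based colocalization,
FRET and calcium-uptake readouts. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices that were
genuinely open.

## Tight binding with ligand depletion

Sub-micromolar dissociation constants measured at 0.1 uM labeled protein
put these titrations squarely in the *ligand-depletion* regime: the free
titrant concentration differs appreciably from the total, and the
hyperbolic (Langmuir) isotherm is biased. All binding mathematics
therefore use the exact 1:1 mass-action solution (the Morrison quadratic),

$$B = \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4PL}}{2},$$

for total receptor $P$, total titrant $L$ and bound complex $B$.
Internally the algebraically equivalent product form
$B = 2PL/(S + \sqrt{S^2 - 4PL})$, $S = P + L + K_D$, is used: the naive
difference form cancels catastrophically as $K_D \to 0$, while the
product form is stable there, and $K_D = 0$ itself is short-circuited to
the stoichiometric limit $B = \min(P, L)$. Stoichiometry is fixed at one
site per monomer throughout — including for ANS, where a titration of the
dye into fixed protein is fit with the *protein* as the depleted partner.
All internal concentrations are micromolar; `mgml_to_micromolar()` and
`a280_to_mgml()` convert at the I/O boundary using the constructs'
monomer masses (13.8637 and 12.0098 kDa) and 280-nm extinction
coefficients (0.3693 and 0.4280 (mg/mL)$^{-1}$cm$^{-1}$).

`fit_one_site()` estimates $(K_D, S_{free}, S_{sat})$ in the signal model
$S(L) = S_{free} + (S_{sat}-S_{free})\,B/P$ by Levenberg–Marquardt, with
$S_{free}$/$S_{sat}$ initialized from the curve endpoints and $K_D$ from
the half-signal concentration — a robust recipe for monotone curves in
either direction. Convergence uses a sum-of-squares tolerance of 1e-10;
non-convergence is reported, never hidden. A fit whose amplitude
$|S_{sat}-S_{free}|$ falls below three residual standard deviations is
flagged non-identifiable and reports no $K_D$: three sigma is the usual
detection criterion, and a stricter floor starts discarding genuinely
informative curves of moderate signal-to-noise. MST data are fit as
supplied on the $F/F_0$ scale; the package deliberately does not model
thermophoresis physics.

### The dilution-expectation statistic

When a protein–ANS mixture is serially diluted at constant molar ratio,
the expected fractional intensity drop per $f$-fold step is
$D = 1 - B(P/f, L/f)/B(P, L)$, bounded by the two analytic limits
$1 - 1/f$ (stoichiometric) and $1 - 1/f^2$ (weak binding). At the assay
concentrations (protein 41.6 uM from 0.5 mg/mL, ANS 50 uM, $K_D$ 1.5 uM,
$f = 2$) this form gives 53.3, 54.8 and 56.7 % for three successive
dilutions. Published expectations for this experiment (54.2, 56.0,
58.1 %) are close but not identical and their exact formula is not
stated; `expected_dilution_decrease()` implements the depletion form
above and we document the ~1-point discrepancy rather than reverse
engineering an unstated calculation.

## Thermal melts

`fit_boltzmann_melt()` models the CD melt signal as one or two Boltzmann
sigmoids, $y(T) = b_0 + \sum_k a_k/(1+e^{(T_{m,k}-T)/s_k})$, with
amplitudes constrained nonnegative (decreasing melts are flipped
internally). Baselines are constant by default — melt data are normally
normalized to $[0,1]$ first, which flattens them — with a global linear
term available via `baseline = "sloping"`. The transition count is the
caller's choice, not model selection: which model a melt warrants is an
experimental-design decision. The headline $T_m$ is the midpoint of the
largest-amplitude transition (the one carrying the maximum normalized
change in signal); midpoints within 2 degC of the scan edge are flagged
unreliable. The monitored wavelength is treated as metadata only.

Mean residue ellipticity uses the standard normalization
$MRE = \theta_{mdeg}/(10\,\ell\,c_M\,n)$ with path length $\ell$ in cm,
molar concentration $c_M$ and residue count $n$; pass $n-1$ to normalize
per peptide bond instead.

## NMR: CSP statistics and the global slow-exchange fit

Chemical shift perturbations combine the amide shift changes as
$\sqrt{\Delta H^2 + (0.14\,\Delta N)^2}$. The square root is the
universal convention (without it the quantity would carry ppm$^2$), and
0.14 is the customary nitrogen weight. Residues are called significantly
perturbed when their CSP strictly exceeds the mean + 1 sample standard
deviation of all CSPs.

In slow exchange, free- and bound-state peak intensities track the state
populations, so with bound fraction $f_B(L) = B(K_D, P, L)/P$ each free
peak follows $I_i^0\,(1-f_B)$ and each bound peak $I_i^{max} f_B$.
`fit_global_slow_exchange()` shares one $K_D$ across all series while
giving every peak its own scale. Because the model is linear in the
scales at fixed $K_D$, the fit uses variable projection: scales are
solved in closed form and the 1-D profile over $K_D$ is minimized
exactly. This matters for error reporting: at 100 uM labeled protein and
sub-micromolar $K_D$ the system is nearly stoichiometric
($f_B \approx \min(L/P, 1)$), the profile is extremely shallow, and
asymptotic standard errors understate the uncertainty. The fit therefore
also reports a 95 % profile-likelihood interval from the sum-of-squares
ratio threshold, which is routinely asymmetric and can be unbounded
above — an honest description of a weakly identified constant. Intensity
errors are treated as homoscedastic per peak; negative intensities are
clipped to zero and flagged. Free- and bound-state ensembles can be fit
together or separately, mirroring the practice of reporting the two fits
side by side.

## SEC-MALS molecular weights

Each chromatogram slice gets a concentration from the differential
refractive index, $c = dRI/(dn/dc)$ with the standard protein increment
0.185, and a molar mass by Zimm-type zero-angle analysis: the reduced
scattering $R(\theta)/(K^*c)$ is regressed on $\sin^2(\theta/2)$ and
extrapolated to zero angle. The second virial coefficient is set to zero
— the dilute regime that SEC itself enforces (~20-fold on-column
dilution). Slices below 5 % of the peak concentration report no mass;
the wings are noise-dominated and would otherwise contaminate the
weight-average $\sum c_i M_i / \sum c_i$ over the dominant peak. The
analysis accepts any set of at least three detector angles and never
assumes the full 16-angle bench. Per-angle calibration and band
broadening are vendor-internal and out of scope; the package works in
excess-Rayleigh-ratio units by construction.

## Colocalization

`manders_coefficients()` computes the intensity-weighted co-occurrence
coefficients M1 (red with green) and M2 (green with red) above per-channel
thresholds; for binary masks these reduce to exact overlap fractions.
`costes_threshold()` implements the standard Costes (2004) automatic
threshold: an orthogonal regression $G = a + bR$ defines candidate pairs
$(T, a+bT)$, scanned downward from the red maximum, and the largest $T$
whose below-threshold pixel population has Pearson correlation $\le 0$
(population formula; ties at exactly zero accept) is returned. Candidate
sets that are degenerate — fewer than two pixels, or zero variance in a
channel — cannot support a correlation and are skipped; if no candidate
qualifies the minimum intensity is returned so that no pixel is
excluded, which is the correct answer for perfectly co-varying channels.
Every distinct intensity is a candidate up to 4096 distinct values, with
256-bin quantization beyond that. An `equal = TRUE` mode applies a
single threshold to both channels, matching analyses run with
equivalent threshold values for both fluorophores. The exact thresholding
variant inside any particular plugin implementation is not published;
the textbook procedure is implemented and tested against an exhaustive
scan. The upstream microscopy cleanup chain is available as an optional,
explicitly parameterized pipeline (`preprocess_channel()`:
running-minimum background subtraction, percentile-clip normalization,
3x3 mean smoothing) whose applied steps are attached to the image;
bit-exact replication of any GUI toolchain is a non-goal.

## FRET spectra

Donor (eGFP) levels inside mixed cell spectra are estimated from a
510:545 nm intensity-ratio standard curve built from synthetic
`background + alpha x donor` sums and inverted monotonically (bracketed
root refinement, exact for noiseless mixtures). Single
nearest-grid-point intensities are used at 510 and 545 nm — the method
names two wavelengths, not bands. Acceptor (mCherry) FRET spectra come
from subtracting the scaled donor-only spectrum; the residual's peak
position is checked against 609 +/- 5 nm and *flagged* when off — we read
the 609-nm normalization as a QC statement about the acceptor peak
position, with amplitude rescaling available as an option
(`normalize_amplitude = TRUE`) since the method sentence is ambiguous
between the two readings. Both FRET ratios are ratios of trapezoid areas
on 550–700 nm with negative residual values floored at zero for
integration only; returned spectra keep their negatives so diagnostics
stay honest.

## Calcium traces

GCaMP6f traces are exponentially smoothed with
$s_t = (1-d)x_t + d\,s_{t-1}$, $d = 0.93$ — the damping factor is read as
the weight on the previous smoothed value, the common spreadsheet
convention, and is configurable. Traces are normalized by the minimum
fluorescence before the stimulus (F/F$_{min}$), and the histamine
response amplitude is the post-stimulus maximum minus the pre-stimulus
mean of the normalized trace, which makes it invariant to detector gain.

## What the synthetic data do and do not show

Raw instrument exports for studies like this are rarely deposited, so the
`sim_*` generators are first-class package code that emulate each input
with the statistical structure the analyzers assume: depletion-model
titrations, sigmoidal melts over the 20–95 degC scan at 1 degC pitch,
slow-exchange intensity series on the {0, 25, 50, 100, 150} uM grid at
100 uM labeled protein, Gaussian elution peaks with
$R(\theta) = K^* c M P(\theta)$, two-population pixel images with a
designed overlap fraction, Gaussian emission bands at 510/609 nm, and
5 Hz uptake traces with a 60 s baseline. Default experimental conditions
are the assays' own (labeled 0.1 uM for fluorescein and MST, protein
5.204 uM for ANS); grids the source experiments don't specify were fixed
once at field-typical values (a quasi-geometric 0–2 uM fluorescein grid,
a 16-point 2-fold MST dilution series from 100 uM). Noise defaults are
2 % multiplicative for optical signals and 5 % for NMR intensities —
visually typical scatter, documented as a choice, not a measurement.
Each generator draws from its own seed stream (caller seed plus a fixed
per-generator offset) so adding one generator never perturbs another's
output, and identical seeds reproduce outputs bit-identically.

Passing recovery tests on these synthetics demonstrates that each
analyzer inverts its own forward model correctly at realistic noise —
i.e., correctness of the estimators, not of the instruments. They cannot
certify instrument-specific systematics that the generators do not
model: photobleaching and inner-filter effects, MST T-jump kinetics,
melt irreversibility, band broadening and inter-detector delays in
SEC-MALS, optical crosstalk beyond the modeled bands, or segmentation
error in real micrographs.

## Problem sizes and numerical conventions

Recovery ensembles use 200 replicate titration fits and 100 replicate
melt and NMR fits — enough for a stable median at the documented
tolerances while keeping the whole suite around half a minute. Other
conventions collected in one place: optimizer tolerance 1e-10 on the sum
of squares with explicit non-convergence flags; $K_D \ge 0$ and
amplitude/slope positivity enforced by bounds rather than
transformations; melt transitions reported in ascending $T_m$;
trapezoid integration with linear interpolation at window edges; Pearson
correlations in the Costes scan use the population ($n$) formula.

## Known limitations

Binding is strictly 1:1 — no Hill coefficients, no multi-site or
competition models, and ANS "one site per monomer" is taken literally.
Melts yield apparent midpoints only, with no van 't Hoff enthalpy or
reversibility analysis. The NMR module consumes peak tables; spectral
processing, peak picking and exchange-regime classification are
upstream. DLS regularization, sequence alignment and routine inferential
statistics are intentionally absent.
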