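---
title: "Spectroscopic and electrochemical characterization of drug-albumin binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic and electrochemical characterization of drug-albumin binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchlab)
```

## The problem

Serum albumins are the main transport proteins of the circulation; how
strongly and by what forces a small-molecule drug binds to them governs its
free plasma concentration, distribution and clearance. The standard desk
workflow to characterize such an interaction is a battery of spectroscopic
and electrochemical titrations: fluorescence quenching of the protein's
intrinsic tryptophan/tyrosine emission (excited at 280 nm, emitting near
347 nm) as the drug is titrated in, circular dichroism (CD) before and
after complexation, synchronous and three-dimensional (excitation-emission
matrix, EEM) fluorescence, and differential pulse voltammetry (DPV) of the
electroactive ligand. `quenchlab` implements that workflow end to end as
tested, reusable functions, together with a synthetic-data generator that
produces every input with known ground truth.

## Models and procedures

### Inner-filter correction

When the ligand absorbs at the excitation or emission wavelength, the
measured fluorescence is depressed for purely optical reasons. The
multiplicative correction

$$F_{cor} = F_{obs}\,10^{(A_{ex}+A_{em})/2}$$

is applied before any fitting (`correct_inner_filter()`,
`correct_titration()`). The correction needs one $A_{ex}$ and one $A_{em}$
per titration rung; we evaluate $A_{em}$ at the emission maximum of the
zero-ligand spectrum and hold that wavelength fixed across the titration,
since the emission-wavelength convention for the scalar form is not
standardized. A point-wise variant ($A_{em}$ re-evaluated at every emission
wavelength) is available via `pointwise = TRUE`. $A_{ex}$ and $A_{em}$ are
taken as the plain absorbances of each titration solution.

### Stern-Volmer analysis and mechanism

Quenching is quantified by ordinary least squares of $F_0/F$ on the
quencher concentration,

$$F_0/F = 1 + K_{SV}[Q], \qquad k_q = K_{SV}/\tau_0 ,$$

with the unquenched lifetime $\tau_0$ defaulting to $10^{-8}$ s, the
standard intrinsic-fluorescence scale for proteins (configurable). The
regression keeps its intercept free rather than forcing it through 1:
the intercept is itself a diagnostic, and the correlation coefficient is
reported for the unconstrained line. A strictly increasing $K_{SV}(T)$ is
classified as dynamic (collisional) quenching, strictly decreasing as
static (ground-state complex), anything else as indeterminate
(`classify_mechanism()`). No $k_q$-threshold rule is applied by default —
the temperature trend is the primary argument — but an annotation against
the diffusion-controlled limit ($2\times10^{10}\ M^{-1}s^{-1}$) can be
switched on.

### Binding constant and stoichiometry

The double-logarithmic isotherm with free-ligand depletion correction,

$$\log_{10}\frac{F_0-F}{F} = n\,\log_{10}K_a +
  n\,\log_{10}\!\left([L_T] - \frac{(F_0-F)[P_T]}{F_0}\right),$$

is fitted by OLS; the slope is the apparent site number $n$ and
$K_a = 10^{\,\mathrm{intercept}/n}$. Points with apparent enhancement
($F \ge F_0$) or a non-positive free-ligand term — noise artifacts near
the ends of the ladder — are dropped with a warning rather than failing
the fit; a non-positive slope flags the result instead of erroring.

### Van't Hoff thermodynamics and force classification

From association constants at two or more temperatures,

$$\ln K_a = -\frac{\Delta H}{RT} + \frac{\Delta S}{R}, \qquad
  \Delta G = \Delta H - T\Delta S,$$

with $R = 8.314$ J mol$^{-1}$K$^{-1}$ and SI joules throughout (reports
display kJ). $\Delta G$ is taken from the fitted $\Delta H$ and $\Delta S$
rather than from $-RT\ln K_a$; the latter is emitted as a per-temperature
consistency diagnostic, and the two agree within the regression residual.
The dominant force follows the Ross-Subramanian sign rules: both changes
positive, hydrophobic; both negative, van der Waals/hydrogen bonding;
negative enthalpy with positive entropy, electrostatic. Because an
enthalpy "near zero" also indicates electrostatic control but no numeric
threshold is standard, we use a configurable band of 4 kJ/mol, about $RT$
at room temperature.

### Intensity readout

Fluorescence intensity per rung is read at the per-spectrum emission
maximum by default; a fixed-wavelength mode (e.g. 347 nm) is used for
site-marker experiments where all series must be read at the same point.
For noisy spectra, `titration_intensities()` offers a boxcar mean over a
window around the readout point (`smooth_halfwidth`). Near a band maximum
the window applies the same band-shape attenuation to every rung, so the
factor cancels exactly in the $F_0/F$ and $(F_0-F)/F$ ratios the fits
consume, while the point noise drops roughly with the square root of the
window size. Reading a single noisy grid point instead leaves the fits
statistically valid but noticeably less precise.

### Site-marker competition

Titrations premixed 1:1 with markers of the two principal albumin drug
pockets (Sudlow site I, e.g. phenylbutazone; site II, e.g. ibuprofen) are
compared with the bare-protein titration as $F/F_0$ curves read at a fixed
wavelength (default 347 nm). Each marker's divergence score is the mean
absolute difference from the bare-protein curve; the ligand is assigned to
the site of the marker with the larger divergence, since pre-occupying the
ligand's own pocket perturbs its quenching curve the most. Tied scores
give an indeterminate assignment.

### CD secondary structure

Observed ellipticity (mdeg) is converted to mean residue ellipticity by
the mass-concentration form

$$[\theta]_{MRE} = \frac{\theta_{obs}\cdot MRW}{10\,c\,l},$$

with $c$ in mg/mL, $l$ in cm and $MRW \approx 110$ Da for albumins. (An
equivalent molar form, molar concentration times residue count, is
selectable; the two agree identically when the parameters are consistent.
Only these forms yield deg cm$^2$ dmol$^{-1}$ from the stated units.)
Helix content follows Bowman's equation at 208 nm,

$$\alpha\text{-helix}(\%) = 100\cdot\frac{-[\theta]_{208} - 4000}{33000-4000},$$

whose reference values are exact boundary cases ($-33{,}000 \to 100\%$,
$-4{,}000 \to 0\%$). The formula is unbounded, so reported percentages are
clamped to $[0, 100]$ with the raw value preserved alongside.

### EEM peaks, synchronous metrics, DPV

EEM fluorophore peaks are read as 8-neighbour local maxima after masking
first-order ($\lambda_{em}=\lambda_{ex}$) and second-order
($\lambda_{em}=2\lambda_{ex}$) Rayleigh ridges within a configurable
half-width (default 15 nm). Cells bordering the mask are excluded from
candidacy: the clipped flank of a ridge would otherwise surface as a
spurious maximum at the mask edge. Ties break to the first cell in
row-major order.

Synchronous-fluorescence series ($\Delta\lambda$ = 15 nm probing tyrosine,
60 nm tryptophan) are summarized per rung as peak position, height, signed
shift versus the first rung (negative = blue shift) and signed percent
height change (`shift_and_quench_table()`).

DPV peak potentials and currents are extracted per voltammogram with
parabolic refinement on by default — DPV peaks are broad relative to the
2 mV sampling pitch, so the grid maximum alone wastes resolution — and the
series metrics report $\Delta E_p$, $\Delta I_p$ (last minus first) and
whether the peak current falls strictly, the signature of progressive
sequestration of the electroactive ligand into a non-electroactive
complex.

## The synthetic-data generator

No public repository of raw spectra exists for this kind of titration
study, so `quenchlab` ships generators whose defaults are the study
conditions the package targets: 3 uM protein, ligand from 0 to 80 uM in
10 uM steps, temperatures 287/298/307 K, excitation 280 nm, emission band
centred at 347 nm (width 25 nm, a typical albumin band), $F_0$ amplitude
1000 a.u. Emission spectra are Gaussian bands whose peak follows the
configured quenching law:

* `dynamic`: $F = F_0/(1 + K_{SV}[Q])$, the Stern-Volmer closed form;
* `static_binding`: $F$ solves the double-log isotherm (with depletion)
  self-consistently by damped fixed-point iteration to $10^{-12}$ — the
  study's own isotherm is the only binding model it states, so the
  generator defines truth through it and `double_log_fit()` is exactly
  consistent by construction.

The optional inner-filter effect multiplies each spectrum by
$10^{-(A_{ex}+A_{em})/2}$ with absorbances taken from the emitted ligand
absorbance spectra (a near-UV band anchored at 280 nm, absorptivity
5000 M$^{-1}$cm$^{-1}$, plus a weak 500 M$^{-1}$cm$^{-1}$ tail under the
emission band — a generic strong near-UV absorber), so
`correct_titration()` inverts the attenuation exactly. Gaussian noise
(s.d. relative to $F_0$) is applied to signal values only, last; the seed
fully determines the output, and ground truth is returned alongside every
dataset.

CD spectra are weighted sums of a helix basis (double minima at 208/222 nm,
depth $-33{,}000$ at 208 nm) and a coil basis ($-4{,}000$ at 208 nm)
converted back to mdeg through the inverse MRE formula, so the helix
round trip is exact by construction. EEMs are sums of 2-D Gaussians plus
optional Rayleigh ridges on the study's acquisition grids (excitation
220-350 nm at 5 nm pitch, emission 220-500 nm at 1 nm pitch);
voltammograms are Gaussian peaks on a linear baseline over 0.5-1.3 V at
2 mV pitch.

What the generator does **not** emulate: photobleaching, instrument drift,
pH effects, scatter other than Rayleigh ridges, non-Gaussian band shapes,
multi-site binding. Passing recovery tests therefore demonstrates the
correctness of the estimators and their numerical chain, not robustness to
every artifact of real instruments.

## Numerical choices

* OLS throughout (the package's own `ols_line()` over `lm.fit`), exact on
  two points against the closed-form line.
* Fixed-point solving of the static isotherm is damped (step halving) with
  a $10^{-12}$ relative tolerance and a $10^4$ iteration cap; non-
  convergence is an error, never a silent approximation.
* Peak ties break to the smallest abscissa; parabolic refinement is only
  accepted when the fitted parabola is concave and its vertex lies within
  the bracketing points, otherwise the grid maximum stands.
* Degenerate inputs (constant signals) yield `NA` correlation rather than
  a spurious $\pm 1$.
* Validation failures name the offending row or index.

## Problem sizes

The default validation suite fits titrations of 9 rungs and 151-point
spectra, 27 x 281 EEMs, and a 200-seed noise-recovery study at 1% noise —
sizes chosen to mirror the study design while keeping a full run in the
order of seconds on one core.

## Known limitations

* The scalar inner-filter form assumes a 1 cm, centrally-illuminated
  cuvette; geometry-dependent corrections are out of scope.
* CD analysis is single-wavelength (Bowman); full deconvolution
  (CONTIN/SELCON/K2D) is out of scope.
* The mechanism verdict is reported with its evidence (the $K_{SV}$
  trend); dynamic and static quenching can coexist, and lifetime
  measurements — not modelled here — would be needed to separate them
  conclusively.
* `quenchlab::spectrum()` masks `stats::spectrum()` (spectral density
  estimation); call the latter with its namespace if needed.

## A worked end-to-end run

```{r}
temps <- c(287, 298, 307)
K <- simulate_vant_hoff(52630, 261.73, temps)
titrations <- lapply(seq_along(temps), function(i) {
  simulate_titration(sim_config(seed = 100 + i,
                                mechanism = "static_binding",
                                true_K_a = K[i],
                                temperature = temps[i]))$series
})
report <- run_pipeline(list(
  titrations = titrations,
  cd = list(spectrum = simulate_cd(0.627), conc = 0.1995,
            path_length = 0.1),
  eem = simulate_eem(data.frame(ex = c(280, 230), em = c(350, 343),
                                height = c(248, 198))),
  dpv = list(simulate_voltammogram(0.95, 12),
             simulate_voltammogram(1.08, 4))))
report
```
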