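# quenchlab

Tools for characterizing how a small-molecule drug binds a serum albumin
from spectroscopic and electrochemical titrations. The package is aimed at
biophysical / pharmaceutical chemists who run fluorescence-quenching
titrations, circular dichroism, synchronous / 3-D fluorescence and
differential pulse voltammetry on drug–protein mixtures and want the full
numeric chain — corrections, fits, thermodynamics, classifications — as
tested, scriptable functions instead of spreadsheet arithmetic.

## What it computes

Fluorescence intensities are first corrected for the inner filter effect,

    F_cor = F_obs · 10^((A_ex + A_em)/2),

then fitted per temperature with the Stern–Volmer relation

    F0/F = 1 + K_SV [Q],        k_q = K_SV / τ0   (τ0 = 10⁻⁸ s by default).

A rising K_SV with temperature is classified as dynamic (collisional)
quenching, a falling one as static. Association constants and apparent
site numbers come from the double-log isotherm with free-ligand depletion,

    log10((F0−F)/F) = n·log10(K_a) + n·log10([L_T] − (F0−F)[P_T]/F0),

and Van't Hoff regression of ln K_a on 1/T yields ΔH and ΔS, Gibbs
energies ΔG = ΔH − TΔS, and a Ross–Subramanian force classification
(hydrophobic / van der Waals–H-bond / electrostatic). CD spectra are
converted to mean residue ellipticity and helix content via Bowman's
equation at 208 nm; EEMs get Rayleigh-masked peak tables; synchronous
series get shift/quench tables; DPV series get peak potential/current
metrics; and site-marker competition experiments get divergence scores
and a site assignment.

A synthetic-data module (`simulate_titration()`, `simulate_cd()`,
`simulate_eem()`, `simulate_voltammogram()`, `simulate_vant_hoff()`)
generates every input with known ground truth, so the whole pipeline is
testable without instrument data.

## Worked example

```r
library(quenchlab)

# thermodynamics from association constants at three temperatures
vant_hoff_fit(c(1.25e4, 2.76e4, 5.24e4), c(287, 298, 307))
#> <thermo_result> dH = +52.43 kJ/mol, dS = +261.06 J/(mol K), r = -0.9999, force: hydrophobic
#>   T = 287 K: dG = -22.50 kJ/mol (spontaneous)
#>   T = 298 K: dG = -25.37 kJ/mol (spontaneous)
#>   T = 307 K: dG = -27.72 kJ/mol (spontaneous)

# Stern-Volmer fit of a synthetic titration (3 uM protein, 0-80 uM ligand)
sim <- simulate_titration(sim_config(seed = 1, true_K_SV = 3.62e4))
f <- titration_intensities(sim$series)
stern_volmer_fit(f[1], f[-1], sim$series$ligand_concs[-1])
#> <quenching_fit> K_SV = 3.62e+04 M^-1, k_q = 3.62e+12 M^-1 s^-1 (tau0 = 1e-08 s), intercept = 1, r = 1.0000, 8 points

# CD helix content from a simulated far-UV spectrum
cd_analysis(simulate_cd(0.627), conc = 0.1995, path_length = 0.1)
#> <cd_record> MRE(208) = -22183 deg cm^2 dmol^-1, alpha-helix = 62.7%
```

The positive ΔH and ΔS read as hydrophobic driving forces; the negative
ΔG at every temperature means spontaneous binding; K_SV ≈ 3.6×10⁴ M⁻¹
with k_q far above the diffusion-controlled limit is a strong quencher;
and 62.7% helix is typical of native albumin.

`run_pipeline(config)` orchestrates all stages from one (JSON/YAML or in-
memory) config and writes `report.json` / `report.md` / CSV tables; see
the vignette in `vignettes/binding-characterization.Rmd` for the model
details and an end-to-end run.

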