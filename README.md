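# flprobe

Characterisation of fluorescent dyes as G-quadruplex-selective
fluorescence-lifetime probes.

Dyes such as the triangulenium family report on DNA topology through
their fluorescence lifetime: the free dye is quenched by intramolecular
photoinduced electron transfer (PET) from pendant amine groups, and
binding to different nucleic-acid structures (duplex, single strand,
G-quadruplex) alleviates that quenching to different degrees. Turning
that physics into numbers takes three linked analysis chains, and
`flprobe` implements all of them for R users working from raw
instrument exports:

1. **TCSPC lifetime analysis** — multi-exponential iterative
   reconvolution fitting of time-correlated single-photon-counting
   decays,
   `I(t) = I0 [(1 − α1 − α2) e^(−t/τ1) + α1 e^(−t/τ2) + α2 e^(−t/τ3)]`,
   convolved with the measured IRF (with a sub-channel prompt shift);
   global analysis of whole titrations with shared lifetimes and
   per-trace amplitudes; fractional intensities `f_i = α_i τ_i / Σ α_j τ_j`
   and average lifetimes `τ̄ = Σ α_j τ_j`; reduced-chi-square acceptance
   (χ²r < 1.17 at v = 200, P = 0.05) and F-statistic support-plane
   accuracy intervals, `F_χ = 1 + (p/v) F(P; p, v)`.
2. **Emission titration analysis** — fold enhancement, mole-ratio
   stoichiometry (two-segment breakpoint fit), and association constants
   from the exact 1:1 compound-to-binding-motif quadratic mass balance,
   fitted by trust-region least squares.
3. **Electrochemistry / PET energetics** — peak extraction and midpoint
   potentials from cyclic voltammograms, √(scan-rate) diffusion
   diagnostics, Fc⁺/Fc → NHE referencing (+0.64 V), Rehm–Weller
   ΔG = e[E_ox − E_red] − ΔG00 − e²/εd, and thermodynamic-cycle redox
   potentials from computed Gibbs energies (vs NHE at 4.4 V).

A synthetic-data module generates every input with known ground truth
(Poisson-sampled reconvolved decays at 10⁴ peak counts, 1:1-equilibrium
titration series, reversible CV peak pairs), so the whole pipeline is
testable end-to-end; small geometry utilities (dihedrals, distances, XYZ
reader) support conformational comparisons between crystallographic and
modelled structures.

## Worked example

Simulate a DNA titration of a probe (8 decays, 10⁴ peak counts, Poisson
noise, Ka = 10⁶ M⁻¹), run the global lifetime fit, profile the long
lifetime, fit the binding constant, and close the PET loop from a
simulated voltammogram:

```r
library(flprobe)

cfg <- sim_config(seed = 42)
sim <- gen_titration_series(cfg, Ka = 1e6, tau_free = 1.3,
                            tau_bound = c(6, 12))

fit <- fit_global(sim$series, ncomp = 3, fixed_free_dye_tau = 1.3)
fit
#> <global_fit> 8 traces, 3 shared component(s), chisq_r = 0.9473
#>   shared tau (ns): 1.300*, 6.083, 12.108  (* held fixed)
#>   p = 34 varied parameters, v = 1600 (fixed200)
#>   per-trace tau_bar (ns): 1.30, 1.95, 2.55, 3.65, 5.29, 7.05, 8.18, 8.71

tau_support_plane(sim$series, fit, component = 3, grid = seq(9, 15, 1))
#> <support_plane> tau[3]: 7 grid points, threshold F_chi = 1.0305
#>   accepted: 11 - 15 ns

fit_1to1(binding_curve_from_spectra(sim$spectra), dye_conc = 2e-6)
#> <binding_fit> Ka = 9.8e+05 1/M (motif of 1 DNA units)
#>   I_free = 2.22e+09, I_bound = 8.84e+09, rss = 1.54e+04

v <- gen_voltammogram(-1.25, 0.1, cfg)     # recorded vs Fc+/Fc
r <- extract_redox(v)
r
#> <redox_summary> E_mid = -1.2500 V (Fc+/Fc), E_pa = -1.2209,
#>   E_pc = -1.2791, ipa/ipc = 1.000
rehm_weller_dG(E_red_acceptor = reference_to_nhe(r$E_mid),
               dG00 = zero_zero_energy(520, 580))$dG
#> [1] -0.344  # eV; negative: PET quenching is favourable
```

Reading the output: the fit recovers the two bound-state lifetimes
(truth 6 and 12 ns) with the free-dye lifetime held at its compound-only
value; `chisq_r` below the 1.17 acceptance bound marks a statistically
acceptable model; the support plane brackets the long lifetime at the
`F_χ` threshold; the titration returns Ka within a few percent of the
simulated 10⁶ M⁻¹; and the CV midpoint, referenced to NHE, feeds the
Rehm–Weller balance with the 0-0 excitation energy to give a negative
ΔG — electron-transfer quenching by guanine is thermodynamically
favourable for this core.

A command-line front end over the same functions ships in
`inst/cli/flprobe.R` (subcommands `simulate`, `fit-decay`, `fit-global`,
`support-plane`, `titrate`, `cv`, `pet`); file formats are plain
two-column CSV (`time_ns,counts`, `potential_V,current_A`) with `# key:
value` metadata comments, a wide spectra CSV plus manifest, and JSON
reports.

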