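---
title: "Methods: lifetime, binding and redox analysis in flprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime, binding and redox analysis in flprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flprobe characterises fluorescent DNA-binding dyes — in particular
triangulenium dyes used as G-quadruplex-selective fluorescence-lifetime
probes — through three linked analysis chains: time-correlated
single-photon counting (TCSPC) decay analysis, steady-state emission
titrations, and cyclic-voltammetry / photoinduced-electron-transfer (PET)
energetics. This vignette documents the models, the defaults and the
numerical choices. Everything shown here is computed by the package; no
quantity is asserted that the test suite or the acceptance script does not
itself reproduce.

## The TCSPC decay model

A measured decay histogram is modelled as the causal convolution of the
instrument response function (IRF) with a multi-exponential decay law,

$$I(t) = I_0\left[(1 - \alpha_1 - \alpha_2)\,e^{-t/\tau_1}
  + \alpha_1 e^{-t/\tau_2} + \alpha_2 e^{-t/\tau_3}\right],$$

with the amplitude fractions normalised to unity (`multiexp_params()`
stores all of them and checks the simplex constraint). Derived quantities
follow the standard definitions: fractional steady-state intensities
$f_i = \alpha_i\tau_i / \sum_j \alpha_j\tau_j$ and the amplitude-weighted
average lifetime $\bar\tau = \sum_j \alpha_j \tau_j$.

Fitting is by *iterative reconvolution*: the model, not the data, is
convolved, so counting statistics stay untouched. A prompt-shift
parameter translates the IRF on its grid by linear interpolation, because
the IRF is recorded at a different wavelength (and through different
filters) than the emission decays and sub-channel timing offsets between
the two are the rule. The IRF is unit-normalised before convolution so
the intensity scale keeps count units.

Residuals are weighted by Poisson (Neyman) weights $w_k = 1/\max(y_k, 1)$
— the standard choice for photon-counting histograms — and the
goodness-of-fit window starts at the IRF peak, where the reconvolved
model first becomes informative. The reduced chi-square divides the
windowed weighted sum of squares by the *actual* residual degrees of
freedom (windowed channels minus free parameters).

### Optimiser: quasi-Newton over the nonlinear parameters, exact
### projection of the linear ones

The reconvolved model is linear in the per-component coefficients
$c_i = I_0\alpha_i$ (and in an optional constant background). The package
therefore profiles these out exactly at every step by weighted
non-negative linear least squares (a fast normal-equation solve, falling
back to `pracma::lsqnonneg` if a coefficient pins at zero or the basis is
numerically singular), and runs the quasi-Newton (BFGS) search only over
the genuinely nonlinear parameters: log-transformed lifetimes and
bounded prompt shifts (`shift = 0.25·tanh(u)` ns). This variable
projection halves-to-quarters the nonlinear dimension of a global fit
(e.g. from ~34 to 10 parameters for an 8-trace titration) and removes the
amplitude/scale degeneracy that makes fully simultaneous optimisation of
amplitudes slow and fragile. The log transform enforces $\tau > 0$; a
smooth quadratic barrier on $\log\tau$ outside $[dt/4,\,3\cdot
\mathrm{span}]$ prevents excursions to degenerate flat regions.

Starting lifetimes come from a projection-only grid search over log-spaced
candidates (12/7/5 points per free lifetime for 1/2/3 free components);
because projection is exact, evaluating a candidate set costs one small
linear solve per trace. Fitted lifetimes are reported sorted ascending,
with amplitudes permuted accordingly.

### Global (linked-lifetime) analysis

`fit_global()` fits all decays of a titration with one shared lifetime
set while amplitudes, intensity scale and prompt shift remain free per
trace, and the unbound-dye lifetime is held fixed at its compound-only
value — 1.28 ns by default (the morpholino-substituted dye), 15.75 ns for
the propyl-substituted dye; both appear in the literature rounded to
1.3/15.8 ns in running text, and both are plain arguments. Whether scale
and shift should be shared across traces is not prescribed anywhere;
they are per-trace here, which is the weaker assumption.

### Acceptance thresholds and support-plane accuracy

Two conventional statistics gate and qualify the fits:

* `chisq_acceptance(v, P)` — the upper-$P$ quantile of $\chi^2_v/v$. At
  the conventional $v = 200$, $P = 0.05$ this is 1.17, the usual
  "acceptable TCSPC model" bound.
* `critical_fchi(P, p, v)` — the support-plane threshold
  $F_\chi = 1 + (p/v)\,F(P;p,v)$ on the chi-square ratio
  $\chi^2_r(\mathrm{parm})/\chi^2_r(\mathrm{min})$.

The F-distribution argument order is genuinely ambiguous in the
historical notation $F(P,v,p)$; the package uses numerator dof $= p$,
denominator $= v$ — the convention standard for support-plane analysis,
which reproduces the published thresholds (1.028 at $p{=}33, v{=}1600$;
1.029 at $p{=}29, v{=}1400$) to within 0.002 — and exposes the swapped
order behind `order = "vp"`.

The degrees of freedom entering these *thresholds* follow the reporting
convention $v = 200$ per trace (`dof_policy = "fixed200"`), independent
of the actual channel count; an `"actual"` mode uses the windowed channel
count instead. The reported $\chi^2_r$ itself always uses the actual
residual dof — that is what a reduced chi-square means.

`tau_support_plane()` profiles one shared lifetime over a fixed grid
(e.g. 2–17 ns in 1 ns steps), re-optimising every other free parameter at
each grid point; with `repeats > 1` each point is restarted from jittered
initial values and the lowest chi-square kept, mirroring the
lowest-of-three-repeats comparison used in practice. The accepted region
is reported as the union of contiguous grid runs below the threshold, not
forced into a single interval, because tri-exponential surfaces can have
local minima. A grid point whose re-optimisation fails is flagged
(`ok = FALSE`), never dropped silently. Because the constrained model is
nested in the unconstrained one, the profiled ratio is $\ge 1$ up to
optimiser tolerance, and equals 1 at the unconstrained minimiser.

The coverage of these accepted intervals is checked by simulation in the
acceptance suite (200 bi-exponential series, 3 traces, $10^4$ peak
counts, grid step 0.1 ns): with the conventional $v = 200$/trace
thresholds the accepted interval contains the true lifetime in
effectively all replicates — the published threshold convention is
conservative relative to a per-parameter profile-likelihood cut, so
coverage sits at the top of the 95 ± 5 % band rather than below it.

## Emission titrations and 1:1 binding

Spectra are integrated over 584–634 nm by default (configurable), the
band around the dye emission maximum. Fold enhancement is the ratio of
the integrated end-of-titration spectrum to the dye-only spectrum.

Stoichiometry uses the mole-ratio method: a continuous two-segment line
with a free knee is fitted (64-point grid over the interior plus
golden-section refinement); the knee abscissa divided by the dye
concentration is the DNA-units-per-dye breakpoint. A single line is kept
instead whenever it is not beaten by BIC (the knee costs two extra
parameters) or already fits essentially perfectly — that is the
"no breakpoint" result for featureless curves.

Association constants use the exact 1:1 compound-to-binding-motif
quadratic mass balance,

$$x = \tfrac12\!\left[(D + L + 1/K_a) - \sqrt{(D + L + 1/K_a)^2 - 4DL}\right],
\qquad y = I_{\mathrm{free}}(L - x) + I_{\mathrm{bound}}\,x,$$

with $D$ the motif concentration, $L$ the total dye and $x$ the complex.
The binding *motif* (e.g. 5 base pairs binding 2 dyes, or one
G-quadruplex) is explicit user input (`motif_size`), so constants are
comparable across DNA topologies under the no-cooperativity assumption.
$\log_{10}K_a$, $I_{\mathrm{free}}$ and $I_{\mathrm{bound}}$ are fitted by
Levenberg–Marquardt trust-region least squares (`minpack.lm::nlsLM`); the
exact quadratic is used rather than any binding-isotherm approximation.
Curves that are saturated from the first measured point yield only a
lower bound on $K_a$ and are flagged as such. Dilution is assumed
corrected at acquisition (dye added with the titrant); raw-data users can
pre-correct before constructing the curve.

## Electrochemistry and PET energetics

`extract_redox()` locates the anodic and cathodic waves after a linear
baseline fit over the leading fraction of each sweep segment (default
15 %; no baseline procedure is standard, so it is a parameter), and
reports peak potentials and currents, the midpoint potential
$E_{mid} = (E_{pa} + E_{pc})/2$ — the "effective" redox potential for
quasi-reversible couples, chosen because it stays constant with scan rate
— and the peak ratio $i_{pa}/i_{pc}$. A wave with no resolvable return
peak is flagged irreversible and reported by its single peak potential,
as appropriate for amine-centred oxidations around 1.1–1.3 V.
`scan_rate_diagnostics()` regresses the peak quantities on
$\sqrt{\nu}$ (diffusion control shows up as linearity of peak current in
$\sqrt\nu$) and checks $E_{mid}$ and the peak ratio for constancy.

Potentials recorded against Fc$^+$/Fc are referenced to NHE by +0.64 V.
PET feasibility uses the Rehm–Weller balance

$$\Delta G = e\,[E_{ox} - E_{red}] - \Delta G_{0,0} - e^2/\epsilon d,$$

in eV, with the guanine oxidation potential 1.3 V vs NHE as the default
donor and the Coulomb term 0 by default (normally negligible in high
dielectric media). $\Delta G < 0$ means quenching by electron transfer is
thermodynamically favourable. The 0–0 energy is taken as the photon
energy at the arithmetic-mean wavelength of the absorption and emission
maxima, $hc/[(\lambda_{abs} + \lambda_{em})/2]$ with $hc = 1239.84$
eV·nm; the source notation "$(\lambda_{abs,max} + \lambda_{em,max})$" does
not pin the combination down, and the mean-wavelength (equivalently,
mean-of-crossing) reading is the one consistent with its use as an
$S_0\!\to\!S_1$ crossing energy.

Computed thermodynamic cycles convert gas-phase electron
attachment/detachment and solvation Gibbs energies (all in eV, so the
$nF$ division is a division by $n$) to solution potentials:
$E_{abs} = -[\Delta G_{gas} + \Delta G_{solv}(\mathrm{final}) -
\Delta G_{solv}(\mathrm{initial})]/n$, then $E_{NHE} = E_{abs} - 4.4$ V.
The published rendering of these equations is typographically corrupted;
the sign convention implemented is the standard cycle (reduction with a
negative solution-phase $\Delta G$ gives a positive absolute potential).
The Gibbs energies themselves are user input — no quantum chemistry is
performed.

## The synthetic-data generator

`gen_*` functions produce every input the pipeline consumes, with known
ground truth, under the acquisition conditions the analysis chain is
designed for: a Gaussian IRF of 200 ps FWHM (a stand-in for a
scatterer-measured IRF; any measured IRF file can be substituted), 55 ps
channels (220 ps available for coarse-timing emulation), and decays
scaled to 10 000 expected counts in the peak channel before per-channel
Poisson sampling. Titrations partition decay amplitudes between the free
dye and one or two bound components in proportion to the bound fraction
from the same 1:1 quadratic used in fitting; bound lifetimes default to
6 and 12 ns — a short and a long bound component in the ratio regime the
probes exhibit, without asserting any measured value. Matching emission
spectra are Gaussian bands whose amplitude interpolates between
$I_{\mathrm{free}}$ and $I_{\mathrm{bound}}$ (default ratio 4), with 2 %
multiplicative Gaussian noise, typical fluorimeter repeatability.
Voltammograms are reversible peak-pair templates with $\Delta E_p = 59/n$
mV and $\sqrt\nu$ (Randles–Ševčík) current scaling — sufficient to
exercise peak extraction without a digital electrochemistry simulator.

All generators are deterministic functions of their truth parameters and
a seed; regeneration is bit-identical, and the caller's RNG state is
restored afterwards.

What the generator does *not* emulate bounds what green tests mean for
real data: no detector afterpulsing, pile-up or dead time; no measured
(asymmetric, tailing) IRF shapes; no wavelength-dependent IRF drift
beyond the prompt shift; emission noise is uncorrelated across
wavelengths; CV waves carry no capacitive or ohmic distortion. Passing
recovery tests show the estimators are correct for the stated noise
model, not that these instrumental effects are harmless.

## Problem sizes and numerical choices

* Full-scale lifetime simulations use 768 channels at 55 ps (a 42 ns
  record): with a 28 ns record the 12 ns bound component is truncated
  enough to double the lifetime scatter; 42 ns restores a comfortable
  margin. Coverage simulations use bi-exponential, 3-trace series at 256
  channels, where the profiled lifetime is the single nonlinear
  parameter and each profile point reduces to exact linear projection.
* Optimiser: BFGS with `reltol = 1e-12`, up to 500 iterations; the
  convergence flag is propagated, and non-convergence is a flagged
  result, never a silent success.
* Tie-breaks: lifetimes sorted ascending on output; a zero-amplitude
  component keeps its (sorted) position rather than being dropped.
* Degenerate inputs are rejected at construction: non-uniform time grids
  (no resampling is attempted), negative counts, non-simplex amplitudes,
  empty fit windows, fewer windowed channels than parameters, fits with
  peak counts below 100 (warning below 1000).
* The knee refinement tolerance is `stats::optimize`'s default on a
  bracket of two grid cells; breakpoint positions are therefore resolved
  to ~1e-3 of the concentration range.

## Limitations

* No Poisson maximum-likelihood (deviance) fitting mode; weighted least
  squares only. For peak counts of order $10^4$ the difference is
  negligible; at very low counts Neyman weights bias $\chi^2_r$ upward.
* No stretched-exponential or lifetime-distribution models; at most
  three discrete components.
* No cooperative or multi-site binding models (Hill, McGhee–von Hippel):
  the motif construction deliberately forces 1:1 analysis.
* Support-plane accuracy is the primary uncertainty report;
  covariance-based intervals and photon-level bootstraps are out of
  scope.
* The CV peak extractor assumes one dominant wave pair per scan window;
  overlapping multi-electron transitions need the window narrowed by the
  user.
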