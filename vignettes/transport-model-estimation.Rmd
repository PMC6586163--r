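---
title: "Estimating root transport parameters from pressure-probe kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating root transport parameters from pressure-probe kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootprobe)
```

## The model

A root sealed to a pressure probe behaves, on the time scales of these
experiments, as a single osmotic compartment (the functional xylem,
volume $V_x$) separated from the medium by the root cylinder, whose
transport properties are summarized by three effective parameters: the
hydraulic conductivity $L_{pr}$ (m s$^{-1}$ MPa$^{-1}$), the solute
permeability $P_{sr}$ (m s$^{-1}$) and the reflection coefficient
$\sigma_{sr}$ (dimensionless, 1 for an ideally semipermeable barrier).
The probe couples pressure to volume through its elastic coefficient
$\beta$ (MPa m$^{-3}$), and $A_r$ is the root surface area mounted on
the probe.

**Hydrostatic relaxation.** A pressure offset $\Delta P_0$ imposed with
the micrometer screw relaxes back to the steady root pressure as water
crosses the root:

$$P(t) = P_{ss} + \Delta P_0\, e^{-k_{wr} t}, \qquad
  k_{wr} = \frac{\ln 2}{t_{1/2w}} = L_{pr} A_r \beta .$$

**Osmotic response.** Raising the medium osmotic pressure by
$\Delta\pi^0_s = R\,T\,C_s$ (van't Hoff; $C_s$ the solute osmolality)
first draws water out of the root (rate $k_{wr}$), then the solute
permeates (rate $k_{sr} = A_r P_{sr} / V_x$) and the pressure recovers.
Pressure relaxes toward the moving target
$P_0 - \sigma \Delta\pi^0_s e^{-k_{sr} t}$, giving the biphasic closed
form

$$P(t) = P_0 - \sigma\,\Delta\pi^0_s\,
  \frac{k_{wr}}{k_{wr} - k_{sr}}
  \left(e^{-k_{sr} t} - e^{-k_{wr} t}\right),$$

with the interior minimum at
$t_{min} = \ln(k_{wr}/k_{sr})/(k_{wr} - k_{sr})$. Substituting
$t_{min}$ back shows that the standard estimator

$$\sigma_{sr} = \frac{\Delta P_r}{\Delta\pi^0_s}\, e^{k_{sr} t_{min}}$$

is *exact* under this model — the permeation correction
$e^{k_{sr} t_{min}}$ removes precisely the solute leak that has occurred
by the time the minimum is reached. The test suite asserts this identity
to $10^{-10}$ relative, and cross-checks the closed form against an
independent two-compartment ODE integration (deSolve) to $<0.1\%$.

Two degenerate limits are handled analytically rather than by
perturbation: $k_{sr} = k_{wr}$ uses the series limit
$k_{wr} t\, e^{-k_{wr} t}$, and $k_{sr} = 0$ (impermeant solute) gives a
monotone drop to $P_0 - \sigma\Delta\pi^0_s$ with no finite minimum.

## The estimator

`probe_fit()` inverts the model per root:

1. Each hydrostatic relaxation is fitted as
   $P_\infty + A e^{-kt}$ by nonlinear least squares (`minpack.lm`),
   seeded from a log-linear regression of $|P - \hat P_\infty|$ on
   time. Multiple push/pull relaxations are averaged at the $L_{pr}$
   level before any group statistics. A fit is refused when the trace is
   constant or its envelope does not decay.
2. The biphasic trace is smoothed with a centered moving average
   (default window 5 samples — no estimator for $t_{min}$ is standard,
   and a short window suppresses sensor noise without shifting the
   broad minimum), and the minimum located by argmin. $P_0$ is the raw
   $t=0$ sample: smoothing the first samples would mix in the rapid
   initial drop and bias $\Delta P_r$ low by $\sim 1.5\%$ even without
   noise.
3. The water phase is fitted on $[0, t_{min}]$ with a free asymptote,
   giving the osmotic $L_{pr}$; the solute phase on $[t_{min}, end]$
   with the asymptote *fixed* at $P_0$, since the model recovers fully.
   Both windows are the natural choices given that the phases separate
   at the minimum; they are overridable through
   `fit_exponential_phase()`.
4. $P_{sr} = \ln 2 \cdot V_x / (t_{1/2s} A_r)$ and
   $\sigma_{sr} = (\Delta P_r/\Delta\pi^0_s) e^{k_{sr} t_{min}}$.

When a trace has no usable interior minimum (impermeant or very slowly
permeating solute, or a trace that ends long before recovery), the
solute-side quantities are reported as `NA` rather than failing the
root: this mirrors practice, where such roots contribute to $L_{pr}$ but
not to $P_{sr}$ or $\sigma_{sr}$.

Known bias: the water phase of the osmotic response is not a pure
exponential (its asymptote drifts as $e^{-k_{sr}t}$), so the osmotic
$L_{pr}$ carries a method bias of a few percent — inherent to the
phase-splitting approach, not to this implementation. The hydrostatic
$L_{pr}$ is unaffected.

**Quality control.** The cut test (`qc_cut_test()`) checks that after
cutting the root close to the seal the pressure collapses (default:
below 10 % of the steady pressure) and the relaxation becomes about an
order of magnitude faster (default: $t_{1/2}$ ratio 10). Both thresholds
are parameters, since "approximately one order of magnitude" is a
judgment call.

## Calibrations and units

`peg8000_water_potential()` evaluates the empirical PEG-8000 polynomial
$\psi(\mathrm{bar}) = (1.29\,T - 140)\,C^2 - 4.0\,C$. The concentration
$C$ is interpreted as the **w/w mass fraction of the total solution**;
with that convention, at the 23 °C day temperature, the standard recipes
17.5 / 25.4 / 31.6 % w/w give $-0.41$, $-0.81$ and $-1.23$ MPa,
rounding to the nominal $-0.4 / -0.8 / -1.2$ MPa stress levels. (On the
alternative g-per-g-water convention they would not; this fixes the
interpretation.) $\psi$ is reported as a negative potential in MPa;
osmotic pressures $\pi$ are positive MPa — the two sign conventions are
never mixed silently.

For dilute media the van't Hoff relation treats 1 mOsmol kg$^{-1}$ as
1 mol m$^{-3}$. Half-strength Hoagland solution at 20 mOsmol kg$^{-1}$
computes to $-0.049$ MPa at 23 °C; the commonly quoted $-0.04$ MPa is
likely a rounded or psychrometer-measured value, and the package reports
the computed number without forcing agreement.

## Suberin quantification

Roots are divided by relative length into zones A $[0, 0.25)$,
B $[0.25, 0.50)$ and C $[0.50, 1]$ (for RNA sampling, only the apical
half of each zone). Segments are assigned by midpoint, which is robust
for synthetic segments cut at exact fractions. Monomer labels follow the
GC nomenclature `C<len>[:<unsat>] <class>` with the four aliphatic
classes (primary alcohols, fatty acids, α,ω-diacids, ω-hydroxy acids)
plus the aromatics coumaric and ferulic acid. Amounts are normalized to
the endodermal surface area $A = 2\pi r L$; the endodermis radius is a
per-experiment configuration scalar (synthetic default 200 µm) because
it is not something a monomer table carries. Aromatic totals are flagged
for cautious interpretation: in grasses these aromatics are bound to
many cell walls, not only to suberin lamellae. Group summaries report
mean ± SD with n = 3 biological replicates by default.

## Statistics

`anova_fisher_lsd()` implements one-way ANOVA with Fisher's LSD:
pairwise $t$ statistics use the pooled within-group mean square and its
degrees of freedom, and the compact letter display is built by the
insert–absorb algorithm, which guarantees that two groups share a letter
exactly when their pairwise comparison is non-significant. Letters are
assigned in ascending-mean order starting at "a". The LSD is *protected*
by default (pairwise results are only interpreted when the omnibus F
test is significant) — whether to protect is genuinely open, so both
modes are provided and the choice is recorded in the output. No
multiplicity correction is applied beyond the LSD itself (a `p_adjust`
switch offers Holm for conservative users). Shapiro–Wilk normality
p-values are reported per group but never block the analysis: normality
screening is gatekeeping, not inference. `tpm()` is the usual
within-sample length-normalized expression summary, summing to $10^6$ by
construction.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of a `simulation_config()` and its
seed (identical inputs give identical bytes) and write a ground-truth
manifest next to every dataset so recovery tests never re-derive truth
from outputs.

* **Probe cohorts** — 8 roots per group; per-root transport parameters
  drawn from the shipped reference group means/SDs (control: hydrostatic
  $L_{pr} = 8.11 \pm 2.37 \times 10^{-8}$ m s$^{-1}$ MPa$^{-1}$,
  $P_{sr} = 2.24 \pm 1.54 \times 10^{-9}$ m s$^{-1}$,
  $\sigma = 0.38 \pm 0.06$; stress: $3.19 \pm 1.45$, $0.61 \pm 0.61$,
  $0.38 \pm 0.17$ in the same units), truncated to physical bounds by
  resampling (clipping would create boundary atoms). Gaussian sensor
  noise, default sd 0.002 MPa. The default probe/geometry
  ($\beta = 1.09\times10^{10}$ MPa m$^{-3}$,
  $A_r = 1.57\times10^{-4}$ m$^2$, 0.1 m × 0.5 mm root, 1.5 % xylem)
  is chosen so the control half-times are ~5 s (water) and ~10 min
  (solute) — the magnitudes such experiments actually show. Raw traces,
  $\beta$ and $A_r$ are not published quantities; these defaults are
  simulator choices and are flagged as such.
* **Suberin tables** — lognormal replicate noise (cv 0.15; amounts are
  strictly positive, so lognormal matches the support) around class
  means that encode the basipetal gradient (diacids and ω-OH acids
  ten-fold from zone A to C, alcohols and fatty acids two-fold, zone B
  at the geometric mean), zone-A class shares 33/9/9/49 %
  (fa/alc/diacid/ω-OH), a two-fold aliphatic increase in zone B under
  stress of $-0.8$ MPa or stronger (and in zone C under all stress
  levels, reaching ~7 µg cm$^{-2}$), and treatment-independent aromatics
  at twice the control aliphatic total.
* **Count matrices** — negative-binomial counts with known lengths, as a
  TPM fixture only.

What passing tests on these data do **not** show: real traces contain
drift, unstirred-layer effects, temperature transients and non-Gaussian
artifacts none of which are modelled; real monomer tables have
correlated replicate errors (shared extractions) and detection limits;
and the generator's group SDs subsume all biological and technical
variance into one normal draw. Recovery on synthetic data validates the
estimator arithmetic and its noise robustness, not the experimental
protocol.

## Problem sizes and numerical tolerances

The shipped tests run hydrostatic traces at dt = 0.05–0.1 s over 60 s
and osmotic traces at dt = 0.1–1 s over 1 800–3 000 s; noisy-recovery
checks use 200 replicate traces and the letter-display cohort check 100
simulated cohorts — sizes at which every statistical criterion is
well-resolved while the whole suite runs in about a minute. Noise-free
forward–inverse roundtrips recover $L_{pr}$, $P_{sr}$ and $\sigma$
within 1 % (discretization only) over a 3 × 2 × 3 parameter grid; with
sensor noise sd 0.002 MPa the median relative errors stay below 5 %
($L_{pr}$) and 10 % ($P_{sr}$, $\sigma$).

## Limitations

Single effective-parameter model: no decomposition into apoplastic vs
cell-to-cell pathway conductances (the hydrostatic/osmotic $L_{pr}$
ratio is reported as the usual index instead); no unstirred-layer
correction; no pressure-clamp or single-cell probe protocols; no
non-ideal osmotic coefficients (NaCl is treated as van't Hoff-ideal);
PEG calibration is specific to PEG 8000 within 0–45 % w/w and 5–40 °C.
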