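---
title: "Corneal elastic modulus from air-puff deformation: model, simulator and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal elastic modulus from air-puff deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneaE)
```

## The measurement problem

Dynamic Scheimpflug analyzers (Corvis ST and similar) fire a millisecond
air puff at the cornea and film the anterior surface while it deforms and
recovers.  Most indices derived from those recordings (applanation times
and velocities, deformation amplitude, stiffness parameter SP-A1, the
composite CBI/TBI scores) mix corneal material stiffness with geometry
(thickness, curvature) and intraocular pressure.  For screening *forme
fruste* keratoconus (FFKC) — the topographically normal fellow eye of a
unilateral keratoconus patient — a quantity closer to the tissue's
intrinsic elastic modulus is attractive, because FFKC corneas by
definition show little geometric abnormality.

`corneaE` implements such an analysis end to end on synthetic data with
known ground truth: a forward simulator of air-puff examinations, an
extraction chain for dynamic corneal response (DCR) parameters and the
force–displacement slope, a shallow-spherical-shell inversion of that
slope into an elastic modulus `E`, the statistical battery used to judge
screening indices, and a small 12–5–1 backpropagation classifier.

## The shell relation

The examination is treated as a quasi-static indentation: the air puff is
a uniform pressure over a disc of effective radius $r_p$ (so the apex
force is $f = P \pi r_p^2$, in mN when $P$ is in kPa and $r_p$ in mm),
and the cornea responds as a thin shallow spherical cap of anterior
radius $R$, thickness $t$ and Poisson ratio $\nu$ (0.49 by default,
near-incompressible tissue).  Over the loading stretch in which the apex
displacement $\delta$ lies between 0.2 and 0.4&nbsp;mm the
force–displacement relation is close to linear; its slope
$S_{TSC} = \Delta f / \Delta\delta$ (mN/mm) is the stiffness input, and
the modulus is

$$E \;=\; \frac{\Delta f}{\Delta\delta}\,
  \frac{(R - t/2)\,\sqrt{12\,(1-\nu^2)}}{\pi\,t\,\bigl(1 - c_1\mu^2\bigr)},
\qquad
\mu = r_p \left[ \frac{12\,(1-\nu^2)}{(R - t/2)^2\, t^2} \right]^{1/4}.$$

$\mu$ has a clean mechanical meaning.  Axisymmetric bending of a shallow
spherical shell is equivalent (Reissner) to a flat plate on an elastic
foundation, $D\nabla^4 w + (E t / R_m^2) w = p$ with
$D = E t^3 / 12(1-\nu^2)$ and $R_m = R - t/2$; the characteristic length
of that equation is $\ell = (D R_m^2 / E t)^{1/4}$, and $\mu = r_p/\ell$
is the puff radius in units of $\ell$ — the only shape parameter of the
apex-stiffness problem.

### The correction coefficient $c_1$

The factor $(1 - c_1\mu^2)$ corrects the concentrated-load solution for
the finite footprint of the puff.  No closed form for $c_1$ is fixed by
the relation itself, so this package derives it from the same shell
model: the plate-on-foundation Green's function gives the apex stiffness
under a uniform disc load as

$$S(\mu) = 8\sqrt{Dk}\;\phi(\mu), \qquad
  \phi(\mu) = \frac{\pi\mu^2}{8\int_0^\mu (-\mathrm{kei}\,s)\, s\, \mathrm d s},$$

with $\mathrm{kei}$ the Kelvin function, and $c_1$ is identified from
$\phi(\mu) = 1 - c_1 \mu^2$, i.e. `compute_c1()` returns
$(1-\phi(\mu))/\mu^2$.  Two properties follow: $c_1 < 0$ (spreading the
same force over a wider disc deflects the apex less, so a disc load is
*stiffer* than a point load), and $c_1$ varies weakly — logarithmically —
with $\mu$, which is why it is a function of $\nu, R, t, r_p$ rather
than a constant.  Because of that logarithm the coefficient itself has no
finite $\mu \to 0$ limit even though the correction *factor* tends to 1;
`compute_c1()` therefore evaluates at a small floor
($\mu_{\text{floor}} = 10^{-3}$) below which $c_1\mu^2$ is already below
$10^{-6}$.  The whole coefficient is exposed as an overridable callable
(`c1_fun` arguments throughout), so an alternative published closed form
can be substituted without touching anything else.

The closed form is validated against an independent numerical route:
`shell_disc_stiffness_fd()` discretizes the same bending equation by
second-order finite differences on a large clamped domain and solves for
the apex deflection under the disc load.  Across the validity band
($R$ 5.5–9&nbsp;mm, $t$ 0.45–0.55&nbsp;mm, $r_p$ 0.8–1.8&nbsp;mm) the two
routes agree to well under 1%, comfortably inside the 2% the test suite
demands.

### Units and grouping

The right-hand side of the relation, with the slope in mN/mm and lengths
in mm, is read as kPa and reported as MPa; this convention is applied in
exactly one function (`elastic_modulus()`), and the term grouping is
isolated in one internal helper (`stiffness_per_kpa()`) so either could
be swapped in isolation.  With the published healthy-mean inputs
($S_{TSC} = 25.64$ mN/mm, $R = 7.75$ mm, $t = 0.5345$ mm,
$r_p = 1.25$ mm) the relation yields:

```{r healthy-fixture}
g <- cornea_geometry(R = 7.75, t = 0.5345)
elastic_modulus(25.64, g, rp = 1.25)
```

which sits in the correct physiological decade (healthy corneas are
reported around 0.35 MPa by this family of methods; the exact value
depends on the disc-load correction adopted, and ours is the
self-consistent Reissner one above).  Note that the simulator and the
estimator share the relation only through its public interface — the
estimator never reads simulator internals — so round-trip accuracy below
is a genuine test of the extraction chain, not an algebraic identity.

## What the simulator emulates

`generate_cohort()` draws per-subject ground truth from group-wise
truncated normal distributions calibrated to published cohort summaries
for healthy, FFKC and keratoconus (KC) eyes: CCT 534.5±34.6 /
522.8±39.5 / 462.8±51.8&nbsp;µm, R 7.75±0.92 / 6.94±0.95 /
5.36±1.01&nbsp;mm, bIOP 15.3±2.0 / 14.6±1.8 / 14.3±2.5&nbsp;mmHg, E
0.35±0.04 / 0.30±0.08 / 0.16±0.04&nbsp;MPa, plus SP-A1 and ARTh.  The
underlying normal parameters are moment-matched so the *truncated*
distributions reproduce the printed means and SDs (plain truncation
would, for example, inflate the KC radius mean by ~3%).  B.Ele.Th, Kmax
and Pachymin have no published distributions in that source; their
defaults are synthetic, group-separated and clinically plausible values
whose only job is to give the classifier informative inputs — they are
labelled as such in `cohort_defaults()`.  E and bIOP are drawn
independently by default: the real-cohort E–IOP correlations
(r ≈ 0.3–0.56) have no published generative relation, so none is
invented; a user can correlate the draws through a custom config if the
dependence matters to them.

`simulate_examination()` builds the elevation field

$$y(x, t) = \underbrace{\sqrt{R^2 - x^2} - R}_{\text{arc}}
  \;-\; \delta(t)\, g(x) \;+\; a t^2 \;+\; \varepsilon,$$

with the apex response $\delta(t) = \mathrm{softclip}(f(t)/k)$, where
$k$ is the forward stiffness implied by the subject's true modulus.
Defaults and the reasoning behind them:

* **Frames and chord** — 140 frames over 32 ms across an 8 mm chord
  (141 lateral samples), the public convention for this device class.
* **Pulse** — baseline-subtracted Gaussian, peak 9.5 kPa at 15 ms, half
  width at half maximum 6 ms.  The subtraction makes the pressure exactly
  zero at the first frame, so frame 0 is the genuinely unloaded arc; a
  raw Gaussian would pre-load the apex by ~18 µm and bias the anterior
  radius fit.
* **Deformation bump** — Gaussian core of width 2 mm at the reference
  radius 7.75 mm, scaled proportionally to $R$ (the indentation zone of
  a steeper, smaller cornea is narrower; with a fixed 2 mm width the
  steepest KC corneas could never flatten before their deformation
  saturates), and tapered to exactly zero between 2.2 and 2.8 mm.  The
  compact support is what makes whole-eye motion identifiable: the
  peripheral zone $|x| \ge 3.5$ mm then carries *only* eye motion and
  noise, and the peripheral-mean estimator removes any quadratic drift
  exactly.  The taper radii also set the lateral crest positions, giving
  peak distances around 5.2–5.5 mm, the physiological scale.
* **Saturation** — the linear response is clipped smoothly toward
  $DA_{\max} = 0.25 R$, with an exactly linear segment up to 55% of the
  cap.  The knee therefore sits above 0.55 mm for every admissible
  geometry, safely beyond the 0.2–0.4 mm slope window, and the simulator
  warns if a custom config violates that.
* **Nuisances** — whole-eye motion $a t^2$ with
  $a = 10^{-4}$ mm/ms² (~0.1 mm over the examination) and i.i.d.
  Gaussian elevation noise of 2 µm per sample, a realistic edge-detection
  jitter for this image resolution.

Every examination embeds its ground truth (true modulus and stiffness,
true deformation series, eye-motion series, noise SD, and the
applanation time implied by the extractor's own curvature convention on
the noiseless field), so extraction error is measurable without
re-simulation.  What the simulator deliberately does **not** emulate:
viscoelasticity and corneal damping (the response is quasi-static),
posterior-surface dynamics, spatially structured speckle, IOP-coupled
stiffening, and any real optics of Scheimpflug imaging.  Passing tests
therefore demonstrate that the estimator inverts the assumed forward
model correctly under realistic noise — not that the shell relation is
an accurate constitutive description of living corneas.

## Extraction conventions

* **Whole-eye motion** is the per-frame mean elevation change over
  $|x| \ge 3.5$ mm; the corrected deformation is the apex change minus
  that estimate, sign-flipped so inward is positive.
* **Applanation** is "locally flat": the zero crossing of the quadratic
  best-fit curvature over the central $|x| \le 1$ mm, localized to
  sub-frame precision by a local linear fit of curvature against time
  over ±2 frames around the sign change (plain two-frame interpolation
  is the fallback).  The first crossing during loading is A1T, the
  crossing during recovery A2T.  With 2 µm noise this lands within a
  quarter frame of the truth in median.
* **Velocities** are central finite differences of the corrected
  deformation, interpolated at the event times; A2V is reported signed
  (negative on recovery).
* **Highest concavity** is the deformation maximum with a three-point
  parabolic refinement; **PD** is the distance between the two highest
  lightly-smoothed surface crests flanking the apex at that frame, ties
  broken toward larger $|x|$.
* **Slope window** — ordinary least squares of $f$ on $\delta$ over
  loading samples with $\delta \in [0.2, 0.4]$ mm; fewer than three
  in-window samples raises an `insufficient_window` condition that
  becomes a subject-level quality flag.  Flagged subjects are excluded
  from group statistics and counted, mirroring device-style QC gating,
  never silently dropped.
* **Geometry for the inversion** — $R$ is re-fitted from the frame-0
  edge by an algebraic circle fit; $t$ is taken from subject metadata
  (a single anterior edge cannot yield pachymetry).  The effective puff
  radius defaults to the configured $r_p$; `effective_puff_radius()`
  optionally measures the flattened-zone half-width at A1 instead
  (adding back the half-width of its sliding fit window, since a window
  centred at the plateau edge already sees curvature).

## Statistics and classifier decisions

* **Normality** — Lilliefors-corrected one-sample K-S (estimated
  parameters), delegated to `nortest::lillie.test()`; the statistic is
  cross-checked against a brute-force ECDF loop in the tests.
* **ICC form** — two-way random effects, absolute agreement, single
  measure (ICC(A,1)), the standard choice for two-device agreement; the
  form name is recorded in the output.  CCC uses population moments, so
  `agreement_suite(c(1,2,3), c(2,3,4))$ccc` is exactly 4/7.
* **ROC** — empirical curve over all thresholds; trapezoidal AUC
  (provably the Mann–Whitney pair count with ties at 1/2, and tested as
  such exhaustively); Youden cutoff with ties broken toward higher
  specificity; orientation auto-chosen so AUC ≥ 0.5 and recorded.
  Paired AUC comparison uses the DeLong placement-value covariance,
  validated against a brute-force double loop and against `pROC`.
* **Multiplicity** — LSD contrasts report raw p-values (that is what the
  procedure is); the number of comparisons is recorded alongside.
* **Network** — 12 inputs, 5 tanh hidden units, 1 linear output.  The
  optimizer is Levenberg–Marquardt on the squared-error Jacobian
  (`trainlm` semantics; the stated learning rate 0.01 drives the
  gradient-descent fallback instead), stopping at training MSE 0.005 or
  1000 iterations.  Features are z-scored with parameters fitted on the
  70% training split only.  Targets are coded healthy = 1, FFKC = 0,
  KC = −1 and decoded with thresholds at ±0.5; the coding and the
  thresholds are kept mutually consistent (a value above +0.5 is the
  class coded 1, i.e. healthy), and a boundary value of exactly ±0.5
  goes to the middle class.  Published descriptions of this architecture
  are not fully self-consistent on the value↔group mapping; this package
  fixes the self-consistent one and documents it here rather than
  guessing.

## Problem sizes and what the checks show

The packaged checks run, by choice, at desk scale: a 9-point noiseless
modulus grid (recovery is exact to machine precision, because the
noiseless linear regime makes OLS reproduce the forward stiffness
identically); 50 noisy replicates at 0.35 and 0.16 MPa (median absolute
error ~1%, bias well under 1%); twenty simulated 50/36/50 cohorts for
the discrimination check — AUC(E) for healthy-vs-KC is ≥ 0.95 in every
seed, while healthy-vs-FFKC lands around 0.6–0.85, consistent in
location with the ~0.75 reported for real cohorts without claiming to
reproduce it (the raw clinical data are not public, and the simulator is
calibrated only to printed group summaries).  On the default overlapping
cohort the classifier reaches ~80–90% validation accuracy; the ≥95%
contract is demonstrated on a cohort with group SDs shrunk to 25%, where
class structure, not sampling luck, is being tested.

## Known limitations

The absolute scale of E inherits whatever disc-load correction is used;
with the Reissner correction here, the healthy-mean slope maps to
~0.26 MPa rather than the ~0.35 MPa a different (unpublished) correction
would give — comparisons *between* groups, which drive every diagnostic
quantity in the package, are unaffected because the same correction is
applied everywhere.  The simulator's quasi-static, purely elastic
response cannot probe viscoelastic indices; the eye-motion model is a
smooth drift, not saccades; and the classifier is a fixed architecture
with a single split, exactly as specified, not a tuned model with
cross-validation.
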