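# corneaE

Corneal elastic modulus from simulated air-puff deformation examinations,
with the full evaluation pipeline used to judge keratoconus screening
indices.

Dynamic Scheimpflug tonometry (Corvis ST and similar) films the cornea
while a millisecond air puff deforms it.  The device's built-in indices
confound tissue stiffness with geometry and intraocular pressure, which
is why they struggle on *forme fruste* keratoconus (FFKC) — the
topographically normal fellow eye of a unilateral keratoconus patient.
This package implements, and stress-tests on synthetic data with known
ground truth, an analysis that converts the recording into a
material-like elastic modulus:

1. the loading-phase force–displacement slope
   `S_TSC = Δf/Δδ` (mN/mm) is fitted over the approximately linear
   0.2–0.4 mm apex-displacement window, with the apex force
   `f = P·π·rp²` from the puff pressure and effective radius `rp`;
2. the slope becomes a modulus through the shallow-spherical-shell
   (Reissner) relation

   ```
   E = (Δf/Δδ) · (R − t/2) · sqrt(12(1 − ν²)) / (π t (1 − c1 μ²)),
   μ = rp · [12(1 − ν²) / ((R − t/2)² t²)]^(1/4)
   ```

   with `R` the anterior curvature radius, `t` the central thickness,
   `ν = 0.49`, and `c1` the disc-load correction derived from the same
   shell theory (Kelvin-function closed form, validated against an
   independent finite-difference bending solution);
3. cohorts of healthy / FFKC / keratoconus (KC) subjects, calibrated to
   published group summaries, are simulated, extracted, and compared with
   the standard battery: K-S normality, Bland–Altman/ICC/CCC agreement,
   one-way ANOVA with LSD contrasts, Pearson correlation, ROC with
   Youden cutoffs and DeLong paired AUC tests, plus a 12–5–1
   backpropagation network (Levenberg–Marquardt) for three-group
   classification.

For the model, conventions and design decisions see the methods vignette
in `vignettes/corneal-elastic-modulus.Rmd`.

## Worked example

```r
library(corneaE)

# the shell relation on healthy-mean inputs
g <- cornea_geometry(R = 7.75, t = 0.5345)
elastic_modulus(25.64, g, rp = 1.25)
#> E = 0.2595 MPa  (slope 25.64 mN/mm, mu 1.086, c1 -0.2792,
#>                  correction 1.329, rp 1.25 mm)

# a full simulated 50/36/50 study, reproducible from one seed
rep <- run_study(pipeline_config(seed = 1), verbose = FALSE)
print(rep)
#> Study report: 136 subjects (0 excluded by QC)
#>   E recovery: bias -0.03%, median |rel err| 0.84%
#>   AUC(E, KC vs healthy) = 1.000
#>   AUC(E, FFKC vs healthy) = 0.694
#>   AUC(E, FFKC vs KC) = 0.956
#>   classifier validation accuracy: 85.4%
```

Reading the numbers: the extraction chain recovers each subject's true
modulus to better than 1% in median under 2 µm sensor noise and
whole-eye drift; `E` separates clinical keratoconus from healthy corneas
essentially perfectly, while the FFKC contrast — whose group
distributions genuinely overlap — lands around 0.7, the regime reported
for real cohorts; and the 12-input network classifies the held-out 30%
with ~85% accuracy on this overlapping cohort.

`write_study_report(rep, "out/")` emits the tidy CSV tables (cohort,
per-subject parameters, group comparisons, ROC tables), the serialized
classifier and a Markdown summary.  A thin command-line wrapper with
`simulate` / `extract` / `stats` / `run` subcommands lives at
`inst/cli/cornea_emod.R`.

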