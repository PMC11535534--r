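---
title: "Fractionator estimation of follicle numbers: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractionator estimation of follicle numbers: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follistereo)
```

## The estimand and the design

The ovarian reserve is the number of primordial follicles an ovary houses in
its cortex. Exhaustive counting is impossible at organ scale, so the total
is estimated by the fractionator: sample the tissue with known
probabilities, count in the sample with a rule that counts each follicle at
most once, and divide by the product of the sampling fractions,

$$\hat N \;=\; \sum Q \times \frac{1}{f_1 \, f_2 \, f_3},$$

where $\sum Q$ is the raw count over the examined sections, $f_1$ the
fraction of the organ available for histology, $f_2$ the slab sampling
fraction and $f_3$ the section sampling fraction. The design simulated here
is the one used for human primordial/primary follicle counting: 1-mm slabs
cut perpendicular to the ovary's long axis, every third slab kept with a
uniformly random start (systematic uniform random sampling), 5-µm sections,
and a serial run of 5 sections collected from every 50.

The estimator is design-unbiased because every follicle's probability of
being examined is exactly $f_1 f_2 f_3$, *provided* the counting rule gives
each follicle one and only one chance to be counted. That proviso is where
all the interesting decisions live, and it is what the simulator is for.

## The synthetic ovary

`generate_ovary()` builds a ground-truth organ: a prolate ellipsoid (default
semi-axes 15 000 × 7 500 × 5 000 µm, i.e. a 3 × 1.5 × 1 cm ovary typical of
the perimenopausal range; the first axis is the sectioning axis), with
follicles placed uniformly at random in a cortical shell (default depth
1 500 µm — follicles live in the cortex) subject to the whole follicle
sphere lying inside the organ. Each follicle is a nest of concentric spheres
(follicle ⊇ oocyte ⊇ nucleus) plus a nucleolus placed uniformly at random
strictly inside the nucleus.

Stage-specific default diameters (all overridable; dispersion is a
positive-truncated normal with CV 0.08):

| stage | follicle | oocyte | nucleus | nucleolus |
|---|---|---|---|---|
| primordial | 35 | 30 | 18 | 3 |
| primary | 60 | 45 | 22 | 4 |
| secondary | 150 | 80 | 30 | 5 |
| antral | 1000 | 110 | 35 | 6 |

These are simulator parameters informed by the morphometric literature, not
measurements: the source study reports no oocyte/nucleus diameters, so no
default here is anchored to a published value. What matters for the
estimator's validation is only the *geometry class* — spheres much thicker
than one section, with a small interior gating particle.

The available fraction $f_1$ is modelled as independent thinning: each
follicle is deleted with probability $1 - f_1$ before sectioning, mimicking
removal of a tissue wedge for pathology; the nominal $f_1$ (known from
tissue weights in practice) enters the estimator. A planar wedge-cut mode
was considered and not implemented: thinning preserves the uniform-placement
assumption exactly and the estimator only consumes $f_1$ as a scalar either
way.

The generator is deliberately idealized. It does **not** emulate granulosa
layers, stroma, vasculature or fibrosis, tissue shrinkage during processing,
lost section caps, staining artifacts, observer misclassification, or the
spatial clustering real follicles show. Passing tests therefore validate the
*sampling and estimation machinery*, not the histology: on real tissue the
additional error sources enter through $\sum Q$ and the realized fractions,
not through the arithmetic validated here.

## The virtual microtome

Coordinates: $z$ along the long axis, origin at the lower pole; every slab
and section interval is half-open $[z_{lo}, z_{hi})$, so a boundary
coordinate belongs to exactly one interval and nothing can be counted twice
at a cut. Slabs tile the extent with a ceiling rule (the final partial slab
is kept); sections tile each slab, with a final partial frame absorbing any
remainder narrower than one section. Keeping the tiling exact — rather than
forcing every frame to the nominal thickness — is what guarantees that every
nucleolus intersects at least one frame, which exhaustive-recovery tests
rely on.

Profiles are computed from sphere–slab intersection: a follicle appears on a
section when its oocyte sphere intersects the frame; oocyte and nucleus
profile diameters are chord diameters at the frame mid-plane
($2\sqrt{(d/2)^2 - \Delta z^2}$); the nucleolus is intersected against the
full 5-µm frame and its chord is read at the in-section plane closest to its
center, because a physical section is a volume, not a plane, and the
nucleolus is in focus where it is widest.

Realized fractions are always recorded: 10 slabs sampled at interval 3 from
slab 1 give $f_2 = 0.4$, not the nominal 1/3, and it is 0.4 that divides
$\sum Q$. A nominal-fraction mode exists behind a flag purely to measure the
error the nominal value would introduce. The serial-run offset is drawn once
per ovary and reused across groups and slabs — the simplest reading of
"five serial sections from every 50" — with a per-slab re-randomization
available behind a flag; both are unbiased, and the choice only affects
variance bookkeeping.

## The counting rule and the gate

A follicle is counted when its oocyte nucleolus is observed, once per serial
run; once counted it is excluded from all subsequent adjacent sections of
that run (not merely the next one — a nucleolus spanning three sections must
still count once; with 5-µm sections and 3-µm nucleoli the readings
coincide, and the stricter one is safe). Serial runs are identified as
maximal stretches of physically contiguous sampled sections, merged across
slab boundaries when adjacent slabs are both kept: under an exhaustive plan
the whole organ is one run, so exclusion collapses every duplicate and the
pipeline must return the true count exactly — a property the test suite
checks on 50 random ovaries.

What does "a clearly defined nucleolus" mean geometrically? Two gates are
implemented:

* **`gate = "center"` (default):** the follicle is counted in the unique
  section containing the nucleolus midpoint — operationally, the section in
  which the nucleolus is in sharpest focus and fully within the section
  volume. Each follicle then has inclusion probability exactly
  $f_2 f_3$, and the estimator is exactly design-unbiased.
* **`gate = "chord"`:** the follicle is counted in the first sampled section
  where the nucleolus shows any chord of at least a configurable threshold
  (0 = any visible trace). A nucleolus of axial extent $h$ intersects
  $(h + t)/t$ sections of thickness $t$ on average, so a serial run of $L$
  sections captures it with probability about
  $(L + h/t)/G$ rather than $L/G$ for a group of $G$ sections — an
  inflation of roughly $h/(Lt)$, i.e. about +12 % at the defaults
  ($h = 3$, $t = 5$, $L = 5$, $G = 50$). The printed estimator applies no
  correction term for this, so rather than silently correcting we expose the
  gate as a sensitivity: the Monte-Carlo harness and the acceptance script
  quantify the inflation (about +11 % measured), and the strict-focus
  center gate is the default precisely because it needs no correction.

Stage labels at counting time come from the generator's ground truth (or
from the input table in real-count mode); no morphological classifier is
implemented.

Two auxiliary schemes mirror the study's practice: secondary follicles are
counted relatively (1 section in 50, nucleolus-gated, **no** scale-up — the
function refuses any other plan), because their size makes fractionator
totals fragile; and growing-follicle raw counts (any oocyte profile, no
gate, no scale-up) reproduce the per-section counts used for the monkey
ovaries, where the sections were read whole without a stated gate — an
interpretation, documented as such. For the same reason, fractionator
totals for antral follicles (which dwarf the 225-µm gap between serial
runs) should be treated with caution; the package computes them if asked
but the study design does not use them.

## Numerical choices

* Ties at interval boundaries always resolve to the upper half-open
  interval; there is exactly one such convention applied everywhere.
* Placement is rejection sampling against analytic boundaries; containment
  of a follicle of radius $r$ is "center inside the ellipsoid with semi-axes
  reduced by $r$", a conservative criterion that is exact for spheres and
  tight for our axis ratios (the smallest boundary curvature radius,
  $c^2/a \approx 1.7$ mm, exceeds the largest follicle radius).
* Diameters are drawn as independent truncated normals and re-drawn jointly
  until nested; with the default CVs the rejection rate is negligible.
* Non-overlap mode (off by default — overcrowding is irrelevant to the
  estimator's correctness) places follicles sequentially with up to 1 000
  attempts each and fails loudly naming the stage.
* Every stochastic operation draws from one seeded stream in a documented
  order (per stage: sizes, centers, offsets; then design offsets: slab
  start, run start). Replicate studies derive child seeds from the master
  seed via a seeded `sample.int`, so summaries are pure functions of the
  master seed.
* Degenerate inputs: a zero-extent ovary yields zero slabs (empty, not an
  error); a slab narrower than one section becomes a single partial frame;
  zero counted follicles give `NA` morphometry flagged `defined = FALSE`;
  a zero primordial estimate makes the primary:primordial ratio `NA` rather
  than an error.

## Validation scale

The shipped tests and the acceptance script size their simulations to run
in minutes on a single core: 500 replicate ovaries of 1 000 primordial
follicles for the unbiasedness check (observed |relative bias| under 3
standard errors, CV ≈ 18 %), 50 mixed-stage ovaries for exhaustive exact
recovery, a 30-replicate sweep at 30 µm and 150 µm for the overcounting
mechanism (sections hit per object = 7 and 31, matching $(d+t)/t$ exactly
because both diameters are multiples of the section thickness), and 10 000
follicles for counted-profile morphometry (mean counted oocyte profile
≈ 29.1 µm against a true 30 µm, never exceeding it). Larger runs are a
matter of raising `reps` and the stage counts.

## Known limitations

* The simulator validates design properties, not histology: misclassified
  stages, missed nucleoli, or shrinkage-distorted fractions are outside its
  scope and enter real estimates directly.
* The uniform-placement assumption makes the variance optimistic relative
  to clustered real cortices; the bias properties do not depend on it, but
  reported CVs are a lower bound.
* The chord-gate bias factor is reported for the default nucleolus size; as
  the true nucleolus size distribution in tissue is unknown, the bias is a
  sensitivity curve in `h/t`, not a single correctable constant.
* Bilateral averaging and age-group summaries assume each ovary's estimate
  is exchangeable within subject; no hierarchical variance model is fit.
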