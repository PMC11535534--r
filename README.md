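# follistereo

Design-based estimation of the ovarian reserve — the total number of
follicles in an ovary — from systematically sampled histological sections,
with a synthetic 3-D ovary generator and a virtual microtome that make the
whole procedure testable end to end without any tissue.

## The problem and the estimator

Counting every follicle in a serially sectioned human ovary is infeasible:
one organ yields thousands of 5-µm sections. Stereology solves this with the
**fractionator**: sample the tissue in known fractions, count in the sample
with an unbiased counting rule, and scale up by the inverse of the sampling
probability. The design implemented here has three levels:

* **f1** — the fraction of the ovary available for histology (the rest may
  be removed for pathology review);
* **f2** — the ovary is cut into 1-mm slabs perpendicular to its long axis
  and every third slab is kept (systematic uniform random start);
* **f3** — each kept slab is cut into 5-µm sections, and a serial run of 5
  sections is collected from every 50.

Follicles are counted per stage (primordial, primary, secondary, antral)
under a nucleolus-gated rule — a follicle is counted only in the section
where its oocyte nucleolus qualifies, and is excluded from subsequent
adjacent sections of the run — and the total is estimated as

```
N = ΣQ × 1 / (f1 × f2 × f3)
```

with *realized* fractions (e.g. 4 kept slabs of 10 gives f2 = 0.4, not the
nominal 1/3). Because large follicles span many sections (a sphere of
diameter *d* hits about (d + t)/t sections of thickness *t*), secondary
follicles are handled by a separate relative scheme (1 section in 50, no
scale-up); the package's Monte-Carlo harness quantifies exactly this
overcounting mechanism.

The package provides: `generate_ovary()` (ground-truth synthetic ovaries
with nested follicle ⊃ oocyte ⊃ nucleus ⊃ nucleolus sphere geometry),
`sampling_plan()` / `section_ovary()` (the virtual microtome),
`count_follicles()` and friends (the counting rules), `fractionator()` (the
classed estimator with `print`/`summary`/`coef` methods),
`run_replicates()` / `overcount_experiment()` (bias, CV and the size sweep),
and a small CLI (`inst/cli/follistereo.R`).

## Worked example

```r
library(follistereo)

ov <- generate_ovary(c(primordial = 1000, primary = 100), seed = 42)
ov
#> Synthetic ovary (prolate ellipsoid)
#>   semi-axes: 15000 x  7500 x  5000 um (sectioning along the first axis)
#>   cortical shell: 1500 um (cortex placement); f1 = 1; seed = 42
#>   follicles: primordial=1000, primary=100, secondary=0, antral=0

res <- fractionate_ovary(ov, sampling_plan(), seed = 7)
res$obs
#> Virtual sectioning of ovary1
#>   2000 frames in 10 selected slabs; 200 sampled sections in runs
#>   realized fractions: f1 = 1, f2 = 0.3333, f3 = 0.1
#>   226 follicle profiles observed on sampled sections
res$fit
#> Fractionator estimates: N = sum(Q) / (f1 * f2 * f3)
#>
#>  ovary_id      stage sum_Q f1        f2  f3 N_hat
#>    ovary1 primordial    26  1 0.3333333 0.1   780
#>    ovary1    primary     3  1 0.3333333 0.1    90
#>    ovary1  secondary     0  1 0.3333333 0.1     0
#>    ovary1     antral     0  1 0.3333333 0.1     0
```

The virtual histologist saw 26 primordial nucleolus-gated counting events on
the 200 sampled sections; dividing by the realized sampling probability
(1/3 × 1/10) estimates 780 primordial follicles against a ground truth of
1000 — a single noisy draw of an estimator whose mean across replicates is
unbiased (`run_replicates()` verifies |relative bias| below 3 standard
errors at 500 replicates, with a CV of about 18 % under this design).

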