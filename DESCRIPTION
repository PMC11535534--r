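Package: follistereo
Title: Fractionator Estimation of Ovarian Follicle Numbers with a Virtual
    Sectioning Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based (fractionator) estimation of total follicle numbers
    per ovary from systematically sampled histological sections, together with
    a synthetic three-dimensional ovary generator and a virtual microtome.
    Simulated ovaries carry staged follicle populations (primordial, primary,
    secondary, antral) with nested oocyte/nucleus/nucleolus sphere geometry;
    the sampling design (1-mm slabs, systematic uniform random slab selection,
    5-um sections, serial-run subsampling) is applied to them, follicles are
    counted under a nucleolus-gated rule with adjacent-section exclusion, and
    raw counts are scaled by the realized sampling fractions,
    N = sum(Q) / (f1 * f2 * f3). A Monte-Carlo harness quantifies the bias and
    precision of the design and the size-dependent overcounting of large
    follicles under naive profile counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
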