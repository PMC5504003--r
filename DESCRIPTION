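Package: capvelo
Title: Parafoveal Capillary Velocimetry and Ocular Perfusion Study Statistics
Version: 0.1.0
Authors@R: person("capvelo", "maintainers", email = "capvelo@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring parafoveal capillary blood-flow velocity from
    adaptive-optics scanning laser ophthalmoscopy (AOSLO) video: motion-contrast
    perfusion mapping, vessel tracing, spatiotemporal (kymograph) image
    construction, and band-slope velocity estimation in metric units via
    axial-length-based angular scaling.  Includes a synthetic AOSLO video and
    clinical-cohort generator with known ground truth, and the clinical
    statistics used in longitudinal glaucoma perfusion studies: ocular perfusion
    pressure, logMAR conversion, 24-2 visual-field eligibility classification,
    baseline group comparison, repeated-measures ANOVA with Bonferroni-corrected
    paired post hoc tests, percent-change summaries, and a-priori sample-size
    computation for within-subject designs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
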