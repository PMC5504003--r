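# capvelo

Parafoveal capillary blood-flow velocimetry from adaptive-optics scanning
laser ophthalmoscopy (AOSLO) video, plus the clinical statistics of a
longitudinal ocular-perfusion study — with a synthetic-data module that makes
the whole chain testable end-to-end against known ground truth.

## Who this is for

Ophthalmic imaging groups measuring capillary blood-flow velocity with
AOSLO, and clinical researchers analysing how perfusion measures (IOP, OPP,
capillary velocity, optic-disc flow indices, retinal vessel diameters)
change under treatment in glaucoma cohorts.

## The measurement

In capillary single-file flow, leukocytes are transparent to the AOSLO laser
and appear as bright moving plugs; the packed erythrocytes trailing them
absorb it and appear dark.  Sampling each video frame along the vessel
centreline gives a spatiotemporal image ("kymograph") with one row per frame
and one column per micrometre of arc length: a moving blood column traces a
slanted band.  If a band's fitted line has slope `m` (frames per µm), the
cells advance `1/m` µm per frame, so the parafoveal blood-flow velocity is

    pBFV = 1 / (m · Δt)        [µm/s],   Δt = 1/64 s per frame

averaged over all accepted bands.  Angles are converted to retinal distance
with a Bennett-style schematic eye, `q = 0.01306·(AL − 1.82)` mm/deg for
axial length `AL`.

The pipeline is: rigid frame registration → motion-contrast perfusion map
(temporal SD / mean) → minimum-cost ridge tracing through user seed points →
kymograph → per-row edge detection + Hough-style orientation search +
robust per-band line fits → velocity.

The cohort module implements: ocular perfusion pressure
`OPP = 2/3·[dBP + 1/3·(sBP − dBP)] − IOP`; logMAR conversion; 24-2
visual-field eligibility (Anderson–Patella style cluster criteria with
reliability cut-offs); baseline group comparison (unpaired t, chi-square);
within-subject repeated-measures ANOVA with Bonferroni-corrected paired
post hoc tests and per-subject percent changes; and the a-priori sample size
for the within-subject F test via the noncentral-F power function.

## Worked example

```r
library(capvelo)

## synthesise a 2-s, 64 fps AOSLO video of one capillary at ~1.2 mm/s
cfg <- video_sim_config(field_deg = c(0.35, 1.05),
                        true_velocity_mm_s = 1.2, seed = 42)
sim <- simulate_capillary_video(cfg)

## measure it back, seeding the trace near the vessel ends
seeds <- sim$truth$centreline[c(3, nrow(sim$truth$centreline) - 2), ]
res <- measure_video(sim$stack, seeds)
res$estimate
#> pBFV 1.221 mm/s (SD 0.083, 60 bands)
mean(sim$truth$per_frame_velocity_mm_s)   # ground truth: 1.214 mm/s

## a synthetic two-group cohort (11 healthy, 11 POAG over 4 visits)
co <- simulate_cohort(cohort_sim_config(), seed = 42)
report <- run_study(co)
report$table2[c(1, 5), c("variable","rm_anova_p","p_wk1","p_wk4","p_wk12","pct_wk4")]
#>    variable rm_anova_p    p_wk1    p_wk4  p_wk12 pct_wk4
#> 1 pbfv_mm_s   3.60e-02 0.214738 0.001943 0.03077    23.4
#> 5  iop_mmHg   2.81e-06 0.000552 0.000973 0.00234   -20.1

compute_opp(116.0, 69.2, 17.1)            # 39.43 mmHg
required_sample_size(power_spec())        # 10 subjects
```

The cohort table shows what the generator builds in: under treatment the
simulated POAG eyes gain ~20 % capillary velocity by week 4 while IOP falls
~20 %; the RM-ANOVA and Bonferroni-corrected paired tests recover both.

## Command line

A thin CLI wraps the same functions (`system.file("cli/capvelo",
package = "capvelo")`):

```sh
capvelo simulate video|cohort|vf --config cfg.json --seed 1 --out out.tif
capvelo velocity --video video.tif --seeds "50,10 50,290" --out results/
capvelo cohort   --cohort cohort.csv --vf vf.json --out report/
capvelo power    --f 0.4 --alpha 0.05 --power 0.8 --m 4 --rho 0.5
```

Videos travel as multi-page grayscale TIFF with a JSON metadata sidecar;
cohorts as CSV; visual fields and reports as JSON.

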