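# petmtv

Automated delineation of **metabolic tumor volume (MTV)** on FDG-PET
images of lung nodules, with a digital PET/CT phantom framework for
validating the delineation methods against known ground truth.

MTV is prognostic in lung cancer, but the volume you measure depends on
how you segment. For large, high-uptake, solid tumors almost any
threshold works; for the small, low-uptake, ground-glass (nonsolid)
nodules typical of early lung adenocarcinoma, PET's 4–5 mm resolution
(partial-volume effect) and the thin margin between lesion and lung
background make method choice decisive. `petmtv` implements the four
standard automated methods so they can be compared head-to-head, per
lesion stratum, against a CT anatomical reference:

| Method | Threshold | Character |
|---|---|---|
| T42% | `T = 0.42 · SUVmax` | fixed percentage threshold |
| T42%×RC | `T = 0.42 · RC(d) · SUVmax` | partial-volume-corrected by the recovery coefficient for CT diameter `d` (`RC = 1` above 30 mm) |
| AT-AIA | iterate `T ← 0.42 (0.5 · SUVmax + 0.5 · SUVmean(R))` | adaptive to the lesion's own uptake distribution |
| AT40% | `T = BG + 0.40 (SUVmax − BG)` | adaptive to mean background SUV `BG` from a mirrored contralateral-lung ROI |

All methods keep the 26-connected supra-threshold component containing
the SUVmax voxel inside a user bounding box. Around them the package
provides:

* a **hot-sphere calibration phantom** and the threshold-isocontour
  recovery-coefficient measurement, `RC = (C_hot/C_bg)/(a_hot/a_bg)`,
  with a diameter-interpolated lookup table (CSV round-trip);
* a **CT reference pipeline**: largest connected component above a HU
  threshold, exact volume (CTV), long diameter, and nodule consistency
  typing (nonsolid / part-solid / solid);
* an **evaluation framework**: percentage volume error
  `%VE = (MTV − CTV)/CTV × 100`, the ±50% accuracy criterion,
  size (20 mm) and uptake (SUVmax 2) strata, Pearson consistency bands,
  ICC(2,1) observer reliability, and a type-first method recommendation;
* a **synthetic phantom generator** (spherical lesions, Gaussian PSF on
  an oversampled grid, seeded noise, paired CT with analytic truth
  masks) and a one-call study runner, `run_study()`, that goes from a
  YAML-serialisable configuration to evaluation tables and a JSON
  report, deterministically.

## Worked example

Delineate a single synthetic 14 mm nonsolid nodule (pre-blur SUV 1.8 on
a 0.5 background) with all four methods:

```r
library(petmtv)

grid <- default_cohort_grid()                       # 40x24x24 @ 3.27 mm, PSF 4.5 mm
spec <- lesion_spec("nonsolid", long_diameter_mm = 14, lesion_activity = 1.8,
                    background_activity = 0.5, center_mm = c(32.7, 39.2, 39.2))
case <- generate_lesion_phantom(spec, grid, noise_sd = 0.05, seed = 42)

voi    <- lesion_voi(case)
ref    <- segment_ct_volume(case$ct, voi)           # CT reference volume + diameter + type
rc_tab <- calibrate_rc_table(generate_calibration_phantom())
bg     <- measure_background(case$pet, spec$center_mm, lesion_voi = voi)

results <- list(segment_t42(case$pet, voi),
                segment_t42_rc(case$pet, voi, rc_tab, ref$long_diameter_mm),
                segment_aia(case$pet, voi),
                segment_at40(case$pet, voi, bg))
for (r in results) {
  ve <- percent_volume_error(r$mtv_mm3, ref$ctv_mm3)
  cat(sprintf("%-6s T = %5.3f SUV   MTV = %6.0f mm^3   %%VE = %+7.1f   %s\n",
              r$method, r$threshold_suv, r$mtv_mm3, ve, classify_accuracy(ve)))
}
```

```
T42    T = 0.759 SUV   MTV =   1993 mm^3   %VE =   +37.8   within
T42RC  T = 0.637 SUV   MTV =   3217 mm^3   %VE =  +122.5   over
AIA    T = 0.578 SUV   MTV =   4546 mm^3   %VE =  +214.4   over
AT40   T = 1.022 SUV   MTV =   1224 mm^3   %VE =   -15.4   within
```

The true (analytic) lesion volume here is 1446 mm³ and the CT reference
recovers it exactly. On this low-contrast nonsolid lesion the fixed 42%
threshold lands barely above lung background and overestimates; lowering
it further (T42%×RC, and AIA's blend-adapted threshold) swallows more
background; only the background-adaptive AT40% threshold (1.02 SUV, well
clear of the 0.5 background) stays within the ±50% acceptance band —
whereas on large solid lesions AIA and T42% are the accurate choices.
`recommend_method("nonsolid", "small", "low")` accordingly returns
`"AT40"`.

A full simulated study — RC calibration, a 133-lesion cohort
(16 nonsolid / 30 part-solid / 87 solid), four methods, stratified
accuracy, observer-reliability experiment, report files — is one call:

```r
report <- run_study(study_config(), out_dir = "study_out")
print(report)
```

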