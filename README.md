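# eruptq

Measurement-based assessment of mandibular third molar eruption on dental
panoramic radiographs (DPRs), for forensic age assessment research.

Most radiographic eruption methods assign ordinal morphological *stages*.
`eruptq` implements a continuous alternative: annotate four landmarks in the
lower molar region — the highest mesial cusp point of the first molar, the
highest distal cusp point of the second molar (together spanning a
*simplified occlusal line*), and the mesial cementoenamel junction (CEJ) of
the second and third molars — drop perpendiculars from the line to the two
CEJs, and score eruption with the dimensionless quotient

```
Q = d_M2 / d_M3
```

which rises towards ≈ 1 as the third molar erupts. Because both lengths share
the radiograph's local projection magnification, `Q` is invariant to uniform
scaling — the property that makes a ratio preferable to any absolute distance
on non-isometric panoramic images.

The package is aimed at forensic odontology / biostatistics researchers and
provides:

- **Geometry** — occlusal-line construction, signed perpendicular distances,
  quotient measurement with optional 0.1 mm half-up rounding of calibrated
  lengths, Winter-style mesio-distal angulation, and eligibility rules
  (mesial angulation strictly greater than 30° excludes; any distal
  angulation excludes; missing or degenerate geometry excludes with reason
  codes).
- **Agreement statistics** — Spearman's rank correlation with Fisher
  z / Bonett–Wright 95% confidence intervals (or a unit bootstrap), and
  Krippendorff's alpha for continuous ratings (interval or ratio metric,
  missing-tolerant) with cluster-bootstrap confidence intervals.
- **A seeded synthetic cohort generator** — a logistic latent-eruption model
  over an age-by-sex cohort (423 radiographs, ages 15–25, in the packaged
  reference distribution), with per-radiograph magnification and tilt,
  per-rater/session landmark noise, and ground truth returned for recovery
  testing.
- **A study pipeline** — eligibility filtering, vectorized measurement,
  per-tooth/per-sex correlation with age, intra-rater (two sessions of one
  rater) and inter-rater reliability, written out as TSV tables plus a
  full-precision JSON report with provenance.

Annotations travel as long-format CSV/JSON (one landmark per row:
`subject_id, age, sex, side, rater_id, session, label, x, y, mm_per_px`);
see `?read_annotations`.

## Worked example

Simulate a full two-rater annotated cohort and run the complete study:

```r
library(eruptq)

sim <- simulate_cohort(simulator_params(seed = 1))
report <- run_full_study(sim$records, study_config(seed = 1))
report
#> Eruption quotient study report
#>   subjects: 423 (220 female, 203 male); records: 2538 (2289 included)
#>   correlation (rho by tooth x sex):
#>  side    sex   rho   lcl   ucl
#>    38 female 0.725 0.641 0.791
#>    38   male 0.740 0.656 0.806
#>    48 female 0.687 0.596 0.760
#>    48   male 0.746 0.664 0.811
#>   intra-rater alpha:
#>  side    sex alpha   lcl   ucl
#>    38 female 0.991 0.988 0.993
#>    38   male 0.990 0.987 0.993
#>    48 female 0.991 0.989 0.993
#>    48   male 0.994 0.992 0.996
#>   inter-rater alpha:
#>  side    sex alpha   lcl   ucl
#>    38 female 0.993 0.990 0.995
#>    38   male 0.992 0.989 0.994
#>    48 female 0.992 0.990 0.994
#>    48   male 0.992 0.989 0.995
```

Reading the output: each of the four cells is one tooth (FDI 38 = lower
left, 48 = lower right third molar) by sex. `rho` is the Spearman
correlation between the eruption quotient and exact chronological age —
here strong and positive in every cell, as the latent eruption model
implies. The alpha tables give chance-corrected agreement between the two
sessions of rater R1 (intra) and between raters R1 and R2 (inter); values
near 0.99 sit in the "almost perfect" band (> 0.81) and reflect that the
landmark-click noise is small against the between-subject spread of `Q`.
Of the 2538 annotation records, 249 (the distoangulated teeth, ≈ 5% of
radiographs × 3 annotation runs) were excluded by the angulation filter —
`report$exclusions` holds the tally.

Single-record measurement works on any annotation record:

```r
rec <- sim$records[1, ]
measure_quotient(rec, direction = "m2_over_m3", round_lengths = TRUE)
```

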