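# achr — alveolar crestal height from bitewing radiographs

Periodontal bone loss is graded on intra-oral radiographs by measuring the
**alveolar crestal height (ACH)**: the distance from the cemento-enamel
junction (CEJ, where enamel meets cementum) down to the alveolar bone
crestal level (ABCL, the most coronal point of the bone next to the tooth).
An ACH of 5 mm or more at a tooth site is conventionally called *severe*
bone loss. In practice most clinicians only eyeball this distance; automated
pipelines detect the CEJ and ABCL points and the tooth outlines with neural
networks, then need a deterministic geometric post-processing stage to turn
raw detections into per-site millimeter measurements.

`achr` implements that post-processing stage for bitewing radiographs (which
show the maxillary and mandibular arches in one frame), plus everything
needed to validate it without clinical images. It is aimed at people
building or auditing dental CAD systems: the detectors are pluggable, and a
synthetic phantom generator with exact ground truth stands in for them.

## The method

Given landmark detections from two complementary detectors and teeth / bone
segmentation masks, for one image:

1. **Fusion.** The two detectors' landmark sets are pooled and deduplicated
   by greedy non-maximum suppression within each class (ABCL, CEJ): any
   pair closer than *r* = 30 px collapses to the higher-confidence member.
2. **Arch partition.** An ordinary-least-squares line *y = βx + α* is
   fitted through every ABCL-mask foreground pixel; it separates maxillary
   (above) from mandibular (below) landmarks.
3. **Arch curves.** Per arch, least-squares polynomials *y(x)* (default
   degree 2) are fitted to the ABCL points and to the CEJ points — four
   curves in total.
4. **Teeth.** The two teeth masks are unioned; 8-connected components with
   area ≥ 200 px become tooth instances, numbered left to right.
5. **Gate.** A tooth is measured only if its outline crosses both of its
   arch's curves (tolerance band plus sign-change test).
6. **Measurement.** At each tooth side (left/right of the instance, the
   image-frame proxy for mesial/distal), the nearest in-window CEJ and ABCL
   landmarks are paired and
   `ACH = ||CEJ − ABCL||₂ · mm_per_px`,
   with a severe call at `ACH ≥ 5 mm` (configurable rule and threshold).

The calibration `mm_per_px` is a required input — it is sensor-specific and
never guessed.

The package also provides the evaluation suite used to score such a
pipeline: pooled and per-image severity accuracy, severe-class sensitivity
and specificity, and the two-way absolute-agreement single-measurement
intraclass correlation ICC(A,1) for repeated readings.

## Worked example

Generate a synthetic bitewing phantom, simulate noisy detector output
(2 px landmark jitter), run the pipeline, and score it against the known
truth:

```r
library(achr)

ph  <- generate_phantom(phantom_spec(seed = 7))      # 8 teeth, 16 sites
det <- oracle_detect(ph$truth, noise_params(jitter_sigma_px = 2, seed = 7))
fit <- ach_measure(det$landmarks_a, det$landmarks_b,
                   det$teeth_mask_1, det$teeth_mask_2, det$abcl_mask,
                   config = ach_config(mm_per_px = 0.1))
fit
#> Alveolar crestal height measurement -- image
#>   32 fused landmark(s), 8 tooth instance(s), 16 measured site(s)
#>   ACH range 2.29 - 8.48 mm; 12 site(s) severe (>= 5 mm)

head(fit$measurements[c("tooth_id", "site", "ach_px", "ach_mm", "severe")], 4)
#>   tooth_id  site   ach_px   ach_mm severe
#> 1        1  left 22.92594 2.292594  FALSE
#> 2        1 right 52.98315 5.298315   TRUE
#> 3        2  left 84.80193 8.480193   TRUE
#> 4        2 right 66.63765 6.663765   TRUE

evaluate_classification(severity_records(fit$measurements, ph$truth$sites))
#> severity classification on 16 site(s): accuracy 100% (100%)
#>   severe-class sensitivity 100%, specificity 100%
#>   phantom_seed7: n = 16, accuracy 100%
```

Each measurement row is one tooth side: the fused CEJ and ABCL landmark
coordinates, their Euclidean distance in pixels and millimeters, and the
severity call. `plot(fit)` or `render_overlay()` draws the partition line,
the four arch curves, and each ACH segment (red = severe, green = not) over
the radiograph.

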