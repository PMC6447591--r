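# flybeat

Automated heartbeat counting for optical coherence tomography (OCT) B-mode
recordings of the Drosophila heart tube, for labs using the fly as a cardiac
disease model. The heart's five chambers (the conical chamber and four
ostia) appear as dark lumens in bright speckled tissue beneath a bright
dorsal stripe; manual beat counting on such movies is slow and
operator-dependent. `flybeat` segments the chambers frame by frame and
counts beats from the chamber-area signal.

The pipeline:

1. **Detection** — frames are smoothed by opening/closing by morphological
   reconstruction; chamber seeds are regional minima screened by their
   vertical distance to the dorsal back stripe.
2. **Segmentation** — distance-regularized level-set evolution minimizing
   `E(φ) = μ R_p(φ) + λ L_g(φ) + α A_g(φ)`, with the double-well
   regularizer `p`, geodesic length weighted by the edge indicator
   `g = 1/(1 + |∇(G_σ * I)|)`, and a balloon term (`α < 0` expands; the
   field is negative inside a chamber).
3. **Shape prior** — a PCA point-distribution model (45 landmarks per
   contour, one retained mode) trained on delineated contours adds a
   distance energy `β D(φ, φ_ref)` once the chamber grows past an area
   threshold, pulling the zero set onto the area-scaled, centroid-aligned
   model contour; this stops leaks through weak or missing wall segments.
4. **Counting** — per-frame areas are Gaussian-smoothed (`S_a = G(A_m)`)
   and beats are the local peaks (discrete `S′ = 0 ∧ S″ < 0` with a
   prominence gate); `rate = beats · fps / M`.
5. **Evaluation** — Dice overlap `2|A∩B|/(|A|+|B|)` and the symmetric mean
   contour distance, reported per chamber as mean ± sd.

A synthetic beating-chamber phantom generator (bright back stripe,
multiplicative gamma speckle, dark elliptical lumens with bright walls,
optional weak-boundary gaps, full per-frame ground truth) makes every stage
testable without animal recordings. See the methods vignette
(`vignettes/flybeat-methods.Rmd`) for the model details and parameter
rationale.

## Worked example

```r
library(flybeat)

ph  <- generate_phantom(phantom_spec(n_frames = 200, rng_seed = 11))
ph
#> <phantom: 200 frames 96x160 @ 100 fps, 3 chamber(s), true beats: 10, 10, 10>

run <- run_pipeline(ph$sequence, truth_masks = ph$truth_masks)
run
#> <flybeat_run: back row 16, 3 chamber(s)>
#>   C1: 10 beats, 5.00 beats/s
#>   C2: 10 beats, 5.00 beats/s
#>   C3: 10 beats, 5.00 beats/s
#> Evaluation (per chamber, mean +/- sd over frames)
#> Chamber    Dice                   Mean distance (px)
#> C1         0.99 +/- 0.00           0.19 +/- 0.05
#> C2         0.99 +/- 0.00           0.12 +/- 0.06
#> C3         0.99 +/- 0.00           0.12 +/- 0.06
```

The three chambers beat at 5 beats/s for 2 s, so 10 beats each is exact
recovery; Dice near 1 and sub-pixel mean contour distance say the segmented
masks almost coincide with the analytic truth. With a weak-boundary phantom
(`gap_fraction = 0.25`) the no-prior baseline leaks through the erased wall
(Dice ≈ 0.46) while segmentation with a trained shape model stays on the
chamber (Dice ≈ 0.96) — the mechanism the shape prior exists for:

```r
fam   <- generate_training_contours(28, 45, chamber_spec(c(55, 64), c(22, 16), phase = pi/2),
                                    variation_scale = 2.5, rng_seed = 100)
model <- train_shape_model(fam, 45, resample = FALSE)
model
#> <shape_model: 45 landmarks, 28 training contours, 1 component(s) explaining 95.5% variance>
```

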