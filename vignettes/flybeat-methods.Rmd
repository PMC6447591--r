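---
title: "Methods: shape-prior level-set segmentation and heartbeat counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-prior level-set segmentation and heartbeat counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flybeat)
```

## The problem

The Drosophila heart is a tube of five contractile chambers — the conical
chamber and four ostia — that appears on optical coherence tomography (OCT)
B-mode cross-sections as dark, nearly echo-free lumens surrounded by bright
speckled tissue, beneath a bright dorsal ("back") stripe. A healthy adult
beats at roughly 4–6 beats/s; at 100 frames/s a recording resolves each
contraction with ~20 frames. Manual beat counting on B-mode movies, or
M-mode lines placed by hand, is slow and operator-dependent. `flybeat`
automates the whole chain: locate the chambers, segment every frame, convert
the per-frame chamber area to a 1-D signal, and count its peaks.

Conventions used everywhere: raster indices are `(row, col)`; contour
coordinates are `(x = col, y = row)`, 0-based, sub-pixel, with pixel centres
at integers; intensities are normalized to `[0, 1]` at load; the level-set
field is negative inside a chamber.

## Chamber detection

Lumens are the darkest structures below the back stripe, so seeds are
regional minima. Raw minima are speckle-sensitive; the frame is first
smoothed by *opening-by-reconstruction* followed by
*closing-by-reconstruction* with a disk (radius 3 px by default). Unlike
plain opening/closing, reconstruction filtering removes extrema smaller
than the disk while leaving every surviving boundary exactly in place. The
back stripe is the row maximizing the row-wise mean of the smoothed frame
(it must exceed the global mean by a contrast margin, 0.1 by default).
Regional minima are equal-value plateaus (8-connectivity) whose outer
neighbours are all higher; plateaus touching the image border are treated
as open background. Each minimum grows into its basin — the connected
component within `h = 0.05` of the minimum value — and basins are kept when
their centroid lies 8–80 rows below the back and their area reaches 30 px².
The band and area limits are configuration parameters calibrated on the
bundled phantoms; overlapping basins keep the deeper minimum.

## Level-set segmentation

The chamber contour is the zero level set of a field $\phi$ evolving by
explicit gradient descent on

$$E(\phi)=\mu R_p(\phi)+\lambda L_g(\phi)+\alpha A_g(\phi),$$

with the distance-regularizing double-well potential
$p(s)=\tfrac{1}{(2\pi)^2}(1-\cos 2\pi s)$ for $s\le 1$ and
$\tfrac12(s-1)^2$ for $s\ge 1$ (minima at slopes 0 and 1, so the field
stays distance-like without re-initialization), the geodesic length
$L_g=\int g\,\delta(\phi)|\nabla\phi|$, and the weighted area
$A_g=\int g\,H(-\phi)$. The edge indicator is
$g = 1/(1+|\nabla(G_\sigma * I)|)$. The update per step is

$$\phi \leftarrow \phi + \Delta t\left[\mu\,\mathrm{div}(d_p(|\nabla\phi|)\nabla\phi)
+\lambda\,\delta_\varepsilon(\phi)\,\mathrm{div}\!\left(g\tfrac{\nabla\phi}{|\nabla\phi|}\right)
+\alpha\,g\,\delta_\varepsilon(\phi)\right],$$

with central differences, a Neumann border condition, a $10^{-10}$ floor on
$|\nabla\phi|$, and the smoothed Dirac
$\delta_\varepsilon(x)=\tfrac{1}{2\varepsilon}(1+\cos\tfrac{\pi x}{\varepsilon})$
on $|x|\le\varepsilon$. $\alpha<0$ inflates the region (balloon),
$\alpha>0$ deflates it.

**Parameter defaults and why.** On the `[0, 1]` intensity scale the smoothed
gradient of even a strong edge is only ~0.2–0.25, so $g \gtrsim 0.8$
everywhere — edges brake the balloon only weakly, and the geodesic
attraction $\lambda|\nabla g|$ does most of the stopping. The expansion
window is therefore narrow: the balloon must beat the curvature shrinkage
of the seed ($|\alpha| > \lambda/r_{\text{seed}}$) yet stay below the edge
capacity $\lambda(|\nabla g|/g + \kappa)$. The defaults $\mu = 0.2$,
$\lambda = 5$, $\alpha = -0.6$, $\sigma = 1$ px, $\varepsilon = 1.5$ px,
$\Delta t = 0.5$, $c_0 = 2$ were calibrated once on the bundled disk and
phantom geometries; $\Delta t = 0.5$ keeps the explicit curvature step
stable (here $g$ is $O(1)$ near edges, unlike on 0–255-scale images), and
$\Delta t\,\mu < 0.25$ is enforced. Convergence is declared when the
$L^\infty$ field update *on the interface band* $|\phi|\le\varepsilon$
stays below `conv_tol = 0.002` for 5 consecutive iterations (far from the
zero set the regularizer keeps rebuilding the distance profile long after
the contour has stopped; judging convergence globally would never
terminate a warm-started frame).

## The PCA shape prior

Weak or missing wall segments (typically the lower wall of a dilated
conical chamber) let an edge-driven contour leak. The remedy is a point
distribution model: training contours are resampled to 45 landmarks equally
spaced in arc length — starting where the contour crosses the downward
vertical ray from its centroid, counter-clockwise, so landmarks correspond
across contours (a literal "maximum-y vertex" start is unstable: landmark
jitter near the ventral apex shifts the whole correspondence cyclically) —
centred, stacked as 90-vectors, and the covariance eigendecomposed. One
component is retained by default. Reconstruction is the standard
$Y=\bar X+\sum_k b_k p_k$ with scalar coefficients.

During segmentation the evolution runs plainly while the region is smaller
than an area threshold `th`; once past it, the model mean contour is scaled
isotropically so its polygon area equals the current region area,
translated onto the region centroid (no rotation — the chambers keep a
stable orientation in B-mode), and the force
$\beta\,\delta_\varepsilon(\phi)\,d_{\text{model}}$ is added, where
$d_{\text{model}}$ is the signed distance to the aligned model polygon
(negative inside it). The force advects the zero set onto the nearest
model point from either side. In the pipeline `th` defaults to 1.3 × the
median chamber area of a first no-prior pass; the prior is needed only when
the chamber dilates past its typical size.

**Balloon hand-off.** Because the model is rescaled to the current area
every iteration, it carries no size information: if the balloon stays on at
full strength while the prior acts, any leak inflates the model, whose
outward pull at edge-pinned wall sections ($\beta d \approx |\alpha| g
\times$ the leak/pinned perimeter ratio, independent of $\beta$) eventually
breaches true walls and the area runs away. During prior-active iterations
the balloon is therefore scaled by $\max(0, 1-\beta/\beta_{\text{full}})$
(with $\beta_{\text{full}} = 0.5$, the default weight): at working strength
the shape force *replaces* the balloon as the motive force, which is
stable, while $\beta \to 0$ recovers the plain evolution continuously and
$\beta = 0$ or `th = Inf` reduce to it bitwise. On a featureless image the
active prior is a pure shape attractor: the zero set settles on the aligned
model contour (the region size itself then drifts slowly under curvature —
shape, not size, is constrained by design).

## Heartbeat counting

Per-frame chamber areas are smoothed by a 1-D Gaussian (reflect borders;
$\sigma$ = frame_rate/50 frames, i.e. 2 frames at 100 fps) and interior
local peaks are flagged by the discrete analogue of $S'=0 \wedge S''<0$:
a strict rise and a weak fall, so plateaus count once at their first frame
and endpoints never count. A topographic-prominence gate (default 1% of the
series range; set 0 for the literal curvature rule) suppresses micro-ripples
that survive smoothing. The count is the number of flagged peaks and the
rate is `count * frame_rate / M` beats/s.

## Evaluation metrics

Dice is $2|A\cap B|/(|A|+|B|)$ (two empty masks count as identical). The
mean contour distance is the symmetric average of nearest-point distances,
$\big[\sum_{a} d(a, B)+\sum_{b} d(b, A)\big]/(|A|+|B|)$, with point-to-set
distance measured to the other contour's *segments*, not vertices; the
denominator is the sum of the two cardinalities. Sequence evaluation traces
mask boundaries by marching squares and reports per-chamber mean ± sd of
both metrics.

## The synthetic phantom

Real recordings of beating hearts with expert delineations are not
distributable, so the package validates against a phantom that reproduces
the features the algorithms actually depend on: a bright back stripe, a
dark background above it, multiplicative unit-mean gamma speckle (OCT
speckle is multiplicative; `speckle_strength` is the multiplier's sd,
default 0.1), bright elliptical walls around dark lumens at `lumen_level <
tissue_level`, semi-axes modulated as $a(t)=a(1+A\sin(2\pi f t+\varphi))$,
and an optional "weak boundary": a contiguous angular arc of the wall
(fraction `gap_fraction` of the perimeter, centred on the lower wall by
default) erased to lumen intensity. Ground-truth masks, analytic sub-pixel
contours, and the beat count $\lfloor f\,M/\text{fps}\rfloor$ come from the
construction itself. Training families for the prior add a known
unit-norm radial $\cos 2\theta$ deformation mode and small landmark jitter
(0.04 px), keeping the dominant mode analytically recoverable.

What the phantom does *not* emulate — depth-dependent attenuation, A-scan
physics, neighbouring organs, motion blur, non-elliptical lumens (the
spec's tubular chambers are approximated by ellipses) — bounds what passing
tests show: they validate the algorithms' mechanics and their behaviour
under speckle and weak boundaries, not performance on any particular
instrument's recordings.

## Problem sizes and numerical choices

The bundled study cases are a 128 × 128 analytic disk (radius 30 px), single-
chamber 96 × 128 weak-boundary phantoms, and a 200-frame, 96 × 160,
3-chamber phantom at 5 beats/s and 100 fps; beat-count validation runs
3–7 beats/s × 1–10 s on 64 × 64 single-chamber phantoms. In the pipeline
each chamber is evolved on a window 16 px beyond its seed bounding box
(frames move the contour by ~1 px at 100 fps), warm-started from the
previous mask eroded by 2 px so the seed stays interior during
contraction; a centroid jump above 15 px triggers re-detection, and area
gaps up to 5 frames are interpolated linearly. Ties, floors and degenerate
inputs: overlapping basins keep the deeper minimum; $|\nabla\phi|$ is
floored at $10^{-10}$; single-signed fields raise a degenerate-field error;
identical training contours are allowed only with `n_retained = 0`
(the covariance rank is checked).

## Known limitations

- Alignment of the prior is translation + isotropic scale only; rotated or
  sheared chambers would need a Procrustes step.
- One retained component suffices for the bundled families; multi-modal
  shape spaces are untested.
- The explicit solver is full-grid within each chamber window; very large
  frames would want a narrow-band scheme.
- Chamber identity across frames is nearest-centroid association, adequate
  at 100 fps but not for slow acquisitions.
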