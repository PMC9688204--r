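---
title: "Scala tympani geometry and the Capstan model of insertion forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scala tympani geometry and the Capstan model of insertion forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaST)
```

## The problem

A straight cochlear-implant (CI) electrode array inserted through the round
window slides along the outer (lateral) wall of the scala tympani (ST), the
spiral chamber of the cochlea. The friction between the array and the wall
is amplified by the wrap of the spiral in the same way a rope wrapped
around a bollard amplifies a restraining force, so the insertion force is
governed by how far *around* the spiral the tip has travelled - the angular
insertion depth - rather than by how many millimetres of array have been
fed in. cochleaST implements the whole in-silico workflow around that
claim: parametrising ST geometry from a surface mesh, procedurally
manipulating that geometry one factor at a time, reconstructing watertight
meshes for 3D printing, and simulating and fitting insertion-force traces.

## Geometry parametrisation

The inputs are a triangulated ST lumen mesh (PLY/STL, mm) and an ordered
set of landmarks along the basilar-membrane edge (68 by default, base to
apex). The pipeline is:

1. **Basal plane** (`fit_basal_plane`): a total-least-squares plane through
   the landmarks of the first 270 degrees of the basal turn, fitted by SVD.
   The subset is chosen with a provisional all-landmark plane, then
   refitted. The normal is oriented so apical landmarks lie at positive
   height. For a rising spiral this plane is genuinely tilted relative to
   the generator's reference plane (about 9 degrees for the default
   fixture); heights and radii inherit that tilt, which is a property of
   the measurement definition, not an implementation artefact.
2. **Cross-sections** (`extract_cross_sections`): the mesh is cut by a
   plane through each landmark whose normal is the local trajectory
   tangent (centred differences; second-order one-sided stencils at the
   ends - a first-order end tangent cuts the tapering basal funnel
   obliquely and inflates its radius and area). Cutting planes usually
   slice several turns of the spiral; the connected intersection component
   nearest the landmark is kept.
3. **Properties** (`section_properties`): planar shoelace area, polygon
   centroid, and lateral-wall height, defined as the ring extent along the
   projection of the basal-plane normal into the section plane. Measuring
   the extent within the section plane (rather than along the tilted
   global normal) makes the height of an upright ring exact.
4. **Centreline and spiral fit** (`build_centreline`, `fit_spiral`): the
   in-plane radii of the section centroids are fitted with the continuous
   double-exponential radius law

   $$R(\theta) = R_{scale}\,\bigl(e^{-\theta/\theta_1} + e^{-\theta/\theta_2}\bigr),$$

   with $\theta$ in degrees, $\theta_1$ capturing the basal flaring and
   $\theta_2$ the central spiral. The fit co-estimates the 2D spiral
   centre and a small angular origin offset $\theta_0$ (the basal-most
   landmark need not sit at the spiral's nominal origin; without
   $\theta_0$, an inset of a few degrees shifts both exponential terms and
   parameter recovery cannot be exact). Levenberg-Marquardt
   (`minpack.lm::nls.lm`) is run from a 3x3 multi-start grid
   ($\theta_1 \in \{45, 90, 180\}$, $\theta_2 \in \{180, 360, 720\}$);
   because the model is symmetric in the two terms, the result is
   canonicalised to $\theta_1 \le \theta_2$. Constant-radius data drives
   $\theta_2$ to huge values; the fit then returns with a `degenerate`
   flag and a warning rather than failing.
5. **Angle-distance map** (`build_angle_distance_map`): cumulative chord
   length along the landmarks (the lateral-wall path the array follows)
   against unwrapped in-plane angle about the fitted centre, exposed as a
   monotone piecewise-linear map in both directions. This is the bridge
   between commanded insertion distance (mm) and angular depth (degrees).

## Shape manipulations

Each manipulation isolates one geometric factor:

* `scale_volume(mesh, ratio)` multiplies vertices by `ratio^(1/3)` about
  the vertex centroid, so a "large" model at 110% volume uses ratio 1.10.
* `flatten(stack)` translates each section along the basal-plane normal to
  zero centroid height. With the vertical separation gone, the inner part
  of the spiral eventually collides with the turn outside it; the stack is
  truncated at the first section whose projected radial interval reaches
  the radially aligned section one turn further out.
* `add_non_planarity(stack, amplitude, period)` adds a vertical sinusoid
  `amplitude * sin(360 * theta / period)` over the first 270 degrees. The
  sine (not cosine) convention with zero phase guarantees the displacement
  vanishes at both 0 and 270 degrees for periods of 270 and 135 degrees,
  avoiding a step at the boundary; the period must divide the extent so
  this holds, and the default amplitude in the experiment suite is 0.2 mm.
* `reshape_curvature(stack, m)` recomputes target radii from the fitted
  spiral with $\theta_2 \mapsto m\theta_2$ (doubling loosens, halving
  tightens the central spiral), moves each centroid radially at its
  original angle, and rigidly re-orients each ring to the new local
  tangent. Rings are transported in a (lateral, up, tangent) orthonormal
  frame derived from the basal-plane normal, which prevents twist from
  accumulating along the spiral. In the experiment pipeline curvature is
  reshaped *before* flattening so the flat-model truncation reflects the
  reshaped spiral's own inter-turn clearance.
* `uniformise_cross_section(stack, depth)` replaces every ring with the
  ring found at `depth` mm of lateral-wall arc (1 mm by default),
  transported rigidly to each section's frame; the centreline is
  untouched, so only the cross-sectional profile changes.

## Lofting and deviation analysis

`loft` rebuilds a surface from an ordered section stack: rings are sorted
clockwise as seen from the base along the advancing tangent, resampled to
100 points by uniform arc length, seam-aligned by nearest-point start
correspondence (naive index alignment produces visible twist bands),
triangulated band by band, and capped with centroid fans. A fully capped
loft is watertight with consistent outward winding (every directed edge
used exactly once in each direction; flipped globally if the signed volume
comes out negative).

`prepare_print_model` re-lofts with the print conventions: the chord of
the first 15 degrees of centreline along +x (exactly; the basal-plane
normal goes as close to +z as orthogonality allows for a rising
centreline), an open basal boundary for a consistent entry trajectory, and
an apical access hole for flushing. The hole is built directly into the
apical cap as an annulus down to a 0.6 mm circle rather than by a boolean
subtraction of a cylinder - the direct construction cannot fail on
tangential intersections and leaves exactly the intended two boundary
loops (base opening and vent).

`nominal_actual_deviation` samples the test surface uniformly by area
(seeded), finds exact nearest points on the reference mesh with a
uniform-grid accelerated point-to-triangle search (compiled via Rcpp; an
exhaustive R implementation cross-checks it in the tests), signs distances
by the reference face normals, and reports 50/90/95/100% quantiles of the
absolute deviation in micrometres. The default 1e5 samples keep the 90th
percentile stable to well under a micrometre on the fixture meshes.

## The Capstan force model

The classical Capstan relation $T_1 = T_2\,e^{\mu\theta}$ (`capstan_load`)
becomes, for a CI sliding along the lateral wall,

$$F(\theta) = F_{tip}\,e^{\mu'(\theta - \theta_{contact})},$$

where $F_{tip}$ (mN) is the tip-bending force at first lateral-wall
contact, $\theta_{contact}$ the angular depth of that contact (100 degrees
by default, configurable per condition), and $\mu'$ (per degree) an
effective exponential coefficient folding in friction, surface roughness
and the spiral geometry. `simulate_insertion` produces a full
insert-hold-retract trace at 0.5 mm/s with additive i.i.d. Gaussian force
noise; the hold phase decays exponentially (rate 5 per hold duration,
shifted so the end value is hit exactly) to 0.69 times the maximum
insertion force - the published median relaxation ratio - and retraction
mirrors the insertion profile scaled by the same ratio. The hold and
retract shapes are simulator conveniences for exercising the metrics, not
mechanistic claims; no relaxation mechanism is modelled.

`fit_capstan` fixes $F_{tip}$ (tip forces at first contact are essentially
identical across insertions of one experiment) and estimates $\mu'$ by
zero-intercept least squares of $\ln F - \ln F_{tip}$ on
$\theta - \theta_{contact}$ over the insert phase from contact to maximum
insertion, reporting $r^2$ on the linear scale. `compare_groups` runs
one-way ANOVA across condition groups with Tukey HSD pairwise comparisons
at $\alpha = 0.05$ (plus unadjusted Welch p-values for cross-checking
against resampling tests).

One measurable subtlety: because $E[\ln(F + \varepsilon)] < \ln F$, the
log-scale fit carries a small negative bias that shrinks with force, so
conditions inserted to different depths acquire a systematic offset in
$\hat\mu'$ of order 0.1-0.2% under the default noise level. Per-trace
fits are precise enough (hundreds of samples) that a comparison across
unequal depths can resolve this purely numerical offset; equal-depth
comparisons are calibrated at the nominal 5% type-I rate.

## The synthetic fixture cochlea

`generate_st` builds the test-bench ST without any imaging data: the
centreline follows the double-exponential law with a linear vertical rise,
sections are superellipse rings (exponent 3 - slightly boxier than an
ellipse, closer to the rounded-triangular ST section), and landmarks sit
on the superior-lateral ring point (the basilar-membrane edge analogue),
evenly spaced in arc length as a human annotator would place them. Areas
interpolate log-linearly through (0 mm, 2.6 mm^2), (1 mm, 2.5 mm^2) and
(20 mm, 1.0 mm^2) of lateral-wall arc distance, and lateral-wall height
linearly from 1.6 to 0.9 mm over the same extent - the published
anatomical anchors.

The spiral defaults (`R_scale` 1.6 mm, $\theta_1$ 90, $\theta_2$ 900,
810 degrees total, 4.2 mm rise) were chosen once, by constrained search,
to satisfy simultaneously: a 20 mm insertion exceeding 540 degrees of
angular depth (as in published insertion figures); no self-overlap of the
tube around the spiral axis anywhere along its length; three-dimensional
clearance between consecutive turns (including for the uniform
cross-section variant, whose full-height rings need the larger rise); and
a plausible basal lateral-wall diameter (7.9 mm). These constraints
genuinely conflict with a longer first-turn arc: with the anchored section
sizes, a lateral wall reaching 540 degrees within 20 mm forces a first
full turn of about 15-16 mm of arc rather than the ~20 mm of an average
human cochlea, so the fixture is best read as a slightly tight but
valid cochlea. A consequence worth knowing: the flattened model truncates
at ~399 degrees (16 mm of lateral wall), so flat-family conditions are
inserted to the available depth, mirroring the reduced 17 mm depth used
for constrained physical models; the experiment report records every
clamp. The uniform cross-section variant is geometrically meaningful over
the insertion extent; near the apex its full-size rings graze the spiral
axis and sectioning planes there no longer isolate a single local ring,
so verification samples the basal 15 mm.

What the generator does *not* emulate: population anatomical variation,
left/right chirality, the non-elliptic bumpiness of real segmentations,
segmentation noise, and any mechanical compliance of the wall. Passing
tests on the fixture therefore demonstrate the correctness of the
geometry and inference machinery, not clinical realism.

## Numerical choices and problem sizes

* Rings cut from faceted meshes carry micrometre-scale zigzags where the
  plane grazes mesh edges; the ring-simplicity test ignores crossings
  whose segments are both below 0.1% of the perimeter so that facet noise
  is not misread as a figure-eight.
* Spiral fitting works on log-transformed positive parameters, with
  tight (1e-15) convergence tolerances so noiseless recovery is exact to
  numerical precision.
* Default fixture sizes keep everything interactive: 163 sections of 100
  points, a ~36k-triangle mesh (~0.5 s to generate), full
  characterisation in ~2 s, and the complete nine-condition experiment
  with ten insertions per condition in well under a minute. Tests use
  2e4-3e4 deviation samples; the deviation default is 1e5.
* All stochastic steps (force noise, surface sampling, replicated
  datasets) consume explicit seeds, and the experiment pipeline derives
  every sub-seed from one master seed, so reports are bit-reproducible.

## A minimal session

```{r example, eval = FALSE}
st <- generate_st()
char <- characterise_st(st$mesh, st$landmarks)
char$spiral

map <- char$map
trace <- simulate_insertion(insertion_model(), map, noise_sd = 2, seed = 1)
fit_capstan(trace, F_tip_fixed = 10, contact_angle = 100)

res <- run_experiment(experiment_config(n_reps = 10, seed = 1),
                      out_dir = "st_experiment")
res$comparison
```

## Known limitations

* The basal-plane tilt of a rising cochlea propagates into the in-plane
  radii, so spiral parameters recovered through the fully estimated plane
  are a few percent off the generator truth; recovery through the known
  reference plane is within 2%. Real applications have no generator truth
  and simply report the fit and its rmse.
* The simulator's hold/retract phases are phenomenological; relaxation
  metrics computed on simulated traces validate plumbing, not physics.
* Mesh booleans are deliberately absent; print preparation covers the
  open base and apical vent but not mounting fixtures.
* `flatten`'s truncation test compares section rings one turn apart; it
  assumes the stack is sampled finely enough (a few degrees) that tube
  overlap between sections is captured by ring overlap.
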