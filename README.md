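# cbctreorient

Landmark-free, PCA-based reorientation of serial cone beam CT (CBCT) head
volumes.

## The problem

Serial CBCT scans of the same patient are captured in poorly reproducible
head poses, and the usual fix — manually labelling landmarks to construct
reference planes such as the Frankfurt horizontal — is itself a major source
of inter- and intra-examiner variability. This package assigns each volume
an *individualized global axis* derived purely from bone-surface geometry,
so that serial volumes land in a common head frame with no operator input.
It is aimed at orthodontic / orthognathic imaging workflows that compare
longitudinal CBCT records (T0, T1, T2).

## The method

For each volume, in the working frame (+x patient-left, +y anterior,
+z superior):

1. **Bone segmentation** — three-class Otsu thresholding of the intensity
   histogram (air | soft tissue | bone), largest 26-connected component,
   morphological closing.
2. **Nose tip** — the skull is concave except near the nasal apex, so the 3D
   convex hull of the bone surface touches it only there; hull vertices
   inside a naso-orbital ROI within 2 mm of the anterior extreme are
   averaged into the tip.
3. **Arrangement** — each volume is translated so its tip sits at the
   origin.
4. **Axes** — over the bone voxels *P* inside a 35 mm sphere at the tip, the
   eigenvector of the smallest eigenvalue of `cov(P)` is the
   anteroposterior axis `y` (the bone is locally a thin plate, thinnest
   through the face); the binarized projection of *P* along `y` gives the
   transverse axis `x` through the two far ends of its inferior half; and
   `z = x × y` completes the right-handed frame. The volume is resampled
   into these axes about the tip.
5. **Evaluation** — alignment of a serial pair is the symmetric Hausdorff
   distance `HD(A,B) = max( max_a min_b ‖a−b‖ , max_b min_a ‖a−b‖ )`
   between forehead surfaces (anterior surface voxels 20–70 mm above the
   tip); *matching improvement* is the percentage reduction of HD from the
   arrangement-only state to the reoriented state.

A synthetic head phantom (ellipsoidal bone shell, paraboloid nose with
closed-form apex, orbital concavities, zygomatico-maxillary ridges,
mandibular wedge with adjustable menton deviation, soft tissue, Gaussian
noise) provides exact ground truth for every stage, and k-medoids (PAM)
clustering with silhouette scoring stratifies simulated cohorts by clinical
asymmetry magnitude.

## Worked example

Simulate three serial captures of one subject (random rigid pose changes up
to 10° / 10 mm) and reorient them:

```r
library(cbctreorient)

ph <- phantom_generate(phantom_spec())   # default head, 1 mm voxels
set.seed(1)
vols <- lapply(1:3, function(i) {
  phantom_perturb(ph$volume, ph$truth,
                  angles_deg     = runif(3, -10, 10),
                  translation_mm = runif(3, -10, 10), seed = i)$volume
})
reorient_serial(vols)
```

```
<serial_report> 3 volume(s)
  T0: tip (5.3, 123.5, -13.8) mm, rotation 8.04 deg
  T1: tip (-13.9, 124.8, 0.0) mm, rotation 6.52 deg
  T2: tip (-11.1, 134.8, 5.8) mm, rotation 5.92 deg
 pair hd_before hd_after improvement_pct
 T0T1  22.81176 4.087772        82.08042
 T0T2  16.07909 4.556233        71.66361
 T1T2  10.51924 4.267303        59.43333
```

Each volume's detected nose tip and the net rotation applied by its new
frame are listed first; `rotation` is the angle between the estimated head
frame and the scanner frame (here 6–8°, i.e. the simulated poses were
substantially off-axis). The pair table shows the forehead-surface
Hausdorff distance before (tips matched, no rotation) and after
reorientation: the pose scatter of 10–23 mm collapses to ~4 mm, an
improvement of 59–82% per pair.

File-based workflows use the same functions via `load_volume()` /
`load_dicom_series()` / `save_volume()`, or the thin command-line wrapper
`exec/cbct-reorient` (`run`, `convert`, `segment`, `nosetip`, `cluster`,
`phantom` subcommands).

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline simulation figure
from scratch: it generates the default phantom, creates three serial copies
with seeded random rigid perturbations (rotations uniform in ±10° per axis,
translations uniform in ±10 mm), runs segmentation → nose tip →
arrangement → PCA orientation → reorientation, scores the three serial
pairs by forehead Hausdorff distance before and after, and averages the
mean percentage improvement over five seeded repetitions.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The `--seed` argument drives every source of randomness, so a given seed
reproduces the report exactly.

## Documentation

The methods vignette (`vignettes/reorientation-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the phantom does and does not emulate, numerical tie-breaks and
degenerate-input handling, and known limitations.
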