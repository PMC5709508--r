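---
title: "The rhizohair growth model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rhizohair growth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rhizohair)
```

## The model

Root hairs elongate by adding material at the tip. rhizohair idealises a
hair as a polyline grown step by step through a labelled voxel volume in
which four phases matter to growth:

* **primary mineral (P)** -- hard grains, impenetrable (and so is the
  root itself);
* **hydrated textural (S)** -- the clay/silt/organic matrix holding most
  soil water; hairs may enter it;
* **gaseous pore** -- air-filled voids in which hairs grow nearly
  straight;
* **outside** -- beyond the domain boundary; not a valid growth target.

Each growth step places `n` quasi-equally spaced test points on a sphere
of radius `r` about the current tip (a generalised spiral construction:
heights $z_i = -1 + 2(i-1)/(n-1)$, azimuth increments
$3.6/\sqrt{n(1-z_i^2)}$, poles handled explicitly). Test vectors are
classified by their true included angle against a *reference heading*
into `k` sets of width $\pi/(2k)$; vectors at or beyond $\pi/2$ are
discarded, as are vectors whose end-point leaves the domain, enters a
mineral grain or the root, or (under condition F1, when the tip is in S)
leaves S. The growth vector is drawn **uniformly at random** from the
lowest-angle non-empty set; if no set has a valid vector, growth ceases.
A hair of virtual length $l_v$ takes $\lfloor l_v/r\rfloor$ full steps
plus one shorter final step, so the achieved length equals $l_v$ exactly
unless the hair is trapped.

The four growth conditions combine two switches:

* **A0 / A1** -- the reference heading stays at the seed's initial vector
  (rigidity-limited hairs) or follows the previous growth vector
  (geometry-dominated hairs). Under A1 repeated grain contacts can turn a
  hair more than $\pi/2$ from its original heading, i.e. back towards the
  root.
* **F0 / F1** -- hairs cross fluid boundaries freely, or are confined to
  the textural phase once their tip is inside it (surface-energy
  constraint at pore/fluid interfaces). We apply the F1 rule from the
  first step, including seeds whose transition point already sits in S.

## Length assignment by survival analysis

Hair length populations are unimodal and normal-like; a two-parameter
Weibull (location fixed at 0) covers them. A partially visible hair of
length $l_r$ is treated as having "survived" to $l_r$; its remaining
length is drawn from the future-lifetime law
$p(l) = f(l + l_r)/(1 - g(l_r))$ with the closed-form inversion
$l_v = \beta[(l_r/\beta)^\alpha - \ln(1-u)]^{1/\alpha} - l_r$,
$u \sim U(0,1)$ drawn from the open interval. The inversion is verified
against numerical root-finding of the conditional CDF to better than
$10^{-6}$ in the tests.

One caveat is worth stating precisely: resampled totals $l_r + l_v$
follow the fitted Weibull *truncated at each seed's* $l_r$. The marginal
over a population with non-degenerate $l_r$ is therefore **not** the
fitted Weibull; only a fully synthetic population ($l_r = 0$, the
standard use here) reproduces the fitted distribution exactly. The tests
check the conditional law via its probability integral transform.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| step length `r` | 32 | um | must stay below the smallest surviving grain diameter; grain filter threshold equals `r` |
| fan size `n` | 100 | points | dense enough that the lowest bin is never artificially empty |
| bin count `k` | 4 | sets | bin width 22.5 degrees; upper bound of deviation per step is 90 degrees |
| hair density | 121 | mm^-2 | canonical surface initiation density |
| total length `c` | 500 | um | encompasses the observed hair length range |
| shell width | 50 | um | profile integration distance |
| grain filter | 32 | um | equivalent-sphere diameter below which grains are removed |

Removed grains are relabelled to the majority face-adjacent non-mineral
phase (ties and enclosed grains fall back to textural); the replacement
phase is not dictated by the problem, and this choice avoids creating
spurious pore channels inside otherwise textural regions.

## What the synthetic geometries emulate

* **Sphere packings** (BCC/HCP, 90 and 270 um) are exact lattices of
  touching spheres. Each domain axis is snapped to a whole number of unit
  cells and seam spheres are completed periodically, so the voxelised
  mineral fraction converges on the analytic packing density
  ($\pi\sqrt3/8$, $\pi/\sqrt{18}$). The initiation face then coincides
  with a lattice plane; note that for BCC no axial plane avoids slicing
  spheres (layer spacing is $1.155\,r$), so seeds necessarily start
  between sphere cross-sections.
* **Three-phase soil** stands in for a segmented soil cube: a Gaussian
  random field smoothed at a 100 um correlation length (the order of
  small grain diameters) and double-thresholded at empirical quantiles
  into mineral (upper tail, grain-like blobs), a textural band adjacent
  to the mineral, and pore. Realised fractions match the request to well
  within 1%. The noise is generated on a 3-sigma-padded grid and cropped:
  smoothing with reflected boundaries would otherwise inflate the field
  variance at the faces and deplete the middle (textural) band exactly
  where near-surface wet statistics are measured.
* **Cylindrical domains** wrap a three-phase annulus (default 600 um of
  soil) around an explicit 600 um diameter root; voxels beyond the
  annulus are labelled outside.

What these fixtures do **not** emulate: real grain shape and size
distributions, spatial correlation between phases beyond a single
length scale, anisotropy, or the pore-network connectivity of real
rhizosphere soil. A green qualitative test on them establishes that the
algorithm responds to explicit structure in the stated directions, not
that any quantitative profile matches a real soil.

## Morphometrics

Profiles accumulate hair length into 50 um distance shells from the
initiating surface; every segment is subdivided into ~1 um sub-segments
(well below both shell width and voxel size; worst-case attribution
error below 2%) and each sub-segment accrues to the shell containing its
midpoint, with the wet profile additionally requiring the midpoint voxel
to be textural. Profiles are plain length per shell -- no volume
normalisation -- so cartesian and cylindrical cases compare directly.
Controls grown into an empty domain approximate their wet profile as
$L_{wet} = j\,L_{tot}$, with $j$ the textural fraction of the
non-mineral domain.

Periodicity detection subtracts a centred 3-shell moving-average trend
before autocorrelation: profiles decay away from the surface, and
without detrending the decay dominates the lattice ripple. The first
positive non-zero-lag autocorrelation maximum gives the period; for BCC
the detected period corresponds to the axial inter-centroid layer
spacing $a/2 = d/\sqrt3$.

## Numerical and design choices

* Coordinates are physical micrometres; a point belongs to the voxel
  whose centre is nearest (round half up per axis). Membership tests use
  step end-points only -- the step-length rule, not segment sampling, is
  what prevents grain traversal. A 32 um chord can still graze a 90 um
  sphere to at most its sagitta (~2.9 um); the no-tunnelling test bounds
  sampled penetration accordingly.
* Angles use `atan2(||a x b||, a . b)`, robust near 0 and $\pi$. The
  half-angle formula sometimes quoted for this purpose, with the cross
  and dot arguments interchanged, evaluates to $|\pi/2-\theta|$ and is
  not replicated.
* Per-hair RNG substreams are derived from `(rng_seed, hair_id)`, so a
  computational replicate is reproducible and independent of growth
  order or parallel scheduling.
* Seeds falling in a mineral surface voxel are resampled (up to 100
  attempts): a hair cannot initiate inside an impenetrable grain.
* The fan is deterministic in `n`. A consequence worth knowing: control
  tortuosity does *not* decrease with fan size. A sparse fan often
  leaves exactly one candidate in the lowest bin, which the hair then
  follows deterministically (nearly straight); denser fans add in-bin
  wobble. What holds instead is the hard bound: with `k` bins every step
  deviates less than $\pi/(2k)$ from the reference in an empty domain,
  so A0 control tortuosity never exceeds $1/\cos(\pi/(2k))$.

## Known limitations

* Hairs are polylines: no radius, volume or mechanical deformation of
  hair or soil, and no chemotropism.
* The explicit-vs-control agreement for coarse (270 um) BCC packings is
  weaker than for fine ones: the initiation face necessarily slices
  large spheres, and detours around 135 um cross-sections inflate
  near-face length by ~25% while depleting the terminal shell. At the
  10% mean-deviation band this case stays red in the acceptance suite;
  see the decisions notes accompanying the repository.
* Absolute elevation percentages depend on the real imaged geometries,
  which are not available; only orderings and directions are asserted.

## A worked example

```{r example}
vol <- generate_three_phase_soil(c(0.35, 0.325, 0.325),
                                 c(1860, 1860, 650), 12,
                                 correlation_length = 100, rng_seed = 42)
vol <- filter_small_grains(vol, 32)
surf <- extract_surface(vol, "face", axis = "z", side = "low")
seeds <- sample_transition_points(surf, 121, rng_seed = 1, volume = vol)
lens <- assign_lengths(seeds, "fixed", c = 500)
cfg <- growth_config(32, 100, 4, "A1", "F1", rng_seed = 1)
explicit <- grow_population(seeds, lens, vol, cfg)
control <- grow_population(seeds, lens, NULL, cfg)
dref <- planar_distance(surf)
pe <- length_profile(explicit, dref, vol, 50)
pc <- control_wet_approximation(length_profile(control, dref, NULL, 50),
                                accessible_wet_fraction(vol))
elevation_percent(pe, pc)
```
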