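---
title: "Recovering cardiomyocyte orientation from membrane-stained volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering cardiomyocyte orientation from membrane-stained volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiofiber)
```

## The problem

Cardiomyocytes are elongated cells whose collective winding around the
ventricle — summarized by the *helix angle* $\alpha_H$ — governs cardiac
mechanics. Micrometre-scale fluorescence volumes of membrane-stained
tissue (a wheat-germ-agglutinin-type stain, which labels cell boundaries
rather than interiors) make it possible to measure this organization cell
by cell, at a resolution three orders of magnitude finer than the
diffusion-MRI data behind most whole-heart fiber models. `cardiofiber`
implements the full computational chain: image restoration, per-voxel
orientation estimation, cardiac coordinate frames and angle maps,
sector-wise transmural profiles, multiscale comparison, and glyph /
streamline export. A synthetic phantom generator with exact ground truth
makes every stage testable without microscope data.

## The estimator

Because the stain lives on membranes, every strong intensity gradient in
the image is *perpendicular* to the local cell long axis. The package
therefore computes, at each voxel, the structure tensor

$$ J(x) \;=\; G_{\sigma_w} \ast \left( \nabla I \, \nabla I^{\mathsf T} \right), $$

with $\nabla I$ from Gaussian-derivative filtering at the gradient scale
$\sigma_g$ and component-wise smoothing at the window scale $\sigma_w$.
The eigenvector belonging to the eigenvalue of *smallest magnitude* — the
direction in which intensity varies least — is the per-voxel estimate of
the cell long axis. The estimate is axial: $v$ and $-v$ are the same
orientation, and every consumer in the package treats them so (tests use
$\arccos|\langle v_1, v_2\rangle|$, profile averaging uses doubled-angle
means, streamlines re-align signs at every step).

Reliability filters: voxels with fractional anisotropy
$FA = \sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert / \lVert\lambda\rVert$
below `fa_floor` (default 0.1), with a near-degenerate smallest
eigen-pair ($(|\lambda|_{mid}-|\lambda|_{min})/|\lambda|_{max} < 0.05$),
or with a tensor magnitude below $10^{-9}$ of the field-wide maximum
(flat background, where the "tensor" is numerical dust and its
eigenvectors are arbitrary) are flagged invalid rather than reported.
The relative eigenvalue separation is returned as a per-voxel `margin`
attribute so downstream code can demand a stricter separation where the
axis must be trustworthy.

### Parameters that matter

* `sigma_gradient_um` (default 2 µm = one voxel): the derivative scale.
  Below one voxel the derivative kernel is undersampled (a warning is
  emitted).
* `sigma_window_um` (default 8 µm): the integration scale. It must
  bridge at least two membrane sheet families of one cell (tube diameter
  ≈ 12 µm here) or the tensor stays rank-one and the axis is decided by
  noise; it must also stay small against the scale on which orientation
  itself changes, or the window mixes differently-oriented tissue and
  biases the estimate. 8 µm — about half a myocyte width — satisfies
  both on the default phantom; both scales are exposed everywhere.
* `fa_floor`, degeneracy tolerance: conservative defaults; raising
  `fa_floor` trades coverage for reliability.

## The cardiac frame and the angle maps

From a wall mask, `build_wall_frame()` identifies the outer boundary per
short-axis slice (the interface with border-connected background),
computes the transmural depth as a distance transform from that boundary
(calibrated by half a voxel, since a boundary voxel's centre sits half a
voxel deep), and takes the penetration direction $R$ as the normalized
Gaussian-smoothed gradient of the signed distance — the inward boundary
normal of the level sets. The longitudinal direction $L$ is the global
$+z$ axis orthogonalized against $R$; $C = L \times R$ closes a
right-handed orthonormal triad. The boundary-normal smoothing scale
(default 5 voxels) was chosen relative to the default phantom's 100-voxel
wall; for data with much thicker walls a larger value is reasonable.

The angle maps follow the short-axis-plane conventions: $\Phi =
\arcsin|v_z|$ (out-of-plane elevation), $\theta = \arccos(|v_x| /
\lVert(v_x,v_y)\rVert)$ (in-plane angle to the x axis), both magnitudes
in $[0^\circ, 90^\circ]$; and the helix angle $\alpha_H = \mathrm{atan2}
(\langle v,L\rangle, \langle v,C\rangle)$ folded into $(-90^\circ,
90^\circ]$. Positive $\alpha_H$ means the orientation tilts toward $+L$
when moving along $+C$. Profiles are reported in $(-90, 90]$ with no
unwrapping; continuity across the $\pm 90^\circ$ wrap is handled by
axial-aware averaging (below) and by unwrapping *within* slope and line
fits only.

### Transmural profiles

`sector_profile()` assigns voxels to wedges (default 10°, combined in
pairs) by angular position about the wall centroid and to transmural bins
(default 2 µm) by depth, then averages $\alpha_H$ per (sector, bin) over
all slices. Averaging is axial: the bin mean is
$\tfrac12\,\mathrm{atan2}(\overline{\sin 2\alpha},
\overline{\cos 2\alpha})$, the principal angle of the averaged
tangent-plane orientation tensor. An arithmetic mean of angles would be
wrong wherever the profile approaches $\pm 90^\circ$ — which the default
phantom's course crosses.

Two scalar summaries are derived from profiles:

* `band_change_deg()`: the axial distance between the shallowest and the
  deepest bin inside the first 50 µm. A resolved constant-angle outer
  band followed by a sharp transition produces a large value; a
  DT-MRI-scale average does not.
* `outer_band_extent_um()`: the thickness of a constant outer band,
  estimated as the midpoint of the transition segment of a three-segment
  continuous piecewise-linear fit on the unwrapped profile. The midpoint
  (rather than the plateau end) is used because estimation smears the
  band edge symmetrically by roughly the window scale, so the plateau
  alone underestimates the band by about half the transition width.

### Pseudo low-resolution comparison

`coarsen_tensor_field()` block-averages tensors element-wise and
re-derives orientations at the coarse scale, emulating low-resolution
acquisition; `pseudo_lowres_orientation()` replicates the result back
onto the fine grid so the same profiling code applies. The multiscale
experiment in the acceptance checks uses a 250-voxel block — 500 µm at
2 µm voxels, i.e. a DT-MRI-class voxel — under which the 50 µm outer
band of the banded phantom becomes invisible (`band_change_deg` < 5°)
while the micron-scale analysis resolves it (≥ 20°).

## The phantom generator

`make_helical_annulus()` renders a cylindrical annulus (axis = z =
longitudinal) in which the prescribed fiber direction at normalized
transmural depth $d$ is the circumferential direction rotated by
`alpha_profile(d)` within the wall tangent plane. Membranes are drawn as
two families of bright Gaussian-profile sheets that enclose fiber-aligned
tubes:

* concentric cylindrical shells at the tube spacing (these contain both
  the circumferential and longitudinal directions, hence any fiber
  direction in the tangent plane);
* helical sheets whose normals are exactly perpendicular to the local
  fiber direction, built per one-voxel radial shell with an *integer*
  azimuthal wavenumber $m = \mathrm{round}(c\,r\,\sin\alpha)$ (so the
  pattern is single-valued around the annulus) and the axial wavenumber
  chosen to keep the normal exactly fiber-perpendicular.

Phase seams between shells only create radial intensity gradients, which
are perpendicular to the fiber axis and therefore cannot bias the
structure-tensor estimate; each shell additionally receives an
independent seeded azimuthal phase, since real cells are not radially
registered. Cell interiors sit on a low plateau, not zero — the signal
model puts gradients only at boundaries, which is the point of a
membrane stain.

Default study conditions (all in `phantom_spec()`): 320×320×48 voxels at
2 µm, outer radius 300 µm, wall 200 µm, tubes 12 µm with 2 µm membranes,
linear $\alpha_H$ from $-60^\circ$ (outer) to $+60^\circ$ (inner). The
banded variant overrides the outer 50 µm with a constant $80^\circ$ and
maps the linear course over the remaining depth. The wall is a
scaled-down ventricle: real walls are millimetres thick, so the phantom's
transmural gradient (0.6°/µm) is still several times steeper — i.e.
harder for a window-based estimator — than tissue. Degradation applies a
Gaussian PSF (σ = 2 µm), linear depth attenuation to 0.6 at the deepest
slice, Poisson noise at 100 expected photons at the brightest voxel, and
Gaussian read noise (σ = 2 intensity units); one integer seed drives all
randomness, and the global RNG state is left untouched.

What the phantom does **not** emulate: cell branching and intercalated
discs, vasculature and collagen sheetlets, anisotropic PSFs, intensity
seams between fields of view, or any deviation of the wall from a
circular annulus. Passing the phantom checks therefore demonstrates that
the estimator chain is correct and well-calibrated under its own signal
model — not that real tissue meets that model.

## Restoration

* `richardson_lucy_tv()`: multiplicative Richardson–Lucy updates with
  the total-variation prior applied as a per-voxel divisor
  $1 - \lambda\,\mathrm{div}(\nabla o/|\nabla o|)$ on the current
  estimate. `tv_weight = 0` is classic RL (flux-conserving for unit-sum
  PSFs); `tv_weight ≥ 1` is rejected since the divisor can vanish.
  Boundaries are reflect-padded to avoid wrap-around ringing; the TV
  gradient magnitude is stabilized with $\varepsilon = 10^{-8}$.
  Defaults: 25 iterations, weight 0.002 — configurable, as no canonical
  values exist for this class of data.
* `learn_patch_dictionary()` / `sparse_denoise()`: 256 atoms of 16×16
  pixels by default, learned only from the shallowest slices (where the
  signal is trusted) by alternating batch orthogonal matching pursuit
  with a method-of-optimal-directions update on zero-mean patches; dead
  atoms are reseeded from the worst-coded patches. Denoising
  sparse-codes overlapping patches per slice (default sparsity 4, stride
  4) and averages the overlaps. Dictionaries are per field of view by
  design — structures from one region must not influence another — and
  the pipeline driver never crosses them.
* `phase_correlation_offset()` / `refine_offsets()` / `stitch_tiles()`:
  integer translations from the argmax of the inverse-transformed
  normalized cross-power spectrum (exact for circular shifts; the peak
  value is the confidence). Nominal mosaic offsets initialize the
  search; pairwise refinements beyond 25 % of the tile extent are
  discarded; the pairwise graph is reconciled into absolute positions by
  least squares with the first tile anchored. Fusion feathers overlaps
  with separable triangle weights and copies single-tile voxels
  verbatim.

## Tractography

Streamline seeds are drawn uniformly from valid masked voxels (seeded
RNG, at most 25 000). Integration is fixed-step (default one voxel) and
bidirectional, with the local axial vector sign-aligned to the previous
direction at every lookup; a midpoint (RK2) update is used under
trilinear interpolation because plain Euler drifts outward by
$\approx s^2/2r$ per step on curved fields — enough to leave a thin
wall within one revolution. A nearest-voxel lookup mode is available
for strict fidelity to per-voxel stepping. Lines stop on leaving the
mask, entering an invalid voxel, exceeding the point budget, or turning
more than 60° in one step. Glyphs subsample every 12th voxel by default
and raise the stride minimally if the 75 000-vertex cap would be
exceeded. Both exports carry the elevation angle
$\Phi = \arccos|v_z|$ (in degrees) as their color scalar, with a
parula-like lookup table shipped as a data file.

## Numerical choices and degenerate inputs

* Separable convolutions use dense banded matrices with mirror
  reflection; FFT convolution (reflect-padded) handles arbitrary 3D
  PSFs. Both are exactly 90°-rotation-equivariant, which the test suite
  exercises end to end.
* Per-voxel 3×3 eigendecomposition runs in compiled code
  (`eig_sym` per voxel); tests compare it against an independent
  characteristic-polynomial solver on a thousand random PSD tensors.
* "Smallest magnitude" is implemented literally — sorting by
  $|\lambda|$ — although for PSD tensors this coincides with the
  smallest eigenvalue.
* Sign canonicalization makes the first nonzero vector component
  positive; this is cosmetic, all semantics stay axial.
* Zero tensors get $FA = 0$; spherical cell masks are flagged
  degenerate; empty masks, all-zero inputs to phase correlation,
  constant dictionary sources, zero-norm directions and disconnected
  tile graphs raise errors naming the problem.
* Piecewise-linear fits break ties toward the earliest admissible
  breakpoints and flag degenerate (pure-line) inputs.

## Problem sizes

The validation suite and the acceptance script run the full pipeline on
the default 320×320×48 phantom (about 5 million voxels, ~1.4 million
in-wall) twice — linear and banded — plus small constructed cases per
operation. Unit tests use a 96×96×24 annulus (52 µm wall) where the
full-scale conditions are not the point.

## Known limitations

* The wall frame derives depth per short-axis slice (2D distance
  transform); strongly oblique or apical geometries would need a fully
  3D boundary treatment.
* Profiles assume an annulus-like topology per slice with a single
  outer boundary; papillary structures and the septum are out of scope.
* The helix-angle range is $(-90, 90]$ with no global unwrapping, so a
  true transmural span greater than 180° would alias; span-type
  statistics should be read accordingly.
* The dictionary denoiser is a generic sparse-coding implementation
  tuned for membrane imagery; it is not a learned prior for any
  specific microscope.
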