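# cardiofiber

Micrometre-scale recovery of cardiomyocyte long-axis orientation from
membrane-stained 3D image stacks.

Cardiomyocytes wind around the ventricle in a transmural pattern
classically summarized by the **helix angle** α_H — the signed angle
between a cell's tangent-plane projection and the circumferential
direction. Most whole-heart fiber models derive this pattern from
diffusion-tensor MRI at millimetre voxels, where hundreds of cells share
one measurement. Volumetric fluorescence imaging of membrane-stained
(WGA-type) tissue at ~2 µm voxels resolves it cell by cell; this package
provides the computational chain that turns such stacks into orientation
fields, cardiac angle maps, transmural profiles, and visualization
primitives — for image-analysis researchers and cardiac-microscopy labs
who want a tested, scriptable reference implementation.

## The method in brief

A membrane stain puts every strong intensity gradient perpendicular to
the cell long axis. At each voxel the **structure tensor**

    J(x) = G_σw * ( ∇I ∇Iᵀ ),   ∇I from Gaussian derivatives at σ_g

is computed, and the eigenvector of the eigenvalue with **smallest
magnitude** — the direction of least intensity variation — is the axial
(v ≡ −v) estimate of the cell orientation. Fractional anisotropy
FA = √(3/2)·‖λ−λ̄‖/‖λ‖ gauges reliability. From a wall mask the package
derives the per-voxel cardiac triad {C, L, R} (circumferential,
longitudinal, penetration) via a distance transform from the outer
boundary, and reports

* Φ = arcsin|v_z| and θ = arccos(|v_x|/‖(v_x,v_y)‖), magnitudes in [0°, 90°];
* α_H = atan2(⟨v,L⟩, ⟨v,C⟩) folded into (−90°, 90°];
* sector-wise transmural profiles of α_H (10° wedges, axial-aware bin
  means), local rates of change, and continuous piecewise-line fits
  (outer-band extent);
* pseudo low-resolution comparisons by element-wise tensor block
  averaging (a 250-voxel block at 2 µm emulates a 500 µm DT-MRI-class
  voxel);
* glyph and bidirectional streamline exports (legacy VTK), colored by Φ.

Restoration stages — Richardson–Lucy deconvolution with total-variation
regularization, shallow-layer 256-atom 16×16 patch-dictionary denoising,
and phase-correlation stitching of ≥25 %-overlap mosaics — are included,
as is a synthetic phantom generator (membrane-bright tube bundles and
helical annulus "ventricle walls" with exact ground truth) that makes the
whole chain testable without microscope data.

## Worked example

```r
library(cardiofiber)

# default study conditions: 320x320x48 voxels at 2 um, 200 um wall,
# linear alpha_H from -60 (outer) to +60 (inner)
spec  <- phantom_spec(rng_seed = 1)
ph    <- make_helical_annulus(spec)
noisy <- degrade_volume(ph$volume, psf = gaussian_psf(2, 2),
                        photons_at_peak = 100, read_noise_sd = 2,
                        attenuation_floor = 0.6, seed = 1)

tf    <- compute_structure_tensor(noisy)      # sigma_g 2 um, sigma_w 8 um
of    <- smallest_eigenvector_field(tf)
frame <- build_wall_frame(ph$truth$mask, 2)
ah    <- compute_helix_angle(of, frame)

mask <- evaluation_mask(ph$truth, 6) & attr(of, "valid") & ah$valid
err  <- angular_error(of, ph$truth$orientation, mask)
round(c(mean = err$mean_deg, sd = err$sd_deg), 2)
#> mean   sd
#> 1.73 1.42

prof <- sector_profile(list(alpha_h_deg = ifelse(mask, ah$alpha_h_deg, NA),
                            valid = mask), frame)
head(prof[prof$sector == 3, ], 3)
#>     sector depth_um mean_alpha_deg    n
#> 301      3        1      -57.33519 2412
#> 302      3        3      -56.75975 1728
#> 303      3        5      -56.19649 1728
plot(prof)
```

The mean angular error of ~1.7° against the known ground truth is the
phantom analogue of validating estimated orientations against
hand-segmented cells (real-data agreement for this class of method is
about 6°). The profile table reads: in sector 3, the 2-µm depth bin
centred 1 µm below the outer boundary averages α_H ≈ −57.3° against a
prescribed −59.4° at that depth — the −60° → +60° course recovered to
within a couple of degrees at the wall surface, and more closely in the
interior.

Command-line use (installed under `inst/cli/`):

```sh
cardiofiber phantom --out run1 --seed 7
cardiofiber orient  --in run1/volume.tif --out run1/orient
cardiofiber profile --orient run1/orient/orientation.nrrd --mask run1/mask.tif \
                    --out run1/profiles.csv
cardiofiber validate          # phantom -> recovery check, exit 0 iff < 6 deg
```

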