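---
title: "Methods: multiscale tubular enhancement and 3D fiber orientation mapping"
author: "fiber3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale tubular enhancement and 3D fiber orientation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiber3d)
```

## The problem

Fluorescence microscopy can resolve individual myelinated axons in brain
tissue, but unlike polarimetry-based modalities it does not measure fiber
orientation directly: orientations must be extracted by image analysis, and
generic operators (Fourier or structure-tensor analysis) assign an
orientation to *every* voxel, fiber or not. `fiber3d` implements a pipeline
that (i) selectively enhances bright tubular structures with a multiscale 3D
vesselness filter, (ii) classifies fiber voxels automatically, (iii) reads
the local fiber axis off the Hessian eigenstructure of the enhanced voxels,
and (iv) aggregates the resulting vector field into spherical-harmonics
orientation distribution functions (ODFs) over super-voxels of arbitrary
size, in a format consumable by standard ODF viewers (MRtrix). A rotation
-based validation harness quantifies the angular accuracy of the whole chain.

## Vesselness model

At scale $\sigma$ the image is convolved with a 3D Gaussian and its second
derivatives form the Hessian $H_{\sigma}$, scale-normalized by $\sigma^2$
(one factor of $\sigma$ per derivative order) so that responses are
comparable across scales. With eigenvalues ordered
$|\lambda_1|\le|\lambda_2|\le|\lambda_3|$, a bright tube on a dark
background has $\lambda_1\approx 0$ and $\lambda_2\approx\lambda_3<0$;
the eigenvector $v_1$ of $\lambda_1$ is the fiber axis. Three features feed
the vesselness score:

* blobness $R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$,
* in-plane aspect ratio $R_A = |\lambda_2|/|\lambda_3|$,
* structureness $S = \sqrt{\sum_d \lambda_d^2}$ (Frobenius norm),

combined as
$V(\sigma)=e^{-R_B^2/2\beta^2}\,(1-e^{-R_A^2/2\alpha^2})\,(1-e^{-S^2/2\gamma^2})$
and set to zero when $\lambda_2>0$ or $\lambda_3>0$ (wrong contrast
polarity). The multiscale map is the voxel-wise maximum over scales, and the
orientation is $v_1$ at the winning scale (ties resolve to the smallest
scale — the original tool's tie rule is not documented, and the choice is
ours).

**Parameters.** $\alpha = 0.001$ (strong amplification of elongated
structures) and $\beta = 1$ are the defaults throughout; they are the final
sensitivity configuration for two-photon myelin autofluorescence. $\gamma$
is data-driven: half the maximum structureness of the processed (sub-)volume
at the current scale, recomputed per chunk and per scale. A flat chunk
($\max S = 0$) falls back to $\gamma = 1$; its vesselness is identically
zero anyway. Under this automatic $\gamma$, an ideal tube at the
structureness maximum responds at the ceiling $1-e^{-2}\approx 0.8647$.

**Degenerate voxels.** Where $|\lambda_3| = 0$ all eigenvalues vanish; we
define $R_B = 0$, $R_A = 1$ there. This avoids NaN propagation and cannot
change $V$, which is already zero through the structureness term.

**Numerics.** Derivatives are separable sampled Gaussian-derivative
convolutions truncated at $4\sigma$, with the second-derivative kernel
corrected to exact zero DC response (a constant image has an exactly zero
Hessian). Computation is in double precision (R's native numeric type).
Per-voxel eigenanalysis uses the closed-form (Cardano) solution with
eigenvectors from row cross-products, falling back to LAPACK within
$10^{-12}$ of degeneracy; the full-decomposition API (`eigen_decompose`)
always uses LAPACK. Eigenvectors are axial, so their sign is fixed by a
$z\ge 0$ hemisphere convention (ties $y\ge 0$, then $x\ge 0$) purely for
reproducibility.

## Matched scale selection

Filtering a simulated cylinder (aspect ratio 12) across scale-to-radius
ratios shows two failure regimes. When $\sigma$ is small relative to the
radius the filter responds with a spurious high-probability ridge at the
fiber edge and a hollow axis: the axis-midpoint response is near zero up to
a ratio of $\approx 0.3$, reaches $\sim 70\%$ of the ceiling at $0.4$, and
sits at the ceiling from $0.5$ on. When $\sigma$ is large the response
smears: its FWHM grows monotonically past the true diameter. The matched
scale is therefore the *preservation boundary* — the smallest ratio whose
axis response reaches at least 95% of the sweep maximum
(`optimal_response_row()`). The 95% cut lies in a wide insensitive window
(roughly 0.75–0.98 of the ceiling); it was fixed once from the transition
shape. On a 10 px/µm cylinder this yields a 50% scale-to-radius ratio, and
the dual sweep at fixed scale (`diameter_sweep`) maps scales 1, 1.25 and
1.5 µm to fiber diameters 4, 5 and 6 µm. Each sweep filters only a central
z-slab of thickness $2\lceil 4\sigma\rceil+1$: the Gaussian support cannot
reach the slab boundary from the mid-slice, so the profile equals a
full-volume run at a fraction of the cost.

Note that the per-voxel argmax over scales is *not* how the 50% rule
manifests: with per-scale automatic $\gamma$, the axis response keeps
creeping toward the ceiling as $\sigma$ grows (0.854 at $r/2$ vs 0.865 at
$r$), so scale-index maps should be read as rough caliber indicators only.

## Preprocessing

Scanning fluorescence microscopes have an elongated axial PSF; uncorrected,
this biases Hessian orientations toward the imaging plane. Modeling the PSF
as Gaussian (FWHM $= 2\sqrt{2\ln 2}\,\sigma$), each XY plane is blurred
with $\sigma_x^2=\sigma_{PSF_z}^2-\sigma_{PSF_x}^2$ (likewise $y$), which
equalizes the three widths of a point source to within 10%. Volumes are then
downsampled laterally (linear interpolation — after the blur, higher orders
only add ringing) to an isotropic 1 µm grid. Both stages are optional and
skippable, e.g. for deconvolved inputs; the default PSF FWHM values
(0.692, 0.692, 2.612 µm) describe a 0.8-NA two-photon system. Only lateral
resampling is implemented: the axial voxel size must already equal the
target, the acquisition geometry this stage is designed for.

## Masking

Fiber voxels are classified by thresholding the vesselness map with Li's
minimum cross-entropy criterion, computed iteratively on the floating-point
values (no requantization), per chunk in the streaming pipeline (a
`global_normalization` flag computes one volume-wide threshold instead).
Soma rejection uses Yen's maximum-correlation threshold (256-bin histogram)
on the second channel, where lipofuscin autofluorescence makes cell bodies
bright; it is optional and simply skipped without that channel. Both
operators are tested against exhaustive brute-force minimization of their
criteria on coarse histograms. The threshold is applied to the vesselness
map itself; on these data the enhanced intensity and V are monotonically
related, so the choice is immaterial up to threshold placement.

## ODFs

Within each super-voxel the $K$ masked orientations are modeled as Dirac
deltas on the unit sphere; projecting onto real even-order spherical
harmonics turns each coefficient into a closed-form mean of basis values
over the orientations — no directional binning, no quadrature, and every
native-resolution vector contributes regardless of super-voxel size. The
basis is the real symmetric convention (order $l\le 6$, 28 coefficients)
with MRtrix-compatible ordering and normalization: $m>0 \to \cos m\phi$,
$m<0 \to \sin|m|\phi$, with the $\sqrt{2}$ factor for $m\ne 0$ and the
$(-1)^m$ factor canceling the Condon–Shortley phase of the associated
Legendre functions. Orientations are axial, so odd orders vanish
identically and are not stored; the $l=0$ coefficient is
$1/(2\sqrt{\pi})$ for any non-empty compartment, a useful invariant.
Empty super-voxels carry zero coefficients and are flagged by the stored
count map $K$; partial edge super-voxels are kept, with $K$ letting users
filter them. Coefficients are stored raw (no per-super-voxel display
normalization) as a float64 4D NIfTI (bit-exact round trips) with the
super-voxel size as voxel spacing, plus a JSON sidecar and a 16-bit K map.

## Rotation-based validation

The accuracy harness samples 75×75×15 µm patches from image stacks,
randomly flips each along the three axes, rotates each patch about the
z-axis (in-plane) and the x-axis (out-of-plane) from −45° to 45° in 5°
steps (18 nonzero rotations per axis; cubic B-spline interpolation with
prefiltering), and re-runs the orientation analysis at scales 1, 1.25 and
1.5 µm. Azimuth ($\phi_{xy}$) distributions are scored for z-rotations and
elevation ($\theta_{zy}$) distributions for x-rotations, each over 180
1°-wide bins spanning the 180° axial range, against the unrotated patch's
distribution with its angular reference rotated by the applied angle.
Agreement is summarized by the inter-median distance — circular medians by
exhaustive scan over bin centers, needed near the ±90° wrap — and the
Bhattacharyya coefficient $\sum_x\sqrt{p(x)q(x)}$. Patches whose
fiber-classified fraction falls below 1% at any tested rotation are dropped
entirely, keeping patch counts equal across rotations.

Design points worth making explicit:

* **Margins.** Each patch is extended on every side before rotation. The
  margin must cover (a) the Gaussian boundary artifacts, $\lceil 4
  \sigma_{max}\rceil$ voxels, and (b) the rotation fill-in — not just of
  the core but of the core *dilated by (a)*, since core voxels' filter
  support must also stay inside validly rotated data. We compute the
  fill-in per axis from the exact rotated extent of the dilated core at
  ≤45°; for the flat 15 µm-deep patch the z-margin (33 voxels) is by far
  the largest.
* **Fill-in handling.** Voxels whose rotated source falls outside the
  original patch are flagged invalid and excluded from all statistics,
  rather than trusted as zero-filled intensities.
* **Flips and the elevation correction.** Flipping a patch along x or y
  reverses the sense in which an x-rotation tilts its content once
  orientations are folded to the axial azimuth range [−90°, 90°): the
  elevation correction therefore uses the applied angle times the x/y flip
  parity, i.e. it is applied in each patch's own flipped frame. The azimuth
  correction is an exact circular shift for any in-plane content and needs
  no such adjustment.

## What the synthetic stacks emulate

The validation stacks (`make_fiber_stack`) are dense, coherently oriented
bundles: 110 straight in-plane fibers per 160×160×100 µm volume (≈13%
fiber volume fraction, in the white-matter range), calibers 2, 2.5 and 3 µm
matched to the three analysis scales, a per-stack dominant azimuth between
78° and 86° with 3° per-fiber spread, anti-aliased edges (3×3×3
supersampling of boundary voxels — hard staircase edges would be amplified
by the Hessian), 8-bit-like gray levels 200/10, and a minimum axis
separation so neighboring fibers stay resolved. Two of these choices are
load-bearing and deliberate:

* the azimuth band keeps fibers roughly perpendicular to the x rotation
  axis, where the shift-based elevation correction is exact (a fiber at
  azimuth $\varphi$ rotated by $A$ acquires elevation
  $\arcsin(\sin\varphi\sin A)$, within 0.9° of $A$ across the band). Real
  white-matter tiles have exactly this kind of dominant orientation;
* density matters for the overlap statistics: with only a handful of
  fibers per patch the angular histograms are nearly discrete spikes, and
  sub-bin redistribution after interpolation caps the Bhattacharyya
  coefficient well below what the same estimator achieves on dense tissue.

What the phantoms do *not* emulate: autofluorescence texture and noise,
fiber curvature, branching, crossing bundles at the patch scale, and
partial-volume background structure. Passing the harness on these phantoms
demonstrates the geometric fidelity of the rotation/estimation chain — not
robustness to real-tissue contrast, which only real stacks can show.

Problem sizes: the bundled checks run 3 stacks × 1 patch (test suite) and
5 stacks × 1 patch (acceptance script) through all 36 rotations; both
reproduce azimuth errors ≤2°, elevation errors ≤3° and azimuth overlap
≥0.99, and the protocol scales to more patches via `n_patches`.

## Chunked processing

Large volumes are processed in near-cubic cores that tile the volume
exactly; each core is read with a margin of $\lceil 4\sigma_{max}\rceil$
voxels, which equals the truncated kernel radius, so a core's vesselness
and orientations are bit-identical whether the volume is processed whole or
chunked — except that $\gamma$ and the Li threshold are per-chunk by
default (the streaming behavior; seams in flat regions are possible and
accepted). `global_normalization = TRUE` precomputes volume-wide $\gamma$
per scale (via the Frobenius-norm identity $S = \|H\|_F$, no
eigendecomposition needed) and one global threshold, making chunked and
whole-volume runs exactly identical at the cost of a second pass. Chunk
cores are sized to a memory budget at 4 bytes per voxel.

## Known limitations

* TIFF (+ JSON sidecar) and in-memory arrays only; no HDF5 reader is
  available in the supported R stack.
* Bright-on-dark polarity only; 2D filtering is out of scope.
* Only lateral isotropization (downsampling); axial resampling is not
  implemented.
* The elevation correction in the validation harness is exact only for
  fibers perpendicular to the rotation axis; for isotropically oriented
  content the out-of-plane scores conflate correction error with estimator
  error, as discussed above.
* Eigenvector orientation at voxels with $\lambda_2 \approx \lambda_3$
  degeneracy (plates, blobs, background) is arbitrary within the degenerate
  plane; such voxels carry near-zero vesselness and are excluded by the
  mask in practice.
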