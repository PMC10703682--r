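---
title: "Constrained single-particle refinement for cryo-electron tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained single-particle refinement for cryo-electron tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In cryo-electron tomography a specimen is imaged at a series of stage
tilts (typically -60 to +60 degrees in 3-degree steps). Each particle in
the field therefore contributes one low-dose 2D projection per tilt, and
the goal of sub-tomogram analysis is to recover particle positions,
orientations and conformational states, and to average tens of thousands
of particles into a high-resolution 3D map. The conventional route —
reconstructing full tomograms, extracting a 3D sub-volume per particle,
and aligning sub-volumes — multiplies storage by orders of magnitude
(12,000 sub-volumes at box 384 already occupy 2.5 TB) and forces every
downstream step through large intermediate files.

cetrefine implements the alternative: all refinement operates directly
on the 2D particle projections, with the tilt geometry imposed as a hard
constraint, and only small Fourier-space partial reconstructions are
ever kept. The package covers the computational core of such a pipeline
— geometry, CTF handling, constrained and region-based refinement,
video-frame refinement with score-driven exposure weighting, constrained
3D classification, reconstruction with half-map FSC, and 3D particle
picking — together with a simulator that generates tilt series with
known ground truth, so every stage is testable against the truth that
produced its input.

# Geometry and the pose-composition mapping

Every particle carries six parameters: a position $(x_P, y_P, z_P)$ in
tomogram voxels and an intrinsic ZYZ Euler triplet
$(\theta_P, \phi_P, \psi_P)$ with
$R = R_z(\theta)\,R_y(\phi)\,R_z(\psi)$ mapping the reference frame to
the particle frame. Each tilt carries a tilt-axis angle $\alpha$, a tilt
angle $\beta$ and an in-plane image shift. The tilt operator rotates the
image frame so the tilt axis is vertical, tilts about it, and rotates
back:

$$R_{\mathrm{tilt}} = R_z(\alpha)\, R_y(\beta)\, R_z(-\alpha).$$

The 2D alignment of particle $P$ on tilt $t$ is then *derived*, never
stored: the projection orientation is
$R_{\mathrm{tilt}} R_P$ and the projection shift is
$\bigl(R_{\mathrm{tilt}} (p - c)\bigr)_{xy}$ plus the per-tilt image
shift, where $c$ is the tomogram centre voxel. `composeProjectionPose()`
implements this mapping with exact rotation-matrix algebra; a dedicated
acceptance test checks it against an independently coded brute-force
oracle to $10^{-10}$.

Conventions the underlying literature leaves to implementation
internals are fixed here once and verified by round-trip tests: angles
in degrees with $\theta,\psi \in [-180,180)$, $\phi \in [0,180]$;
gimbal-locked orientations canonicalise with $\psi = 0$; tomogram
coordinates are 0-based voxels with the rotation origin at
`floor(dims/2)`; per-tilt shifts are applied after the tilt rotation.
Note that under this convention the *first* Euler angle $\theta$ is the
in-plane rotation of a zero-tilt projection (it is the last rotation
applied, about the beam axis); the equivariance test exercises exactly
that angle.

For region-based work the tomogram is split into an
$n_x \times n_y \times n_z$ grid of half-open uniform cells (boundary
coordinates fall in the upper cell). Each region owns per-tilt
corrections to $(\alpha, \beta, \mathrm{shift})$ — a piecewise-constant
model of beam-induced deformation — and a per-region defocus /
astigmatism correction shared across tilts.

# Scoring and refinement

The score $d$ between a particle crop and the reference is a normalised
cross-correlation computed in Fourier space over a resolution band,
between the crop's transform and the CTF-multiplied central slice of
the reference transform at the composed pose. It is invariant to image
scale and offset and lies in $[-1, 1]$. Refinement maximises the sum of
$d$ over a particle's tilts (the objective $D$ sums further over
particles of a region for region-based steps). The central-slice
extraction, band-limited scoring and gridded slice insertion are
implemented in compiled code; everything else is R.

*Fully constrained refinement* optimises the six particle parameters
with a Nelder–Mead simplex on offset coordinates, under a band schedule:
a low-resolution stage (up to 10 Å) provides a wide capture basin for
5-degree errors, and a finer stage (20–4.5 Å) sharpens the pose. A
single fine band has no capture basin at such errors, and coordinate-wise
line searches cannot follow the coupled Euler directions — both were
measured on noiseless data before settling on this scheme. A keep-best
guard makes the aggregate score non-decreasing regardless of optimiser
behaviour.

*Region-based geometry refinement* holds particle poses fixed and
optimises each region's per-tilt corrections. Because the fine-band
objective is multimodal for deformations beyond about a pixel, shifts
are first captured on a coarse grid (1.5 px steps within the search
limit) and then polished by golden-section line searches. The
refine/reconstruct loop repeats, rebuilding the reference between
passes, until the recovered field moves less than 0.1 px RMS between
passes (typically three passes); that recovers a 4 px deformation field
to well under half a pixel RMS.

*Region-based CTF refinement* optimises a per-region defocus pair and
astigmatism correction (applied on top of the per-tilt estimates and
the depth-dependent per-particle defocus offset
$\Delta f = -z_{\mathrm{beam}} \cdot \mathrm{pixel\ size}$) by the same
derivative-free coordinate maximisation within a user tolerance. The
defocus objective is locally unimodal within the default ±2000 Å
tolerance at the default band, which is why no grid stage is needed
there.

The reference-based *global search* evaluates an Euler grid (optionally
restricted by a surface-normal prior to a single in-plane angle, which
cuts evaluations by an order of magnitude) and scores each candidate
through the same constrained composition, so no per-projection
parameter is ever free.

# CTF model and estimation

The CTF follows the standard form
$\mathrm{CTF}(k,\vartheta) = -\bigl[\sqrt{1-A^2}\sin\gamma + A\cos\gamma\bigr]$
with
$\gamma = \pi\lambda f(\vartheta) k^2 - \tfrac{\pi}{2} C_s \lambda^3 k^4 + \varphi$
and
$f(\vartheta) = \bar f + \tfrac{\Delta f}{2}\cos 2(\vartheta - \vartheta_0)$,
underfocus positive, defocus in Å. Per-tilt estimation maximises the
correlation between the radially averaged, background-subtracted power
spectrum and $|\mathrm{CTF}|^2$ over a defocus grid, then fits
per-sector defocus estimates with a $\cos 2\vartheta$ model for
astigmatism; the background is a smooth spline through the spectrum's
local minima. Sector searches use a grid-then-polish scheme because the
ring-matching correlation oscillates with defocus. A normalised fit
score below 0.3 flags a featureless spectrum instead of erroring.

# The simulator

The simulator is first-class code, not a fixture: it generates the
statistical structure every other module assumes, through the same pose
composition and slice extraction used by refinement, so a noiseless
simulation scores 1.0 against its own ground truth by construction.

- **Phantom.** A composite of hard spheres rendered with
  edge-supersampled coverage (the integral matches the analytic
  component volumes) and band-limited by a Gaussian of 0.8 voxels. The
  default is an envelope plus a fixed asymmetric constellation of 16
  small lobes: featureless smooth blobs carry almost no mid-frequency
  power, which makes orientations nearly unidentifiable; the granular
  default restores the angular sensitivity real particles have. The
  two-variant phantom appends one lobe of radius $0.14\times$ box
  (amplitude 1.4) — a domain-sized difference chosen so the two
  variants are separable at the benchmark SNR to the degree reported
  for the reference single-particle mixture validation.
- **Noise and SNR.** Additive white Gaussian noise in the projections.
  SNR is defined as signal variance over noise variance measured inside
  the particle boxes of the *first-exposure* tilt; later tilts are
  weaker through the dose model, as in real data.
- **Dose model.** Per-tilt amplitude envelope
  $\cos\beta \cdot \exp(-k^2 B(e)/4)$ with $B(e)$ linear in the
  accumulated exposure $e$ (default 1 Å² per e/Å², 3 e/Å² per tilt) and
  a dose-symmetric acquisition order. This is the simplest model that
  reproduces the characteristic bell-shaped score-versus-tilt curves
  and the monotone decay with accumulated exposure.
- **Frames.** Each tilt optionally splits into $F$ frames carrying
  $1/F$ of the signal, shifted along a trajectory (linear drift plus a
  random walk, relative to frame 1), with within-tilt B-factor
  increments so later frames are damage-attenuated, and noise scaled so
  the frame sum matches the tilt image. With a constant-rate drift
  model the within-tilt score curve shows the decaying (dose) flank of
  the bell; the rising flank seen in real data comes from the rapid
  early motion that a linear-plus-random-walk model deliberately does
  not include.
- **Deformation and CTF errors.** True per-region shift/angle fields
  and defocus offsets enter the simulation through the same region
  model the refiners estimate, so recovery is measured against exact
  ground truth.
- **Field size.** Benchmark tomograms are sized so particle boxes stay
  essentially disjoint (e.g. 448×448×128 voxels for 50 particles at
  box 64). At higher densities neighbouring particles leak into each
  other's crops; that interference — not the estimator — then caps
  pose-recovery and classification accuracy. The defaults emulate a
  well-dispersed specimen; crowded specimens will do worse for this
  physical reason, which passing tests on the defaults do not contradict.

What the simulator does *not* emulate: structured noise (membranes,
crowding, ice gradients), alignment errors from fiducial tracking,
non-rigid particle flexibility, and realistic atomic phantoms. Passing
recovery tests here demonstrates correctness of the estimators under
the stated model, not performance on any particular real specimen.

# Reconstruction, FSC and exposure weighting

Reconstruction is direct Fourier inversion: each projection's
CTF-multiplied transform is gridded (trilinear) as a central slice into
a complex numerator, CTF² into a real denominator, and the map is
$N/(D + w)$ with a Wiener constant $w$ of 1% of the mean denominator.
Partial reconstructions merge by addition — commutative and
associative — so the result is bit-identical for any bundle split or
processing order; that property is what makes the scratch-and-merge
architecture safe. Half-sets split by particle-id parity. FSC is
computed per integer Fourier shell and resolution read at the first
0.143 crossing with linear interpolation.

Exposure weights convert per-unit (frame or tilt) mean scores into
frequency weights $w_u(k) = \exp(-k^2 / 4 b_u)$, normalised to sum to
one across units at every $k$, with $b_u = b_0 e^{z_u}$ and $z_u$ the
unit's standardised score — a monotone map, so better-scoring units
contribute more high-frequency signal. The functional family is this
package's choice; only its verifiable properties (normalisation,
monotonicity, equal-score degeneracy, non-degrading resolution on
dose-attenuated data) are asserted.

# Video-frame refinement

Per particle and tilt, frame shifts are estimated by maximising the
projection score of running-averaged frame crops over a bounded shift
range (the running window doubles automatically while the mean score
stays below a floor — the self-tuning response to very low per-frame
dose), then regularised in closed form by minimising

$$\sum \lVert x - x_{\mathrm{raw}}\rVert^2
 + \lambda_t \sum \lVert D_2 x\rVert^2
 + \lambda_s \sum_{\text{neighbours}} \lVert x_p - x_q\rVert^2,$$

with second-order temporal differences and radius-based spatial
neighbourhoods (defaults $\lambda_t = 2$, $\lambda_s = 0.5$, 80-voxel
radius, chosen so the zero-drift null case stays below 0.2 px). As
$\lambda_t \to \infty$ trajectories collapse to least-squares straight
lines, which the tests verify. Trajectories are reported relative to
the first frame; because the clamped running window maps edge frames
onto interior window centres, drift slopes are read off interior
frames.

# Constrained classification

Classification follows an expectation–maximisation pattern constrained
by the tilt geometry. Initial references come from a random
whole-particle assignment (deterministic given the seed). Each
iteration scores every projection against every class reference,
converts scores to per-projection occupancies with a softmax
standardised by *global* statistics (never per bundle), and averages
them per particle with Gaussian tilt weights of s.d. 6 degrees centred
at zero tilt, so all projections of a particle share one class
distribution; class maps are rebuilt by occupancy-weighted insertion
over the full tilt range. Score-based weights are deliberately not used
in the averaging (they overfit at tomographic SNR). Classes falling
below a population floor are reseeded from a random half of the largest
class, with a logged message.

The softmax temperature is the one genuinely open design point: the
reference implementation invokes refinement statistics without printing
a formula. Using the raw global score s.d. freezes the iteration — that
spread is dominated by per-particle quality variation and *grows* as
classes separate, so occupancies stay near-uniform. The package instead
standardises by the s.d. of within-projection class-score deviations,
the scale on which classes are actually discriminated; the
synthetic-mixture benchmark validates the choice (98% correct particles
at SNR 0.2 within ten iterations).

In the unconstrained comparison mode each projection keeps its own
occupancies end-to-end. Because the assignment unit is then the
projection, the paired benchmark compares constrained particle accuracy
(shared by construction across a particle's projections) with
unconstrained per-projection accuracy — the scattering of one
particle's projections across classes is precisely the failure mode the
constraint removes. A focused variant scores within a spherical mask
only (centre and radius in the particle frame), for heterogeneity
confined to a known site.

One physical limitation surfaced by the benchmark is worth noting: for
particles whose discriminating lobe points along the beam, the missing
wedge suppresses the difference in every projection, and no estimator
can fully recover it; the benchmark's accuracy ceiling reflects
orientation statistics, not a defect of the constraint.

# Particle picking and cleaning

Contamination masking band-passes the tomogram (2 / 16 voxel Gaussians),
binarises at mean + 3 s.d. of the dense-contrast result, removes small
connected components (6-connectivity), fills holes, and dilates.
Size-based picking low-pass filters with $\sigma$ = radius/2, detects
local minima of the density (dense = dark; a flag inverts), discards
peaks weaker than mean + 2 s.d. of the filtered contrast computed
outside the mask, and enforces one-diameter separation greedily with
deterministic ordering. Sphere detection is a gradient-based 3D Hough
vote with vote pooling over a 2-voxel ball and non-maximum suppression
at half the minimum radius; surface sampling places a Fibonacci lattice
at the requested arc spacing with outward normals. Cleaning thresholds
per-particle mean scores — automatically only when the score histogram
is clearly bimodal. The Otsu inter-class variance ratio of a *single*
Gaussian is already about 0.64, so the bimodality gate is set at 0.85;
a lower gate would shave the top of unimodal score distributions and
make cleaning non-idempotent.

# Numerical choices and degenerate inputs

- Boxes are even everywhere; spectra are centred with DC at
  `n/2 + 1`; trilinear interpolation is used for both slice extraction
  and insertion. Its gridding error limits isolated extract–insert
  round trips to about 0.995 real-space correlation at box 32.
- Scoring bands always exclude DC and cap below Nyquist; an empty band
  is an error.
- Optimisers are derivative-free with keep-best guards, so every
  refinement's aggregate objective is non-decreasing even on degenerate
  inputs; zero search limits return inputs unchanged.
- Ties in grid searches resolve to the first candidate in grid order;
  pick orderings break ties lexicographically by position.
- Regions below the minimum particle count keep zero corrections and
  warn; empty half-sets and empty class sets are errors.
- All simulation is deterministic given the seed; classification is
  deterministic given its seed.

# Problem sizes used by the test-suite and acceptance runs

Pose recovery runs 50 particles at box 64 with all 41 tilts; the
deformation and CTF benchmarks run 40 particles on a 2×2×1 grid (ten
per region); classification runs 300 + 300 particles at box 32; frame
refinement runs 12 particles over 11 tilts with 8 frames. These sizes
were chosen as the smallest at which the estimated quantities are
stable against seed changes; the same generators scale to larger fields
by changing the specification only.

# Known limitations

- The deformation model is piecewise-constant per region; real
  beam-induced motion is smooth, and a fine grid trades spatial
  resolution against overfitting exactly as coarse grids trade the
  reverse.
- Frame refinement assumes the particle poses are final; it does not
  re-refine poses against frame averages.
- The CTF estimator implements a documented simplification of
  tilted-spectrum estimation (global strips/sectors, no
  resolution-dependent fit ranges).
- Ab initio reference generation, fiducial-based tilt-series alignment,
  neural-network picking and GPU execution are out of scope.
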