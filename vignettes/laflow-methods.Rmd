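---
title: "Quantifying left-atrial hemodynamics from 4D flow MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-atrial hemodynamics from 4D flow MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`laflow` turns a masked, time-resolved three-directional velocity field — a 4D
flow MRI acquisition of the left atrium (LA) — into a compact set of
hemodynamic descriptors: a phase-contrast MR angiogram (PC-MRA) for
segmentation support and volumetry, energy indices (kinetic energy, viscous
energy loss), rotation indices (vorticity, Q-criterion vortex-core fraction),
pulmonary-vein (PV) and mitral (MV) flow-rate waveforms with their clinical
wave features, pathlines for visualization, and an age-adjusted cohort
comparison layer. This vignette explains the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not demonstrate.

## Data model and conventions

A `flow_dataset` holds velocity as a 5-axis array indexed
`(phase, z, y, x, component)` together with the magnitude image, grid spacing
(mm), origin (mm) and the RR interval (s). Everything internal is SI: velocity
in m/s (inputs declared in cm/s are converted on ingestion), voxel volumes in
m^3; presentation units (ml/s, mJ, mW, ml/m^2) are applied when curves and
features are emitted. World coordinates follow the VTK image-data convention
`world = origin + index * spacing` with 0-based indices, and velocity
components are expressed along the world x/y/z axes. Phase k (0-based) is at
time `k * RR / N`; uniform phase spacing is assumed, with the RR interval
taken from the file metadata or the configuration (a 1 s default is applied,
with a warning, when neither is available — acquisition files rarely state the
RR explicitly and the cohort statistics only require a consistent time base
per subject).

Masks are integer label volumes on the same grid (`LA = 1` by convention,
optional LV and aortic labels). `apply_mask()` zeroes every velocity vector
outside the chosen label at all phases, leaving in-mask values and the
magnitude untouched; it is idempotent, and all downstream indices operate on
the masked field.

## PC-MRA

The angiogram is the time average
$$\mathrm{PCMRA} = \frac{1}{N}\sum_{t=1}^{N} M(t)\,\bigl(V_x^2+V_y^2+V_z^2\bigr)^{\gamma},$$
which highlights the blood pool: the velocity term separates moving blood
from static tissue while the magnitude factor suppresses regions with no
signal (air, lung). The exponent `gamma` compresses the dynamic range so that
the slow atrial flow is not drowned out by fast aortic flow; `gamma = 0.4` is
the LA default and a sweep utility (`pcmra_gamma_sweep()`) supports visual
re-tuning. Because `gamma != 0.5` makes the power term unit-dependent, the
units used inside the power are an explicit argument; the default is cm/s,
the acquisition convention. The magnitude image is passed through raw — any
normalization would cancel per subject in the time average and the
segmentation consumer is intensity-scale invariant anyway. Time-resolved
(per-phase) PC-MRA is deliberately out of scope: single-phase angiograms in
low-flow intervals carry too little signal to segment.

## Velocity-gradient machinery

Vorticity, Q-criterion and viscous dissipation all derive from the per-voxel
velocity-gradient tensor. Derivatives use central differences where both axis
neighbors lie in the mask, one-sided differences where only one does, and
zero (with a reduced-accuracy flag) where neither does; the flagged fraction
is available from `velocity_gradient()`. This stencil is exact for affine
fields, which pins the calibration oracles: rigid rotation at rate
$\Omega_z$ gives $|\omega| = 2\Omega_z$ and $Q = \Omega_z^2$ exactly,
including at mask boundaries. Tensor norms in the Q-criterion are Frobenius
norms — the choice under which the rigid-rotation identity holds.

* **Kinetic energy.** $KE(t) = \tfrac12 \rho \sum_i v_i^2\,\mathrm{Vol}_i$
  over LA voxels, reported in mJ, with a volume-normalized variant (mJ/ml)
  that removes chamber-size bias. Blood density defaults to
  $\rho = 1060\ \mathrm{kg/m^3}$ (configurable). The per-voxel-volume reading
  of the mass term is the only dimensionally consistent one.
* **Viscous energy loss.** The Navier-Stokes dissipation function
  $$\Phi_v = \tfrac12 \sum_{ij}\Bigl[\bigl(\partial_j v_i + \partial_i v_j\bigr)
    - \tfrac23 (\nabla\!\cdot\!\mathbf v)\,\delta_{ij}\Bigr]^2,\qquad
    EL(t) = \mu \sum_i \Phi_{v,i}\,\mathrm{Vol}_i,$$
  with $\mu = 0.0035$ Pa·s. The bracketed term is squared — without the
  square the quantity is sign-indefinite and the Poiseuille closed form
  ($EL = 2\pi\mu L v_0^2$) fails; with it, VEL is non-negative for every
  field and vanishes for rigid motion. The divergence term is retained even
  though incompressible flow makes it zero in the continuum: measured MRI
  fields are not discretely divergence-free.
* **Vorticity.** $\omega = \nabla\times\mathbf v$ per voxel;
  the summary $|\omega_{LA}|(t)$ is the volume-averaged vorticity magnitude
  (sum of $|\omega|\,\mathrm{Vol}_i$ over the LA divided by LA volume), which
  removes dilation bias. With uniform voxels this equals the plain mean of
  per-voxel magnitudes, so the distinction between the two published
  conventions is immaterial here.
* **Q-criterion.** $Q = \tfrac12(\|\Omega\|_F^2 - \|S\|_F^2)$ separates
  rotation-dominated from strain-dominated regions; the summary curve is the
  fraction of LA voxels with $Q$ above a threshold, default
  $500\ \mathrm{s^{-2}}$ (results are insensitive above
  $\sim 100\ \mathrm{s^{-2}}$; the threshold is a parameter). For
  visualization a 3×3×3 median filter (`median_filter3()`, nearest-edge
  replication at borders — the border policy is ours, chosen to avoid
  shrinking the field) suppresses speckle before volume rendering.

## Cross-sections, flow rates and wave features

Each vessel is located by a user-placed sample sphere (RS/RI/LS/LI PVs and the
MV). The cross-section normal is the normalized sum of the per-phase mean
in-sphere velocity vectors over the `min(5, N)` phases with the largest mean
speed — averaging over the strongest phases stabilizes the direction against
diastolic flow reversal. In-sphere means (voxel centers inside the sphere) are
used rather than maxima, which are noise-sensitive. The plane through the
sphere center is sampled on a uniform in-plane grid with step half the
smallest voxel spacing and extent three sphere radii (resolving ~5 mm vessels
on 1.2-2.4 mm grids); a sample is lumen when the trilinearly interpolated
binary label is at least 0.5, restricted to the connected component containing
the center so a neighboring vessel crossing the plane is excluded. The flow
rate is the discrete flux $Q(t) = \sum v\cdot\hat n\,\Delta A$ (ml/s) with
trilinear velocity interpolation; the sign is flipped when necessary so the
cycle-integrated flow is positive, matching how PV and MV curves are
conventionally plotted.

Wave detection operationalizes definitions that clinical practice leaves
informal; every threshold is a parameter:

* **PV (S/D/Ar).** The systolic window runs from cycle start until the
  subject's MV flow first exceeds 10% of its maximum (E-wave onset); S is the
  PV maximum inside the window, D the maximum after it, Ar the minimum over
  the last 30% of the cycle (atrial contraction). A non-negative Ar is
  reported with a "no reversal" flag.
* **MV (E/A).** Candidate peaks are local maxima of at least 20% of the
  global maximum; E is the first, A the last. Defining E as the first
  prominent peak (rather than the global maximum) keeps the detector correct
  for the impaired-relaxation pattern E < A, where no peak follows the global
  maximum. The split point is the flow minimum between E and A; passive
  volume integrates from E onset (start of E's contiguous run above 10% of
  E) to the split and active volume from the split to cycle end, trapezoidal
  with negative lobes clipped and the cycle closed by wrapping the first
  phase sample (the cardiac cycle is periodic). E/A fusion is flagged when
  the trough exceeds 20% of E.

## Volumetry, agreement and overlap metrics

LA volume is voxel count times voxel volume; LAVi indexes it to the DuBois
body surface area $0.007184\,W^{0.425}H^{0.725}$. The 2D comparator is
biplane disk summation $V = (\pi/4)\sum a_i b_i (L/N)$ with diameters read at
disk centers (midpoint rule); measuring the 2D cine contours themselves is
out of scope. Method agreement reports Pearson r with a Fisher-z 95% CI and
Bland-Altman bias with limits of agreement `bias ± 1.96 sd` (sample SD).
Segmentation overlap uses Dice (two empty masks define Dice 1, with a
warning) and HD95 — the 95th percentile, linearly interpolated, of the pooled
bidirectional surface distances between boundary-voxel centers (the common
segmentation-evaluation convention).

Surface meshes are extracted at the 0.5 iso-level of the label indicator by
marching tetrahedra (Kuhn 6-tet cube decomposition, linear edge
interpolation, welded and consistently outward-oriented). Raw binary
extraction stair-cases the surface and overestimates the area of smooth
shapes by upwards of 20%, so the default pipeline Gaussian pre-filters the
indicator (sigma 0.6 voxel) and applies 10 Taubin smoothing passes
(lambda 0.5, mu -0.53); these values were calibrated once on digitized-sphere
benchmarks to bring both area and enclosed volume of resolved blobs within
~2% of closed forms. Regions too small to survive the pre-filter (e.g. a
single voxel) automatically fall back to the raw indicator, and both
smoothing steps can be disabled. Sharp-cornered regions (boxes) lose ~2% of
volume to corner rounding — a known limitation; the tetrahedral volume mesh
(exact by construction) is the reference for volumes. Meshes export to ASCII
STL and legacy VTK.

## Pathlines

Particles emitted from the PV cross-sections are advected with classical RK4,
trilinear interpolation in space, linear in time, cyclic over the cardiac
cycle; particles leaving the mask terminate and are flagged. Each particle
keeps a six-phase trail with a per-point speed attribute, written as legacy
VTK polylines for any VTK viewer; rendering itself is delegated. RK4 with
these interpolation orders is exact on uniform fields and conserves
circular-orbit radii to well below 0.1% per revolution at the default
sub-stepping.

## Cohort statistics

For each scalar feature the cohort layer fits the homogeneous-slopes ANCOVA
`value ~ age + group` (no group×age interaction — the default reading when
age is a nuisance covariate), tests the group factor with the covariate
partialled out (equivalently type-II sums of squares for this two-term
model), and reports partial $\eta^2 = SS_g/(SS_g+SS_{res})$. Only when the
group effect is significant at $\alpha = 0.05$ does the post hoc run: pairwise
Tukey tests on the covariate-adjusted means (studentized-range p-values on
the model residual df), Cohen's d on the raw values with pooled SD (the
unadjusted convention, labeled as such), and Benjamini-Hochberg adjustment
over the pairwise family within one feature (the family scope is a choice;
adjusting across features would conflate unrelated hypotheses). The
implementation is cross-checked in the test suite against independent
references (`car::Anova`, `multcomp::glht`).

## The synthetic module: what it emulates and what it does not

Analytic fields — rigid rotation, Poiseuille tube, Lamb-Oseen vortex — have
closed-form gradients, energies and fluxes and serve as oracles for every
differential operator. The LA phantom assembles a full synthetic subject:
an ellipsoidal chamber (semi-axes 25, 25, 30 mm), four PV tubes (radius 7 mm)
carrying Poiseuille profiles scaled by triphasic S/D/Ar Gaussian-pulse
waveforms (80, 64, -24 ml/s; S/D = 1.25), an MV tube (radius 13 mm) with a
biphasic E/A waveform (shape ratio 2.0) rescaled by a single factor so the
cycle-integrated MV volume equals the summed PV volumes (mass balance by
construction), and a decaying Lamb-Oseen vortex (Gamma 0.02 m^2/s, core 8 mm)
in the chamber during the S and D windows. Defaults mirror a clinical
acquisition — 1.5 mm isotropic spacing, 20 phases over 1 s, all speeds below
a 150 cm/s VENC — and per-beat volumes (~96 ml total PV inflow) sit in the
physiologic range. Ground truth is defined on the phantom's own phase grid,
since the discrete field *is* the phantom; analytic pulse integrals are
recorded alongside.

The phantom validates geometry, flux, waveform and feature plumbing — not MR
physics. It has no noise by default (`add_noise()` adds calibrated Gaussian
noise when wanted), no partial-volume or aliasing effects, no wall motion,
and its chamber field is not globally divergence-free (the tubes end inside
the chamber). Passing the phantom therefore demonstrates that the pipeline
recovers what the data contain; it does not bound errors on real
acquisitions, where noise, segmentation error and VENC limits dominate.

## Numerical choices and problem sizes

Discretization facts worth knowing, all reproduced by the test suite:

* One-sided boundary differences make gradient oracles exact for affine
  fields but underestimate wall shear for curved profiles; the Poiseuille
  dissipation error decreases from coarse to fine grids (2.4 → 1.2 → 0.6 mm)
  yet oscillates with wall/voxel alignment, so the headline closed-form check
  uses a well-resolved wall (20 voxels per diameter), where it lands within
  0.5%.
* Fluxes are much more forgiving than dissipation: Poiseuille flow rate is
  recovered within ~1% at 6 voxels per radius, obliquity-invariant within 3%
  up to 60 degrees.
* Upsampling uses separable cubic splines per axis (3-D cubic rather than
  slice-wise 2-D bicubic); it reproduces affine fields exactly and halves the
  spacing about the same physical extent.
* Validation problem sizes are chosen for sub-minute runs on one CPU: 40^3
  oracle grids, a ~67×37×55 phantom, 1000 null simulations for the ANCOVA
  type-I rate, 300 for power, and n = 200 agreement pairs; all stochastic
  checks fix their seeds.

## Known limitations

Static (time-averaged) segmentation only — no valve tracking or time-resolved
LA emptying; no phase unwrapping, eddy-current or background-offset
correction (assumed done upstream, as is standard for vendor-processed
data); no DICOM ingestion (NIfTI/VTI only); relative-pressure estimation is
out of scope; the biplane comparator consumes pre-measured diameters; mesh
areas of sharp-cornered regions are biased by smoothing as noted above; and
the wave-feature thresholds, while configurable, are operational definitions
rather than standardized clinical criteria.
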