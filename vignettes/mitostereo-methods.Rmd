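---
title: "Virtual stereology of microsporidian mitosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual stereology of microsporidian mitosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitostereo)
```

## The problem

Mitosomes are the smallest known mitochondria: genome-less,
double-membraned organelles of roughly 50–250 nm found in microsporidian
parasites. At that scale the only quantitative access is electron
microscopy of serial sections, and every number of biological interest —
how many mitosomes a cell has, how large they are, what fraction of the
cytoplasm they occupy, whether they sit at the spindle pole body (mSPB) —
must be *estimated* from 2D profiles with design-based stereology. Two
systematic effects dominate:

* **Overprojection (the Holmes effect).** A 43 nm section imaged as a
  projection shows the *shadow* of everything in the slab, not a plane
  cross-section. For objects comparable in size to the section thickness
  the apparent profile area, and hence any Cavalieri volume, is inflated
  substantially.
* **Profiles are not particles.** A 200 nm organelle appears in several
  consecutive sections; counting profiles overcounts. The appearance rule
  — count a profile present in one section but absent in the next — counts
  each particle exactly once.

This package rebuilds that entire measurement chain *in silico*: a
generator of 3D phantom cells with known ground truth, a virtual microtome
that cuts them the way the real workflows do, the estimators themselves,
and the downstream partition/correlation statistics. Because the truth is
known, every estimator can be validated by parameter recovery, which is
what the test suite and `scripts/acceptance.R` do.

## Geometry

Three convex solids cover everything in the model (lengths in nm,
volumes in nm³ internally; µm³ only at I/O through `nm3_to_um3()` — one
internal unit avoids silent 10⁹ errors):

| kind             | volume                        | surface                   | used for |
|------------------|-------------------------------|---------------------------|----------|
| sphere           | $\tfrac{4}{3}\pi r^3$         | $4\pi r^2$                | nucleus, cell |
| spherocylinder   | $\pi r^2(L-2r)+\tfrac{4}{3}\pi r^3$ | $2\pi r(L-2r)+4\pi r^2$ | mitosome ("dumbbell") |
| half sphere      | $\tfrac{2}{3}\pi r^3$         | $2\pi r^2$ (curved cap)   | mSPB |

The half-sphere surface deliberately excludes the flat face: it rests on
the nuclear envelope, and the occupancy model counts mitosome footprints
on the cytoplasm-facing cap only.

The cutting axis is the global $z$ axis and sections are half-open slabs
$[z_\mathrm{lo}, z_\mathrm{hi})$, so a boundary point belongs to exactly
one section. Membership tests are strict `<=` comparisons of squared
distances in exact arithmetic — no epsilon inflation — which makes
boundary behaviour testable. The slab-shadow query for a spherocylinder
minimises the convex point-to-segment distance over $z$; the minimum of a
convex piecewise quadratic is found exactly from the piece minimisers and
the slab boundaries, so shadows are evaluated in closed form, vectorised.

Two reporting conversions are provided because size at this scale is
conventionally communicated through equivalent solids:
$d = (6v/\pi)^{1/3}$ (equivalent sphere; a 0.0001 µm³ organelle reads as
58 nm) and $L = 2r + (v - \tfrac{4}{3}\pi r^3)/(\pi r^2)$ (equivalent
capped cylinder at fixed cap diameter). The second formula makes a known
inconsistency visible: at a 50 nm cap, a length of 340 nm corresponds to
≈0.000635 µm³, not to 0.00025 µm³ (which maps to 144 nm). The package
exposes the exact closed form and does not attempt to reproduce the
inconsistent pairing.

## The synthetic world

`generate_cohort()` builds cells in their own frames (nucleus centred at
the origin) with ground truth recorded per cell and never touched by the
estimators. Defaults encode the measured biology; where a value is stated
nowhere, it was chosen once on biological plausibility and is listed here:

* **Mitosome sizes.** Minor axis (diameter) uniform on 47–119 nm, major
  axis (tip-to-tip length) uniform on 78–267 nm, conditioned on
  $L \ge 2r$ by rejection. These are the published identification bounds.
* **Counts.** *E. cuniculi*:
  $N = \max(1, \mathrm{round}(\alpha + \beta V_\mathrm{nuc} +
  \varepsilon))$, $\varepsilon \sim \mathcal N(0, 1.2^2)$, with
  $\alpha = 3.7$ and $\beta = 3.7/\mathbb E[V_\mathrm{nuc}]$ so the cohort
  mean is 7.4 and half of it scales with nucleus volume — reproducing the
  observed smooth scaling of the mitosome complement with nuclear size
  without asserting a mechanism. *T. hominis*: uniform on 14–18 (the
  "rather constant ~16 per cell" regime).
* **Cell geometry.** Nucleus radius uniform on 300–500 nm
  (*E. cuniculi*) or 450–700 nm (*T. hominis*); cell radius = nucleus
  radius + 400 nm (or + 500 nm). These put nuclei at ~0.1–0.5 µm³ and the
  mitosome volume fraction at a few tenths of a percent of cytoplasm —
  the observed order of magnitude.
* **mSPBs.** Two half spheres on opposite poles of the nuclear envelope
  (isotropic pole direction), radii uniform on 35–60 nm, i.e. volumes
  ≈0.0002–0.0006 µm³, the measured range.
* **Tethering.** Each mitosome is tethered with probability 0.92
  (*E. cuniculi* interphase) or per the *T. hominis* stage schedule
  0.10 → 0.30 → 0.45 → 0.60 → 0.73 (early → prespore; only the endpoint
  0.73 is a published number, the ramp is the package's monotone
  interpolation of "progressive association"). A tethered mitosome is
  "at the mSPB" iff the surface-to-surface distance between its nearer
  cap and the mSPB cap is at most 10 nm — "direct contact" needs a
  metric, and 10 nm is below membrane resolution at these section
  thicknesses. Tethered mitosomes grow outward along the local
  nuclear normal, jittered within a 25° cone (they "grow out into the
  cytoplasm from a tethering zone"); free mitosomes are placed uniformly
  in the cytoplasm shell by bounded rejection (the within-cell
  distribution of free mitosomes is not published; uniform is the
  assumption).
* **Partitioning.** `ordered_even` assigns tethered mitosomes to the two
  poles differing by at most one (surplus side random); `binomial_random`
  flips a fair coin per mitosome — the null model.
* **Dynamin inhibition.** `apply_dynamin_inhibition()` merges consecutive
  pairs within each cell (tethered first): summed volume, the larger cap
  diameter, length re-derived from the volume formula. An odd count
  carries one mitosome unmerged, so totals are conserved exactly and the
  count becomes $\lceil n/2 \rceil$ — which is why the mean individual
  volume ratio is ≈1.85 rather than exactly 2 (odd-remainder dilution).
  Merged tethered bodies are re-anchored at their pole with the contact
  gap preserved; a long merged body may locally protrude beyond the
  idealised cell sphere, and the microtome spans all bodies so nothing is
  lost.
* **Reproducibility.** One root seed; every cell derives an independent
  substream keyed by its index, so a cohort's first $k$ cells are
  identical whatever the cohort size, and the caller's RNG state is
  always restored.

What the phantom does **not** emulate: image formation (contrast, noise,
staining), section compression and tilt, membrane bilayer thickness,
non-spherical nuclei or multinucleate syncytia (each simulated "cell" is
one nucleus with its own cytoplasm shell), ER contacts, and any temporal
dynamics. A green recovery test therefore establishes correctness of the
*estimators* under ideal sectioning, not robustness to imaging artefacts.

## The virtual microtome

`cut_serial()` produces conventional sections (overprojected slab
shadows, default 43 nm); `cut_tomographic()` produces thin slices
(mid-plane cross-sections, default 2 nm — the tomographic slice thickness
is not published; 2 nm is an implementation choice tested down to 1 nm);
`assemble_superslices()` merges $k$ thin slices into blocks whose profile
is the union of member cross-sections, the discrete shadow that emulates
a conventional section built from tomography. The section phase is
uniform on $[0, t)$, making Cavalieri estimates design-unbiased.
`subsample_intermittent()` implements one-in-$k$ recording (spacing
metadata becomes $kt$), and `sample_ministacks()` places short runs of
consecutive sections uniformly in the cell for density estimation, each
with a lookahead section so appearance counting can terminate runs at the
stack end without truncation bias.

Profile areas are obtained the way they are on micrographs: a square
lattice of stated pitch is dropped with a random offset per section and
hits of the *exact* membership query are counted — no rasterised mask is
involved in point counting, so there is no rasterisation bias; masks
(unions) appear only inside superslices.

## Estimators

* **Cavalieri:** $\hat V = d \sum_i A_i$ with $A_i = s^2 P_i$ from point
  counts.
* **Overprojection factor:** empirical
  $f = \hat V_\mathrm{thick}/\hat V_\mathrm{thin}$ from a thin-vs-thick
  calibration of the same objects; corrected estimates are raw$/f$, and
  both are always emitted. The model-based comparator is the full-shadow
  Holmes form under isotropic orientation, $f = 1 + tS/(4V)$, using
  Cauchy's mean projected area $S/4$ (the cited "model-based approach"
  names no formula; this is the standard formalisation and is labelled as
  such). For a sphere it reduces to $1 + 3t/(4r)$, and the simulated
  phase-averaged shadow pipeline reproduces it — that identity is the
  oracle-equivalence acceptance criterion. For the configured mitosome
  size distribution the aggregate factor $1 + t\Sigma S/(4\Sigma V)$
  evaluates to ≈1.5–1.6, which is also where the simulated calibration
  lands — the same magnitude as the published empirical 1/1.61.
* **Appearance counting:** profile runs (linked by body identity, the
  simulation truth) ending inside the stack; exact, not merely unbiased,
  for convex particles fully spanned. Runs alive at the final section are
  terminated only by a lookahead section or the explicit
  `assume_empty_after` flag; otherwise they are flagged truncated.
* **Densities:** $V_V$ as point-count ratios, $N_V$ as ends per sampled
  reference volume, totals as $N_V \hat V_\mathrm{ref}$. In the ministack
  driver the reference (cell minus nucleus) is recorded as mid-plane
  cross-sections: for µm-scale compartments the Holmes inflation is only
  ~4%, and recovery criteria need an unbiased reference; mitosome
  profiles always use the shadow model. The driver counts ends via the
  z-extent form of the appearance rule (a convex body's run ends in the
  section containing its top); a test pins its equality with the explicit
  rule on reproduced stack placements.
* **Star volume:** $v^* = \tfrac{\pi}{3}\,\overline{\ell^3}$ over
  point-sampled isotropic intercepts; chords are measured by bisection
  along the ray (valid because every body is convex), and for a sphere
  $v^*$ equals the volume — the identity used as an acceptance check.
* **Error coefficients:** `coefficient_of_error()` is the between-cell
  CE of a cohort mean, $(\mathrm{SD}/\sqrt n)/\bar x$, matching the
  $CE_n$ notation attached to cohort means; the within-stack
  Gundersen–Jensen CE is a separate, clearly named function
  (`ce_systematic()`) and never silently substituted.
* **Partition statistics:** evenness is $|n_1 - n_2| \le 1$; the pooled
  ("weighted average") binomial proportion is
  $\hat P = \Sigma n_1 / \Sigma(n_1+n_2)$ with a normal-approximation
  interval (Wilson optional), reported as the larger of $\hat P$ and
  $1-\hat P$ because pole labels are arbitrary; the null probability of
  an even-or-near-even split is the central binomial term
  ($2\binom{n}{(n-1)/2}/2^n$ for odd $n$). Contingency comparisons use
  Pearson's chi-square without continuity correction; correlations are
  Pearson $r$ with two-sided $t$ p-values, reported raw (no multiplicity
  adjustment, matching the reporting style of the original tables).
* **mSPB occupancy:** from a half-sphere volume,
  $r = (3v/2\pi)^{1/3}$, curved-cap area $2\pi r^2$, end-on footprint
  $\pi (d/2)^2$, capacity their integer ratio — all intermediates are
  returned because the published mSPB area of 4,218 nm² matches no single
  convention exactly and users may want to test alternatives.

## Numerical and design choices

* Half-open slabs resolve boundary ties; the $z_\mathrm{hi}$ face of a
  shadow query is handled so that membership attained only exactly at the
  open boundary does not count.
* Rejection samplers (sizes, free placement, jitter) are bounded (200 to
  1000 retries) and fail loudly rather than loop.
* The tethered-placement fallback is the purely radial axis, which is
  always feasible; nucleus intersection is checked exactly via
  segment-to-point distance.
* JSON (via jsonlite) is the configuration format: it round-trips
  losslessly and needs no dependency outside Imports; every pipeline run
  writes its resolved configuration next to its outputs, minus the output
  path itself (which would break byte-reproducibility across
  directories).
* In the perturbation-detection validation the two arms are paired — the
  treated arm is the inhibited copy of the same simulated population,
  sectioned with independent seeds. Independent cohorts per arm add
  cohort-sampling noise (the true count ratio varies by ±0.04 between
  seed pairs) that has nothing to do with what the check validates,
  namely that the ministack estimators detect halved $N_V$ at conserved
  $V_V$.
* Mitosomes may overlap each other near a crowded pole (five footprints
  do not pack on a 40 nm cap); per-body profile sums keep volume
  estimates consistent with the recorded per-body ground truth, so this
  does not bias recovery.

## Limitations

Recovery is demonstrated under the phantom's assumptions: ideal slab
geometry, perfect profile identification and linkage, convex organelles.
Real material adds segmentation error, section thickness variability,
lost or faint caps and anisotropic deformation, none of which are
modelled; the overprojection correction recovered here is therefore an
upper bound on what the same workflow achieves on micrographs. The
binomial partition machinery assumes independent assignment and cannot
by itself distinguish ordered segregation from any other strongly
even-biased mechanism.

## A worked pass through the pipeline

```{r example, eval = FALSE}
library(mitostereo)

cfg <- cohort_config(n_cells = 18, seed = 1)
cohort <- generate_cohort(cfg)
glance(cohort)

# thin-vs-thick calibration on four cells, then corrected estimates
cal <- derive_overprojection_factor(cohort, cohort$cells$cell_id[1:4],
                                    t_nm = 43, dz_nm = 2, seed = 2)
thick <- estimate_volume_serial(cohort, t_nm = 43, seed = 3)
corrected <- apply_volume_correction(thick, cal$factor)

# exact particle numbers by the appearance rule
counts <- estimate_number_serial(cohort, t_nm = 43, seed = 4)

# partitioning across the two spindle pole bodies
pooled_binomial_proportion(partition_table(cohort))
plot_partition(cohort)
```
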