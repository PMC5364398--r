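---
title: "Methods: analysing membrane-spanning DNA nanotube trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing membrane-spanning DNA nanotube trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the data model

A DNA nanotube (DNT) pore is a bundle of six interconnected B-DNA duplexes
spanning a lipid bilayer, held in the hydrophobic membrane core by rings
("bands") of ethyl-phosphate modifications on its outer surface. The
observables this package computes are geometric and statistical functions of
particle trajectories: positions are stored in nm, times in ps, and each
particle carries a semantic *role* (DNA backbone/base, ethyl anchor, the
lipid choline/phosphate/glycerol/tail moieties, water, Na⁺, Cl⁻). Role
assignment from file naming goes through an editable dialect table; unknown
names are a hard error listing the offenders, because silently misclassified
particles would corrupt every density downstream (an explicit opt-in maps
them to `OTHER` instead).

Two conventions apply everywhere:

* **z is the bilayer normal**, and the bilayer reference plane (z = 0 for
  thickness and leaflet assignment) is the median z of the lipid phosphates,
  recomputed per frame, so no pre-centred input is assumed.
* **Coordinates are never rewrapped.** Boxes are orthorhombic and the
  minimum-image convention is applied inside distance computations only,
  keeping raw data immutable.

Stored particle and frame indices are 1-based, the natural R convention;
file formats keep their own 1-based serials on write. Helix ids run 0–5.
Because generic GRO/PDB naming cannot carry helix/strand identity, the
writer encodes it (residue name `DNT<h>`, atom suffix `A`/`B`), which makes
write/read round-trips lossless under the `cg-martini` dialect; generic DNA
naming falls back to helix 0, strand 0.

# The idealized tube model

`buildHexagonalScaffold()` places parallel duplex axes on a regular hexagon
whose side (equal to its circumradius) is the inter-helix spacing
`spacing_d` (default 2.0 nm). Each duplex carries one backbone
pseudo-particle per nucleotide on an ideal helical path: rise 0.34 nm/bp,
twist 34.3°/bp, two strands offset by 144° in phase, helix radius 1.0 nm
(the canonical B-DNA duplex radius; with the 2.0 nm spacing, adjacent duplex
surfaces exactly touch). Helix starting phases advance by 60° per helix so
the six-helix model is invariant under a 60° rotation — a convenient
symmetry for testing. This level of detail is deliberate: none of the
in-scope analyses consume sequence, so junction routing is represented only
as optional inter-helix bonds in the elastic-network specification, whose
rest lengths equal build-time distances exactly and whose soft mode uses
k = 100 kJ mol⁻¹ nm⁻² (stiff mode defaults to 500 kJ mol⁻¹ nm⁻², a typical
stiff elastic-network constant, as only the soft value is fixed by the
modelling convention).

**Groove assignment rule.** Analyses that label lipid contacts as
minor/major groove need a geometric definition that the source modelling
conventions leave unstated. The package's declared rule: project the contact
point onto the nearest duplex axis, compute its helical phase, and call it
*minor* when it lies within ±60° of the minor-groove bisector (the
reference-strand phase plus half the 144° strand offset), *major* otherwise.
The 144° wedge between strands is the minor groove side in B-DNA; the ±60°
window covers most of it while leaving slivers adjacent to the strands to
the major side. Fixtures may alternatively label DNA particles explicitly.

# Pore radius profiling and conductance

The pore radius at axial position z is the radius of the largest sphere
centred in that slice plane that touches no particle surface,
`R(z) = max_c min_i (|c − x_i| − r_i)` with 3-D distances (particles in
neighbouring slices constrain the sphere, as in largest-inscribed-sphere
channel profilers). Water and ions are excluded by default; bead radii come
from the dialect (0.26 nm for regular CG beads, 0.23 nm for the small bead
class, a bundled van der Waals table per element for atomistic input —
declared defaults, since no standard exists for CG probe radii).

The per-slice maximization is a two-stage optimizer:

1. a **deterministic coarse scan** on a 0.05 nm grid restricted to a 1.5 nm
   search disc around the seed centre, keeping the top three mutually
   separated candidates;
2. **simulated-annealing refinement** (1000 moves shared across candidates,
   Gaussian steps cooling geometrically 0.1 → 0.005 nm, Metropolis
   temperature proportional to the step, walk confined to the search disc).

The coarse stage exists because single-start annealing alone can miss
narrow off-centre pockets; against an exhaustive 0.01 nm grid search on 100
random 50-particle slices the two-stage optimizer's worst shortfall is
0.002 nm (the test suite enforces < 0.01 nm). Confining the walk to the
search disc keeps the centre path inside the channel: within a frame each
slice is seeded from the previous slice's optimum, with an independent
restart on the axis every 10 slices to escape side channels. Every
(frame, slice) pair uses a fixed derived seed, so profiles are reproducible;
two frames with identical coordinates agree to the optimizer accuracy
(~10⁻³ nm), not bit-for-bit. Radii are capped at half the smaller lateral
box length; capped slices are flagged "open" and excluded from averages and
conductance.

Conductance uses the electrolyte-resistance model `g = πR²/(ρL)`, either
with the mean radius (`uniform`) or slice-wise in series,
`1/g = (ρ/π) Σ dz/R(z)²` (`series_integral`, the default — it is the
natural discretization and is stable under dz refinement). A zero radius
closes the pore (g = 0 with a `closed_at` flag). Bundled resistivities
(Ω·cm: KCl 1.0 M = 8.9, KCl 0.3 M = 27.4, NaCl 0.15 M = 62) are overridable
defaults; the conductance ratio between two salt conditions divides the two
series-integral estimates, so with conductivity proportional to
concentration and identical geometry the 1.0 M : 0.3 M prediction is 10/3.
Access resistance is deliberately out of scope.

# Membrane profiles

* **Radial densities** count particles per role in 0.1 nm cylindrical
  shells of a 4 nm-long cylinder (approximating the membrane thickness)
  centred on the bilayer midplane along the pore axis; densities are counts
  divided by exact shell volumes, so Σ density·volume reproduces the mean
  in-cylinder count to rounding error — asserted as an invariant.
* **The pore axis** is the symmetry axis of the covariance tensor of the
  transmembrane DNA particles: the eigenvector whose eigenvalue is best
  separated from the other two. For a squat tube section the two lateral
  eigenvalues are nearly equal and the distinct one belongs to the symmetry
  axis; for an elongated selection the distinct eigenvalue is the largest.
  Degenerate inputs (fewer than 3 particles, or an exactly planar/collinear
  set with a near-zero eigenvalue) are errors rather than guesses.
* **Thickness** is the phosphate–phosphate distance: per frame, phosphates
  split into leaflets by the median plane (flip-flop is not modelled), then
  per radial shell mean(upper z) − mean(lower z); shells with an empty
  leaflet are reported missing, never zero. The thinning fit
  `h(r) = h0 − A·exp(−(r − r_wall)/λ)` is a Levenberg–Marquardt least
  squares fit beyond the wall radius.
* **Order parameters** use consecutive tail-bead bond vectors against z,
  `S = ⟨(3cos²θ − 1)/2⟩`, accumulated in 1×1 nm² xy cells located by each
  lipid's phosphate. Cells with fewer than 10 bond samples are reported
  missing, because S estimates from a handful of bonds are noise-dominated.
* **RDFs** are standard minimum-image pair histograms normalized by the
  ideal-gas shell expectation at the box density of the partner set,
  excluding self-pairs.
* **Lumen selectivity** counts Na⁺ and Cl⁻ inside a cylinder on the pore
  axis. "Lumen" is defined operationally (the source conventions do not):
  default radius 1.0 nm — the built tube's open radius, and in practice the
  time-averaged minimum pore radius — with the tube's axial extent. The
  ratio carries a binomial 95% CI computed from the mean per-frame counts;
  frames are correlated, so this is an honest lower bound on uncertainty
  only for near-static compositions. A zero anion count reports an infinite
  ratio with the counts attached.

# Dynamics

**Residence times.** A contact event is a maximal run of frames with
minimum-image distance ≤ 0.5 nm between a lipid bead and any selected DNA
particle; runs separated by at most `gap_tolerance` frames are merged
(default 0: no merging, so alternating contacts are single-frame events and
total contact frames are conserved across events). "Perturbed lipids" are
defined operationally as beads with at least one event. Events are labelled
by groove, either geometrically through the model rule above or from the
contacted particle's label.

**Displacement classification.** Δz(t) is the band COM minus the bilayer
COM. A trace is *relaxed* when it enters and stays within ±0.3 nm of zero
to the end — the relaxation time is the first frame of that longest
terminal in-band run (the declared tie-break) — and *exited* when |Δz|
reaches the exit threshold (default 4.0 nm: bilayer half-thickness 2.0 +
band half-extent ~1.0 + 1.0 nm margin) and never re-enters the band;
anything else is *undecided*. Note that with an exponential decay constant
of `relax_time/3`, the first entry into the band occurs at
`relax_time·ln(Δz₀/0.3)/3`, i.e. earlier than `relax_time` itself for
moderate displacements — the classification, not the nominal time scale, is
the tested contract.

**SMD barriers.** The force trace is smoothed with a 5 ns centred running
mean; the entry barrier is located where the smoothed force peaks while the
pulled COM is on the entry side of the bilayer (com-z ≤ lower boundary),
the exit barrier after the transmembrane plateau (com-z ≥ upper boundary).
The default height estimator then refits a local Gaussian (±50 ns window)
to the *raw* force around the located peak. This choice is deliberate:
picking the maximum of a smoothed noisy curve is positively biased by
construction (the bias scales with the same noise amplitude as the
seed-to-seed spread, so no smoothing width fixes it), whereas the local fit
is effectively linear in the data, unbiased under noise — verified
Monte-Carlo over 20 seeds in the tests — and exact on noiseless traces.
`method = "max"` provides the plain smoothed-maximum pick for comparison.
Forces convert to single-molecule units as 1 kJ mol⁻¹ nm⁻¹ = 1.66054 pN.

**Partitioned r.m.s.d.** superposes every frame onto the reference by
least squares over *all* DNA particles (one common fit, not per-partition
fits — the declared convention, so the two partitions are measured in the
same frame), then reports r.m.s.d. separately for particles whose reference
z lies in the transmembrane range and for the rest.

**Membrane deformation** is the xz-projected surface: lipid COM z per
leaflet per x-bin, optionally sampled on a stride (e.g. every 4 ns), with
empty bins flagged.

# The synthetic-data generators

`generateMembraneSystem()` emulates the coarse-grained study conditions: an
18 × 18 × 25 nm box; two leaflets of templated 12-bead PC lipids (choline,
phosphate, two glycerols, two 4-bead chains; ~450 per leaflet, matching the
free area at ~0.6 nm² per lipid) whose phosphate planes follow
`h(r) = h0 − A·exp(−(r − r_wall)/λ)` with h0 = 4.0 nm, A = 0.8 nm,
λ = 1.0 nm — an exponential stand-in for the observed near-tube thinning,
which decays to noise ~2 nm from the wall; acyl-chain bonds drawn with the
fixed polar angle that makes the per-zone order parameter exact in
expectation (defaults 0.25 within 1.5 nm of the wall, 0.45 beyond,
emulating disordering near the tube); the built tube inserted at a set tilt;
lumen ions drawn cation-first with probability ratio/(1+ratio) (the drawn
composition is the recorded ground truth, and bulk ions/water are kept out
of the lumen cylinder so the analysis target is unambiguous); a neutral
bulk electrolyte; and per-frame Gaussian jitter (σ = 0.05 nm). Lipids are
rigid templates jittered per frame, not simulated — sufficient because all
in-scope analyses are geometric/statistical. Identical seed + parameters
give bit-identical trajectories.

`generateSMDTrace()` produces constant-velocity pulling records
(10 nm μs⁻¹) with Gaussian entry/exit force bumps centred where the band
COM crosses the bilayer boundaries (defaults 1000 and 400 kJ mol⁻¹ nm⁻¹,
widths 0.8 nm — narrow enough that the two barriers do not overlap, which
keeps the configured heights equal to the trace's actual local maxima) plus
white noise. `generateDisplacementTrace()` produces exponential-relaxation
or drift-plus-diffusion COM traces; `generateContactFixture()` toggles
lipid beads in and out of contact with exponential lifetimes per bead type
and groove (sn2 longer than sn1 by default).

What the generators do *not* emulate: real lipid dynamics and flip-flop,
water structure, electrostatics, correlated noise in SMD forces, and
conformational fluctuations of the DNA itself. Passing recovery tests
therefore demonstrates the correctness of the estimators on data with known
truth and realistic geometry — not that MD-derived data would satisfy the
same tolerances.

# Problem sizes and tolerances in the test suite

The suite runs on desk-scale versions of the study conditions: synthetic
membranes of 50–450 lipids per leaflet and 2–20 frames, SMD traces of 2 μs
at 10 ps sampling (20 seeds for the Monte-Carlo unbiasedness check),
pore profiles on 17–41 slices, and 100 random slices for the
optimizer-vs-grid-oracle equivalence at 0.01 nm. Thinning parameters are
required to be recovered within 10%, tilt within 0.5°, the lumen ratio
within its binomial 95% CI, and numeric invariants (density conservation,
order-parameter bounds, exact S = 1/−0.5 chains, RDF → 1, r.m.s.d. = 0 on
self-reference, bit-identical pipeline reruns) at the tolerances stated in
the tests.

# Known limitations

* Orthorhombic boxes only; triclinic cells are out of scope.
* The tilt estimator reports the acute axis angle only (no azimuth), and
  the axis rule needs a clearly non-spherical selection.
* Conductance ignores access resistance and assumes the electrolyte fills
  the geometric lumen; predictions are upper bounds for narrow pores.
* The binomial CI on ion selectivity understates uncertainty for strongly
  time-correlated occupancies.
* DCD input takes frame times from `frame_interval`, as the format stores
  none.
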