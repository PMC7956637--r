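---
title: "Cholesterol and ligand contact analysis for membrane-protein trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cholesterol and ligand contact analysis for membrane-protein trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choltraj)
```

# Scope and model

choltraj implements the family of analyses used to characterize how
cholesterol and a bound ligand interact with a five-transmembrane-helix
membrane protein of the TSPO family over a molecular-dynamics trajectory.
All statistics are *occupancy* statistics: a binary contact criterion is
evaluated per frame, and fractions of frames are reported. The package makes
three modelling commitments up front:

* **Heavy atoms only.** Every distance criterion (cholesterol contacts,
  ligand contacts, the H-bond criterion) ignores hydrogens.
* **Contact = minimum distance ≤ cutoff.** A molecule is in contact with a
  residue region when any heavy-atom pair between them is within the cutoff;
  the boundary case (distance exactly equal to the cutoff) counts as a
  contact. Defaults: 5.0 Å for cholesterol–region contacts, 4.5 Å for
  ligand–residue contacts, 3.5 Å for the donor–acceptor H-bond distance.
* **Frame-count normalization.** Percentages divide by the number of frames
  analyzed, and every report records that frame count and the stride, since
  the percentages are meaningless without them. The canonical setup is 1000
  frames at 1 ns stride.

# Motif scanning

Cholesterol-recognition motifs are represented as ordered anchors with exact
gap counts, instantiated from their known TSPO instances rather than from
looser literature consensus patterns (which admit many spurious matches):
CRAC `L–X–Y–X(3)–R`, CARC `R–X(2)–Y–X(2)–L`, CRAC-like `L–X(2)–F–X(3)–R`,
GXXXG, WXPXF, and the LAF tripeptide. The scanner reports *all* matches,
including overlapping ones and every distinct anchor placement of a
variable-gap pattern; ambiguity is resolved by annotating each hit with the
helix/loop region containing its start, never by dropping hits. On the
bundled human TSPO record (UniProt P30536) each motif has exactly one hit in
its expected helix (CRAC and CARC in TM V, CRAC-like in TM I, the
oligomerization GXXXG at 83–87 in TM III), which the test suite pins down.

Percent identity uses Needleman–Wunsch global alignment (via Biostrings)
with BLOSUM62, gap open 10, gap extend 0.5 — a conventional choice, made
explicit and configurable because identity values can shift by a point or
two under other conventions. Identity is identical columns divided by
aligned columns, excluding terminal-gap columns.

# Contact series and occupancy statistics

`region_contact_series()` produces the central data structure: a logical
array over (frame × cholesterol molecule × named region). Regions are
residue ranges (helices TM I–TM V, loops, and the motifs above, which
deliberately overlap their helices). From it derive:

* `occupancy_percent()` — 100 × (frames with ≥ 1 bound molecule) / frames,
  the per-helix table statistic;
* `mean_bound_per_frame()` — total (frame, molecule) bound pairs / frames;
* `total_bound_ratio()` — between two systems (e.g. apo / holo), where a
  bound event is one (frame, molecule) pair touching *any* region. A
  molecule bound to several regions in one frame counts once per region for
  per-region statistics but once in total for the system ratio, keeping the
  two kinds of statistic independent.

The minimum-distance test is grid-accelerated (cell lists at the cutoff
length) but contractually identical to the all-pairs search, which the test
suite enforces against an independent brute-force oracle on random
configurations. Minimum-image distances are applied only when box dimensions
are present; the synthetic fixtures are non-periodic.

## Simultaneous versus bridging motif occupancy

For a motif pair (CRAC, CARC), each frame is classified as `none`, `only_A`,
`only_B`, `simultaneous`, or `bridged_only`. *Simultaneous* requires two
**distinct** molecules, one on each motif — formally, a system of distinct
representatives for the two binder sets, which for two motifs reduces to:
both sets non-empty and their union containing at least two molecules. A
lone molecule bridging both motifs is `bridged_only` and excluded from
simultaneous binding. The mixed case (a bridging molecule plus an
independent partner on one motif) *is* simultaneous, because a distinct pair
exists; this is the weakest rule consistent with requiring two different
molecules, and the tests verify it against exhaustive enumeration of all
three-molecule configurations. The five classes partition the frames.

## Leaflet assignment

Each lipid is assigned to the upper or lower leaflet by the z coordinate of
a reference atom (cholesterol hydroxyl oxygen; phospholipid phosphorus)
relative to the membrane midplane, computed as the mean z of all lipid
reference atoms rather than the box centre so that rigid membrane drift
cancels. Upper/lower sub-segments of a helix can be analyzed by supplying
split residue ranges as extra regions.

# Ligand fingerprints

`residue_contact_fractions()` reports, per protein residue, the fraction of
frames with any residue heavy atom within 4.5 Å of any ligand heavy atom,
over the full trajectory or over split windows (e.g. before/after a
binding-pose change); windowed fractions over disjoint windows average,
weighted by frame counts, to the full-trajectory fraction, and this is
tested as an invariant. `classify_binders()` maps fractions to classes with
*left-closed* boundaries: ≥ 0.90 constant, ≥ 0.75 frequent, > 0 transient.
Treating exactly 0.90 as constant keeps both boundaries consistent
("at least" semantics); the convention is recorded in the report header.
H-bond occupancy is deliberately a pure distance criterion (≤ 3.5 Å between
a configured donor and acceptor heavy atom, no angular term), and
donor/acceptor atoms are configuration, not inferred — the package performs
no bond perception. Geometric interaction typing (π-stacking and relatives)
is out of scope.

# Structural metrics

* **Superposition** is Kabsch's SVD solution with the reflection corrected,
  so the rotation is always proper. Tests check it against a direct
  numerical minimization over rotation angles.
* **RMSD** series superpose each frame's selection (by default the heavy
  backbone atoms of the core residue range, residues 5–158, excluding the
  flexible termini) onto a reference frame — the first analyzed frame by
  default, configurable, since trajectory tools differ here.
* **RMSF** is computed about the window-average structure after two passes
  of iterative superposition, matching the common toolchain convention, over
  the equilibrated window (default start 400 ns). For Gaussian positional
  noise of standard deviation σ per coordinate the expected RMSF is σ√3,
  shrunk by the rigid-body degrees of freedom the fit absorbs
  (factor √(1 − 2/N) for N fitted atoms); the tests use this corrected
  closed form.
* **PCA** eigendecomposes the 3N-dimensional coordinate covariance via SVD
  of the centred frame matrix after superposition onto the window average.
  Eigenvalues are non-negative, descending, and sum to the total coordinate
  variance (trace identity, tested to 10⁻⁶ relative).
* **Bend profiles** follow the Bendix idea of sliding-window local helix
  axes. The local axis of each C-alpha quadruple is computed by the exact
  geometric construction (the cross product of successive chord
  differences), which returns the true axis *exactly* for an ideal helix —
  hence an ideal helix scores 0° at every window size, comfortably inside
  the "blue" < 6° bin. Axes are aggregated over the window (default 4
  quadruples) by a componentwise median after a helical-geometry validity
  filter (chord lengths within 2.8–4.8 Å, radial turn between 60° and 140°)
  that discards quadruples straddling a kink; the bend angle at a position
  is the angle between the aggregated axes before and after it. Binned
  labels follow the published colour code literally: blue < 6°, cyan 6–12°,
  green 12–18°, yellow 18–24°, red > 24° (so 24° is yellow and 6° is cyan).
  Because the prose description of the plotted per-residue quantity is
  ambiguous, both the instantaneous angles and the change relative to the
  first analyzed frame are returned. Numerical agreement with the original
  visualization plugin is not claimed; correctness is established on
  synthetic kinks of known angle, which are recovered exactly at zero noise
  and within a degree (as the time-median profile) under realistic noise.
  The time-median per-position profile is the recommended summary for noisy
  data; per-frame maxima have heavy upper tails.

# The synthetic generator and its ground truth

`synthesize_trajectory()` emits a trajectory *and* the exact value of every
statistic the pipeline will compute on it. The geometry is deliberately
minimal but sufficient to exercise every rule:

* Five ideal α-helices (1.5 Å rise, 100° twist, C-alpha radius 2.3 Å; six
  atoms per residue — N, CA, C, O, a pseudo side-chain CB, and one amide
  hydrogen so heavy-atom filters are exercised) stand on a circle of radius
  16 Å with alternating direction, using the hTSPO residue numbering for the
  helix ranges (loop residues are simply absent). Helices may carry a kink
  of known angle at a known residue, built by rigidly rotating the distal
  segment about the kink C-alpha.
* The lipid population is 30 POPC + 30 POPE + 10 cholesterol (the 3:3:1
  mitochondrial-like mix) in two leaflets of an implicit slab; cholesterol
  is a five-heavy-atom rod with a designated hydroxyl oxygen, the ligand an
  eight-heavy-atom body with a designated carbonyl oxygen and amide
  nitrogen — enough structure for every cutoff rule without any chemistry.
* **Schedules are realized by placement margins.** A cholesterol scheduled
  as bound is placed with its nearest atom at cutoff − 1 Å from the target
  residue's CB along the local helix-radial direction; unbound molecules
  are parked far beyond cutoff + 2 Å. Scheduled ligand residues each get a
  dedicated ligand atom at the midpoint of the H-bond/contact band
  (4.0 Å), H-bond frames place the carbonyl oxygen at 2.7 Å; the
  pseudo-molecules flex to meet multi-residue and bridging schedules.
  Schedules are explicit frame lists or two-state Markov chains
  (per-frame probabilities `k_on`/`k_off`, started from the stationary
  state), all drawn from the single spec seed.
* **Noise cannot flip a label.** Thermal noise is per-atom Gaussian (σ
  default 0.12 Å) with the displacement *norm clipped* just under half the
  bound-placement margin (0.45 Å). Unbounded Gaussian noise would cross a
  1 Å margin with small but non-zero probability, so label preservation is
  made deterministic by the clip instead; at the default σ the clip
  truncates under 1 % of draws and the Gaussian RMSF statistics are intact.
  The spec constructor rejects clips too large for the margins (including
  the narrower H-bond/contact band when an H-bond schedule is present) and
  warns when the clip visibly truncates the noise distribution.
* **Ground truth is computed from the exact pre-noise, pre-drift
  coordinates** by direct brute-force distance evaluation, independent of
  the grid-accelerated analysis path. This also captures incidental
  contacts that a pure schedule table would miss — a cholesterol placed on
  CRAC necessarily also contacts the enclosing TM V. When σ > 0 the
  generator additionally verifies that no molecule–region distance falls
  inside the ambiguous band around a cutoff and raises an error otherwise.
* **Rigid drift** (a z-rotation plus translation ramped over the
  trajectory) is applied after truth evaluation; it preserves internal
  distances exactly and, being a z-rotation, preserves leaflet geometry,
  so it stresses the superposition-based metrics without invalidating any
  label.

What the generator does *not* emulate: real lipid packing and diffusion,
side-chain chemistry, periodic boundaries, force-field energetics, and
correlated collective motions beyond the planted rigid drift. Passing tests
therefore demonstrate the correctness of the *analysis* logic under known
conditions, not the realism of any simulation.

## The demonstration systems

`demo_apo_spec()` and `demo_holo_spec()` encode the study conditions of the
apo and ligand-bound systems as deterministic schedules, so that the
pipeline's outputs on them equal the published statistics by construction:
per-helix occupancies 32/51/23/27/100 % (apo) and 47/26/19/15/48 % (holo);
apo TM V holding one cholesterol on CRAC throughout plus one on CARC for
half the run (mean 1.5 per frame; 500 simultaneous distinct-molecule
frames); holo cholesterol on the TM I CRAC-like motif and CRAC only, with
simultaneous binding abolished; total bound events 2850 versus 1900 (ratio
1.5, i.e. about 3 versus 2 molecules per frame); apo TM I kinked 51° versus
a 10° holo kink; six full-residence constant binders in the holo pocket,
frequent binders at 0.80/0.76, and a W53–carbonyl H-bond in 60 % of frames
(a chosen demonstration value; the source analyses report the H-bond's
existence, not its percentage). Schedules scale with the frame count, so
scaled-down runs keep the same fractions where the arithmetic allows.
The holo demo uses σ = 0.08 Å with clip 0.23 Å because contact-but-no-H-bond
placements must sit inside a 1 Å band; the apo demo uses the defaults.

# Numerical choices and degenerate inputs

Superposition requires ≥ 3 non-collinear points and corrects reflections;
PCA requires ≥ 2 frames and truncates requested components with a warning;
bend profiles require at least twice the window size in C-alpha atoms;
empty atom selections are errors unless explicitly allowed; a region
resolving to no atoms is an error naming the region; trajectory frames with
mismatched atom counts are errors naming the frame. Distances tie toward
contact (≤). Identity percentages round half away from the convention of
`round()`; report CSVs print one decimal for percentages and six for
fractions. All randomness flows from a single integer seed per spec, and
identical config plus seed reproduces every report byte for byte (the
manifest records parameters, frame count, stride, seed and package version).

# Problem sizes used in the checks

The bundled validation runs use trajectories of 60–2000 frames on systems of
one to five helices (up to roughly 1200 atoms), with the full demonstration
systems at 1000 frames; these sizes give exact recovery for deterministic
schedules and comfortable 3-standard-error margins for the stochastic ones.

# Known limitations

Helix boundary defaults for hTSPO are inferred from the published loop
definitions and should be overridden when better annotations exist; the
pairwise-identity convention is one of several reasonable ones; the bend
analysis is a reimplementation of the sliding-axis idea, not a numerical
clone of the original plugin; binary trajectory formats are supported only
through the reader-adapter contract (a function yielding frames), not
natively; and the package does not compute binding free energies, residence
kinetics beyond on/off fractions, or 3D density maps.
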