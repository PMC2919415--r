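---
title: "Modelling oligomer topology from collision cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oligomer topology from collision cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ccstopo` builds low-resolution models of protein quaternary structure from
two sparse inputs: incomplete atomic structures and ion-mobility collision
cross-sections (CCS) measured per oligomeric state.  This vignette explains
the model behind each stage, the tunable parameters, and the choices made
where the design was genuinely open.

## The projection approximation

The experimental observable is Ω, the orientationally averaged area an ion
presents to buffer gas.  We estimate it by the projection approximation
(PA): draw a uniformly random orientation (quaternion method), project
every atom or coarse-grained sphere onto the viewing plane as a hard disk,
and measure the area of the union of disks by uniform point sampling over
its tight bounding box.  Two assumptions follow:

* **Hard spheres.**  Each heavy atom carries a collision radius; the
  default is a single 2.2 Å radius for all elements, overridable per
  element (`collision_radii()`, YAML-readable).  Because the PA ignores
  scattering it systematically underestimates measured CCS; a single
  multiplicative `scale` (default 1, fit with `fit_pa_scale()` on
  structures whose CCS is known) treats that as a uniform systematic
  error.  A consequence worth stating: the method is sensitive to
  *quaternary* arrangement, not to subunit-level rearrangements hidden
  inside the scale factor.
* **Monte-Carlo sampling.**  Defaults are 300 rotations × 4000 points,
  chosen so a single sphere is reproduced to well under 1% (the standard
  error is estimated from the between-rotation spread and reported in
  every `ccs_estimate`).  All sampling is seeded; identical seeds give
  identical estimates, and the caller's RNG state is never disturbed.
  Ranking-scale work inside the pipeline uses 150 × 2000 — enough for
  ~0.5% precision against a 10% acceptance tolerance — so that a full
  eight-order pipeline run stays in the tens of seconds.

## Completing a building block

`mass_account()` compares observed residues (present iff ≥ 1 heavy atom)
with the declared full-length sequence (SEQRES, overridden by a user FASTA
because crystallized constructs are often shorter than the biological
protein).  Masses use average amino-acid residue masses plus one water per
chain; position *i* of the declared sequence corresponds to residue number
*i* in the file.  The missing fraction routes the structure
(`decide_path()`):

* `f_missing = 0` → use as is;
* `f_missing < 5%` → multiply the computed CCS by `m_full/m_present`.
  Whether this correction should be linear in mass or follow a 2/3-power
  (area of a uniform-density body) is not settled; we default to linear and
  expose `exponent = 2/3` in `linear_scale_ccs()`;
* a homology template with sequence identity > 30% and structural
  completeness < 95% → a user-supplied homology model is validated and used
  (template construction itself is out of scope); structural completeness
  is defined as the percentage of full mass present in the template,
  `100 × (1 − f_missing)`;
* otherwise → coarse-grained completion.  The ambiguous corners (identity
  > 30% but a ≥ 95%-complete template; ≥ 5% missing with no template
  information) route to coarse-graining with a warning.

## Coarse-graining and the missing-mass sphere

`decompose_domains()` builds a Gaussian network on Cα atoms (contact cutoff
8 Å, the usual GNM range) and clusters residues on the two slowest
nontrivial Kirchhoff modes.  Automatic selection accepts the largest
k ≤ 3 whose k − 1 slow eigenvalues sit below 0.08 × the spectral median
with a ≥ 1.7-fold gap to the next eigenvalue, whose domains each hold
≥ 15% of residues, and whose boundaries cut ≤ 10% of contacts.  The
spectral gate is what lets a compact single body remain one domain: k-means
alone will happily split any cloud in two, but only genuine rigid domains
produce near-zero modes well separated from the bulk.  These thresholds
were fixed against the synthetic shape families described below.

Each domain becomes one sphere at its mass-weighted centre with radius
`sqrt(CCS_domain/π)`.  `calibrate_radii()` then multiplies **all** radii by
one global bisection-found factor until the sphere model's CCS matches the
atomic CCS to ≤ 1%.  A single factor (rather than per-sphere freedom)
preserves relative domain sizes and is already sufficient for the 1%
criterion; the bisection solves to a quarter of the tolerance so the
post-condition holds under re-measurement.

Unresolved residues become one sphere.  Its radius follows the mean
density of the resolved spheres, `ρ = Σmᵢ / Σ(4/3 π rᵢ³)`, so
`r = (3 m_missing / 4πρ)^{1/3}`.  Its position is scanned
(`place_missing_sphere()`) over a 21 × 36 grid of (overlap, θ): overlap is
the burial depth as a fraction of the anchor radius (0 = tangent,
1 = centre at anchor-radius depth), θ the angle around the anchor in the
plane spanned by the anchor–COM axis and a fixed perpendicular.  The
reference frame of θ is a convention of this package; the physically
meaningful coordinate is the achieved CCS, which is monotone in overlap.
The grid point minimizing |CCS − measured| wins; near-ties resolve toward
deepest burial (the most compact placement adds the least area).  If even
the most compact placement overshoots the measurement by more than the
experimental error (default 10%), the scan aborts with an infeasibility
report rather than returning a forced fit.  Mass is conserved exactly: the
completed model weighs `m_full`.

A deliberate simplification: one sphere per missing segment, placed
deterministically.  A string-of-beads representation for extended missing
segments, and any learned placement, are out of scope.

## Archetypes and trend lines

`generate_archetype()` places n rigid copies of the block.  The contact
rule is tangency of per-copy bounding spheres with 10% allowed overlap
(protein interfaces interpenetrate; the exact value only shifts all trend
lines slightly).  Linear chains run along the longest principal axis; rings
are regular n-gons; double-tiered rings stack two offset (n/2)-gons;
face/end stacks and edge-to-edge arrangements use the block extent along
the respective principal axis (end stacks flip alternate copies 180° about
the stacking axis, capturing head-to-head versus tail-to-tail dimers).
The **collapsed** packing minimizes the summed pairwise centre distances by
greedy insertion plus centroid-pull refinement under shape-aware
no-overlap constraints between the blocks' own spheres (reduced to ≤ 25
enclosing spheres for large atomic blocks).  Shape-awareness matters: an
elongated block packs side-by-side far closer than bounding-sphere
tangency allows, and only then is the collapsed curve a true lower bound.
Exactness is not required of this optimizer — the collapsed archetype is a
bound for classification, not a structural candidate.

`trend_lines()` tabulates CCS against n per topology.  Linear and
collapsed bound the family; ring, stacks and edge-to-edge are frequently
CCS-degenerate for near-isotropic blocks, which is a statement about the
observable (a single scalar per oligomer), not about the implementation —
the tests therefore assert bounds and within-error consistency, not label
identity, for archetypes.

## Crystal-symmetry mining

`expand_symmetry()` applies every symmetry operator (REMARK 290 rows,
Cartesian convention with translations in Å; fractional operators are
converted through the cell orthogonalization matrix) combined with lattice
translations within ± `shell` cells (default 1), deduplicates identical
transforms, and records each copy's COM.  `enumerate_candidates()` then
lists connected n-subsets containing the reference copy — neighbours are
copies whose COM distance is ≤ 1.2 × the block diameter, i.e. near
touching — by a rooted ESU-style search that visits each subset exactly
once, ranks them by compactness, and discards candidates whose copy
bounding spheres interpenetrate by more than 5% of a sphere volume (at the
10%-overlap contact rule this is exactly the tangency limit).  On blocks of
≤ 14 copies the enumeration is provably exhaustive (tested against a
brute-force oracle); larger blocks are capped by a node budget and a
per-order candidate cap (default 500).

`stepwise_series()` selects one candidate per order n = 2…n_max:
minimum |CCS deviation| among candidates that contain the previously
selected (n−1)-assembly.  The nesting rule is both biology (subcomplexes
share building blocks) and algorithmics (it collapses the search to
single-copy extensions of the previous selection, making each step
exhaustive).  Deviations within 0.01 of the best are ties, resolved by a
higher point-group symmetry score of the COM arrangement — proteins favour
symmetric complexes — then by lower compactness.  The symmetry score
counts order-2 and order-3 rotations (about principal axes, COM rays, and
midpoint rays) that map the COM set onto itself within 1 Å.  Orders with
no measurement are selected by compactness alone; orders where no candidate
falls within tolerance truncate the series with a report rather than
forcing a fit.

## What the synthetic generator does and does not emulate

`make_unit()` builds poly-alanine units — four heavy atoms per residue
(N, CA, C, O) — sampled at protein-like density (0.8 Da/Å³) inside
globular, two-lobed or three-lobed envelopes, with linker residues placed
every ≤ 4.5 Å between lobe surfaces so the Cα contact network is connected
the way a polypeptide chain would be.  Residues within a lobe are ordered
along an axis so that a C-terminal truncation (the `gap_fraction`) removes
a spatially coherent cap, mimicking a construct boundary; SEQRES still
declares the full sequence.  The crystal environment is either a P1
lattice with near-tangent translational neighbours (cell edges 1.9–2.0 ×
the unit bounding radius, slightly unequal to break ties) or four
orthorhombic-like operators (identity plus three two-fold screws).
`make_planted_ccs_table()` computes the PA CCS of planted oligomers —
an archetype or the compactness-greedy nested symmetry series — and
perturbs it multiplicatively by a chosen noise level.

What this does **not** emulate: real side-chain packing, sequence-dependent
mass heterogeneity, non-spherical domain shapes, solvent compaction, or
charge effects.  Passing the closed-loop tests therefore demonstrates that
the machinery is self-consistent — geometry in, geometry back out through
a CCS bottleneck — not that any particular biological assignment is
correct.  With noiseless tables the recovered series is geometrically
identical to the planted one at every order up to 8; at 3% measurement
noise the full nested series is still returned within the 10% working
tolerance, but geometric identity is no longer guaranteed wherever
distinct packings differ by less CCS than the noise — an intrinsic limit
of a single-scalar observable, visible in the tests as fingerprint
equality only for the noiseless case.  At 25% noise the pipeline declines
a consistent model.

## Numerical choices and problem sizes

* Monte-Carlo defaults 300 × 4000 (about 0.05–0.3% standard error on the
  models used here); pipeline ranking 150 × 2000; placement scans
  100 × 1500 per grid point.
* Bisection bracket [0.25, 4] with automatic widening; 60-step cap; failure
  to meet 1% raises an error rather than returning the best effort.
* Test and acceptance workloads: 20 calibration structures of 200 atoms;
  50 random enumeration oracles of ≤ 14 copies; closed-loop recovery on a
  160-atom unit to the octamer.  These sizes give sub-minute module suites
  while keeping every Monte-Carlo comparison at ≥ 3σ separation.
* Ties everywhere (placement grid, candidate ordering, k-means seeding)
  are broken deterministically; reports rerun byte-identically from the
  same config and seed.

## Known limitations

* PA only; trajectory-method and exact-hard-sphere-scattering CCS are out
  of scope, as are charge and gas-polarizability effects.
* PDB input only (first NMR model; highest-occupancy alternates); no mmCIF.
* Homology models are consumed, never constructed.
* The archetype set is a fixed vocabulary; packings outside it are reached
  only through crystal symmetry.
* Symmetry mining requires operators in the file or supplied explicitly;
  space-group names are not expanded.
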