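---
title: "Halogen-bond trajectory analysis: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halogen-bond trajectory analysis: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbtraj)
```

## The model

A halogen bond (XB) is a directional interaction between the σ-hole
of a covalently bound halogen (Cl, Br, I — fluorine's σ-hole is too
weak and is excluded throughout) and a Lewis-base acceptor. `xbtraj`
reduces every frame of a tracked donor–acceptor contact to the pair

* *d* — the X···A distance (Å), and
* *θ* — the C–X···A angle with vertex at the halogen (degrees).

The vertex convention matters: θ → 180° means the acceptor sits on
the extension of the C–X bond, over the σ-hole. `sigma_hole_angle()`
is a plain arccos of normalised dot products; it is invariant under
rigid motions of the complex (tested with random rotations and
translations) and errors out on degenerate zero-length vectors rather
than guessing.

### Regions of the distance–angle plane

`classify_region()` partitions the plane with two thresholds,
`d_cut = 4.0` Å and `theta_cut = 140°`:

* **primary** — d < 4.0 Å **and** θ > 140°: a geometrically correct XB;
* **secondary_short** / **secondary_long** — exactly one condition
  holds: a weak XB, frequent in biological systems and worth tracking
  rather than discarding;
* **none** — neither holds.

The defining inequalities for the favourable side are strict
("< 4.0 Å", "> 140°"), so values exactly at a threshold are assigned
to the *less* favourable region. Whether a trajectory frame at
exactly 4.0 Å should be primary is genuinely undecidable from the
inequalities alone; we declare the strict convention rather than
infer it, and note the choice has measure-zero effect on occupancy
statistics for continuous data. There is deliberately no outer
distance bound on `none`: a series is computed wherever a contact is
tracked, and contact *detection* is a separate, explicit step
(`auto_contacts()`, default: X···A ≤ 5.5 Å in ≥ 10 % of frames —
permissive on purpose, so that secondary and intermittent contacts
are not silently lost before statistics are computed).

### Acceptor classes

Acceptors are labelled `"c"` (backbone carbonyl O) or `"s"`
(side-chain O/N: Ser OG, Thr OG1, His ND1/NE2, Asn/Gln amide O and N,
carboxylates, Lys NZ, Arg NE/NH1/NH2, Trp NE1, Tyr OH). The
distinction is scientific, not cosmetic: backbone acceptors are
positionally rigid anchor points, side chains are mobile and give
"blurred" geometry distributions. For histidine both ring nitrogens
are tracked as separate `"s"` candidates — published analyses often
say only "the His side chain", and which nitrogen accepts is a
result, not an input, so the package refuses to hard-code one;
downstream reporting can keep whichever shows the higher
primary-region occupancy.

## Statistics conventions

All of these are fixed, documented choices; none is tunable by data.

* **Occupancy** is the fraction of frames with region `primary`. It
  is the headline statistic because mean ± SD alone hides bimodality:
  a bond that is perfect 60 % of the time and broken 40 % has a
  mediocre mean and a large SD, but a meaningful occupancy.
* **Mean ± SD** uses the *population* SD (divisor n): the trajectory
  is the entire population of frames being described, not a sample
  from which we infer a larger one.
* **Interval medians** (`interval_medians()`, default 6 ns) use
  half-open windows [kL, (k+1)L) anchored at the first time stamp,
  with anything beyond the last full window folded into the final
  interval — so a 60 ns trajectory yields exactly 10 intervals and a
  frame stamped exactly 60 ns is not orphaned into an eleventh.
  Empty intervals are reported as missing values, not errors.
* **Boxplot statistics** use linearly interpolated quartiles
  (`stats::quantile` type 7, the common default) and whiskers at the
  most extreme observation within 1.5·IQR. Both choices are
  cross-checked in the test suite against an independent sort-based
  quantile oracle.
* **Ligand RMSD** superposes each frame onto the reference
  (least-squares, via bio3d) using receptor Cα atoms within 6 Å of
  the ligand in the reference frame, then measures heavy-atom ligand
  RMSD *without re-fitting the ligand*. The pocket-Cα selection is
  our choice (a binding-mode statistic should not be diluted by
  whole-receptor breathing); the 6 Å radius is the conventional
  first-shell cutoff. Fitting on fewer than three non-collinear
  atoms is ill-posed; the synthetic topology therefore carries four
  pocket Cα positions.
* **Frame clustering** (`cluster_frames()`, default k = 10) is
  agglomerative with average linkage on the pairwise ligand-RMSD
  matrix after pocket superposition. Average linkage is a declared
  default — hierarchical protocols in MD tooling rarely state their
  linkage, and average is the least shape-biased of the common
  options. The representative frame is the member of the most
  populated cluster minimising summed RMSD to its cluster; every tie
  (equal sizes, equal sums, zero distances) breaks towards the lower
  frame index, so degenerate inputs cluster deterministically.
* **Replicate selection** (`select_replicate()`) scores each
  replicate by CV(d) + CV(θ) (population SD over mean) and returns
  the argmin (1-based, ties to the lower index). The sum of
  dimensionless CVs is used so that the distance (Å, magnitude ~4)
  and the angle (degrees, magnitude ~150) contribute comparably.

## The XSAR module

`find_xsar_sets()` implements matched-pair construction: every
record's aryl-bound Cl/Br/I atoms are replaced by hydrogen and the
resulting skeleton is matched against the non-halogenated records by
canonical-SMILES equality (canonicalisation via OpenBabel, graph and
ring perception via ChemmineR). Matching is restricted to
aryl-bound halogens — aliphatic C–X bonds are chemically and
pharmacologically a different substitution and are excluded by
default. The **Xeffect** is the plain activity ratio
parent/derivative on a lower-is-better nM scale (so 122-fold
improvements print as 122); the module does not guess units, and pKi
inputs must be converted by the caller.

### PI–AR chemotype distance

`pi_ar_distance()` measures the distance between the basic centre
(PI) and the aromatic ring (AR):

* **PI** — the most basic aliphatic amine nitrogen: aromatic,
  aryl-conjugated and amide nitrogens are excluded (they are not
  protonated at physiological pH); ring amines are preferred over
  acyclic ones, ties to the first atom. For an arylpiperazine this
  selects the distal nitrogen; for a benzylpiperidine the ring NH.
* **AR** — the centroid of the aromatic ring bearing the most
  halogens (the halogenated, or candidate-halogenation, ring); with
  no halogenated ring, the first aromatic ring.

The geometry comes from a conformer ensemble, not a single structure:
OpenBabel `--gen3d` builds and minimises one conformer, Confab then
enumerates rotamers systematically (0.3 Å diversity cutoff, 50
kcal/mol energy window), and the reported value is the *median*
distance over up to 20 conformers. The systematic enumeration is
deterministic; the `seed` only governs subsampling when more than
`n_conformers` rotamers exist, so repeated same-seed calls are
bit-identical. A median over an ensemble was chosen because no
single-conformer protocol is defensible for flexible fragments; for
the two class archetypes the ensemble spread is small (≲ 0.1 Å) and
the class separation (5.7 Å vs 3.8 Å as computed by the package) is
an order of magnitude larger.

`classify_chemotype()` splits at 4.75 Å, the midpoint of the two
archetype distances (5.6 Å arylpiperazine, 3.9 Å benzylpiperidine),
boundary to "long". The benzylpiperidine archetype places the benzyl
group *on* the basic nitrogen: a C4-benzyl isomer has a PI–AR
distance of ~6.3 Å and would belong to the long class — the short
class is defined by the N-benzyl topology.

## The synthetic generator

Published MD trajectories for this kind of study are rarely
deposited, so every pipeline stage is validated against
`simulate_xb_trajectory()`, which emulates the *statistical* structure
the analysis assumes: a contact switching between a bound state with
primary-XB geometry and a broken state, each emitting (d, θ) from
truncated Gaussians (d > 2.5 Å, θ ∈ [0, 180], redraw on violation),
either i.i.d. per frame or as a two-state Markov chain with a given
stay-probability. Defaults (60 ns at 0.06 ns/frame; bound state
3.8 ± 0.4 Å, 163.7 ± 8.2° with weight 0.6; broken state 6.5 ± 0.7 Å,
110 ± 20°) mirror the magnitudes a stable GPCR–ligand XB contact
shows in practice.

The realisation is exact by construction: the C–Cl donor is fixed and
the acceptor oxygen is placed on a cone about the C–Cl axis at
distance d and angle θ with a random azimuth, so the drawn values are
reproduced to machine precision and statistical tests are not
confounded by coordinate noise. The generator emits per-frame ground
truth (state, d, θ, region), which is what the occupancy-recovery and
pipeline-closure tests check against at the 3·√(p(1−p)/n) binomial
bound.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: a force field, solvent and membrane,
correlated internal ligand motion, acceptor side-chain dynamics,
multiple simultaneous contacts competing for one halogen, and
coordinate noise in d and θ themselves. It validates the measurement
and statistics machinery, not molecular mechanics.

## Problem sizes and numerical choices

The shipped test-suite and benchmark sizes are chosen as the smallest
that make the statistics meaningful: occupancy recovery uses n = 2000
frames at planted p ∈ {0.1, 0.5, 0.9} over three seeds (binomial SE
≲ 1.1 %), clustering recovery uses 1000 frames in two planted
conformations, Markov-chain calibration uses n = 5000, oracle
comparisons (angle vs brute-force vectors, RMSD vs an independent
Kabsch implementation, quantiles vs a sort-based oracle) use 100
random instances at 10⁻⁸ tolerance, and the chemotype benchmarks use
20-conformer ensembles. A full analysis at these sizes runs in
seconds.

Other numerical details: covalent C–X bonds are inferred from a
1.6–2.2 Å distance window in the first frame rather than trusting
CONECT records; alternate locations keep 'A' or blank; acos arguments
are clamped to [−1, 1] against rounding; coordinates are Å, times ns,
angles degrees, and PDB residue numbering is kept 1-based as in the
file.

## Known limitations

* Generic residue numbering (e.g. "5x40") is a user-supplied lookup
  table; the package does not compute structure-based alignments.
* Acceptor perception is name-based over standard residues;
  non-standard residues need explicit atom selection.
* π-system acceptors, halogen–halogen contacts and hydrogen-bond
  perception are out of scope, as are energy models of the XB.
* OpenBabel's gen3d/Confab protocol, while deterministic, explores
  rotamers only; ring-conformer flips (chair–chair) are not
  enumerated, which is acceptable for the rigid-ring chemotypes the
  PI–AR classification targets.
* The XSAR matcher requires exact skeleton equality; matched *series*
  with scaffold variation (beyond halogenation) are not paired.
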