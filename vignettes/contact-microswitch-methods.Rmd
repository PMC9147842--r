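---
title: "Quantifying GPCR microswitch rearrangements from MD ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GPCR microswitch rearrangements from MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroswitchMD)
```

## The scientific problem

Class A G-protein-coupled receptors (GPCRs) transmit an extracellular
ligand-binding event to the intracellular G-protein interface through a
conserved relay of residue-residue contacts. A small number of
*microswitches* — the Trp6.48 toggle of the CWxP motif, the Tyr7.53 toggle
of the NPxxY motif, the DRY ionic lock on helix 3, the sodium-binding
pocket at Asp2.50 — rearrange their local packing when the receptor moves
towards its active state. Molecular-dynamics (MD) simulations of a
receptor with and without a bound ligand let one ask, frame by frame,
whether a candidate agonist pushes these contacts in the activating
direction.

MicroswitchMD implements the analysis layer of that question. It takes
coordinate ensembles (multi-MODEL PDB files, one file per independent MD
replicate), a table of Ballesteros-Weinstein (BW) generic residue labels,
and a registry of pathway residue pairs annotated with the direction of
contact change expected upon activation, and computes:

1. **Per-frame residue-residue contact scores (RRCS)** — a graded,
   distance-based measure of how tightly two residues pack;
2. **Van-der-Waals contact fractions (ACF)** — the share of simulation
   time a pair spends in atomic contact;
3. **A global-effect (GE) metric** — a scalar summary of how far a ligand
   shifts the contact-fraction profile away from the apo receptor, split
   into gains (GE+) and losses (GE-);
4. **Geometric probes** — minimum ligand-residue distances, superposed
   ligand occupancy clouds, and a simplified channel-bottleneck series
   with a water-permissiveness criterion.

## The contact score

For residues A and B in one frame, the score sums a piecewise-linear
kernel over all heavy-atom pairs, without weighting:

$$\mathrm{RRCS} = \sum_{i \in A}\sum_{j \in B} \delta_{ij}, \qquad
\delta_{ij} = \begin{cases}
1 & r_{ij} \le r_{\min} \\
0 & r_{ij} \ge r_{\max} \\
\dfrac{r_{\max} - r_{ij}}{r_{\max} - r_{\min}} & \text{otherwise,}
\end{cases}$$

with $r_{\min} = 3.23$ Å and $r_{\max} = 4.63$ Å. One fully engaged
atom pair contributes 1.0; the score is continuous, non-increasing in
every pairwise distance, and invariant under rigid motion, so no
trajectory superposition is required (or applied) before scoring.

Two rules shape the atom selection:

* **Heavy atoms only.** Hydrogens (H/D) never participate, in the score
  or in the van-der-Waals criterion.
* **Backbone exclusion for sequence neighbours.** When the two residues
  lie on the same chain within 4 sequence positions of each other, the
  backbone atoms (`N, CA, C, O, OXT`) of *both* residues are excluded.
  Sequence neighbours keep their backbones within contact range
  permanently; without this rule their scores would be dominated by a
  constant, uninformative term. We apply the rule to both residues — the
  alternative (excluding one side only) still leaves every
  backbone-backbone pair in the sum, defeating the rule's purpose. Pairs
  on different chains have no defined sequence separation and are always
  treated as "far".

## Van-der-Waals contacts and the global-effect metric

Two atoms are in contact when the distance between their centres is
**strictly less than** the sum of their van-der-Waals radii plus a slack
of $\varepsilon = 0.25$ Å. Radii default to the Bondi set (C 1.70, N
1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å); an element missing from the
table is an error, never a silent default. A distance exactly at the
bound is *not* a contact; the boundary convention is tested explicitly.

A residue pair's **average contact fraction** is the share of frames,
pooled across all replicates, in which any qualifying atom pair is in
contact. Pooling (rather than averaging per-replicate fractions)
reproduces the convention of reporting occupancy over the concatenated
simulation time of independent repetitions; for equal-length replicates
the two conventions coincide.

The **global effect** of a ligand compares its ACF profile with the apo
profile over the pairs expected to gain (+) or lose (-) contacts upon
activation:

$$\mathrm{GE}^{+} = \sum_{i} \left(\mathrm{ACF}^{+}_{i,\mathrm{APO}}
  - \mathrm{ACF}^{+}_{i,\mathrm{LIG}}\right)^2, \qquad
\mathrm{GE}^{-} = \sum_{i} \left(\mathrm{ACF}^{-}_{i,\mathrm{APO}}
  - \mathrm{ACF}^{-}_{i,\mathrm{LIG}}\right)^2.$$

The sums run over literal signed differences, squared, with no square
root — exactly as the quantity is conventionally printed. Because the
typesetting of such formulas is sometimes ambiguous, `geMetric(...,
rooted = TRUE)` offers the Euclidean (square-rooted) variant; the default
is the plain sum of squares. GE is zero iff the two profiles agree on the
pair set, scales quadratically in the differences, and is invariant
under reordering pairs within a set.

## Verdicts

`classifyPairs()` calls a pair **increased** when the ligand-minus-apo
difference of mean scores is at least the threshold, **decreased** at or
below its negative, and **unaffected** otherwise. The condition mean is
the mean of per-replicate means, so replicates of unequal length carry
equal weight. The default threshold of 0.2 score units is a deliberate
package choice: it is small against the unit step contributed by a
single engaged atom pair, yet large against the sampling noise of the
mean score at the problem sizes we analyse (see below). It is exposed as
a parameter everywhere.

## Ballesteros-Weinstein bookkeeping

BW labels (`"H.NN"`, helix 1-8, position relative to the helix's most
conserved residue, numbered 50) are the lingua franca for comparing GPCR
positions across receptors. The package treats the mapping as explicit
input — a two-column `chain:resnum -> label` table — and never infers it
from sequence. The shipped default map covers the human M1 muscarinic
receptor positions used by the default pathway registry. Two entries
(1.49 = Gly42, 2.43 = Leu64) are derived from published anchors
(1.53 = Val46, 2.50 = Asp71) by the within-helix offset that defines BW
numbering; the remaining sixteen are direct published correspondences.
Where published sources disagree on a residue's amino-acid identity the
label and residue number are taken as authoritative and the amino-acid
letter is ignored. Residue 371 is mapped to 6.43 (it also appears in the
literature as 6.41); the map must stay injective, so one label had to be
chosen, and 6.43 is the label under which the residue appears in the
default pathway pair 3.43x6.43. Loop residues are representable with an
explicit `x-` prefix but excluded from pathway analysis by default.

The default registry ships only the microswitch pairs that are
individually documented for muscarinic receptors (four expected gains,
five expected losses). The full 34-pair class-A activation pathway comes
from a published meta-analysis that we do not reproduce; users supply it
as a three-column TSV when available.

## Geometric probes

* `minDistanceSeries()` — per frame, the minimum distance between heavy
  atoms of a ligand selection and a target residue. Used, e.g., to watch
  a ligand approach the sodium pocket at Asp2.50.
* `occupancyCloud()` — frames are least-squares superposed (Kabsch, via
  bio3d) onto a reference frame using the protein C-alpha atoms by
  default, and ligand heavy-atom positions are pooled. Contacts need no
  alignment, but occupancy densities do; the reference can be supplied
  explicitly so clouds from different runs live in one coordinate
  system. A collinear alignment selection leaves the rotation
  under-determined and is rejected.
* `bottleneckSeries()` — a deliberately simplified channel estimator.
  Points are sampled every `step` (default 0.5 Å) along a straight axis
  from the start-residue centroid (the Trp6.48 region in receptor use);
  the free radius at a point is the smallest distance-to-atom-surface,
  floored at 0 and capped at 5 Å; the per-frame bottleneck is the
  minimum along the path. Points narrower than the probe radius
  (default 0.9 Å) flag the tunnel as closed. This replaces Voronoi-based
  tunnel search (CAVER/MOLE): it assumes a straight tunnel of known
  axis, reports no branching or curvature, and is validated only against
  analytic cylinder fixtures, for which the true bottleneck is
  `ring radius - vdW radius` and the axial discretisation error is
  bounded by `step^2 / (2 * ring radius)`. It is a qualitative
  instrument for synthetic and screening use, not a replacement for
  full tunnel analysis on production trajectories.
* `permissiveFraction()` — the fraction of frames whose bottleneck
  strictly exceeds the water probe radius of 1.4 Å, the conventional
  criterion for water passage.

## The synthetic-data generator

MD trajectories of membrane receptors are too large to ship and too slow
to regenerate, so validation runs on synthetic systems whose ground
truth is known by construction:

* Each designated pair is two residues (1-5 heavy atoms each, standard
  backbone/side-chain atom names) whose anchor-anchor distance follows a
  **two-state Markov chain** between a contact distance (default 3.0 Å)
  and an apart distance (default 8.0 Å), with stationary contact-state
  occupancy `f` and mean contact dwell of 20 frames. The Markov process,
  rather than i.i.d. draws, reproduces the temporal persistence of real
  MD contact series; all statistical tolerances in the tests use the
  autocorrelation-corrected standard error
  $\mathrm{SE} = \sqrt{f(1-f)/n \cdot (1+\rho)/(1-\rho)}$ with
  $\rho = 1 - p_{\mathrm{enter}} - p_{\mathrm{leave}}$, not the naive
  binomial one.
* Isotropic Gaussian jitter (default $\sigma = 0.1$ Å per atom) models
  thermal motion. It is kept small relative to the 0.65 Å margin between
  the contact distance and the carbon-carbon contact threshold
  (3.65 Å), so the realised contact state equals the chain state and
  the chain occupancy is an exact ground truth for the contact
  fraction.
* Residue geometry places all non-anchor atoms on the far side of each
  residue's anchor, so the anchor pair dominates the inter-residue
  distance; sequence separations of 2 and 10 alternate across pairs so
  both branches of the backbone-exclusion rule are exercised.
* Two scaffold residues sit more than 20 Å from every pair and verify
  that spectators contribute nothing.
* The manifest records, per pair, the designed `f`, the realised chain
  occupancy, and the mean contact score of the generated coordinates
  computed by an **independent brute-force oracle** (a plain double loop
  with its own kernel arithmetic) — never by the engine under test.
* Generation is bit-reproducible from `(spec, seed)`.
* `generateChannelSystem()` builds static cylinders of atoms with
  analytic bottleneck `ring radius - vdW radius`; ring radii of 3.0 and
  3.2 Å (carbon) bracket the 1.4 Å water threshold at 1.30 and 1.50 Å.

What the generator does *not* emulate: real side-chain rotamer
dynamics, correlated motions between pairs, solvent and membrane,
anisotropic fluctuations, or ligand chemistry. Passing tests therefore
demonstrate that the *measurement machinery* is correct — kernels,
selection rules, pooling, classification, geometry — not that any
particular receptor behaves in a given way.

## Numerical choices and degenerate inputs

* Distances at the kernel knots give exactly 1 and 0 (closed form, no
  floating-point surprises); the vdW boundary is strictly exclusive.
* Alternate locations in PDB input resolve to the highest-occupancy
  conformer, first-encountered on ties; insertion codes are rejected
  rather than silently merged, since author residue numbering carries
  the sequence-separation semantics of the backbone rule.
* Elements come from PDB columns 77-78 when present, else from
  atom-name heuristics (leading letter after stripping digits, with a
  guard so `CA`/`NA` atom names in standard residues stay carbon and
  nitrogen).
* A glycine-like residue with backbone excluded yields an empty
  selection and a score of exactly 0.
* Multi-MODEL files with inconsistent atom counts are rejected by a
  raw-record scan before parsing.
* Histograms pool frames across replicates of a condition (per-replicate
  series remain available, so per-replicate histograms are computable);
  bins are left-closed, right-open, from zero, default width 0.25.
* Report JSON is written with fixed key order and no timestamps, so a
  rerun of the same configuration is byte-identical.

## Problem sizes used in validation

The shipped tests and the acceptance script use sizes chosen from the
noise analysis above: 200 randomized systems for oracle equivalence
(tolerance $10^{-9}$); 5000 frames for contact-fraction recovery at
$f \in \{0.1, 0.5, 0.6, 0.9\}$ (3 SE, autocorrelation-corrected); 5000
frames per condition for global-effect recovery of a designed 0.25
(delta-method 3-SE tolerance plus the sampling bias of a sum of noisy
squares); and 10 seeds of 3 designed pairs at 4000 frames per condition
for verdict accuracy, where the null pair's mean-score noise
(~0.05 SD) leaves a >4-sigma margin against the 0.2 threshold.

## Known limitations

* The bottleneck estimator is axis-bound and single-path; curved or
  branching tunnels are out of scope by design.
* The package analyses whole-molecule, unwrapped trajectories; periodic
  boundary artefacts must be removed upstream.
* No statistical test is attached to histogram or verdict differences;
  the verdict threshold is a descriptive cutoff, not an inference
  procedure.
* BW annotation is never inferred from sequence; receptors other than
  the shipped M1 default require an explicit map.
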