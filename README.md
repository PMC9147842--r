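# MicroswitchMD

Contact-based analysis of GPCR activation microswitches in
molecular-dynamics ensembles.

## What it is for

Class A G-protein-coupled receptors activate through a conserved relay of
residue–residue contacts linking the ligand pocket to the G-protein
interface — the Trp6.48 toggle (CWxP), the Tyr7.53 toggle (NPxxY), the DRY
ionic lock, the sodium pocket at Asp2.50. Given MD trajectories of a
receptor simulated with and without a candidate ligand, this package
answers: *does the ligand push these microswitch contacts in the
activating direction?*

It is aimed at structural bioinformaticians and molecular modellers who
have coordinate ensembles (multi-MODEL PDB, one file per replicate), a
Ballesteros–Weinstein (BW) residue-label table, and a list of pathway
residue pairs annotated with the direction of contact change expected
upon activation.

## The quantities it computes

**Residue–residue contact score (RRCS)** per frame, for residues A and B:

    RRCS = sum over heavy-atom pairs (i in A, j in B) of delta_ij

    delta_ij = 1                                   if r_ij <= r_min
             = 0                                   if r_ij >= r_max
             = (r_max - r_ij) / (r_max - r_min)    otherwise

with r_min = 3.23 Å, r_max = 4.63 Å. Backbone atoms of both residues are
excluded when the residues are within 4 sequence positions on one chain.

**Average contact fraction (ACF)**: the share of frames (pooled over
replicates) in which any heavy-atom pair of the two residues lies closer
than the sum of their Bondi van-der-Waals radii plus 0.25 Å (strict
inequality).

**Global effect (GE)** of a ligand against the apo reference, over the
pair sets expected to gain (+) or lose (−) contacts:

    GE+ = sum_i (ACF+_i,APO − ACF+_i,LIG)^2
    GE− = sum_i (ACF−_i,APO − ACF−_i,LIG)^2

**Geometric probes**: minimum ligand–residue distance series, Kabsch-
superposed ligand occupancy clouds, and a simplified axis-sweep channel
bottleneck series with the 1.4 Å water-permissiveness criterion.

**Synthetic ground truth**: a deterministic generator of two-state
(contact/apart) Markov contact systems and analytic cylinder channels, so
every stage is testable without MD data.

## Worked example

Generate matched apo/ligand conditions with designed contact-fraction
shifts (0.2→0.8 gain, 0.8→0.2 loss, 0.5→0.5 null), then run the contact
analyses:

```r
library(MicroswitchMD)

cp <- generateConditionPair(
  syntheticSpec(nFrames = 4000, seed = 1, f = c(0.2, 0.8, 0.5), condition = "APO"),
  syntheticSpec(nFrames = 4000, seed = 2, f = c(0.8, 0.2, 0.5), condition = "LIG"))

acfApo <- acfTable(cp$apo$trajectory, cp$pairs, cp$apo$bwMap, condition = "APO")
acfLig <- acfTable(cp$lig$trajectory, cp$pairs, cp$lig$bwMap, condition = "LIG")
acfFractions(acfApo)
#>        pair fraction nFrames
#> 1 1.41x2.41  0.23225    4000
#> 2 1.42x2.42  0.81450    4000
#> 3 1.43x2.43  0.45225    4000

p <- cp$pairs@pairs
geMetric(acfApo, acfLig,
         pairLabel(p$labelA[p$direction == "increase"], p$labelB[p$direction == "increase"]),
         pairLabel(p$labelA[p$direction == "decrease"], p$labelB[p$direction == "decrease"]))
#> GEResult (sum of squares): GE+ = 0.3204 over 1 pairs, GE- = 0.4144 over 1 pairs

v <- classifyPairs(rrcsSeries(cp$apo$trajectory, cp$pairs, cp$apo$bwMap),
                   rrcsSeries(cp$lig$trajectory, cp$pairs, cp$lig$bwMap))
print(v, digits = 3)
#>   pair_label meanApo meanLig    delta    verdict
#> 1  1.41x2.41   0.231   0.796  0.56499  increased
#> 2  1.42x2.42   0.812   0.170 -0.64186  decreased
#> 3  1.43x2.43   0.660   0.654 -0.00599 unaffected
```

The ACF table shows each pair's measured contact occupancy (close to the
designed 0.2/0.8/0.5 up to the Markov chain's sampling noise). The GE
values summarise how far the ligand condition moved the gain and loss
pair sets; the verdicts recover the designed direction of every shift,
with the null pair correctly left "unaffected" at the default 0.2
threshold.

Channel bottleneck on an analytic cylinder fixture (ring radius 3.2 Å of
carbon atoms, true bottleneck 3.2 − 1.70 = 1.50 Å):

```r
ch <- generateChannelSystem(3.2)
prof <- bottleneckSeries(ch$trajectory, start = list(chain = "C", resno = 1L),
                         direction = c(0, 0, 1), pathLength = 9)
prof
#> ChannelProfile from C:1: 1 frames, bottleneck 1.50-1.50 A (probe 0.90 A)
permissiveFraction(prof)
#> [1] 1
```

1.50 Å exceeds the 1.4 Å water radius, so the channel is
water-permissive in every frame.

For an end-to-end run from files, write a YAML configuration (see
`?validateConfig` for the layout) and call `runPipeline("run.yaml")`, or
use the wrapper `inst/scripts/microsw-run.R`. The pipeline writes ACF,
RRCS, histogram and verdict CSVs plus a deterministic `report.json`.

## Layout

- `R/` — S4 classes (`Topology`, `Trajectory`, `BWMap`, `PairSet`, ...)
  and the analysis functions.
- `inst/extdata/` — default M1 BW map and microswitch pair registry.
- `vignettes/contact-microswitch-methods.Rmd` — the model, its
  assumptions, parameter choices and known limitations.
- `tests/testthat/` — unit, property and acceptance tests against
  independent brute-force oracles and analytic fixtures.
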