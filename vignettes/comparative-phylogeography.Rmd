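---
title: "Grid-based comparative phylogeography with phylogrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based comparative phylogeography with phylogrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogrid)
```

## The problem

Co-distributed rainforest plant species often show spatially structured
chloroplast variation shaped by glacial-stage refugia, postglacial
expansion and secondary contact.  Because the plastid genome is
non-recombining and maternally inherited, each individual carries a single
haplotype, and the geography of haplotype relatedness preserves a record of
that history.  `phylogrid` implements the comparative workflow: collapse
aligned organellar sequences into haplotypes, place georeferenced samples
on degree grids, quantify within-cell diversity, endemism and
distinctiveness, test for phylogeographic signal, and ask whether several
species share one spatial pattern — the signature of community-wide
refugia — or disagree, as expected when histories differ.

## From alignments to haplotypes

Sequences are read from aligned FASTA over `{A,C,G,T,-,N}`.  Variation is
coded as discrete characters:

* **Substitution characters** — alignment columns with at least two
  distinct non-gap, non-ambiguous states.
* **Indel characters** — *simple indel coding*: every maximal gap run with
  identical start and end across the samples sharing it becomes one binary
  presence/absence character.  A three-base deletion therefore counts as a
  single mutation, and overlapping but non-identical runs are separate
  characters.  At substitution columns covered by a gap the gap state is
  carried along but never contributes distance, so an indel is never
  counted twice.

`N` is treated as missing.  Samples ambiguous at any varying character
cannot be assigned to a haplotype and are dropped with a warning; this is a
deliberate, conservative choice — imputation would manufacture haplotypes.
Haplotypes are numbered by decreasing frequency (ties by first appearance).
Multi-locus data sets are supported by concatenating coded alignments over
shared sample ids (`concat_coded()`), the usual treatment when a second
spacer is added for resolution.  Unreliable columns (for example suspected
reverse mutations in a fast-evolving spacer) can be masked with
`code_indels(aln, mask_cols = ...)`; no automatic detection is attempted
because no robust criterion exists without an outgroup.

Per-site nucleotide diversity is
$\pi = \frac{n}{n-1}\sum_{h,g} p_h p_g d_{hg} / L$ with $d_{hg}$ the coded
mutation distance; its standard deviation uses the classical
total-variance formula (stochastic plus sampling terms), matching the
convention of the standard population-genetics software.

## Haplotype networks

`mutation_distance_matrix()` counts differing coded characters — the
minimum number of mutations between haplotypes under the no-homoplasy
assumption.  The **minimum-spanning network** is the union of all minimum
spanning trees, characterised through minimax distances (an edge is in some
MST exactly when its weight equals the minimax path weight between its
endpoints); `epsilon > 0` additionally keeps links within `epsilon` of the
threshold at which their components merge.  The default is `epsilon = 0`.

The **median-joining network** iterates: build the relaxed MSN over the
current node set; for every connected triplet add the per-character
strict-majority consensus as a median vector if it is new; stop when
nothing is added; finally prune median vectors whose removal leaves the
network connected at no greater total edge length, so every retained median
vector has degree at least two.  Medians are only generated from triplets
with a strict majority at every character — always true for binary indel
characters, and for substitution characters except the rare three-state
column, which is then skipped for that triplet.  All processing orders are
lexicographic in node id, which makes networks invariant to input order.
"Total length" of a network always means the sum of its edge weights;
`mst_length()` gives the spanning-tree baseline for comparison.

On infinite-sites data (the simulator's default) the true genealogy's
adjacencies are provably contained in the zero-epsilon MSN, and the test
suite checks that the median-joining network retains at least 95% of them
(directly or through median vectors).

## Grid statistics

Samples are binned on degree grids (defaults 0.75, 1.5 and 3 degrees)
anchored at (0E, 0N) so the three grids nest; cells are half-open
`[edge, edge + side)`.  Cell indices are computed on raw latitude/longitude
without projection and cell centroids are coordinate means — adequate near
the equator where the target studies operate, increasingly distorted
poleward.  A cell enters the statistics only with **at least three
individuals**; this trades spatial resolution against estimator precision.

Within each retained cell with haplotype frequencies $p_h$ and sample size
$n$:

* gene diversity $He = \frac{n}{n-1}(1 - \sum_h p_h^2)$,
* ordered-allele diversity $v = \frac{n}{n-1}\sum_{h,g} p_h p_g \pi_{hg}$
  (mean mutation steps between two individuals drawn without replacement),
* effective number of haplotypes
  $NAe = (n-1)^2 / [(\sum_h p_h^2)(n+1)(n-2) + 3 - n]$, the bias-corrected
  estimator (equal to 1 under fixation and approaching $1/\sum p^2$ for
  large $n$).

**Endemism.** Each haplotype's range is the maximal great-circle distance
(haversine, radius 6371 km) between any two carriers over the *whole* data
set.  `End` of a cell is the proportion of its members carrying haplotypes
with range at most 200 km (configurable).  A haplotype spread 300 km within
a single large cell is therefore *not* endemic — the statistic measures
range restriction, not cell membership.

**Differentiation.** Global `GST` and `NST` follow the classical haploid
estimators: within-cell diversities are averaged with equal weight per cell
($h_S$, $v_S$), total diversities use mean cell frequencies plus the
small-sample correction $h_S/(\tilde n C)$ with $\tilde n$ the harmonic
mean cell size, and $G_{ST} = (h_T - h_S)/h_T$,
$N_{ST} = (v_T - v_S)/v_T$.  Equal weighting is the estimator's published
convention and the default; `weighting = "size"` is available for
comparison with software that weights populations by sample size.  A
*phylogeographic signal* — related haplotypes co-occurring in space — makes
$N_{ST} > G_{ST}$.  Its significance is tested by permuting haplotype
identities on the rows/columns of the distance matrix (frequencies fixed)
and recomputing $N_{ST}$, with the add-one estimate
$p = (1 + \#\{N_{ST}^{perm} \ge N_{ST}^{obs}\})/(1 + n_{perm})$; the
default is 999 permutations and the test is one-sided by construction.
Global monomorphism ($h_T = 0$) is an error, not a zero.

## Distinctiveness

For each pair of retained cells, $v_{ij}$ is the mean mutation distance
between one individual from each cell (no self-pair correction — the draws
come from different cells) and $d_{ij}$ the great-circle distance between
member centroids; co-located centroids are a degeneracy error.  Genetic
distance typically increases with $\ln d$ (isolation by distance in two
dimensions), so distinctiveness first decides whether a decay trend exists:
a one-sided Mantel test of $v_{ij}$ against $\ln d_{ij}$ at
`alpha = 0.05`.  One-sided is the right test here because only a
*positive* correlation licenses detrending.  If significant, $S'_{ij}$ are
the OLS residuals of $v_{ij}$ on $\ln d_{ij}$ over unique unordered pairs;
otherwise the centred $v_{ij}$.  Either way $S'_{ij}$ averages to zero over
pairs, and $S'_i$ — the mean over pairs involving cell $i$ — measures how
much more divergent a cell is from the rest of the study area than
geography explains.  Units of $d$ only shift the regression intercept and
cancel in the residuals.

## Cross-species congruence

Metrics are standardized within species (centred, divided by the *sample*
standard deviation; species with one cell or zero variance are excluded
with a flag) so species with different absolute diversity contribute
comparably.  Congruence is then tested three ways:

* **Pearson correlation** per species pair on cells retained for both,
  two-sided, requiring at least 5 shared cells (pairs below the cutoff are
  reported untested with their count);
* **one-way ANOVA** per metric with grid cells as factor and species
  values as observations — species cannot be crossed as a second factor
  because of missing cells; cells with a single observation are excluded
  from the ANOVA but reported;
* **Mantel tests** per species pair on the $S'_{ij}$ matrices restricted
  to shared cells (at least 4), two-sided because congruent structure
  could be of either sign.

`multispecies_cell_means()` averages available species' z-scores per cell
for mapping multi-species trends, reporting how many species inform each
cell.

## The scenario simulator

`simulate_dataset()` generates data sets at the scale of a Lower Guinean
chloroplast-spacer study: a region spanning 8-16E and 6S-8N, 20 sites of 6
individuals (120 sequences), ~800 bp alignments carrying ~20 mutations on
an infinite-sites genealogy (every mutation at its own position, so coded
distances equal genealogy path lengths exactly and the network oracles are
exact), haplotype pools that collapse to roughly 8-12 observed variants
with 1-3 steps between network neighbours, and 11-61 segregating sites.
Mutation positions are laid out on a stride so indel spans can never merge;
positions carry no signal under infinite sites, so this costs no realism.

Scenario geometries (all tunable in `scenario_config()`):

* **panmixia** — haplotypes drawn i.i.d. everywhere from one
  Dirichlet-distributed frequency vector; the null world for calibration.
* **refugia** — refuge founders separated by 5 mutation steps; each refuge
  carries 5 site-local derivatives confined within 90 km of its centre
  (under the 200 km endemism threshold by construction, since 2 x 90 km
  x jitter stays below it).  Sites draw from refugia with
  distance-decaying admixture on a 100 km scale: mixed membership is
  confined to a fringe of roughly one 0.75-degree cell around the
  equidistance line, which is what keeps the haplogroups "geographically
  segregated" as the scenario demands — on a 250 km scale the fringe
  becomes a broad mixing zone and the pattern turns into secondary
  contact, which is modelled separately.  Each refuge gets a centre site
  and a flank site so it is represented by more than one locality.
* **expansion** — one widespread founder everywhere plus rare one-step
  derivatives confined to within 150 km of the origin, where four sites
  are forced; the origin area is the diversity hotspot, everywhere else is
  fixed.
* **contact** — two haplogroups 5 steps apart meeting in a 1-degree
  longitudinal band (two sites forced into it); within-group derivatives
  are widespread, so the band shows high `v` but no endemism.

`expected_pattern()` turns the stored truth into checkable expectations
and `evaluate_pattern()` scores them.  For the contact band the check
compares the *median* band-cell `v` against the upper quartile of all
cells (and median band `End` against the overall median): a per-cell
"every band cell in the top quartile" reading would be ill-posed whenever
band cells exceed a quarter of the retained cells, which random site
placement allows.

What the simulator does **not** emulate: coalescent genealogies with drift
and migration (haplogroup topology is fixed by the scenario), recombination
(absent in plastids anyway), homoplasy (optional indels aside, characters
never recur), sequencing error and alignment ambiguity, and realistic
sampling biases beyond the forced scenario sites.  A green simulation test
therefore establishes that the estimators and tests behave correctly in
worlds with known truth — not that any particular empirical data set has a
given history.

## Numerical conventions and degenerate inputs

* All permutation p-values use the add-one convention and a mandatory
  seed; seeded functions restore the caller's RNG state.
* Ties break lexicographically (node ids) or by lowest index (`which.min`
  in the spanning-tree code), fixing determinism; the full pipeline is
  byte-identical across runs at fixed seeds, with table numbers printed at
  10 significant digits.
* Monomorphic cells give `NAe = 1, He = 0, v = 0`; global monomorphism is
  an error for differentiation; zero variance in a Mantel input or a
  correlation subset is reported as untestable rather than coerced to 0.
* Distinctiveness requires at least three retained cells; the pipeline
  records the reason whenever a stage is skipped instead of failing.

## Limitations

Degree-grid binning ignores meridian convergence away from the equator;
the estimators assume haploid, uniparentally inherited markers; the
median-joining implementation targets the small haplotype sets typical of
plastid spacers (tens of haplotypes), not genome-scale data; and no
attempt is made to date divergences, which plastid spacers cannot support.
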