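# phylogrid

Grid-based comparative phylogeography of organellar haplotypes.

Plastid (and mitochondrial) loci are non-recombining, so every individual
carries one haplotype and the geography of haplotype relatedness records a
species' history: refugia accumulate locally endemic variants, range
expansions spread one haplotype everywhere, and secondary contact zones
mix divergent lineages.  `phylogrid` turns aligned sequences plus sample
coordinates into the comparative statistics used to read that record
across several co-distributed species at once.

## What it computes

From one aligned FASTA per species and a tab-delimited sample table
(`id`, `species`, `lat`, `lon`):

* **Haplotypes** — simple indel coding (each maximal shared gap run is one
  binary character, so an indel counts as a single mutation), collapsing,
  per-site nucleotide diversity `π = n/(n−1) · Σ p_h p_g d_hg / L` with its
  standard deviation, and segregating-site counts.
* **Networks** — mutation-step distance matrices, ε-relaxed
  minimum-spanning networks, and median-joining networks with median
  vectors, exported to GraphML / edge-list TSV.
* **Grid statistics** — per degree-grid cell (cells with ≥ 3 individuals):
  effective number of haplotypes `NAe = (n−1)² / [(Σp²)(n+1)(n−2)+3−n]`,
  gene diversity `He = n/(n−1)(1 − Σp²)`, ordered-allele diversity
  `v = n/(n−1) Σ p_h p_g π_hg`, and haplotypic endemism `End` (share of
  individuals whose haplotype's total range is ≤ 200 km).
* **Phylogeographic signal** — global `G_ST = (h_T − h_S)/h_T` and
  `N_ST = (v_T − v_S)/v_T` (equal cell weights, harmonic-mean small-sample
  correction) with a permutation test of `N_ST > G_ST` that shuffles
  haplotype identities on the distance matrix.
* **Distinctiveness** — between-cell `v_ij` and centroid distances
  `d_ij`; `S'_ij` as residuals of `v_ij` on `ln d_ij` when a one-sided
  Mantel test finds distance decay, centred values otherwise; `S'_i` per
  cell.
* **Congruence across species** — within-species z-scores, pairwise
  Pearson tests on shared cells, one-way ANOVA with cells as factor,
  between-species Mantel tests on `S'_ij`, and multi-species cell means
  for mapping.
* **Scenario simulator** — panmixia / refugia / expansion / secondary
  contact worlds with known truth (`simulate_dataset()`,
  `expected_pattern()`, `evaluate_pattern()`) for testing and power
  analysis.

## Worked example

A two-refuge world: two haplogroups five mutations apart, each refuge
seeding site-local endemic haplotypes.

```r
library(phylogrid)

dat  <- simulate_dataset(scenario_config("refugia", seed = 42))
haps <- collapse_haplotypes(code_indels(dat$alignment), dat$samples)
haps
#> <haplotype_set> 12 haplotypes, 120 samples, 22 characters (22 sub + 0 indel)

D   <- mutation_distance_matrix(haps)
pol <- summarize_polymorphism(haps, D)
sprintf("SNPs %d; pi x 1000 = %.3f +/- %.3f", pol$snps, 1000 * pol$pi, 1000 * pol$pi_sd)
#> "SNPs 22; pi x 1000 = 3.830 +/- 2.222"

as  <- assign_cells(dat$samples, grid_spec(0.75))
as
#> <grid_assignment> 120 samples, 18 cells (18 retained, >= 3 samples) at 0.75 deg

gd <- global_differentiation(as, haps, D, n_perm = 999, seed = 7)
gd
#> <differentiation> 18 cells: GST = 0.5124, NST = 0.5888, P(NST > GST) = 0.004 (999 perms)

ds <- distinctiveness_scores(between_cell_matrices(as, haps, D),
                             n_perm = 999, seed = 8)
ds
#> <distinctiveness> 18 cells, branch = residuals (Mantel r = 0.582, p = 0.001)
```

`NST > GST` with `p = 0.004` says related haplotypes cluster in space —
the refugial signal; the Mantel `p = 0.001` licenses detrending `v_ij` by
`ln d_ij`, and the cell with the top `S'_i` (here the cell holding the
second refuge's divergent haplogroup) is flagged as genetically
distinctive.  The scenario's own truth agrees:

```r
en <- cell_endemism(as, haps, dat$samples)
evaluate_pattern(expected_pattern(dat$truth), diff = gd,
                 diversity = cell_diversity(as, haps, D),
                 endemism = en$cells, assign = as)
#>              nst_signal refuge_end_top_quartile
#>                    TRUE                    TRUE
```

`run_comparative_pipeline()` repeats this over several species and grid
sizes and adds the cross-species congruence tables;
`write_pipeline_tables()` writes everything as TSV.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates eight pseudo-species (two per scenario), runs the full
comparative pipeline at 0.75°, 1.5° and 3° with 999 permutations against
the installed package, writes the output tables under
`results/tables/`, and writes the JSON report to the path given by
`--out`.
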