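# epifeed

Analysis toolkit for nutrient-state-driven chromatin dynamics, built around
interval-level summaries of ChIP-seq experiments in endocrine tissues (e.g.
pancreatic islets from fed and fasted animals). It covers four computations
that such studies chain together, plus a synthetic-data generator that makes
every stage verifiable against planted ground truth:

1. **Permutation-based interval enrichment.** For two coordinate sets on a
   genome — say gene TSSs (reference) and feeding-gained H3K27ac peaks
   (test) — the observed association frequency is the fraction of reference
   sites with a test site within a window *w* (±1 kb or ±10 kb). The null
   distribution comes from repeatedly relocating the *test* set with a
   length-preserving shuffle (chromosome drawn with probability proportional
   to its placeable positions, start uniform), and both one-sided empirical
   p-values use the add-the-observed correction

   p_enrich = (1 + #{null ≥ observed}) / (n_iter + 1),

   with 10,000 iterations by default.

2. **Windowed signal quantification and peak classification.** Tag counts or
   per-base coverage are summed in ±1 kb windows around peak centers
   (optionally extending fragments to 250 bp), depth-normalized to a common
   total (library sizes preferred over column sums), tested between
   conditions with a transparent differential stage
   (log2FC = log2((mean_B+1)/(mean_A+1)); two-sided Welch t on
   log2(count+1)), and classified at P < 0.01: `feeding_gained` /
   `feeding_lost` / `static`, or, over a time course, by the *first* time
   point reaching the cutoff (`gained_first_wk1`, `lost_first_wk3`, ...).
   Spearman co-occupancy correlations, per-class box statistics (whiskers at
   1.5×IQR) and binned profiles round out the module.

3. **Gene-set dynamics.** K-means (Lloyd, best of seeded restarts) clusters
   genes in the space of log2 fold changes across two comparisons; the
   cluster whose centroid is positive in every comparison is the
   "nutrient-response" set. Pre-ranked GSEA (weighted Kolmogorov–Smirnov
   running sum; gene-set permutation null, 1,000 permutations; NES and
   sign-stratified FDR) tests any set against any ranking.

4. **Variant-to-gene linking.** Trait-associated variants with at least
   nominal association (strictly P < 0.05) inside factor-bound sites are
   carried through chromatin loops (promoter-capture Hi-C style): a site
   links to a gene when it overlaps one 5 kb-flanked loop anchor and the
   gene's TSS lies in the other. The distinct linked genes form a set ready
   for GSEA.

The synthetic generator plants all of this structure — negative-binomial
replicate counts with condition effects, TSSs spatially enriched near gained
peaks at a controlled odds ratio, a second binding track rank-correlated via
a Gaussian copula, loops wiring variant-bearing sites to promoters — and
emits machine-readable truth, so recovery can be measured exactly.

## Worked example

```r
library(epifeed)
cfg <- pipeline_config(seed = 1)          # simulate-then-analyse defaults
run <- run_pipeline(cfg, "epifeed_out")

run$permutation[, c("id", "observed", "expected", "p_enrich", "call")]
```

```
                          id observed expected p_enrich     call
1         TSS|feeding_gained  0.28900 0.184884   0.0001 enriched
2           TSS|feeding_lost  0.00400 0.003722   0.5065       ns
3                 TSS|static  0.41900 0.379826   0.0085 enriched
4 bound_sites|feeding_gained  0.45333 0.031021   0.0001 enriched
5   bound_sites|feeding_lost  0.00333 0.000572   0.0477 enriched
6         bound_sites|static  0.57000 0.070833   0.0001 enriched
```

28.9% of TSSs have a feeding-gained peak within ±10 kb against 18.5%
expected by chance (p = 1/10001, the smallest attainable value at 10,000
shuffles) — the planted proximity of DE-gene TSSs to gained peaks, diluted
across all TSSs. Bound sites associate strongly with every sizable peak
class because the second factor was planted to co-occupy peaks
(`run$correlation$rho` returns 0.806 against a copula target of 0.8).

```r
table(run$classes)
## feeding_gained   feeding_lost         static
##            596             11           1393

print(run$gsea, digits = 3)
##                 set    es  nes       p fdr n_set leading_edge_size
## 1 nutrient_response 0.668 3.92 0.00127   0   300               300
```

The nutrient-response cluster (genes up in both simulated comparisons) is
recovered by K-means and scores NES 3.92 at FDR 0 against the
feeding-response ranking. The variant-linking stage recovers all 20 planted
site→gene links (`run$links`). Nine stamped TSV reports land in
`epifeed_out/`; a rerun with the same seed is bit-identical.

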