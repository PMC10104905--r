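---
title: "Methods behind epifeed: permutation nulls, peak classes, gene-set dynamics and loop-based variant linking"
author: "epifeed authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind epifeed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

epifeed implements the interval-level computations that recur in studies of
nutrient-regulated chromatin: enrichment of associations between coordinate
sets, classification of differential ChIP-seq peaks, definition of
nutrient-response gene modules, and the assignment of trait-associated
variants to target genes through chromatin loops. This vignette records the
models, the parameters that matter, the numerical conventions, and what the
synthetic benchmark does and does not demonstrate.

## Coordinates and the interval model

All intervals are 0-based, half-open (`[start, end)`), the BED convention;
"±1 kb" always means a symmetric flank of 1000 bp clamped to `[0, chrom
length]`. Two intervals overlap when `start < other.end` and `other.start <
end`. A genome is an ordered map of chromosome lengths; internally all
interval algebra runs on a single concatenated axis with a 1 bp guard gap
between chromosomes, so adjacent chromosomes can never produce spurious
overlaps and every operation is a vectorized scan (sorting plus cumulative
maxima) rather than a per-interval loop. This matters because the
permutation test re-shuffles and re-intersects the test set up to 10,000
times per pair; per-iteration object construction would dominate runtime.
Merging coalesces overlapping *and* book-ended intervals, matching the
default behaviour of the standard interval tools.

## The permutation null

`permutation_test(reference, test, window_bp, n_iter)` measures the fraction
of reference intervals with a test interval within `window_bp`, then builds
the null by relocating the **test** set only. Each interval is placed
independently and uniformly over all positions where it fits: a chromosome
is drawn with probability proportional to `chrom_len − interval_len + 1`,
the start uniformly among those positions. Lengths are preserved exactly;
shuffled intervals may overlap each other; no exclusion regions
(blacklists, unmappable sequence) are modelled. Both one-sided empirical
p-values are reported with the add-the-observed correction, so p is never 0
and never below `1/(n_iter + 1)`; the bar-plot "expected by chance" value is
the null mean. The significance call takes whichever one-sided p is smaller,
at a caller-chosen alpha; no multiple-testing correction is applied across a
grid of tests — `batch_permutation` returns both p-values per pair and
leaves correction to the analyst. Batch runs derive an independent RNG
substream per pair from the master seed and the pair id, so results are
identical whatever the order of computation.

Two design points deserve emphasis. First, the association direction: the
*reference* set is flanked and the raw test intervals are probed, which for
unclamped intervals equals the symmetric rule "minimum gap ≤ window" (the
test suite verifies this equivalence against a pairwise gap scan). Second,
the null assumes independent uniform placement. Peaks in real data (and in
the generator) are non-overlapping, which is a mild violation; at the
densities used here the measured type-I rate of `p_enrich < 0.05` on null
data stays near nominal (the acceptance suite requires it inside
[0.02, 0.08] over 200 datasets), but extremely dense test sets could drift.

## Signal quantification, normalization, and the differential stage

Signal is quantified in windows `[center − 1000, center + 1000)` where the
center is `floor((start + end)/2)` — odd lengths resolve downward. Fragment
tracks may be extended to 250 bp from the fragment start before counting,
mirroring the common tag-extension convention; coverage (bedGraph) tracks
are summed per base via a prefix-mass function, assuming the segments are
non-overlapping (enforced at construction).

Depth normalization scales every replicate column to the mean of the raw
totals. Which totals is a substantive choice: when 44% of peaks genuinely
gain signal in one condition, the column sums over the quantified peaks
confound sequencing depth with biology — normalizing to them pushes every
static peak negative and inflates "lost" calls. Whole-library tag totals do
not have this problem because the changing peaks are a small fraction of
the library. The `signal_matrix` therefore carries optional per-replicate
library sizes, the generator emits them, and `normalize_total` prefers them
over column sums; the matrix records its normalization state so downstream
tables can report it.

The built-in differential stage is deliberately transparent rather than
state-of-the-art: effect `log2((mean_B + 1)/(mean_A + 1))` on normalized
counts and a two-sided Welch t-test on `log2(count + 1)` with at least two
replicates per group. It is a stand-in for a negative-binomial framework,
and externally computed differential tables are ingested via
`read_differential` for exact reproduction when such results exist.
Degenerate rows are guarded: zero variance with equal means gives p = 1,
zero variance with unequal means the smallest positive double. With n = 3
per group this test is honest but blunt — the Welch–Satterthwaite degrees
of freedom can fall toward 2, pushing the α = 0.01 critical value toward
9.9, so per-peak power at a planted 4-fold change and NB dispersion 0.05
plateaus around 0.7–0.8. Consequences for the benchmark are discussed
below.

Classification is a literal encoding of the cutoff rules: `feeding_gained`
iff p < α and log2FC > 0 (with the fed state as group B), `feeding_lost`
iff p < α and log2FC < 0, else `static`; over a time course the label comes
from the first time point reaching p < α, direction from that time point's
fold change, with week 1 taking precedence when both are significant
(forced by "first"). Labels always partition the peak universe. Box
statistics use whiskers spanning data within 1.5× the interquartile range;
class ratios are ratios of class means; Spearman correlations mid-rank
ties.

## Pre-ranked GSEA

The ranked list orders genes by the statistic, ties broken deterministically
by gene id. Walking down the ranking, the running sum gains
`|stat|^weight / Σ_hits |stat|^weight` at set members and loses
`1/(N − |S|)` elsewhere; the enrichment score is the signed extremum of the
path (evaluated only at just-after-hit maxima and just-before-hit minima,
which is exact). Magnitude ties between the positive and negative excursion
resolve to the positive extremum, within an absolute tolerance of 1e-12 to
absorb accumulated rounding. All-zero hit weights fall back to the
unweighted step. The null is gene-set permutation: `n_perm` random same-size
sets from the ranked universe (default 1,000). NES divides ES by the mean
magnitude of sign-matched null scores; p is sign-matched and
add-the-observed-corrected; the batch FDR pools sign-matched normalized
null scores across sets and takes the null-vs-observed tail ratio, clipped
to [0, 1]. Genes absent from the ranking are dropped from sets with a
message; an empty intersection is an error. Phenotype-permutation GSEA on
expression matrices is out of scope.

K-means uses Lloyd's algorithm with Euclidean distance, keeping the best of
`n_init` seeded restarts by total within-cluster sum of squares (restarts
that collapse a cluster are discarded). The number of clusters is a
required choice — no criterion is imposed — and the default of k = 4 for
the two-comparison fold-change space reflects the coarse structure such
data show (up-up, down-down, mixed, null). The nutrient-response set is the
cluster whose centroid is positive in *every* comparison, ties broken by
centroid norm; if no centroid is all-positive that is an error rather than
a silent nearest match.

## Variant-to-gene linking

Variants are retained at strictly `p < 0.05` — a variant exactly at the
cutoff is excluded. Sites qualify when a retained variant's position lies
inside the *raw* site; an optional flag extends the containment window by
the anchor flank instead, since published descriptions are ambiguous on
this point, but the stricter rule is the default. A qualifying site links
to a gene via a loop iff the site overlaps one anchor extended by 5 kb and
the gene's TSS lies in the other extended anchor; promoters are TSS points
by default with a configurable promoter window. Links are many-to-many,
deduplicated over (site, gene, loop), sorted, and invariant to swapping a
loop's anchors. Trans-chromosomal loops are accepted and flagged. The rule
is deterministic interval algebra, so on the planted fixture recovery is
exact by construction.

## What the generator emulates — and what it does not

`simulate_dataset` produces an internally consistent bundle whose defaults
encode the fed/fasted study design the package targets: 3 replicates per
condition; negative-binomial counts (variance µ + 0.05µ²) around per-peak
log-normal means (median ~100 tags per ±1 kb window, sdlog 1); 44% of
peaks regulated with 99.9% of those gaining on feeding, at a planted
|log2FC| of 2; per-replicate sequencing-depth factors (lognormal, sdlog
0.15) with the matching library sizes emitted; DE-gene TSSs placed by
rejection sampling so their odds of lying within ±10 kb of a gained peak
are 5× baseline (exact odds control, not post-hoc labeling); a second
binding signal tied to realized peak signal through a Gaussian copula at
Spearman ρ = 0.8 (Pearson `2·sin(πρ/6)` on the latent normals); and loops
plus variants planting a known site→gene link set. Genome scale (3 × 20 Mb,
2,000 peaks, 1,000 TSSs) is a desk-scale choice that keeps every property
measurable in seconds; all sizes are configurable.

Two constructions are worth knowing about. Designated variant-bearing sites
are chosen pairwise-separated by more than three times the anchor reach,
their target promoters are TSSs isolated from all other TSSs by more than
that reach, decoy loops keep their promoter-side anchor outside TSS reach,
and background variants are placed outside bound sites — together these
make planted-link recovery a geometric certainty rather than a matter of
collision luck, which is exactly what a correctness benchmark needs. And
the planted in-site variants draw their p-values from a Beta(0.1, 1)
conditioned below the retention cutoff, so every planted link is real by
construction.

The generator does **not** emulate: read-level noise or mapping artifacts
(no FASTQ/BAM), GC or mappability bias, blacklist regions, spatial
autocorrelation of peaks beyond non-overlap, linkage disequilibrium among
variants, or ortholog mapping between species (all ids are shared).
Passing the benchmark therefore demonstrates the correctness of the
computations and the recoverability of planted structure under an idealized
error model, not robustness to the full messiness of sequencing data.

One honest negative result, reproduced by the acceptance suite: with the
Welch-based differential stage at n = 3 and the study-scale regulated
fraction (44%), overall feeding-label recovery measures around 0.85, short
of the 0.95 the benchmark demands, because the recovery ceiling is
`s·0.995 + (1−s)·power` with power ≤ ~0.8 (see above) and static fraction
s = 0.56. The temporal scheme, whose study-scale regulated fraction is
~1.5%, comfortably exceeds 0.95, and the null false-call rate stays below
2%. A negative-binomial test with information sharing across peaks would
lift the feeding number; that is precisely the component this package
deliberately leaves to external tools.

## Determinism and problem sizes

Every stochastic routine takes a seed and restores the caller's RNG state;
one master seed fans out to named substreams (peaks, counts, tss, second,
loops, variants, expression, ...) so components can be regenerated
independently and in any order. Pipeline reports carry the seed and a
config fingerprint, and a rerun with identical configuration is
bit-identical. The test suite runs the calibration property at 200 null
datasets of 300 peaks × 500 shuffles, planted-power at 20 runs × 5,000
shuffles, the interval-algebra oracle at 1,000 random instances, and the
GSEA oracle exhaustively over all gene sets on rankings up to length 8 —
sizes chosen so the full suite and the acceptance script each finish in a
couple of minutes on a single core while keeping every estimate's Monte
Carlo error well inside the asserted bands.
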