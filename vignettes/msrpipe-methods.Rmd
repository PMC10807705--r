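---
title: "Methods: sex-linked region detection, methylation summaries and mutual-rank networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linked region detection, methylation summaries and mutual-rank networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In dioecious plants with young sex chromosomes, the male-determining
haplotype is carried on a *male-specific region* (MSR): an interval present
in males (hemizygous, one copy) and absent in females. On a complete
telomere-to-telomere assembly, the MSR leaves three coupled signatures in
sexed resequencing data:

* **read-depth contrast** — females map almost no reads there, males about
  half their autosomal depth;
* **allele-frequency differentiation** — male-limited variants inflate
  between-sex FST;
* **copy number** — genes inside the region score ~1 in males and ~0 in
  females while autosomal genes score ~2 in both.

The MSR is also typically repeat-rich and hypermethylated, and the genes it
carries (e.g. MADS-box *AG*-family candidates) act inside sex-biased gene
regulatory networks. `msrpipe` implements this whole analysis chain —
telomere/centromere annotation of the assembly, MSR detection and
delimitation, cytosine-methylation summarisation, and mutual-rank network
construction — together with a deterministic simulator that plants all of
these signals with recorded ground truth, so every stage is testable
without any external dataset.

# Simulated study conditions

`sim_config()` defaults describe the benchmark scenario used throughout the
tests and the acceptance script:

* 2 chromosomes of 2 Mb; telomeres of 300 tandem `CCCTAAA`/`TTTAGGG`
  copies at every end; one 162-bp monomer array of 200 copies as the
  centromere of chromosome 1.
* MSR on the first 400 kb of the last chromosome; 10 males and 10 females;
  80% of MSR SNP sites male-limited (all males 0/1 carriers, all females
  homozygous reference); SNP density 0.5/kb drawn outside telomeres.
* Depth: Poisson-like around 30x per sample in 100-kb windows; inside the
  MSR, male windows average 15x (one haplotype) and female windows 0.6x
  (2% of autosomal depth — mapping noise rather than true coverage).
* Methylation: every cytosine on both strands, depth uniform on [10, 50],
  binomial methylated counts at baseline levels CG 0.498, CHG 0.279,
  CHH 0.028 (typical plant genome-wide levels), plus an additive 0.30
  boost inside the MSR.
* Expression: 2 sexes x 3 stages x 3 replicates (18 samples, log2 scale).
  Five TFs each drive 2 targets with weight +/-1 and Gaussian noise
  (sd 0.05); all other genes are independent noise. Each TF's 8-bp
  consensus motif is planted mid-promoter in its targets.

Where a published analysis of a real genome informed a value (window size,
telomere motif, monomer length, methylation call rules, DEG and network
thresholds), that value is the default. Effect sizes with no published
analogue (depth contrast, fixed-difference fraction, methylation boost,
expression noise) were chosen once for testability at desk scale and are
not biological estimates.

What the simulator deliberately does **not** model: read-level data
(FASTQ), sequencing error, linkage disequilibrium, GC content, repeat
landscapes beyond the two planted arrays, or dispersion structure in
expression counts. Passing tests therefore demonstrate that the
*computations* are correct and that the planted effects are recoverable at
the stated sizes — not that the thresholds are optimal for any particular
real dataset.

# Telomeres and centromeres

`scan_telomeres()` anchors on exact motif occurrences within `max_offset`
(default 10 kb) of each chromosome end and grows tandem runs copy by copy.
A candidate copy is absorbed if it matches the motif in a majority of its
positions and the run's cumulative mismatch fraction stays at or below
`max_mismatch_frac` (default 0.1); the per-copy majority rule stops a run
from drifting into random sequence on the strength of earlier perfect
copies. Defaults (`min_copies = 50`, i.e. 350 bp) admit the smallest
telomeres seen on real plant assemblies (~2 kb) with a wide margin.

`infer_tandem_monomer()` is a deliberately transparent re-implementation of
tandem-period detection: for each period $p$ in `[min_period, max_period]`
it scores $\mathrm{frac}(p) = \Pr[s_i = s_{i+p}]$ and takes the maximising
$p$. Numerical choices: ties break toward the **smallest** period (a
perfect array scores 1.0 at every multiple of the true monomer); scoring
uses at most `max_scan` = 50 kb of sequence; a best fraction below 0.5
returns a "no tandem structure" result. The consensus is the per-column
majority base, reported as the lexicographically smallest rotation of
itself and its reverse complement so that calls are independent of array
phase and orientation.

`call_centromeres()` marks bases covered by exact occurrences of the
monomer (either orientation) in 1-kb windows, merges windows with
occupancy at or above `occupancy_threshold` (default 0.5) and keeps the
longest interval of at least `min_array_length` per chromosome. Boundaries
are snapped to window edges — the method claims window resolution, nothing
finer. Chromosomes without a qualifying array simply yield no call; no
attempt is made to force a centromere per chromosome.

# The MSR scan

Per-site statistics use allele counts (missing genotypes excluded). FST is
the Hudson estimator with finite-sample bias correction,

$$F_{ST} = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}}
{p_1(1-p_2) + p_2(1-p_1)},$$

chosen because it is the least sensitive of the common estimators to
unequal sample sizes; Weir-Cockerham is available behind
`site_fst(..., method = "wc")`. Negative site values are retained — they
are part of the estimator's sampling distribution and clamping would bias
window means upward. Per-site diversity is the unbiased heterozygosity
$2a(n-a)/(n(n-1))$; window pi divides the sum over SNPs by the window
length in bp, so monomorphic windows legitimately score 0 while windows
with no SNPs carry a *missing* FST (there is no differentiation to
estimate) — missing-vs-zero is deliberate and asymmetric between the two
statistics.

Segmentation is penalised binary segmentation on the window-mean FST
series: a split is accepted when it reduces within-segment squared error by
more than $\lambda \log(n)\, \hat\sigma^2$, with
$\hat\sigma^2 = \mathrm{var}(\Delta x)/2$ (a changepoint-robust noise
estimate) and $\lambda$ = `penalty` (default 1). Missing window means are
linearly imputed first. Breakpoints are counts of windows left of each
boundary, so boundary positions in bp are `breakpoint * window_size`
exactly — this is what makes "recovered `[0, 400000)` exactly" a
well-posed claim.

`call_msr()` accepts a segment only when **both** lines of evidence hold:
mean FST at least `fst_fold` (default 3) times the genome-wide **median**
window FST, and female/male depth ratio at most `depth_ratio_max` (default
0.2). One caveat is documented rather than patched: with an unbiased FST
estimator the genome-wide median on null data sits near zero (often
slightly below), so the FST criterion alone is weak on clean simulations;
the conjunction with depth depletion is what gives the call its
specificity, as the sex-label permutation test demonstrates. Copy number
is `2 * (overlap-weighted gene depth) / (sample median window depth)` —
the median, not the mean, so the MSR's own depleted windows do not drag
the normaliser.

Hemizygous male genotypes arrive encoded as 0/1 heterozygotes because
diploid VCF has no hemizygote representation. Allele-count FST then sees
male frequency 0.5 (not 1.0) at fixed differences, bounding site FST near
0.47 at these sample sizes rather than 1.0. This is a representation
limit, not an estimator defect, and it is why the window-mean FST step in
the simulations is ~0.37 rather than ~0.8.

# Methylation

Site calls follow the read-support rule: coverage below 5 is filtered;
a covered site is methylated iff methylated reads / total reads **strictly
exceeds** 0.5 (a ratio of exactly 0.5 is unmethylated). A gene is "a
methylated gene" in a context when any methylated-called site of that
context overlaps its CDS.

Region levels are **pooled read ratios** — sum of methylated reads over
sum of reads across the region's sites within depth bounds [5, 400] — not
averages of per-site levels. The two conventions differ whenever depth and
level covary; the pooled form satisfies exact partition additivity (counts
over a disjoint partition sum to the whole), which the tests exploit, and
is the natural region-level generalisation of the site ratio. The per-site
average is recoverable from the returned counts if wanted.

Metagene profiles use 20 scaled gene-body bins plus 2-kb flanks in fixed
200-bp bins (10 each side, 40 bins total), depth bounds [5, 400],
minus-strand genes traversed 5' to 3'. Bins pool counts across genes
rather than averaging per-gene levels, so heavily covered genes weigh
more — consistent with the pooled region convention. A site lands in the
bin containing its position after strand normalisation (half-open bins);
genes shorter than the bin count are skipped and counted.

CG sites on opposite strands are **not** merged: the input format calls
the two strands independently and merging would discard strand-asymmetric
signal; symmetric analyses can merge downstream. The
methylation-expression association is summarised with Spearman's rank
correlation (gene-body pooled level vs mean log2 abundance) — robust to
the strong non-normality of pooled levels.

# Regulatory networks

DEG filtering applies Benjamini-Hochberg over all tested genes and keeps
|fold change| >= 2 with FDR <= 0.01; genes with missing p-values are
excluded from the BH family (adjusting over imputed members would distort
everyone else's FDR) and flagged. Candidate pairs need |Pearson r| >= 0.9
across samples.

Mutual rank: within each gene's retained candidate list, partners are
ranked by descending |r| (ties broken lexicographically by partner id for
determinism), and the raw score is the geometric mean
$\sqrt{r_{12} r_{21}}$ of the two reciprocal ranks. The raw score lives on
$[1, N-1]$, not $[0,1]$; to obtain a bounded score with 1 meaning "each is
the other's top partner" we map $\mathrm{mr} = 1 - (\mathrm{raw}-1)/(N-1)$
with $N$ the number of genes in the candidate graph. This normalisation is
a documented design choice (the bounded-score convention is ambiguous in
the literature this follows); the raw geometric mean is returned alongside
so any other convention can be applied. Edges keep pairs with
mr >= 0.90.

A consequence worth stating explicitly: with threshold $t$ the kept raw
rank product is bounded by $(1 + (1-t)(N-1))^2$, so in a module of $k$
co-regulated genes — where reciprocal ranks range up to $k$ — planted
edges are guaranteed recoverable only while $k \le 1 + (1-t)(N-1)$. The
simulator's default module size (1 TF + 2 targets) sits inside that bound
for its candidate-graph size; larger planted modules would see their
weakest reciprocal pairs fall below the threshold not through noise but
through the geometry of rank thresholds. Recovery benchmarks treat any
within-module edge (TF-target or co-regulated siblings, which are truly
co-expressed by construction) as correct when scoring precision.

Networks are built per sex across stages and replicates (9 samples),
**not** per sex-and-stage stratum: a stratum holds 3 replicates, and with
n = 3 the chance of |r| >= 0.9 between independent genes is ~0.29 per
pair, which makes the correlation threshold meaningless. Stage identity is
carried as a node attribute (stage of peak expression) instead of an edge
set. Recovery benchmarks use the full 18-sample design for the same
reason, stated as such.

Promoters are the 2-kb immediately upstream of the transcription start,
strand-aware, truncated at chromosome edges with the realised length
recorded. Motif scanning scores log-odds against a uniform background with
pseudocount 0.01 at every position on both strands; a promoter hits when
its best score reaches 85% of the PWM's maximum attainable score — a
common PWM practice for strong consensus motifs, exposed as
`score_fraction`. Enrichment is the one-sided Fisher exact test on
promoters-with-hit counts, DEG set vs background, at P < 0.001; regulation
edges TF -> target require the TF's motif enriched, the target's promoter
hit, and both genes differentially expressed. Topology statistics treat
the graph as undirected and simple; local clustering of degree-<2 vertices
counts as 0, and characteristic path length averages over connected pairs
only.

# Numerical and degenerate-input conventions

* All coordinates are 0-based half-open internally; VCF and GFF3 are
  converted at the IO boundary and nowhere else.
* One global integer seed; every simulation stage derives its own stream
  from (seed, stage name), so adding a stage never perturbs earlier
  outputs, and identical configs are byte-identical across runs.
* Zero-variance genes are excluded from correlation with a warning;
  empty candidate sets, empty graphs, and empty region selections return
  typed empty results or `NA`, never errors.
* The changepoint routine returns no breakpoints for constant series
  (noise variance 0 makes any split gain 0, and gains must strictly exceed
  the penalty).
* Fisher p-values, BH adjustment, graph statistics and the exact test's
  hypergeometric tail all go through base R / igraph; the tests verify
  them against independently coded oracles rather than trusting either
  implementation.

# Problem sizes

The test suite and the acceptance script run the benchmark scenario at
2 Mb x 2 chromosomes for the MSR scan (20 replicate seeds) and a reduced
200-kb scenario for annotation, methylation, copy-number and network
replicates; these sizes were chosen so the full planted-truth signal is
present (>= 12 windows per chromosome, >= 5000 methylation sites per
region, 15 network genes) while a complete multi-seed run stays in the
tens of seconds. The pipeline itself has no scale assumptions beyond
memory: all operations are linear or near-linear in sequence length and
site count except period inference, which is quadratic in the scan window
and therefore capped by `max_scan`.

# Known limitations

* Diploid VCF encoding halves the apparent male frequency of male-limited
  alleles (above); FST-based delimitation still works because the scan is
  relative, but absolute site FST values in hemizygous regions should not
  be read as fixation indices.
* The FST-fold criterion referenced to the genome-wide median is weak when
  the median is near zero; detection specificity rests on the depth flag.
* Window-edge snapping limits centromere and MSR boundaries to window
  resolution (1 kb and 100 kb respectively at defaults).
* Promoter definition ignores UTR annotation (start of gene = start of
  transcription) and the motif model ignores local GC background.
* The simulator's expression design has no count noise model; fold-change
  and p-value inputs in real use should come from a dedicated DE tool,
  with only the BH-and-threshold filter applied here.
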