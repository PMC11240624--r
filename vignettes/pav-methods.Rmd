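---
title: "Methods: coverage-based gene PAV calling, pangenome classification, and PAV association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based gene PAV calling, pangenome classification, and PAV association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavpipe)
```

# Scope and model

`pavpipe` treats gene presence–absence variation (PAV) as a binary
property of a (gene, sample) pair, inferred from short-read depth of
coverage. The pipeline has four statistical components: a
breadth-of-coverage presence caller, a frequency classifier over the
resulting binary matrix, distance/ordination summaries of population
structure, and a single-marker linear-model association against
de-regressed breeding values. This vignette documents the model behind
each step, the tunable parameters and their defaults, the numerical
conventions, and what the synthetic validation data do and do not
establish.

# Annotation reduction

Coverage is assessed over exons, so each gene is reduced to a single
transcript before calling. **Longest** is defined as the largest summed
exon length after merging overlapping exons — not the widest genomic
span. Two transcripts can disagree on these two orderings (a
long-intron, short-exon isoform spans more of the chromosome while
carrying fewer exonic bases); since every downstream quantity is a
function of exonic bases only, exonic length is the right size measure.
Ties are broken by the lexicographically smallest transcript identifier,
which makes selection deterministic and invariant to transcript order in
the input. Genes whose transcripts carry no exon features are excluded
with a warning rather than fabricated from the gene span.

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
is converted at the I/O boundary, which keeps interval arithmetic
(lengths, unions, depth indexing) uniform. Interval merging joins
touching intervals, so the length of a merged set equals the number of
distinct covered bases. Strand is carried for reporting but ignored by
coverage, which is strand-agnostic.

# Depth model

Per-sample depth is a run-length map from half-open intervals to
non-negative integers, ingested from 4-column BedGraph (the per-base
output convention of mosdepth and `bedtools genomecov`). Positions not
covered by any run — including whole contigs absent from a file — have
depth zero. This is a semantic choice, not a fallback: the caller treats
lack of coverage as evidence of absence, so "no data" and "depth 0" must
coincide. An optional BAM adapter counts non-duplicate mapped reads per
base and produces the identical structure; no mapping-quality or
proper-pair filtering is applied there, because read-level quality
control belongs to the upstream alignment workflow, whose output this
package consumes.

# Presence calling

With exon union $B(g)$, per-base depth $d_s(\cdot)$, depth threshold
$m$ (`min_cov`) and breadth cutoff $\ell$ (`lost_cutoff`), the covered
fraction is

$$c(g,s) = \frac{\lvert\{\, b \in B(g) : d_s(b) \ge m \,\}\rvert}{\lvert B(g)\rvert},$$

and the call is $\text{present} \iff c(g,s) > \ell$ (strict). The
defaults $m = 5$ reads and $\ell = 0.2$ are the standard settings for
gene-loss detection from ~20× short-read data: at 20× Poisson depth a
truly present base fails $d \ge 5$ with probability
$P(\mathrm{Pois}(20) < 5) \approx 1.7\times 10^{-5}$, while a truly
deleted gene accumulates essentially no qualifying bases, so the two
hypotheses are separated by orders of magnitude in $c$. The strict
inequality at $\ell$ ("more than 20%") sends a fraction exactly at the
cutoff to absent; with integer base counts this boundary is attainable,
so the tie rule is stated rather than left to floating point. Raising
either threshold is monotone: it can only convert present calls to
absent. Covered fractions are always written next to the binary matrix
so borderline calls can be audited.

Calls are strictly binary — this is PAV, not copy-number estimation; a
duplicated gene and a single-copy gene are both simply "present".

# Pangenome classification

Presence frequency $f$ = presence count / number of samples is binned
as core ($f = 1$), softcore ($0.95 \le f < 1$), shell
($0.05 \le f < 0.95$) and cloud ($f < 0.05$). The conventional
integer-percent phrasing of these bins ("95–99%", "5–94%") is not
achievable exactly at arbitrary cohort sizes, so the package fixes
half-open bins on the continuous frequency with closed lower edges;
cloud includes $f = 0$ (genes absent from every sample). These choices
make the four classes an exact partition: class counts always sum to the
gene total, and the variable (dispensable) set is exactly
softcore + shell + cloud. Reported percentages are rounded half-up at
two decimals (`round_half_up()`), matching how such tables are
conventionally printed; R's default round-half-even would differ on
boundary values.

# Population structure

The sample-by-sample distance is the Hamming mismatch fraction over all
genes — the simplest metric consistent with a binary matrix, bounded in
$[0,1]$, and a true metric (the triangle inequality is exercised in the
tests). The neighbor-joining tree is the classic Saitou–Nei
agglomeration on the Q-criterion
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$; ties on $Q$ are broken by the
first pair in row-major order over the current node list, negative
branch lengths are clamped to zero with the clamped deficit reported,
and the result is returned as an `ape` `phylo` object so Newick I/O and
plotting use the standard ecosystem. On additive matrices NJ is exact,
which the tests use as an oracle (path-length matrix of the output tree
equals the input within $10^{-9}$); the independent `ape::nj`
implementation serves as a topology cross-check, never as the
implementation.

PCA operates on samples × genes with gene columns mean-centred and not
variance-scaled: for binary data, a gene's variance $f(1-f)$ carries the
frequency information that scaling would erase. Component signs are
fixed by making each component's largest-magnitude loading positive so
output is bit-stable across platforms. Explained-variance fractions are
taken against the total column variance, so they sum to 1 over a full
decomposition. A constant matrix yields zero components with a warning
rather than an error.

# Association

De-regression divides each PTA by its reliability
($\mathrm{dPTA} = \mathrm{PTA}/r$), undoing evaluation shrinkage so the
response is on an unshrunk scale; reliabilities must lie in $(0,1]$ and
missing cells propagate as missing. Trait–trait Pearson correlations use
pairwise-complete samples with two-sided p-values from the $t$
transform on $n-2$ degrees of freedom; zero-variance traits yield `NA`
cells rather than fabricated values.

Markers are gene PAV indicators filtered at
$\mathrm{MAF} = \min(f, 1-f) > 0.05$, with $f$ computed on the
phenotyped subset — the cohort actually tested — rather than on all
sequenced samples (the choice is an argument, not a constant). The
per-marker model is ordinary least squares of dPTA on the 0/1 indicator
with an intercept: the model F statistic on $(1, n-2)$ degrees of
freedom, algebraically identical to the squared pooled-variance
two-sample $t$. No kinship, covariates or genomic control are included
— the model is the plain GLM, and the single-breed, single-evaluation
setting it targets is exactly the case where that simplification is
defensible; samples missing a trait are dropped casewise per trait.
Bonferroni tiers use $p \le 0.05/n_\text{loci}$ (significant) and
$p \le 0.1/n_\text{loci}$ (suggestive) with inclusive comparisons at
the thresholds and $n_\text{loci}$ = the number of markers surviving the
filters, identical across traits. Gene positions in output tables are
the exon-union start of the gene, a stated convention.

Overrepresentation of a gene list against named annotation sets uses
the one-sided (greater) Fisher's exact test on the 2×2 in/out table —
identical to the hypergeometric upper tail — with Benjamini–Hochberg
adjustment across the sets actually tested and an FDR < 0.05 flag.
Annotation sets are user-supplied; no ontology database is bundled.

# Synthetic data: what it emulates, and what it does not

The generator mimics the data shape of a single-breed resequencing
study at desk scale. Defaults (all overridable in `sim_design()`):

| parameter | default | rationale |
|---|---|---|
| samples | 150 | phenotyped-cohort scale of a pilot WGS study |
| genes | 500 on 5 autosomes | enough per-chromosome structure for distribution tables |
| class quotas | 469/16/9/6 core/softcore/shell/cloud | mirrors a strongly core-dominated (~94%) single-breed pangenome |
| absent-in-all | 3 (within cloud) | exercises the $f=0$ edge of the cloud bin |
| depth | Poisson, mean 20× per exonic base | typical modern WGS coverage |
| contamination | 0 (stray-read Bernoulli available) | clean separation by default; stray single reads never reach `min_cov` |
| reliabilities | U(0.5, 0.99) | realistic evaluation-accuracy spread |
| residual s.d. | 1 | effects are specified in residual-s.d. units |

Presence counts are drawn inside each class's frequency bin (the bin
edges at $n$ samples follow the same closed-lower-edge rule as the
classifier, e.g. at $n = 150$: softcore 143–149, shell 8–142, cloud
0–7), carriers are assigned uniformly at random, and causal genes take
their exact requested presence count from the shell quota. Phenotypes
are $\mathrm{dPTA} = \sum_g \beta_g\,x_g + \varepsilon$ with emitted
$\mathrm{PTA} = \mathrm{dPTA}\times r$; the stored truth is the
de-regressed value implied by the emitted (PTA, $r$) pair, so
`deregress()` recovers it bit-for-bit. All randomness flows from the
single design seed (each stage re-seeds from a fixed offset of it), so
equal seeds give byte-identical GFF3/BedGraph/TSV outputs.

Deliberately **not** modelled: read errors, mappability and GC bias,
repeats, linkage between genes, relatedness among samples, and
population structure. Consequently, passing the closure tests shows the
pipeline's logic is correct under its stated model — depth-separated
presence/absence, independent markers, unstructured samples — and the
perfect recovery rates on synthetic data must not be read as error
rates for real cohorts, where mappability artifacts and relatedness
will blur both the calls and the association null. The low-coverage
sensitivity of breadth-based calling is directly observable in the
generator (`mean_depth = 2` produces false absences), and the tests
assert this qualitatively.

# Numerical and determinism choices

* Interval merging joins touching intervals; zero-length intervals are
  rejected.
* Depth ingestion validates sortedness, non-overlap and non-negativity,
  reporting offending line numbers.
* The NJ tie-break, PCA sign convention, lexicographic transcript
  tie-break and fixed stage seeds make every pipeline output
  reproducible byte-for-byte; `run_pipeline()` writes a manifest with a
  configuration hash (output location excluded) and per-file MD5s.
* Percentages meant for human-readable tables are rounded half-up at 2
  decimals; all underlying computations keep full precision.

# Problem sizes used in validation

The shipped validation runs use the default 150 × 500 design for
end-to-end closure (75,000 calls), 100 seeded replicates for GWAS power
(planted $\beta = 2$ s.d. at frequency 0.3), 200 replicates for the
association null, 20 random additive matrices ($n \le 8$) for the NJ
oracle, 1,000 permutation markers for the p-value uniformity check, and
exhaustive 2×2 tables with margins up to 30 for the Fisher-test
exactness check. These sizes were chosen so each property is measured
with comfortable statistical resolution while the whole suite remains a
desk-scale run.

# Known limitations

* Binary calls only: multi-copy genes are indistinguishable from
  single-copy ones, and partial deletions below the breadth cutoff are
  invisible.
* The plain GLM inflates association signal in structured or related
  cohorts; a mixed-model extension is out of scope.
* Trans-spliced or multi-chromosome genes and CDS/UTR structure are not
  modelled; the exon union of one selected transcript is the unit of
  analysis.
* The BAM adapter counts all non-duplicate mapped reads; any desired
  MAPQ filtering must happen upstream.
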