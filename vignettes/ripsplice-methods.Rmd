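---
title: "ripsplice: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ripsplice: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ripsplice` implements the post-alignment computational stages of an
RNA-binding-protein (RBP) target-discovery experiment: RIP-seq peak calling
with a permutation null, junction-based alternative-splicing (AS) event
classification and ratio testing, FPKM quantification with a threshold
differential-expression (DE) stage, actinomycin-D decay (half-life)
estimation, and the three-way intersection that nominates direct targets.
This vignette explains each model, the tunable parameters, the synthetic
world used for testing, and the choices made where the design was open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. Coordinates and containers

All internal coordinates are 0-based half-open (the BED convention); GTF
conversion at the file boundary is the single place where 1-based inclusive
coordinates are translated, tested in both directions. A splice junction is
keyed by its intron interval — (first intronic base, one past the last
intronic base) — which is alignment-tool independent. The `donor` and
`acceptor` columns of a junction table are the genomic left and right ends of
that interval regardless of strand; biological donor/acceptor roles are
resolved per gene strand during event classification.

## 2. RIP-seq peak calling

Coverage is per-base read depth over each gene. The scanner slides windows of
`window = 5` bp at `step = 5` bp. A candidate peak starts at the first window
of a run of `run_length = 8` consecutive windows whose mean depth exceeds
`start_fold = 2.5` times the baseline, or whose pooled per-base median depth
exceeds `median_start = 50`. It extends window by window and terminates when
the trailing eight-window segment's mean depth falls below
`stop_fraction = 0.04` of the running peak maximum; the terminating segment
is excluded from the peak and scanning resumes after it.

Open points resolved here:

* **Baseline.** Undefined in the published procedure; taken as the gene's
  mean per-base depth, floored at 0.5 to avoid zero-baseline blow-ups.
  A gene-local baseline matches the per-gene shuffle null.
* **Run scope.** The eight-window run requirement is applied to both start
  clauses (the 2.5x clause and the median clause); the source text is
  ambiguous about the second.
* **Significance.** Reads of a gene are repositioned uniformly within the
  gene (counts and read lengths preserved) `n_shuffles = 500` times; the
  maximum per-base depth of each shuffled profile is recorded and
  `p = (1 + #{shuffled max >= observed max}) / (1 + 500)`, which cannot
  return zero. Repositioning is within-gene because per-gene read counts
  define the null.
* **Retention.** `p < 0.05` OR maximum depth >= 10, exactly as published.
* **Enrichment.** Reads overlapping a peak are counted in IP and input,
  scaled to reads-per-million of their library, and the peak is enriched
  when the ratio reaches `enrich_fold = 4` (adjustable, as the source
  states). An input count of zero is floored at one library-normalized read
  so ratios stay bounded; such peaks carry an `input_floored` flag.
* **Replication.** Target genes need a retained, enriched peak overlapping
  (>= 1 bp) across **all** IP replicates (union rule behind a flag). The
  fourfold test itself is made once per peak against the **pooled** IP
  libraries: the source speaks of "IP read counts" singular, and requiring
  an independent fourfold pass in each replicate at realistic counts squares
  the count-noise failure probability and contradicts the recovery behavior
  the procedure is expected to have. Per-replicate enrichment is available
  (`enrich_ip = "per-rep"`).

### Interplay of termination and enrichment

Two structural facts shaped the default synthetic world. First, a planted
peak that adds `fold x background` reads has total IP coverage
`(1 + fold) x background`, so the 4%-of-maximum termination threshold is
`0.04 x (1 + fold)` of background depth — below background for folds up to
~20. Termination therefore only occurs where background coverage has a
near-empty 40 bp stretch, which requires sparse (~1x) coverage; at >= 2x
coverage called intervals bleed hundreds of bases and dilute measured
enrichment to `1 + fold x width / interval`, which crosses below the
fourfold threshold for fold 5. Second, the measured IP/input ratio has a
count-noise CV of roughly `sqrt(1/ip + 1/input)`, so a fold-5 peak must
carry enough reads (a wide binding region) for the fourfold margin to be
stable. The defaults below follow from this budget, not from fitting.

## 3. Alternative splicing from junction reads

Nine event types are classified from junction topology alone (intron
retention, the customary tenth type, needs exon-body coverage and is
deliberately out of scope): exon skipping (ES, >= 2 exons skipped),
cassetteExon (exactly one), A5SS/A3SS (junction pairs sharing one end whose
other ends shift within overlapping exons), MXE (two internal exons never on
one path, each with its own inclusion pair between common flanks), and
5pMXE/3pMXE (the mutually-exclusive pattern at alternative first/last
exons). The combined forms A3SS&ES / A5SS&ES are skipping junctions whose
distal end also shifts the acceptor/donor relative to the inclusion chain.
All rules operate in genomic coordinates and are renamed by strand. The
formal boundaries between cassetteExon and ES, and between 5pMXE/3pMXE and
MXE, are package decisions (the source does not define them).

Inclusion-set conventions: the exon-retaining chain for the skipping family;
the shorter-intron junction for alternative-site events; the path of the
transcript-5'-most variable exon for the mutually-exclusive family.

The splicing ratio of an event in a sample is
`sum(inclusion counts) / (sum(inclusion) + sum(exclusion))`, undefined at
zero depth. Ratios are computed per sample and compared between the two
groups with a two-sample t test — Welch by default, since variance equality
is untestable at n = 2-3 (a flag restores the pooled-variance Student's t) —
followed by Benjamini-Hochberg adjustment across all tested events, with
significance at FDR < 0.05. No minimum-count or effect-size filter is
applied by default (none is published); `min_junction_reads` is available.
The test is unpaired (pairing is unstated in the source).

## 4. Expression stages

FPKM is `counts x 10^9 / (library size x exon-union length)`. The DE stage
is a deliberately simple, clearly labeled stand-in for an NB-GLM engine
(reimplementing DESeq2/edgeR is out of scope; the substance is the published
thresholds): median-of-ratios size factors, log2 fold change of normalized
group means with pseudocount 1, a t test on log2(normalized counts + 1), BH
adjustment, and flags at padj < 0.05 and |log2FC| > 1.

The stand-in's t test defaults to **pooled variance**, a measured deviation
from an initial Welch design: at three replicates per group Welch's
Satterthwaite degrees of freedom collapse toward 2, which costs roughly a
third of the detection power at a planted 8-fold change (mu = 1000,
dispersion 0.05) and is why established count engines pool or shrink
variance rather than test per-gene unequal variances. Welch remains
available via `var_equal = FALSE`.

Relative qPCR quantification follows 2^-ddCt exactly:
`dCt = Ct_target - Ct_reference` per condition, `ddCt` the treated-control
difference, result `2^-ddCt`.

## 5. Decay kinetics

Half-lives are estimated by ordinary least squares of log abundance on time
(log-linear fit): with four time points (0/20/40/60 min) and multiplicative
noise, OLS on logs is the standard stable estimator, and the source states
only that half-lives were "calculated based on the decay curves". Each
replicate's series is first normalized to its own t = 0 value; the intercept
stays free to absorb normalization noise. `k = -slope`,
`half-life = ln 2 / k`; a non-negative slope reports "no decay detected"
rather than a negative half-life. Per-replicate fits are averaged by default
(`pooling = "pooled"` fits one regression). Condition comparisons report the
difference of half-lives with a bootstrap percentile interval over
replicates (1000 seeded draws) — the source reports no interval, so this is
a package addition.

## 6. Evidence integration

The three evidence sets are DEGs (flag != none), RASE genes (genes owning at
least one FDR-significant event — the published Venn intersects at gene
level), and peak target genes. All seven Venn regions are exact set algebra;
candidates are the triple intersection. Ranking of multiple candidates (peak
enrichment, then |delta ratio|, then |log2FC|) is a convenience addition,
labeled as such in run manifests, and irrelevant when the intersection is a
single gene as in the emulated study.

## 7. The synthetic world

The generator produces every input with known planted truth, recorded in a
manifest. Defaults (chosen once, with the reasoning of section 2):

* 30 genes of 4-8 kb on one toy chromosome; 50 bp single-end reads;
  background 20 reads/kb/sample (~1x coverage) — sparse enough for the
  4%-termination rule to close peak intervals promptly.
* 2 IP + 2 input replicates; three IP-only planted peaks at folds 10/5/20
  and widths 300/1000/150 bp. The weakest (fold-5) peak is the widest so its
  pooled read counts make the fourfold enrichment margin stable; RIP
  resolution is fragment-scale, so multi-hundred-bp binding regions are the
  realistic regime.
* 12 planted splicing-ratio shifts covering all nine event types (two on the
  minus strand), |delta psi| >= 0.3, mean junction depth 200, 3 replicates
  per group. The overlap gene's event is the strongest (psi 0.2 -> 0.8), as
  befits a directly bound, strongly regulated target.
* negative-binomial counts with dispersion 0.02 (cell-line-like), baseline
  means log-uniform on [100, 2000], planted DE genes at means of 800 and
  log2 fold changes {2.5, 2, -2, 1.5, -1.5}.
* decay series at t = 0/20/40/60 min with multiplicative lognormal noise
  (CV 5%) — qPCR ratios are positive and roughly log-normal — normalized per
  replicate to the noisy t = 0 draw; control and knockdown half-lives of
  60.31 and 47.82 minutes.
* exactly one gene (`g01`) planted in all three evidence channels.

What the generator does **not** emulate: sequence content and mappability,
fragment-length and positional bias, crosslink-site resolution, isoform-level
expression structure, overdispersion of junction counts beyond
Poisson-binomial, and batch effects. A green end-to-end test therefore
establishes the internal consistency of the pipeline's statistics and its
recovery of signal under its own generative assumptions — not performance on
real libraries.

## 8. Numerical choices and degenerate inputs

* Permutation p-values use the +1/(n+1) estimator; zero-read genes and
  zero-depth peaks get p = 1 by convention.
* Zero-variance t tests: equal means give t = 0, p = 1; unequal means with
  zero variance give p = 0 (infinite t), so constant-but-shifted ratios are
  flagged rather than dropped.
* BH adjustment enforces step-up monotonicity by cumulative minimum;
  a single p-value is returned unchanged.
* Events with fewer than two defined ratios in either group are skipped with
  an explicit status rather than silently dropped.
* Enrichment with empty input uses the one-read pseudo-floor and flags the
  peak; an empty IP library is an error.
* The generator refuses configurations whose gene length range cannot host
  the exon templates, peaks outside gene bounds, ratios outside [0, 1], and
  non-positive half-lives; `half_life = Inf` is the supported no-decay
  limit.

## 9. Known limitations

The DE stage is a threshold stand-in, not a dispersion-shrinking GLM; its
null behavior is calibrated (tested) but its power at low counts is below a
real engine's. Event classification assumes the annotation contains the
participating exon boundaries; fully novel exons are not assembled. The peak
caller operates per gene on unstranded depth by default (strand-split
calling via profiles is possible but not the default), and cross-gene read
reassignment in the permutation null is not implemented — the within-gene
null is the stated interpretation. Bootstrap intervals over three replicates
are coarse and should be read as order-of-magnitude uncertainty.
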