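---
title: "Methods: dual tag-seq and spectral-count differential abundance"
author: "tagProteo maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual tag-seq and spectral-count differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tagProteo` implements the computational core of a paired transcriptome /
proteome comparison of two conditions (here labelled *replete* and
*deficient*, after the phosphorus-stress design it targets) in which

* the transcriptome is profiled by **digital gene expression tag-seq**:
  each mRNA contributes one 21-bp sequence tag anchored at the most 3'
  NlaIII restriction site (`CATG`), and abundance is the tag count; the
  two libraries are **pooled biological material with no replication**;
* the proteome is profiled by **label-free spectral counting**: the number
  of MS/MS spectra matched to each protein is a relative abundance proxy.

The package covers everything downstream of base-called tags and
protein-level spectral counts: tag extraction and genome mapping, gene
assignment, normalization, differential expression, differential protein
abundance, and transcript-protein integration, plus a synthetic-data
generator that emulates the whole design so that every stage is testable
without external data.

# Tag extraction and mapping

## Tag model

A tag is `CATG` plus the next 17 nt downstream. The most 3' site of a
transcript defines its *canonical* tag; when fewer than 17 nt remain
downstream the tag is padded with `A`, modelling read-through into the
poly-A tail of an oligo-dT-captured transcript (vendors differ here, and
no public description settles it; padding is the choice that keeps every
site usable). `allExpectedTags()` ranks all sites from the 3' end, because
incomplete NlaIII digestion makes secondary-site tags an expected minority
signal: if each site is cleaved independently with probability $c$, the
site of rank $k$ from the 3' end emits with probability $c(1-c)^{k-1}$.

## Mapping rules

`buildTagIndex()` indexes, for every genomic `CATG` on either strand, the
21-mer read 5'→3' on that strand from the anchor (windows truncated by a
chromosome end are skipped). Mapping is exact (100% identity, no
mismatches); a tag with two or more genomic locations is discarded as
multi-mapped, and **strand-distinct hits count as distinct locations** —
the stricter of the two possible readings, chosen for reproducibility.

## Gene assignment

A uniquely mapped tag inside a gene model's span on the model's strand is
*sense* and pooled into that gene's count; on the opposite strand it is
*antisense* — tallied for reporting (antisense tags at NlaIII sites are a
known, frequent observation in this protocol) but never counted toward
genes. Tags in no model are *intergenic*, with the distance to the nearest
model 3' end recorded, because 3'-UTR read-through is the dominant
explanation for near-gene intergenic tags. `extendThreePrime()` therefore
extends models into the 3' UTR (default 200 bp); extension is **not**
clipped at neighbouring genes (the data give no guidance), and a tag
falling into two same-strand models is assigned to the model whose 3' end
is nearer — tag-seq signal is 3'-anchored, so proximity to a 3' end is the
right tie-break. An exact tie is excluded and tallied `ambiguous`. All
category read tallies partition the library total exactly; this
conservation is asserted at run time.

Because "the mapped percentage increases by X%" is ambiguous between
percentage points and relative change, `mappingSummary()` reports both.

# Differential expression without replicates

## Model

Counts for gene $g$ are modelled as independent Poisson draws,
$x_{1g} \sim \mathrm{Pois}(N_1\lambda_g)$ and
$x_{2g} \sim \mathrm{Pois}(N_2\lambda_g 2^{\delta_g})$, where $N_i$ are
the library totals and $\delta_g$ is the log2 fold change oriented
**condition 2 : condition 1** (deficient : replete). Conditioning on
$n_g = x_{1g}+x_{2g}$ eliminates the nuisance baseline $\lambda_g$
exactly:
$$x_{1g}\mid n_g \sim \mathrm{Binomial}\!\left(n_g,\;
  \frac{N_1}{N_1 + N_2\,2^{\delta_g}}\right).$$

With no replication, per-gene biological variance is not estimable; the
spread of real fold changes across genes plays that role instead, through
an empirical-Bayes prior with two components:

* a point mass at $\delta = 0$ with weight $\pi_0$ (non-differential
  genes), and
* a Normal$(0, \tau^2)$ slab, discretized on the grid
  $\delta \in [-10, 10]$ in steps of $h = 0.05$ log2 units.

$(\pi_0, \tau)$ are fitted by maximum marginal likelihood via EM
(`fitPrior()`): the E-step computes component responsibilities; the
M-step updates $\pi_0$ in closed form and $\tau$ by 1-D numerical
maximization of the expected complete-data log likelihood over the
discretized-normal weights (exact for the discretized model). Defaults:
deterministic initialization $\pi_0 = 0.9$, $\tau = 1$; relative
log-likelihood tolerance $10^{-6}$; 500 iterations, after which the best
iterate is returned with a warning and a `converged = FALSE` flag.

## Per-gene summaries

`posteriorDE()` reports, per gene,

* $\hat\delta$ — the posterior mean log2 fold change (automatically
  *shrunken* toward 0 for low counts);
* `se` — the posterior SD, the "shrunken standard error", floored at
  $h/\sqrt{12}$ (the quantization SD of one grid cell) so that $z =
  \hat\delta/\mathrm{se}$ is always defined;
* `lfdr` — the posterior probability of the null component (the *local*
  false discovery rate, a per-gene quantity, in contrast to tail-area
  FDR). Genes with `lfdr < 0.05` are called differential.

Genes with $x_1 = x_2 = 0$ carry no information: they return
$\hat\delta = 0$, `lfdr` $= \pi_0$, and a `no_data` flag. Display fold
changes (`log2fc_tpm`) use tags-per-million with +0.5 pseudocounts on the
raw counts; inference never uses pseudocounts. The grid half-width of 10
log2 units comfortably covers the ~10-unit dynamic range such data can
show (a few tpm to thousands of tpm).

The same machinery runs per gene (pooled sense counts) or per tag —
gene-level pooling merges tags from secondary NlaIII sites of the same
model, which is why gene-level call counts are smaller than tag-level
ones. Both modes are exposed because published analyses have used both
and the underlying statistic is identical; only the input table changes.

# Differential protein abundance

Proteins supported by fewer than 2 distinct tryptic peptides are removed
(`filterByPeptides()`); single-peptide identifications are too unreliable
to quantify. Spectral counts are normalized across samples by equal-total
scaling to the mean raw total (`normalizeSpectralCounts()`), the standard
spectral-counting convention; the widely used commercial implementation
does not publish its formula, and equal-total scaling matches its
technical-replicate behaviour. Significance is the **two-sided Fisher
exact test** on the raw integer counts against the library complements,
$[s_1, T_1-s_1; s_2, T_2-s_2]$ — the test needs true sampling counts, so
normalized values are display-only. No multiple-testing correction is
applied to the significance flag (the convention this analysis follows);
a Benjamini–Hochberg q column is emitted for information. Fold changes
use normalized counts with +0.5 pseudocounts, oriented
deficient : replete like the transcript axis.

# Transcript-protein integration

`joinResults()` inner-joins the two result tables on the shared
identifier space; `classifyCoordination()` tallies the deterministic
classes (`both_up`, `both_down`, `protein_only_up`, `protein_only_down`,
`transcript_only`, `opposing`, `neither`). `concordanceRegression()` fits
OLS of protein log2 fold on transcript log2 fold over proteins changing
at least 2-fold **on the protein axis** (the filter's natural axis, per
its usual phrasing), returning slope, intercept and $r^2$. A slope below
1 quantifies attenuation of the protein response relative to the
transcript response. The transcript axis defaults to the pseudocounted
tpm fold (mirroring how such comparisons are plotted); `useDelta = TRUE`
switches to the posterior mean.

Note on intercepts: with fixed-depth (tag) and fixed-run (spectral)
totals, both axes measure *proportions*. Any global imbalance between the
two conditions' true outputs is renormalized away and reappears as a
constant offset on the corresponding axis, which OLS absorbs into the
intercept. Fitted intercepts therefore combine the generative intercept
with these normalization offsets, while the slope is unaffected — only
the slope should be compared across data sets.

# The synthetic-data generator

`simConfig()` + `generateReference()` + `simulateTagLibraries()` +
`simulateSpectralCounts()` emulate the full design:

* i.i.d.-uniform background genome; genes placed with random intergenic
  spacers on both strands; every transcript carries at least one CATG
  with the full 17 nt downstream of its 3'-most anchor (so canonical tags
  exist and are unpadded — padded tags are still exercised through the
  tag-extraction API directly);
* optional introns (rate `intronRate`) whose junction splits the 3'-most
  CATG 21-mer, reproducing the class of transcript tags that cannot map
  to the genome across a splice junction;
* `enforceUniqueTags` regenerates genes whose canonical 21-mer occurs
  more than once in the genome on either strand;
* per-molecule digestion: each site cleaved independently with
  probability $c$ (default 0.8), tags emitted from the 3'-most cut site,
  so rank-$k$ sites emit at rate $c(1-c)^{k-1}$; molecules with no cut
  are undigested and emit nothing;
* antisense emission: with probability $a$ (default 0.1) the tag is the
  opposite-strand 21-mer at the same site (sites closer than 17 nt to the
  transcript 5' end always emit sense — the opposite-strand window does
  not exist there);
* counts drawn multinomially conditioned on the exact library totals
  (fixed-depth sequencing), defaults 12 million per library at the full
  design scale of ~11,000 genes; desk-scale analyses pass smaller values
  explicitly;
* sequencing error: each of the 17 variable bases substituted
  independently with probability $e$ (default 0.005, an ordinary
  short-read substitution rate). The `CATG` anchor is protocol-defined —
  reads without it are never tabulated as tags — so errors are modelled
  on the variable bases and library totals stay exact;
* the proteome: only the top `detectTopFrac` of genes by abundance are
  detected (LC-MS sees abundant proteins; the default 0.11 reproduces the
  ~11% detection fraction typical of a deep single-run survey); protein
  log2 fold change is `slope * delta + intercept * 1{delta != 0} +
  Normal(0, noiseSd)` with defaults slope 0.49, intercept −0.25, noise
  0.3 — an attenuated, noisy echo of the transcript response; spectral
  counts are Poisson; a configurable fraction of proteins get exactly one
  peptide to exercise the support filter.

Digestion efficiency and the antisense rate are not measurable from
published summaries; the defaults (0.8, 0.1) are stated as plausible
round numbers and are fully configurable.

Each stage seeds its own RNG stream from `(seed, stage name)`, so stages
are independently reproducible and the whole pipeline is byte-identical
under a fixed seed.

## What the generator does *not* emulate

No quality scores, PCR duplicates, GC bias, SNPs, alternative
transcripts, or replicate libraries (the design under study is
replicate-free by construction). Passing tests therefore demonstrate
correctness of the algorithms under the stated sampling model, not
robustness to every artefact of real libraries.

## Compositional effects, and the balanced design used in tests

Because both platforms measure proportions, planting strong asymmetric
fold changes shifts *every* null gene's proportion by the same constant
(log2 of the total-output ratio). This is faithful to real fixed-depth
data, but it means a recovery test with a strongly unbalanced truth
measures the renormalization constant, not the estimator. The
integration-recovery checks therefore use a *compositionally balanced*
truth: each up-regulated gene is paired with a down-regulated partner
carrying the mirrored abundance load, so the total transcript output is
condition-invariant (biologically: abundant growth-machinery transcripts
fall while scarce stress transcripts rise). The concordance checks plant
|log2 fold changes| of 4–5: the 2-fold protein-axis filter truncates the
noise distribution of proteins whose planted response sits near the
cutoff, which would bias an OLS recovery check for reasons unrelated to
the estimator, so the planted responses are kept ~2 SD beyond the cutoff.

# Problem sizes used by the tests

The test-suite simulations use 2,000 genes and 1-million-tag libraries
for the statistical checks (false-call control over 10 seeds, sensitivity
of planted 4-fold changes, concordance recovery), 60–150 genes with
30k–200k-tag libraries for mechanical checks, and 20 random ≤100 kb
genomes for mapping-oracle equivalence — sizes at which every check's
Monte-Carlo error is far below its tolerance while the suite stays quick
on a single core. The acceptance script re-runs the same computations at
the 2,000-gene scale.

# Known limitations

* The empirical-Bayes fold-change model is a zero-centred unimodal prior;
  data whose true fold-change distribution is strongly multimodal or
  asymmetric will fit $\tau$ conservatively.
* Per-gene lfdr calibration inherits the Poisson sampling assumption;
  overdispersion beyond it (e.g. residual biological variation between
  pooled cultures) is absorbed into $\tau$ globally rather than modelled
  per gene — the price of a replicate-free design.
* Mapping is exact-match by design; SNPs and splice junctions produce
  unmapped tags (reported, never rescued).
* The Fisher test on spectral counts ignores peptide-level correlation
  within a protein; with very deep spectral totals it can be
  anti-conservative for large proteins.
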