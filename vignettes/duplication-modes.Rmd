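---
title: "Classifying gene duplication modes and measuring duplicate-gene divergence"
author: "dupModes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene duplication modes and measuring duplicate-gene divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupModes)
```

# The problem

Plant genomes retain duplicate genes created by very different mechanisms:
whole-genome duplication (WGD, polyploidy), tandem and proximal small-scale
duplication, RNA-based retrotransposition, DNA-based transposition, and
duplications whose mechanism is no longer recognisable ("dispersed"). The
mechanism of duplication leaves structural fingerprints — synteny for WGD,
gene-order adjacency for tandem arrays, intron loss for retrogenes — and
it also shapes the subsequent fate of the copies: how fast their expression
patterns, coding sequences and promoters diverge. `dupModes` implements a
complete, tested pipeline for this comparative analysis: a mode classifier,
within- and cross-species expression-divergence statistics, Ka/Ks and
Jukes–Cantor sequence divergence, promoter methylation and enrichment
analyses, and the regression/power machinery used to relate mode and age to
divergence. A synthetic-corpus generator with planted ground truth
validates every stage.

# The classifier

The candidate population of duplicate pairs is built from all-vs-all
protein homology hits: for each query, its top `top_n_hits` (default 5)
non-self matches with e-value at or below `evalue_max` contribute
unordered pairs, so a gene can hold up to five duplication relationships;
genes with no qualifying hit in either direction are singletons. The
default `evalue_max = 1e-10` is the conventional stringency in the
duplicate-gene literature; it is a config parameter because published
studies differ, and the pipeline's behaviour is insensitive to it on the
synthetic corpora (planted hits are far below any sensible threshold,
decoys far above).

Pairs are then labelled by a fixed decision order:

1. **WGD** — the pair appears in the supplied syntenic anchor list.
   Anchors are authoritative: an anchor pair missing from the candidate
   population is kept (and logged), and no additional collinearity
   pruning is applied beyond the supplied list.
2. **Tandem** — same chromosome, adjacent in gene order (rank distance 1).
   Ranks are positions in the start-coordinate order over *all* annotated
   genes of the chromosome, not just analysed genes; ties on start are
   broken by (start, end, gene id).
3. **Proximal** — same chromosome, rank distance 2 to `proximal_window`
   (default 20), boundary inclusive, i.e. at most 19 intervening genes.
4. **Transposed** — exactly one copy sits at an ancestral locus
   (supported by presence in a syntenic block with a paralog or
   ortholog); that copy is the parental one. If the parent has
   `retro_min_parent_exons` (default 3, a literal reading of "more than
   two") or more exons and the copy is intronless, the pair is
   **retrotransposed**; if both copies are single-exon the pair is
   **unclassified** (an intronless parent cannot be distinguished from a
   retro copy); anything else is **DNA-based transposed**. Pairs with
   zero or two ancestral members fall through.
5. **Dispersed** — everything left.

Each duplicated gene finally receives a unique origin, the
highest-priority mode among its pairs
(WGD > tandem > proximal > retrotransposed > DNA-transposed > dispersed).
Genes present in hits but absent from the annotation are dropped with a
warning rather than guessed at.

# Expression divergence within a species

Similarity of two expression profiles is the Pearson correlation $r$
across all samples; replicate chips are kept as separate observations and
never averaged. Expression divergence is defined as $d = 1 - r$, so
$d \in [0, 2]$ with 0 for identical and 2 for anti-correlated profiles.
The transform is exposed as a pluggable function; $d = 1 - r$ (rather
than, say, $(1-r)/2$) is the convention consistent with divergence
thresholds stated directly on the $r$ scale. Spearman correlation is
available as a robustness flag.

The "diverged expression" criterion is calibrated on the data themselves:
`randomPairThreshold()` samples (by default) 10,000 distinct random gene
pairs and returns the 95% quantile of their $r$ values; a duplicate pair
is called diverged when its $r$ falls below that threshold. For
independent Gaussian profiles over $n$ samples the null $r$ is
approximately $N(0, 1/(n-1))$, so the threshold should approach
$1.645/\sqrt{n-1}$ — a closed form the tests check by simulation.
Random pairs are drawn uniformly over unordered non-self pairs; pairs
that happen to be true duplicates are not excluded (their density is
negligible at genome scale).

Dual conservation (the genetic-redundancy proxy) calls a pair conserved
when its Ka lies below the 25% quartile of Ka over all valid pairs and
its $d$ lies below a configurable threshold (default: one minus the null
$r$ threshold). The per-mode observed proportions are compared with the
independence expectation — the product of the pooled marginal
proportions.

# Expression conservation across species

Cross-platform expression values are not directly comparable, so
conservation of orthologs across two species is measured on co-expression
patterns instead. With $k$ ortholog pairs indexed identically in the two
expression matrices, each species is converted to its $k \times k$
correlation matrix; the expression conservation of ortholog pair $i$ is
the Pearson correlation of row $i$ of the two matrices, and its
divergence is $1 - \mathrm{EC}$. The self entry (always 1 in both
matrices) is excluded by default because including it mechanically
inflates the correlation; `include_self = TRUE` is provided for
sensitivity analysis, and with $k$ in the hundreds the two choices are
nearly indistinguishable. Orthologs are consumed as a pair list; one gene
mapping into several ortholog pairs simply occupies several rows.
Ortholog pairs are classed S-S, S-D or D-D by whether each member is a
singleton or a duplicate in its own genome, and class contrasts use
two-sample t-tests on $d$.

# Sequence divergence

**Ka/Ks.** Coding divergence uses the Nei–Gojobori (1986) unweighted
pathway method on a frame-preserved codon alignment obtained by
back-translating a protein alignment (protein gaps become codon gaps).
Synonymous site counts per codon are the summed fractions of
single-nucleotide changes that preserve the amino acid; totals are
averaged over the two sequences. Codon pairs differing at two or three
positions are averaged over all substitution orderings; orderings that
pass through a stop codon are discarded, and a codon pair whose orderings
all hit stops is skipped entirely. Codon pairs containing a gap, an
ambiguous base, or a stop in either sequence are likewise skipped and
counted. Proportions $p_S = S_d/S$ and $p_N = N_d/N$ are corrected with
the Jukes–Cantor transform $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$;
$p \ge 3/4$ (or no countable sites) yields an invalid flag (`NA`), and
such pairs are meant to be excluded from downstream analyses, mirroring
how uncorrectable alignments are dropped in practice. No cap is applied
during computation; truncating displays at 2.0 is a presentation choice.

**Noncoding divergence.** Promoter and UTR divergence is the
Jukes–Cantor rate $\mu$ on the mismatch proportion over ungapped
alignment columns, with the same domain rule ($p = 0$ is a valid
$\mu = 0$; $p \ge 3/4$ invalid).

**Promoters.** The promoter of a gene is up to 1,000 bp upstream of the
TSS — the annotated start on the + strand, the annotated end on the −
strand (a minimal GFF3 has no UTR-aware TSS) — truncated at the nearest
annotated gene boundary upstream, clipped at chromosome ends, and
reverse-complemented for − strand genes; it can be empty when a
neighbour abuts the TSS. A promoter pair is called duplicated
(non-disrupted) when global-alignment identity strictly exceeds 45%,
with identity defined as matches over all alignment columns, gaps
included. The built-in aligner is plain Needleman–Wunsch plumbing
(match 1, mismatch 0, gap −1, via Biostrings); pre-aligned input is
accepted.

# Methylation and enrichment

A gene is methylated in its promoter when two probes that are consecutive
in the chromosome's probe track both lie inside the promoter region and
are both methylated. "Adjacent" means consecutive in the track with no
distance cap (array probe spacing is roughly uniform, so a cap would add
a parameter without information); genes with fewer than two in-region
probes are callable and unmethylated, not missing. Per mode, the pipeline
reports the fraction of pairs whose two calls differ; per class
(singleton/duplicate), the fraction methylated.

Term enrichment (GO, Pfam, families) uses the one-sided Fisher exact test
for over-representation, Bonferroni-corrected over the number of terms
actually tested (terms absent from the universe are skipped; correcting
over all annotated terms is available by passing them in). The universe
is the set of genes with an origin assignment, matching how duplicate
populations are analysed. Family/mode enrichment considers only families
with at least 10 genes ("more than nine") and corrects over all
(family × mode) tests.

# Statistical machinery

* `regressDivergence()` fits $d = a + b_1 Ks$, $d = a + b_2 W$ and
  $d = a + b_1 Ks + b_2 W$ by OLS, where $W$ codes polyploidy events by
  recency (most recent = 1). AIC uses the full Gaussian log-likelihood
  with the error variance counted as a parameter — the `stats::AIC`
  convention, $n\ln(2\pi \mathrm{RSS}/n) + n + 2(k+2)$ — so absolute
  values are convention-dependent but model orderings are not.
* `anovaTukey()` is one-way ANOVA plus Tukey HSD via the studentized
  range; with two groups it reduces exactly to the pooled t-test
  ($F = t^2$).
* `splineTrend()` fits a cubic smoothing spline whose penalty is chosen
  so the trace of the smoother matrix equals the requested degrees of
  freedom (default 10), the `smooth.spline` convention; a spline with
  effective df at the null-space boundary reproduces straight lines.
* `correlationPower()` computes two-sided power for a correlation test
  from the Fisher z approximation with the standard small-sample mean
  correction $E\,z(\hat r) = z(r) + r/(2(n-1))$. At $r = 0$ it returns
  exactly $\alpha$; at $n = 30, r = 0.5$ it agrees with 20,000-replicate
  Monte-Carlo power within 0.01 (without the mean correction the
  approximation visibly under-predicts at small $n$, which is why the
  correction is included).

# The synthetic corpus

`simulateGenome()` and its companions generate everything the pipeline
consumes, with known ground truth. The default corpus — 2 chromosomes ×
500 genes, 50 planted events per mode, 200 expression samples — is the
standard validation condition used throughout the tests and the
acceptance script; it runs end to end in well under a minute.

Design choices worth knowing:

* **Non-interference by default.** Each gene takes part in exactly one
  planted event, so per-mode precision and recall of the classifier are
  exactly 1.0 by construction when the classifier is correct. An
  `interference` flag additionally plants tandem copies of WGD genes to
  exercise the origin priority rule.
* **Structure per mode.** WGD pairs are emitted as collinear anchor
  blocks of 10 spanning chromosome pairs; tandem copies sit at adjacent
  ranks; proximal copies at rank distance uniform in [2, 20]; retro and
  DNA-transposed parents carry cross-species ortholog anchors (which is
  what makes them ancestral without adding paralog anchor pairs), with
  exon counts 3–6 for parents, 1 for retro copies, 2–5 for DNA copies;
  dispersed pairs connect non-ancestral loci on different chromosomes.
* **Expression targets.** Pair profiles are built as
  $y = r z + \sqrt{1-r^2}\,\varepsilon$ with shared latent $z$, so the
  population correlation equals the target exactly. Default per-mode
  targets (WGD/tandem 0.45, proximal 0.30, DNA 0.10, dispersed 0.10,
  retro 0.08) reproduce the qualitative ordering seen in real duplicate
  populations — strongest co-expression for WGD/tandem, weakest for
  transposed copies — at a scale where null thresholds still separate
  classes.
* **Sequence targets.** Synonymous changes are applied only at third
  positions of 4-fold degenerate codons (so a synonymous-only corpus has
  Ka = 0 exactly) and nonsynonymous changes at first/second positions of
  disjoint codons; promoter divergence is per-site Bernoulli
  substitution. Targets are drawn per pair from configurable ranges
  (Ks in [0.1, 1.5], Ka in [0.02, 0.5], promoter p in [0.02, 0.4]),
  spanning the low-to-moderate divergence regime where the estimators
  are well behaved.
* **Two-species corpus.** Species 1 follows a 4-factor latent model with
  residual noise so co-expression has real structure; species 2 ortholog
  profiles are species 1 profiles plus class-dependent perturbation
  (σ = 0.1/0.3/0.6 for S-S/S-D/D-D), so true mean divergence is ordered
  S-S < S-D < D-D and zero perturbation gives EC = 1 identically.

What the generator deliberately does **not** emulate: microarray
normalisation artefacts, batch and platform effects, probe-set to gene
mapping ambiguity, indels and rate heterogeneity in sequence evolution,
transposon sequence context, and realistic gene-length or intergenic
distributions. Passing the recovery tests therefore shows that the
*algorithms* are correct under their stated models, not that the
upstream measurement problems of real corpora are solved; genome-scale
results from real annotation/array corpora are inputs this package
consumes, not outputs it promises to reproduce.

# Degenerate inputs and numerical corner cases

* Constant expression profiles have undefined correlation: an error at
  the single-pair level, exclusion with a warning at the batch level.
* Empty promoters are excluded from identity and methylation analyses
  (`promoterDuplicated` refuses them; the region object reports width 0).
* `randomPairThreshold` falls back to all pairs, with a warning, when
  asked for more pairs than exist.
* Identity exactly at 45% is *not* duplicated (strict inequality), and
  $p$ exactly 3/4 is invalid for the Jukes–Cantor transform.
* All stochastic components take explicit seeds and are bit-reproducible.

# Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1)
sim <- simulateGenome(cfg)
res <- classifyAll(sim$annotation, sim$hits, sim$anchors)
table(res$pairs$mode)

m <- simulateExpression(geneIds(sim$annotation), sim$truth$pairs, cfg)
st <- pairExpressionStats(sim$truth$pairs, m)
thr <- randomPairThreshold(m, 10000, 0.95, seed = 2)$threshold
divergenceProportion(st, thr)
```

The README shows this example with the numbers it prints.

# Known limitations

* The classifier trusts the supplied anchor list entirely; errors in
  synteny calls propagate directly into WGD labels and the ancestral set.
* The EC statistic depends on the shared ortholog index: biased ortholog
  sampling biases every row's co-expression vector.
* Nei–Gojobori counting has no transition/transversion or codon-usage
  bias correction; for saturated pairs the invalid-flag, not a number,
  is the output.
* Promoter extraction uses annotated gene ends as TSS proxies; with
  UTR-less annotations the "promoter" may overlap true 5′UTR.
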