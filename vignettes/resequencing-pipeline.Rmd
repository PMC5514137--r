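---
title: "Comparing resequenced crop genotypes: variants, relatedness, PAVs and resistance-gene analogs"
author: "ReseqScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing resequenced crop genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReseqScan)
```

## The problem

A whole-genome resequencing panel maps short reads from several
genotypes of a crop species (and of a close relative) against a single
reference assembly. Downstream of calling, a series of bespoke
computations turns the calls into biology: per-genotype SNP/indel counts
and rates, genome-wide zygosity scans that expose regions driven to
homozygosity by breeding, genotype relatedness, genes present in one
genotype but missing in another (presence/absence variants, PAVs),
candidate disease-resistance loci (resistance gene analogs, RGAs), and
the predicted functional impact of coding variants on metabolic pathway
genes. `ReseqScan` implements that post-calling pipeline as reusable,
tested functions, together with a synthetic-data generator so that every
stage can be exercised — and its statistical behaviour verified — without
any sequencing data.

## The model and its stages

### Variant filtering and rate summaries

Input calls carry a phred-like call quality and a read depth. A record
is retained iff quality $\ge 20$ and depth $\in [8, 450]$, all bounds
inclusive: the convention "quality lower than 20 is removed" keeps 20,
and the depth limits are read as an inclusive window. Filtering is
idempotent and order-preserving.

For a genotype with $S$ SNPs, $I$ indels and reference length $L$, the
summary rows are

$$\mathrm{rate} = 100\,\frac{S+I}{L}\,\%,\qquad
  \mathrm{per\ kb} = 1000\,\frac{S}{L},\qquad
  \text{one SNP every } \frac{L}{S}\ \mathrm{bp},$$

with the analogous indel and combined rows. Exact values are kept
internally; presentation rounding (2 decimals for rates, 1 decimal for
spacings under 1000 bp, integers above) is a separate formatting step.
$L$ is explicit configuration (default 724,700,000 bp, the scaffold
length of the reference assembly) because the choice of denominator is
the single largest source of disagreement when reproducing published
rate tables: with this $L$ every per-genotype row of the published
panel reproduces except the reference genotype's "1 SNP every" cell
(927.6 printed, 927.3 computed), which evidently used a slightly
different denominator. We document this rather than chase it.

### Window tracks and homozygous-fixed regions

Chromosomes are tiled into 1-Mb windows (configurable), 1-based
inclusive, window $k$ covering $[(k-1)w+1,\,kw]$ — a variant at
position $w$ exactly belongs to window 1 — and the last window
truncated. Each variant falls in exactly one window, so window counts
always sum to the input count; that conservation law is asserted
throughout the tests. Tracks serialize as bedGraph (0-based half-open)
only at the I/O boundary; internally everything stays 1-based
inclusive, matching GFF3 and VCF, which minimizes off-by-one surface.

A homozygous-fixed region is a maximal run of consecutive windows with
heterozygous-SNP density at most 10/Mb and homozygous-SNP density at
least 100/Mb. The thresholds are configuration defaults chosen so that
in a genotype with a few heterozygous SNPs per kb a window qualifies
essentially only when heterozygosity collapses — the published analysis
reports such regions qualitatively but states no numeric rule. Runs
merge across adjacent qualifying windows and never across a
non-qualifying window or a chromosome boundary. Each region is
annotated with its gene count, since fixation in gene-dense regions is
the expected footprint of selection during domestication.

### Relatedness

The site universe is the union of called sites across genotypes
(optionally intersected with CDS intervals for the coding subset). Each
genotype's dosage at a site is the number of ALT copies: 2 (homozygous),
1 (heterozygous) or 0 — a genotype with no record at a site called in
another genotype is reference-homozygous, which is how single-reference
resequencing VCFs are produced. The distance is the allele-sharing
$1-\mathrm{IBS}$ form

$$d(a,b) = \frac{1}{m}\sum_{s=1}^{m} \frac{|x_{as}-x_{bs}|}{2} \in [0,1].$$

The original analysis delegated the distance to a package without
printing a formula; we fix this standard definition and expose
`snpsOnly` because whether indels entered the published computation is
not stated (we include them by default). UPGMA is implemented directly:
each merge sits at half the merged pair distance, distances to the new
cluster are size-weighted averages, and ties break on the
lexicographically smallest label pair so output is deterministic. The
result is ultrametric by construction, asserted numerically at 1e-9,
and checked against an independent implementation (`phangorn`) on
random matrices.

### PAV calling

Per-gene mapped-read counts are normalized by each genotype's
genome-wide mapped total, rescaled to the mean library so the
thresholds stay on a read-count scale:
$\tilde c_{gi} = c_{gi}\,\bar N / N_i$. A gene is a putative PAV gene
iff some genotype has $\tilde c < 6$ (absent) while another has
$\tilde c > 29$ (confidently present). Counts between the thresholds
count as present but cannot themselves qualify a gene. Whether the
published thresholds were applied before or after normalization is
ambiguous in the source description; we normalize first, and the mean
rescaling keeps the two choices numerically close when libraries are
balanced. Because a gene absent in *every* resequenced genotype can
only satisfy the selection rule if the reference genotype's own counts
sit in the table, the caller accepts a reference column (present by
construction) which participates in selection but is excluded from
absence categorization.

### RGA classification

Candidate proteins passing an upstream homology screen (E < 1e-60,
consumed as a boolean — we do not run BLAST) carry Pfam domain hits.
Hits at E ≤ 1e-10 map to eight categories (NB-ARC, TIR, LRR — nine
accessions collapsed to one, Pkinase, ABC_tran, WD40, plus coiled-coil
and transmembrane flags from upstream predictors). The domain *set*
(copy numbers ignored) is looked up in a verbatim 25-row decision
table (NL, CNL, TNL, RLK, RLP, …). The published generated acronyms
are letter-order-inconsistent among themselves, so the 25 printed
combinations are hard-coded verbatim and only unlisted sets go through
the generation rule: `other-` plus one letter per domain in the fixed
order L, N, T, K, A, TM, C. WD40 appears in the screened set but in no
printed acronym; WD40-containing unlisted sets append `W` last.
Chromosomal clusters of a family group (NB, RLK, RLP, other-KTM, …)
are windows of 1 Mb holding at least 4 group members (the cluster size
is configuration; the source reports clusters but no numeric rule),
merged across adjacent qualifying windows.

### Effect annotation

Regions are assigned with precedence CDS > UTR > splice site > intron >
intergenic; splice sites are the first and last 2 bp of each intron
(canonical donor/acceptor). A coding SNP is classified by rebuilding
its codon on the coding strand and translating with the standard code:
synonymous, missense, nonsense, stop-lost or start-lost; indels are
frameshift when the length change is not a multiple of 3, else
in-frame. Impact tiers follow the four-class scheme: high for
splice/stop/start-modifying variants, moderate for amino-acid changes,
low for synonymous, modifier for everything non-coding (UTRs included:
the published modifier fraction of ≈98% folds all non-CDS, non-splice
positions together). Frameshifts are counted as high although the
published wording lists only splice/stop/start events — the upstream
annotation tool's convention includes them, and we follow it. One
annotation per variant: the most severe across overlapping
transcripts. Deleteriousness aggregation over pathway gene sets counts
a non-synonymous variant as deleterious at score ≤ −2.5, boundary
inclusive.

## The synthetic-data generator

`simulateStudy()` emulates the statistical structure of the study's
data, not its sequences: per-genotype variant sets at a 2% default rate
with a 12:1 SNP:indel ratio and ~60% heterozygous calls; planted
homozygous-fixed blocks in which every emitted call is homozygous;
per-gene read counts Poisson(100 × library factor) against
Poisson(0.5) for planted absent genes (a ~10σ separation, which is why
perfect PAV recovery is the expected outcome rather than a tuned one);
domain architectures drawn from the published combination table; and
QUAL/depth values of which a configurable 10% violate the filter
bounds, so the filter has something to remove. Indels are 1–10 bp,
uniform — no indel length spectrum is published, and short indels
suffice to exercise frameshift logic. Each stage draws from its own
seeded RNG stream (seed + stage offset) so regenerating one output
does not shift the others.

What the generator does *not* emulate: real linkage structure, mapping
bias, repeat-induced coverage artefacts, error-model noise or
multi-allelic complexity beyond per-ALT splitting. Passing tests
therefore demonstrate the correctness of the computations under the
stated statistical model, not robustness to artefacts of real
alignments.

## Numerical and design choices

* Coordinates: 1-based inclusive internally; conversion to 0-based
  half-open happens only in bedGraph I/O, tested by byte-identical
  write–read–write round trips.
* Multi-allelic VCF rows split into one record per ALT before
  filtering, since downstream counts are per variant class. How the
  published counts treated multi-allelic sites is not stated.
* Zero counts produce `NA` spacing sentinels ("one SNP every —"), never
  infinities.
* Chromosome name matching is exact and case-sensitive to avoid silent
  mis-joins.
* Conflicting REF alleles at one position across genotypes are an
  error, but a SNP and a spanning deletion at the same position are
  legitimate (prefix-compatibility check).
* Tests and the acceptance script run the simulator at two 500-kb
  chromosomes, 40 genes and three genotypes at a 1% rate — small
  enough to iterate on, large enough that every stage (including ~10k
  variants per genotype) is exercised; rate-recovery checks use a 1-Mb
  chromosome at 1% (10,000 ± 300 expected variants, a Poisson 3σ
  band).

## Worked example

```{r example}
spec <- simulationSpec(rngSeed = 11, nChromosomes = 2,
                       chromosomeLength = 2e5, nGenes = 20,
                       nGenotypes = 3, variantRate = 0.01)
ref <- simulateReference(spec)
vars <- simulateVariants(ref, spec)
vs <- filterVariants(vars$variantSets$G1)
formatRateSummary(summarizeRates(vs))[, c("S", "I", "T", "snp_rate_pct",
                                          "one_snp_every")]
```

```{r relate}
sets <- lapply(vars$variantSets, filterVariants)
tree <- upgma(ibsDistance(buildGenotypeMatrix(sets, ref$models)))
dendroDepths(tree)
```

## Known limitations

* The pipeline starts at called variants and count tables; read
  mapping, pileup, assembly and gene prediction are out of scope.
* The IBS/UPGMA module targets small panels (tens of genotypes); the
  pairwise loops are not written for thousands of samples.
* Provean-style scores and the BLAST homology screen are consumed, not
  computed.
* The published "1 SNP every" cell of the reference genotype does not
  reproduce with the configured denominator (see above); no attempt is
  made to force it.
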