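---
title: "Mapping and comparing SOLiD color-space tag libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and comparing SOLiD color-space tag libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solidtags)
```

## The problem

SOLiD sequencers read DNA as *colors*: each of the four colors encodes a
di-base transition, so a 35-nt tag is recorded as an anchor (primer) base
followed by 35 color calls. Decoding is a running XOR from the anchor, which
means a single miscalled color corrupts every decoded base downstream of it.
The classical remedy is never to decode the reads: the reference is
translated to color space instead, and alignment happens there, where one
sequencing error costs exactly one mismatch.

`solidtags` implements a complete desk-scale version of the analysis used in
two-library tumor-versus-normal transcriptome comparisons on this platform:

1. quality filtering and ribosomal-RNA removal,
2. complete (all-placements) color-space alignment against the genome and an
   exon-junction database, with a trim-and-remap cascade (35 colors at up to
   3 mismatches, then 30 and 25 colors at up to 2),
3. feature assignment of uniquely mapped tags (exon / intron / antisense /
   intergenic), expressed-gene calls and RPKM,
4. an exact conditional binomial test for differential expression under the
   random-sampling model, with p < 0.01 and fold change > 2 calling gates,
5. chromosome coverage and category reports.

Because the original raw libraries of such studies are rarely available, the
package ships a first-class synthetic-data generator that emits two stranded
tag libraries with complete ground truth, so that every stage of the
pipeline can be validated end to end.

## Color space

The di-base code maps a base pair $(x, y)$ to a color
$c(x,y) = \mathrm{code}(x) \oplus \mathrm{code}(y)$ with A, C, G, T coded as
0, 1, 2, 3; this reproduces the standard SOLiD table
({AA,CC,GG,TT} $\to$ 0, {AC,CA,GT,TG} $\to$ 1, {AG,GA,CT,TC} $\to$ 2,
{AT,TA,CG,GC} $\to$ 3). Three algebraic facts carry the whole design:

* the table is symmetric with zero diagonal, so encoding is invertible given
  the previous base;
* complementing both bases leaves the color unchanged, hence the color
  string of a reverse complement is the *reversed* color string — the
  mapper searches the minus strand by reversing the read's colors instead of
  re-encoding the reference;
* a single base substitution changes exactly two adjacent colors (one at the
  3' end), while a single color error changes every decoded base downstream
  — the reason alignment stays in color space.

```{r}
encode_colors("ACGT", anchor = "T")
decode_colors("T", "3131")
```

A missing call `.` is never decoded and counts as a mismatch against
anything, including another `.` — the conservative reading.

### The first-color convention

The first color of a read depends on the anchor base, not on the genome;
the first color of a reference sequence likewise depends on an assumed
preceding base (fixed to `T`). The aligner therefore compares *internal*
colors only: a read's colors 2..L are matched against the reference color
string at offsets $\ge 1$. A placement at 0-based base $p$ uses reference
color offsets $p+1 \dots p+L-1$. One informative color is given up; in
exchange, every comparison is anchor-free and exact.

## The exon-junction database

Mature tags that span a splice junction cannot align contiguously to the
genome. For every multi-exon gene the package concatenates the last
$\min(J, \text{exon length})$ bases of an upstream exon with the first
$\min(J, \text{exon length})$ bases of a downstream exon, on the gene's
strand. The flank length defaults to $J = 34$, one less than the tag
length — the smallest flank such that any junction-spanning 35-nt tag fits
entirely inside the junction sequence.

Pairing is combinatorial by default (`mode = "all_pairs"`: every ordered
exon pair within a gene, $n(n-1)/2$ junctions for $n$ exons), which captures
exon-skipping isoforms; `mode = "adjacent"` restricts to consecutive pairs.
The combinatorial reading was chosen because the junction set exists
precisely to catch alternative exon usage; both are one flag apart and the
records table stores the provenance either way. Pairing across genes is not
done. Duplicate junction sequences are deduplicated, keeping the first
record.

Junction hits are lifted back to genomic coordinates. Only hits covering at
least one base on each side of the breakpoint are kept; a hit confined to
one flank is a substring of the genome and is already found by the genomic
alignment — keeping it would double-count locations and wrongly demote
reads to "multiple".

## The mapping cascade

Reads with mean quality value below 8 are discarded first ("below" is
strict: a mean of exactly 8 survives). Remaining reads aligning anywhere on
the rRNA set within 3 mismatches (the stage-1 allowance; the choice is
configurable) are set aside. The cascade then runs:

| stage | colors compared | max mismatches |
|-------|-----------------|----------------|
| 1     | 35 (34 internal) | 3 |
| 2     | 30 (trimmed 5 from the 3' end) | 2 |
| 3     | 25 | 2 |

Trimming is from the 3' end, where SOLiD quality degrades. The 25-color
allowance of 2 is chosen by analogy with the 30-color stage. A read stops at
the first stage producing at least one hit.

The search is *complete*: every placement on either strand with at most $M$
color mismatches is found. The pattern of $L-1$ internal colors is
partitioned into $M+1$ contiguous blocks; if a window has $\le M$
mismatches, at least one block matches it exactly (pigeonhole), so looking
up the first 8 colors of every block in a k-mer index of the reference and
verifying each candidate window finds all hits. Block lengths of at least 8
hold for all three default stages; shorter configurations fall back to a
full scan. The property suite asserts equality with a brute-force scan at
every stage.

A read is **unique** when, after junction liftover and deduplication of
identical genomic locations, exactly one location attains the minimal
mismatch count; worse-scoring locations do not demote it. Ties make it
**multiple**. The annotation rate reported in the mapping summary divides
annotated (unique + multiple) by the high-quality read count.

## Quantification

Only unique reads are used. Assignment is strand-aware, in priority order,
with any one-base overlap sufficing: exon of exactly one gene (junction
blocks count as exonic) → exon tag; gene body on the same strand → intron
tag (pre-mRNA); gene body on the opposite strand → antisense tag; nothing →
intergenic. A tag touching exons (or bodies) of more than one gene on the
relevant strand is *ambiguous* and excluded from counts but retained in the
class totals, so the five classes always partition the unique reads.
Majority-overlap rules were rejected as harder to reason about and to test;
one-base overlap plus explicit ambiguity is deterministic.

A gene is **expressed** when more than one tag — at least two — lands on its
exons (`--min-exon-tags` exposes the threshold; a reading of "more than one"
as $\ge 1$ is one flag away). Expression values use

$$\mathrm{RPKM} = \frac{10^9 \, C}{N \, L},$$

with $C$ the gene's exon tag count, $N$ the library's uniquely mapped total
(multi-mapped reads never count) and $L$ the merged exon-model length.

## Differential expression

Under the random-sampling model a gene's count in a library is a binomial
draw from the library total. Conditional on the combined count
$n = k_1 + k_2$ and the null of equal expression,

$$k_1 \sim \mathrm{Binomial}\!\left(n, \frac{N_1}{N_1+N_2}\right),$$

and the two-sided p-value sums the probabilities of all outcomes no more
probable than the observed one (minimum-likelihood rule, capped at 1; the
rule is stated explicitly because two-sided exact conventions differ). This
is the exact conditional form of the same model that the field's two-library
tools approximate with a normal MA-plot statistic; the exact form was
preferred deliberately — at desk scale it costs nothing, has no
approximation error, and is directly checkable against brute-force
enumeration.

Fold change is computed on pseudocounted normalized counts,
$\widehat{FC} = \frac{(k_1 + 0.5)/N_1}{(k_2 + 0.5)/N_2}$; gene length
cancels within a gene, so a count ratio and an RPKM ratio differ only
through the pseudocount (an RPKM-based variant sits behind a flag). A gene
is called up when $p < 0.01$ and $\widehat{FC} > 2$, down when $p < 0.01$
and $\widehat{FC} < 1/2$, otherwise not significant. Genes below the
expressed threshold in both libraries are not tested. No multiple-testing
correction is applied: the calling convention this pipeline reproduces uses
raw p-values, and the type-I error of the conservative exact test is
validated empirically on null simulations instead.

## Coverage and region reports

The coverage track assigns every base covered by a unique tag the value
$\mathrm{depth} \times 10^6 / N$ — depth per million uniquely mapped tags.
This definition is an interpretation: published per-chromosome "expression
value" tables of this kind do not define their units, and with libraries of
several million unique tags this choice lands minima and means in the same
magnitude range as those tables. Chromosome summaries (first/last covered
base, value sum, bases covered with percent, min, max, range, mean,
variance, SD) are computed over covered bases only, with the unbiased
$n-1$ variance; an uncovered chromosome yields zero coverage and NA
statistics rather than an error. Percentages are rounded half-up to two
decimals, matching how such tables are printed. Category summaries count
up/down calls per functional category, flag categories holding more than
10% of expressed genes as major, and deliberately double-count genes
carrying several categories. Region listings include any gene whose body
intersects the query interval (BED-style 0-based half-open coordinates;
GTF files are 1-based inclusive on disk; everything in memory is 0-based
half-open).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
defaults that are the package's reference study conditions:

* one 500-kb chromosome at GC 0.45; 300 protein-coding genes (2–4 exons of
  100–300 bp, introns 100–400 bp) and 2 single-exon rRNA genes (500–1500 bp)
  placed without overlap and with random strands;
* log-normal baseline abundances (meanlog 0, sdlog 1.5 — heavy-tailed, like
  real libraries; no abundance model is prescribed by the analysis itself);
* 50 DE genes at true fold change 4, half up and half down, abundances
  renormalized per condition;
* 200,000 tags per library: 10% rRNA, 15% intronic pre-mRNA, 6% antisense,
  the rest mature, sampled uniformly along spliced transcripts with genes
  weighted by abundance × transcript length;
* i.i.d. color errors at 2% per call, replacing the true color with a
  uniformly chosen different one;
* 10% low-quality tags (per-color QV uniform on 2..7, mean guaranteed below
  the filter threshold; others uniform on 15..30). Published raw-to-
  high-quality ratios for this platform are inconsistent between text
  (≈70%) and tables (≈91%); 10% was fixed once as a realistic middle ground
  on the table side.

Two modelling choices deserve emphasis. Intronic (pre-mRNA) tags are drawn
*wholly inside introns*, not uniformly along the unspliced transcript: the
requested intron fraction is then exactly the quantity the exon/intron
assignment rule is supposed to recover, which is what validation measures.
And mRNA fragment-size selection (the 50–110 nt fragments real protocols
excise) is not modelled — tags are sampled directly at 35 nt with no
positional bias. Quality-dependent error rates, paired ends and sequencing
chemistry are likewise out of scope. Consequently, passing tests demonstrate
correctness of the algorithms under the stated statistical model, not
robustness to platform artifacts absent from that model.

## Validation and problem sizes

The test suite validates each operation against independent oracles
(brute-force alignment scans, exact enumeration of the conditional binomial,
two-pass statistics, hand-checked coordinate arithmetic) and the whole
pipeline against simulation ground truth at the reference conditions above:
rRNA-filter recall of 1.0 on error-free rRNA tags, intron-fraction recovery
within three binomial standard deviations, at least 90% correct-direction
calls on DE genes with at least 20 sense mature tags in both libraries, a
Spearman correlation of at least 0.95 between true abundances and RPKM, and
an empirical type-I error within Monte-Carlo bounds of the nominal 0.01 on a
null simulation. Oracle-equivalence checks run on a 10-kb reference with
1,000 reads; the end-to-end runs use the full 2 × 200,000-tag study. These
sizes were chosen so the whole suite runs comfortably on a single CPU.

## Known limitations

* Indels are not modelled or aligned; the cascade is substitution-only.
* No color-space error *correction* (two-color consistency) is attempted.
* Multi-mapped reads are never rescued or fractionally assigned.
* One library per condition: the test inherits the random-sampling model's
  assumption that biological variability is absent; with replicates a
  dispersion-aware model would be required.
* Cytoband-to-coordinate resolution is the caller's responsibility (regions
  are plain BED intervals).
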