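---
title: "Models and methods behind ripscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ripscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripscope)
```

# The scientific problem

Repeat-induced point mutation (RIP) is a fungal genome-defence process
that, during the sexual cycle, peppers duplicated sequence with clustered
G:C→A:T transitions. In *Neurospora crassa* two DNA methyltransferase
homologs shape the process: RID, which is essential for mutating *young*,
unmethylated duplicates, and DIM-2, the vegetative 5mC methyltransferase,
which contributes disproportionately to RIP of *historically methylated*,
heterochromatic duplicates. A newly mutated duplicate also acquires
heterochromatin: DNA methylation is established at transitional levels in
the first post-RIP generation, requires the histone deacetylase HDA-1 to
be established at all, and matures over subsequent crosses into
constitutive heterochromatin that no longer depends on HDA-1.

`ripscope` packages the computational chain needed to quantify these
dynamics — duplicate detection, haploid parent–offspring mutation calling,
RIP rate statistics, and bisulfite window methylation — together with a
forward simulator of crosses that embodies the two-pathway mutation model
and the chromatin state machine, so that every analysis stage can be
exercised and tested without sequencing data.

# The intensity model

The central quantity is the RIP intensity of a chromatin class,
decomposed into three nonnegative coefficients, in expected mutations per
*recognised* spore per kb of duplicate:

$$
\lambda(\text{class}, \text{genotype}) =
  c_{\mathrm{RID}}\,[rid^+] + c_{\mathrm{DIM2}}\,[dim\text{-}2^+] +
  c_{\mathrm{SYN}}\,[rid^+][dim\text{-}2^+]
$$

The indicator terms make the double knockout an exact null in every
class, while single knockouts retain the pathway that does not require
the deleted gene. The default calibration fixes the coefficient
*fractions* from the observed single-knockout residuals:

* euchromatic (young) duplicates: deleting *rid* leaves 0.8% of the
  wild-type rate (a 99.2% reduction), deleting *dim-2* leaves 50%;
* heterochromatic duplicates: deleting *rid* leaves 32.1% (67.9%
  reduction), deleting *dim-2* leaves 18.2% (81.8% reduction);
* the R-L-R linker is entirely synergistic, so either single knockout
  silences it.

The absolute scale is set by two anchors: a conditional mean of 422.4
mutations per recognised spore per 11 kb euchromatic copy (so that the
unconditional mean at a 50% recognition probability is 211.2 per copy),
and a genome-wide unconditional total of 65 heterochromatic-duplicate
mutations per wild-type spore (so that the *rid*-null residual is about
20.9 per spore). Whether such a per-spore load should be read as an
average over all spores or only over RIPed ones is genuinely ambiguous;
we treat the calibration anchor as the unconditional (all-spore) mean,
the convention that makes the two anchors mutually consistent.

The ratio between the high- and low-methylation heterochromatic classes
(4.308) is chosen so that, at the default planted spans (48 kb of
strongly methylated and 24 kb of weakly methylated duplicates), about
89.6% of heterochromatic RIP falls in the stratum whose parental
methylation exceeds 10%.

# The cross simulator

`simulateCross()` draws tetrads of four haploid spores. Chromosomes
segregate 2:2 within a tetrad with independent assortment across
chromosomes; no crossover map is modelled. Each duplicate family is
*recognised* per spore with probability `pEvent` (default 0.5, matching
the ~50% per-spore RIP frequency of unlinked duplicates) or
`pEventLinked` (default 0.9) for the cis-linked R-L-R tester, for which
near-complete recognition is expected but no firm per-spore frequency
is established — the value is an assumption, exposed in the
configuration. Recognition is drawn independently per spore; in reality
RIP acts premeiotically, so tetrad mates are correlated — a simplification
that leaves all per-spore marginal statistics unchanged.

Given recognition, each carried copy receives a Poisson number of
mutations with mean `intensity × span/1kb` (an optional negative-binomial
size parameter adds overdispersion). Mutation positions are *clustered*:
cluster centres are drawn as `1 + Poisson(n/15)`, mutations are assigned
to centres multinomially, displaced by signed geometric offsets with mean
150 bp, and snapped to the nearest unused G/C site. The source analyses
describe clustering qualitatively; these three knobs are declared
defaults, and the property actually asserted in tests is the right one:
nearest-neighbour distances are stochastically smaller than uniform
placement over the same sites. Every mutation is C→T or G→A by
construction; no dinucleotide-context bias is applied by default because
none is quantified in the source.

# The chromatin state machine

Each duplicate copy carries one of four states: `euchromatic`,
`transitional`, `constitutive`, `silenced-null`. Transitions at a cross
(`evolveChromatin()`):

| from | condition | to | target 5mC |
|---|---|---|---|
| euchromatic | RIPed, RID and HDA-1 present | transitional | 0.33 |
| euchromatic | RIPed, HDA-1 absent | silenced-null | ≤ 0.011 |
| euchromatic | RIPed, hda-2 / hda-3 absent | transitional | 0.14 / 0.10 |
| transitional | next cross | constitutive | 0.330 → 0.323 by generation |
| constitutive | any | constitutive | maintained |

Vegetative knockouts of an established state (`knockoutChromatin()`)
follow the maturation series: removing HDA-1 from a generation-1,
-2, -3, -4 strain leaves 0.004, 0.163, 0.140, 0.225 respectively —
the influence of HDA-1 fades as heterochromatin matures — while the
intact lineage interpolates 0.330 → 0.323 (only the first- and
fourth-generation intact levels are anchored; generations 2–3 are linear
interpolations). Removing DIM-2 zeroes every emitted methylation level
without changing the underlying state; this is a hard invariant of the
emitter, not a statistical tendency. The silenced lineage targets
(0.004 → 0.011) rise slightly with generation to reflect the observed
1.1% fourth-generation residual, and are capped by a configurable
ceiling (0.02).

Genome-wide, an exact fraction (13.5%) of established constitutive
windows is designated HDA-1-dependent: a vegetative *hda-1* knockout
collapses those windows to zero while the rest are unchanged, producing
the bimodal change histogram; *hda-2*/*hda-3* knockouts instead apply a
uniform multiplicative reduction (default 0.75 — the magnitude is not
quantified in the source and is flagged as a placeholder). The dependent
windows are drawn as an exact count rather than i.i.d. coin flips: the
quantity of scientific interest is the fraction itself, and exact-count
assignment removes nuisance binomial variance from a structural
parameter.

# Observables

`emitObservables()` produces the two abstractions the analysis stages
consume, bypassing read-level simulation by design:

* **pileups** — per-site, per-allele, per-strand read counts at
  Poisson(depth) coverage (default 40×, the study-design depth), with a
  uniform per-base error rate (default 0.2%) distributed over the three
  non-template bases and a site quality score;
* **bisulfite counts** — per-cytosine methylated/unmethylated counts,
  both strands, with methylated ~ Binomial(coverage, window target).
  Window targets default to the state-machine means without extra
  dispersion, so measured levels converge to targets at binomial rates —
  the property the generational tests assert.

# Duplicate detection

`findDuplicatePairs()` tiles the genome into 500 bp windows and seeds
candidate window pairs with shared 11-mers (both orientations, exact
integer k-mer hashing). Because ~1 shared 11-mer per 500 bp window pair
arises by chance in megabase genomes, a pair is a candidate only when at
least two distinct seeds lie on a consistent alignment diagonal (±20 bp),
and candidate pairs are chained along diagonals into segment pairs. Each
segment is screened by an ungapped identity along the seeded diagonal
(cheap, exact for substitution-dominated divergence — RIP's regime),
then scored with `alignmentIdentity()` over its seeded span; segments
exceeding the cutoff (strictly greater than 0.65) are delineated with a
BLASTN-scored local alignment whose footprint labels every overlapping
window pair.

`alignmentIdentity()` itself is deliberately a *full-span* identity:
matches divided by alignment columns (gap columns included in the
denominator), with a scoring scheme (match +4, mismatch −1, gap open 10,
extend 4) whose expected score is positive even on unrelated sequence,
so the local alignment extends over the whole shared span instead of
reporting the identity of a short lucky island. Unrelated 500-mers score
around 0.4, far below the duplicate cutoff, while planted identities are
recovered to within a few tenths of a percent.

Distance categories between pair features are measured between nearest
ends, with lower-inclusive boundaries at 5 kb and 300 kb, and
interchromosomal as its own class; overlapping features have gap 0. A
window in several pairs is Dup once for span accounting but contributes
one count per (mutation, pair) instance in category summaries.

The engine is not BLAST: totals on a real genome can differ slightly
from a BLAST-based definition (unstated word size, e-value and masking
in the original), which is why whole-genome span comparisons should
carry a ±2% allowance. Segments are assumed locally colinear;
large-indel duplicates would be split into multiple segment pairs.

# Mutation calling

Candidates are sites where the best-supported non-reference allele in
the offspring is supported at least as well as the reference and is
essentially absent from both parents (fewer than 5 supporting reads at
the calling stage). Core filters: depth ≥ 5 in all three samples, a
single supported offspring allele (minor fraction < 0.2 at depth ≥ 10 —
the haploid rule), site quality strictly > 30, and alt support on both
strands. The exclusion screen then automates the usual manual checks:
variants within ±2 bp of homopolymer runs ≥ 6 bp are rejected; variants
whose parental pileups show ≥ 2 alt reads or ≥ 5% alt fraction are
rejected; variants in low-uniqueness regions (a majority of overlapping
31-mers occurring more than once genome-wide, both strands) are *not*
rejected — RIP targets are duplicates by definition — but flagged
`CONSENSUS_REQUIRED` and routed to `consensusCompare()`, which assigns a
reconstructed progeny locus to the parental allele with the higher
global-alignment identity (an identity margin below 0.1 percentage
points is refused as ambiguous) and reports only differences to the
assigned allele, so inter-allele differences are never miscalled as
mutations. The numeric thresholds of the screen are declared
operational definitions, configurable, and not claimed to be inferred
from the source analyses.

# Statistics

Rates are mutations per sample per Mb over a reduced region span;
reductions are `(1 − rate_KO/rate_WT) × 100` on those rates. The
Brunner–Munzel test is implemented in its standard form: relative effect
$\hat p = P(X<Y) + \tfrac12 P(X=Y)$ from pooled ranks, rank-based
variance estimates, and a t approximation with Satterthwaite-type
degrees of freedom; identical samples return (0.5, p = 1) and complete
separation an infinite statistic. A studentized permutation companion
(`brunnerMunzelPermutation()`) enumerates all splits exhaustively for
small samples. The two agree to within 0.02 at samples of ~25, but at
n ≤ 8 the t approximation can deviate from the exhaustive permutation
p-value by up to ~0.1 near the centre of the distribution — the known
small-sample weakness that motivated the permutation variant in the
first place. The package therefore exposes both; for very small samples
the permutation p-value is the one to report.

# What the simulator does and does not emulate

It emulates: haploid tetrad genetics with 2:2 segregation;
genotype-dependent, clustered, strand-symmetric G:C→A:T mutation;
duplicate families of the three designs (R-L-R with 802 bp repeats and a
729 bp linker at AT 45.64%, an 11 kb unlinked transposon pair at 97.4%
identity split between parents, dispersed methylated pairs);
depth-~40 pileups with sequencing error; binomial bisulfite counts
driven by the chromatin state machine; and multi-generation lineages
with accumulating AT enrichment.

It does not emulate: reads, mapping or alignment artifacts beyond the
abstracted error rate; meiotic recombination within chromosomes; indels;
context-dependent mutation preferences; chromatin spreading in *cis*;
or inter-spore correlation of RIP within a tetrad. Passing tests
therefore demonstrate the internal consistency of the calibrated model
and the correctness of the analysis code on data satisfying those
assumptions, not fidelity to any particular sequencing run.

# Numerical choices and problem sizes

Coordinates are 1-based inclusive in memory and in VCF/TSV output,
0-based half-open in BED. Zero-coverage methylation windows are missing
(`NA`), never zero, because the level formula is undefined there.
Mutations exactly on a window boundary belong to the window containing
their 1-based position. All randomness flows from one master seed
through labelled child seeds (`deriveSeed()`), so identical
configuration plus seed reproduces byte-identical artifacts, and each
stage can be replayed in isolation.

The default demonstration genome is two 150 kb chromosomes carrying all
planted families — large enough that every class has hundreds of windows
and thousands of cytosines, small enough that the full pipeline runs in
seconds. Calibration round-trip tests use 200 spores per genotype; the
reproduction script uses 600 spores per genotype (and 1000 spores for
the per-carrier statistics of the young duplicate) so that the
Monte-Carlo standard errors of the reported estimates are small relative
to the quantities themselves.
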