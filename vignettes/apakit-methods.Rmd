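---
title: "APA analysis with apakit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APA analysis with apakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apakit)
```

# The problem

Alternative cleavage and polyadenylation (APA) lets one gene emit mRNA
isoforms that end at different poly(A) sites (PAS). Two modes matter
biologically: **3′UTR APA**, where a proximal versus distal PAS in the
3′-most exon changes only the 3′UTR length, and **intronic APA**, where a
PAS inside an intron creates a truncated coding isoform with an alternative
last exon. 3′-end sequencing reads end at the cleavage site and carry a
stretch of untemplated adenosines from the poly(A) tail; after alignment
these appear as soft-clipped A (or T, on the minus strand) bases, which is
the signature `apakit` uses to separate genuine poly(A) junctions from
internal fragments.

This vignette documents the models and conventions behind each stage, the
tunable parameters with their defaults, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open.

# From alignments to a PAS count matrix

**PAS-supporting reads.** A read supports a PAS iff its tail-side soft clip
(in transcript orientation) is a homopolymer run of A (plus strand) or T
(minus strand) of which at least `min_unaligned_t = 2` bases differ from
the genomic continuation. Requiring a strict run is the conservative
reading of "untemplated tail"; a templated clip (the genome itself
continues in A) is internal priming, not cleavage, and is rejected. The
cleavage position is the last aligned base in transcript orientation,
recorded 0-based. Libraries whose alignments are reverse-complemented
relative to the transcript are handled by `orientation = "reverse"`.

**Clustering.** Cleavage positions within `max_gap = 24` nt are merged by
single linkage — two positions share a PAS iff they are connected by a
chain of steps each at most 24 nt. Single linkage is the deterministic
closure of the pairwise rule: it is order-independent and idempotent, both
of which are tested. The representative position of a cluster is its
most-supported member, ties broken toward the distal (transcript-3′) side,
which is the biologically dominant cleavage site.

**Internal-priming filter.** A cluster is discarded when the `window = 10`
nt immediately downstream (transcript orientation) of its representative
contain `min_a = 6` or more adenosines. Bases beyond a contig end count as
non-A, so edge clusters are never dropped for missing sequence. The filter
defaults to on for the read path and off for the count-table fast path,
whose inputs are assumed pre-filtered.

**Quantification.** Every accepted read increments exactly one cluster in
its sample's column; reads at positions no cluster covers become singleton
clusters, so read totals are conserved — an invariant the tests assert.

# Annotation

**Gene models.** All isoforms of a gene are merged: exons are unioned,
introns are the gaps between merged exons, and the 3′-most exon is the last
merged exon in transcription order. Internal coordinates are uniformly
0-based half-open; GTF (1-based inclusive) and BED (0-based half-open)
convert at the file boundary only, which prevents off-by-one drift.

**Regions.** A PAS in the 3′-most exon is `UTR3`; annotation does not
always extend to the true cleavage site, so a PAS up to
`utr3_extension = 1000` nt downstream of the 3′-most exon (transcript
orientation) is also classed `UTR3`. This extension is an assumption — the
length is configurable and the choice is deliberately generous, since
missing a distal PAS biases every shortening statistic. Intronic PASs get a
transcription-order ordinal: first (+1), second (+2), last (−1), second to
last (−2), middle otherwise. For genes with fewer than four introns the
groups collide; +1/−1 are assigned first, then +2/−2 (a three-intron gene's
middle intron is +2). The polarity analysis restricts itself to genes with
at least `min_introns = 4` introns, where the five groups are well defined,
so the tie rule never affects reported profiles. Everything else — internal
exons, intergenic — is `OTHER`: retained in the matrix, excluded from APA
tests.

**Hexamers.** The −40..−1 nt window upstream of the representative cleavage
position (reverse-complemented on minus) is searched with priority AAUAAA >
AUUAAA > close variants > none; within a tier the match nearest the PAS
wins. The default variant set is the ten single-nucleotide substitutions of
AAUAAA beyond the two canonical hexamers, the set conventionally used in
poly(A)-signal surveys; it is configurable because "close variants" has no
unique definition.

**Census.** A PAS counts as detected in a condition when it has at least
`min_cluster_reads = 2` reads in at least one sample of that condition.
Region-fraction shifts between conditions are tested with an exact
two-sided binomial test of one condition's intronic count against the
intronic fraction estimated from the other condition; this construction is
stated explicitly because the marginal totals that define such a test are
not uniquely determined by the comparison alone.

# APA statistics

For each gene the two most abundant 3′UTR PASs (pooled over all samples;
the pool decides ties toward the distal site) are labelled proximal and
distal by transcript position, and

* `RE = log2((distal + 0.5) / (proximal + 0.5))` per condition,
* `RED = RE(treated) − RE(control)`,
* `delta_abundance` = change in the distal isoform's share of the pair
  (fraction points, computed on raw counts).

RED < 0 is a shift toward the proximal PAS, i.e. shortening. Intronic mode
treats the combined intronic PAS set as "proximal" and the combined 3′UTR
set as "distal", so intronic activation also appears as RED < 0;
`delta_abundance` there is reported for the intronic share, so activation
is positive delta. The 0.5 pseudocount only guards the log ratios;
inference never sees it.

**The switch test.** Replicates are pooled into a 2×2 isoform × condition
table tested with a two-sided Fisher exact test; a significant call
additionally requires `|delta_abundance| > min_delta = 0.05` (absolute
fraction points — the standard reading of an "abundance change > 5%"
threshold in APA work) and sign agreement of the per-replicate-pair deltas
with the pooled delta in a strict majority of pairs. The pooled exact test
is exact but blind to between-replicate structure; the majority-sign gate
is what protects it from single-replicate artifacts. This is a documented
substitute for a per-exon negative-binomial GLM (DEXSeq-style): it is
dependency-free and exactly calibrated on the null (tested: false-positive
rate within 3 binomial SE of alpha on 1,000 all-null genes), at the price
of not modelling extra-multinomial usage noise. Per the source
convention, APA calls use unadjusted p < 0.05 while gene-level DE uses BH
FDR; both are parameters.

**Eligibility.** A gene needs `min_gene_reads = 20` pooled reads on the
tested pair; below that, fraction estimates are meaningless.

**Derived statistics.** Weighted 3′UTR length is the read-weighted mean of
all 3′UTR isoform lengths (transcript distance stop codon → cleavage site)
per condition; it always lies in the convex hull of the isoform lengths.
aUTR analysis bins tested genes into `n_bins = 5` equal-size groups by the
proximal–distal distance and reports mean RED ± SEM per bin with a Wilcoxon
rank-sum test between the extreme bins. The intron-position profile takes
every intronic PAS isoform with ≥ `min_reads = 2` reads in genes with ≥ 4
introns, computes library-size-normalized log2(treated/control) per
isoform (median-of-ratios size factors on gene totals — the paper-scale
ratio statistics need between-sample scaling, and median-of-ratios is the
field default), averages within the five ordinal groups, and mean-centers
the five group means.

# Expression and coupling

Gene expression is counted from reads overlapping the CDS only (≥ 1 bp,
strand-aware; reads touching two genes' CDS are discarded), so 3′UTR
changes cannot masquerade as expression changes. The DE test is a
documented DESeq substitute: median-of-ratios size factors, per-gene Welch
t on log2(normalized + 1), BH. Two honest caveats, both verified in the
test suite: (i) at triplicate scale a per-gene t-test is substantially less
powered than an NB GLM with dispersion shrinkage — the recovery test
therefore runs at 5 replicates and dispersion 0.02, where the substitute is
well powered; and (ii) median-of-ratios normalization under a strongly
one-sided DE program absorbs part of the signal into the size factors and
shifts null log-ratios slightly, a property shared with DESeq2's
estimator, so the recovery test uses a balanced up/down program.
APA–expression coupling summarizes DE log2 ratios per APA class
(boxplot-ready quartiles) with pairwise Wilcoxon tests; under independently
programmed APA and DE the coupling p-values are uniform, which the
acceptance suite checks across 40 seeds with a Kolmogorov–Smirnov test.

# Consequences

Removal logic is genomic, not transcript-reconstructive: a miRNA site of a
shortened gene is removed iff it lies strictly inside the aUTR (between
proximal and distal PAS); a domain of an intronic-activated gene is removed
if entirely downstream of the most-used activated intronic PAS, truncated
if spanning it. Because tallies of "removed" sometimes include truncation
and sometimes do not, both versions are reported. Tallies conserve feature
counts, and classification is mirror-symmetric under genome reflection
(both tested).

# The synthetic-data generator

`generate_reference()` emits a toy genome, GTF and truth program;
`simulate_counts()` and `simulate_reads()` emit the two input paths. The
defaults describe the simulated study conditions: 200 genes with 5–8
introns; a proximal/distal PAS pair in every 3′-most exon (proximal
150–400 nt past the stop codon, aUTR 200–1000 nt); an intronic PAS in half
the genes; hexamer classes planted at 55% AAUAAA, 17% AUUAAA, 20% other
variants, 8% none; control usage 45/55 proximal/distal and a 15% intronic
share; programmed effects as an absolute usage shift of 0.3; triplicate
conditions at 500 reads per gene with negative-binomial dispersion 0.1
(variance mean + 0.1·mean²) and multinomial isoform apportionment —
matching a triplicated two-condition design at typical 3′-seq per-gene
coverage. Simulated reads carry tail length k with P(k ≥ 2) = 0.92 and
uniform cleavage jitter within ±10 nt, safely under the 24-nt clustering
radius.

Two constructions deserve explanation. First, hexamer planting *scrubs*
the rest of the −40..−1 window of any equal-or-higher-priority hexamer:
without scrubbing, roughly 10% of "none" windows would contain a chance
variant and a closed-loop census would measure background k-mer statistics
rather than the planting program. Second, internal-priming decoys are
planted as A-rich but not pure-A tracts (AAGACA followed by twelve As): a
pure A-tract would make the decoy's clipped adenosines templated, so the
untemplated-tail rule would already reject the reads and the downstream
A-rich window filter would be untestable. With two mismatching bases in
the first six nucleotides, decoy reads pass the read filter and are
removed — measurably — by the window filter. Every true PAS is followed by
a 12-nt A-free guard for the complementary reason.

What the generator does **not** emulate: sequencing errors, adapter
artifacts, spliced read alignments (reads are short enough to stay within
one exonic or intronic segment), extra-multinomial isoform-usage
variability between replicates, correlated gene programs, and genome-scale
PAS density. Passing the recovery tests therefore demonstrates that the
statistics recover the programmed signal under the stated noise model — it
does not certify performance on real libraries, where usage overdispersion
in particular would push the Fisher-based test toward optimism and an
analyst should treat borderline calls accordingly.

All randomness flows from a single integer seed; identical seeds give
byte-identical FASTA/GTF/truth outputs, which the suite asserts.

# Numerical conventions and degenerate inputs

* 2×2 tables with a zero margin are uninformative: p = 1 by convention.
* The two-sided binomial p sums outcome probabilities at most the observed
  one; Wilcoxon tests are exact (full enumeration) for n₁+n₂ ≤ 12 without
  ties, normal-approximated with tie correction otherwise. All three match
  independent brute-force enumeration over every table with margins ≤ 12
  in the acceptance suite.
* A condition with zero reads on both isoforms yields an NA event, never an
  error; genes with fewer than two 3′UTR PASs (or no intronic PAS, in
  intronic mode) are silently ineligible.
* Exchanging condition labels maps SHORTENED↔LENGTHENED and
  ACTIVATED↔REPRESSED with identical p-values (antisymmetry, tested).
* Equal-count ties in top-2 selection and cluster representatives resolve
  toward the distal side, making every output deterministic.

# Problem sizes used in validation

The suite validates at sizes chosen to make binomial error bars small while
keeping a laptop-scale run: recovery and calibration at 200 and 1,000
genes (sensitivity ≥ 0.9 and observed FDR ≤ 0.1 at depth 500, triplicates,
dispersion 0.1, shift 0.3), the exact-test oracle sweep over all ~7,000
2×2 tables with margins ≤ 12, clustering against brute force on 1,000
random instances, the read-path closed loop at 150 genes, the hexamer
census at 2,000 PASs, and coupling uniformity over 40 simulation seeds.
`scripts/acceptance.R --seed <s> --out <json>` re-derives the headline
numbers from scratch at these sizes.

# Known limitations

* The switch test pools replicates; biological usage overdispersion is
  handled only by the majority-sign gate, not modelled.
* Region assignment gives each PAS to a single gene; overlapping same-strand
  gene pairs resolve by 3′-exon proximity, which can misattribute PASs in
  dense loci.
* The 1-kb 3′UTR extension is a blunt instrument for unannotated distal
  sites; with good annotation it can be reduced.
* `weighted_utr3_length` uses annotation-derived stop codons; non-coding
  genes have no defined 3′UTR length and are skipped.
* The read simulator emits ungapped alignments only, so the discovery path
  is untested on spliced 3′-end reads (real aligners soft-clip tails the
  same way, but junction-spanning tails are out of scope).
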