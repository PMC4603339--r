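---
title: "Subgenome arbitration and homoeolog-aware differential expression with homeoseq"
author: "homeoseq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome arbitration and homoeolog-aware differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoseq)
```

## The problem

Allotetraploid wheat (genome AABB) carries two diverged copies — homoeologs
— of most genes, one on each parental subgenome. When the combined
reference is too large to index at once, a practical workaround is to
align every RNA-seq library to subgenome A and subgenome B *separately*
and then decide, read pair by read pair, which subgenome each fragment
belongs to. `homeoseq` implements that decision rule and the downstream
analysis chain around it: quality trimming, fragment counting,
negative-binomial differential expression between genotype groups (wild,
landrace, cultivar), small post-hoc computations (novel-contig filtering,
N50, variant depth filtering, mapping-ratio correlations), and the qPCR
arithmetic used to validate expression calls. A synthetic data generator
with recorded ground truth makes every stage testable at desk scale.

## The arbitration rule

For each read pair the evidence per subgenome is collapsed into three
quantities:

* **status** — PAIR (both mates mapped), SINGLETON (one mate), UNMAPPED;
* **uniqueness** — whether every contributing mate has a single best hit
  (`NH = 1`);
* **MQS** — the sum of the mapped mates' MAPQ values.

Arbitration is a lexicographic comparison: read pairs have priority over
singletons; uniquely mapped evidence has priority over ambiguous
evidence; among otherwise equal evidence the larger MQS wins. A strict
winner at the first differing criterion decides the fragment, and the
deciding rule is recorded so the ordering is auditable. A fragment mapped
on one side only is assigned there (`ONLY_ONE`); a full tie is discarded
(`DISCARD_TIE`); both sides unmapped stays `UNMAPPED`. The three criteria
are all stated by the underlying method; their *ordering* is a design
choice here, taken in the order the rules are usually stated, which also
makes the tie-discard well defined (a "same alignment score" tie means
equal MQS after status and uniqueness have already tied). The tie
fraction is reported in the partition statistics as a diagnostic, not
asserted, since it depends on subgenome divergence.

An exhaustive enumeration over all combinations of status, uniqueness and
a small MQS grid on both sides (324 cases) is compared against an
independent rule-by-rule interpreter in the test suite.

## Trimming

`trimRead()` applies, in order: adapter clipping (longest read-suffix /
adapter-prefix overlap of at least 8 bases with at most one mismatch),
LEADING and TRAILING base drops below quality 3, a 5'-to-3' sliding
window cut (window 4, mean quality 20; the read is cut at the start of
the first failing window), and a 40-base minimum length. These defaults
mirror the common Trimmomatic invocation
`LEADING:3 TRAILING:3 SLIDINGWINDOW:4:20 MINLEN:40`. The rule *order*
follows the Trimmomatic convention (adapter first, MINLEN last); the
sliding-window cut point is the start of the first failing window. Both
choices are conventions rather than published specifics of the study
design being emulated, and both are documented here for that reason.
Phred offset defaults to 33 with a 64 switch: legacy phred64 data exist,
but modern reuse overwhelmingly expects offset 33. Trimming is idempotent
and monotone in the window threshold; both are property-tested.

Pair bookkeeping (`trimPair()`, `trimLibrary()`) matters downstream
because arbitration gives pairs priority over singletons: a pair whose
mate dies at MINLEN survives as a flagged singleton.

## The fixture aligner

`fixtureAlign()` is a deliberately small exact-k-mer-seed, ungapped
aligner that exists so that the arbitration, counting and DE stages can
be exercised end to end without an external aligner; it is not a
production aligner. Candidate loci come from exact 21-mer seeds; each
candidate is scored by mismatch count. MAPQ is
`min(60, c * (second_best_score - best_score))` with `c = 6`. Two
details are worth recording:

* a read with a *single* candidate locus takes `second_best_score =
  maxMismatch` (default 10), so a unique perfect hit scores
  `min(60, 6 * 10) = 60` and two tied loci score 0, and
* reads whose best hit exceeds `maxMismatch` are reported unmapped.

This makes MAPQ decay with the number of mismatches, as real aligner
MAPQs do, which is what gives the MQS comparison its signal: a read from
subgenome A aligns perfectly to A (MAPQ 60) and with roughly
`divergence x read length` mismatches to B (lower MAPQ), so the MQS rule
recovers the origin. At 5% homoeolog divergence and 101-bp reads the
probability that a read sees *zero* divergent sites — the only way to
tie — is about 0.6% per mate, which is why ties are rare at realistic
divergence and universal at divergence zero (both behaviours are
asserted in tests).

## Fragment counting

`countFragments()` follows paired-end featureCounts-style semantics: a
fragment (pair or singleton) increments exactly one gene if and only if
every mapped base of its primary records lies within that single gene's
merged exon union; fragments contained in no gene or compatible with two
or more genes are reported unassigned. Counting is unstranded — the
library chemistry of typical datasets is directional, but strand handling
is not part of the emulated method, so the flag defaults to the
permissive choice. A pair counts once. Order of records within name
groups does not matter (property-tested), and on error-free synthetic
data the counts equal the truth-table tallies exactly.

## Differential expression

The DE machinery follows the classic (v1-era) DESeq scheme rather than
modern shrinkage-based estimators, because the emulated analysis reports
unshrunken group-mean ratios, including literal `-Inf`/`Inf` fold changes
for genes expressed in only one group:

* **Size factors** are median-of-ratios over genes with nonzero counts
  in every library (`estimateSizeFactorsMoR()`; cross-checked in tests
  against DESeq2's estimator and a brute-force oracle).
* **Fold changes** are `log2(mean_target / mean_ref)` of
  size-factor-normalised group means, with no pseudo-count.
* **Dispersions** are per-gene method-of-moments estimates on normalised
  counts, smoothed by a gamma-family fit of dispersion against
  `1/baseMean`, with "maximum" sharing: each gene takes the larger of
  its fitted and empirical value. With fewer than 10 informative genes
  the fit is replaced by a pooled method-of-moments value (the gamma fit
  is unstable on tiny fixtures). Pooled (both-condition) estimation is
  used rather than per-condition; a `dispersions` argument lets callers
  supply known values.
* **Testing** uses the conditioned NB sum test: given a gene's total
  count across both groups, the p value is the probability of group
  totals at most as likely as those observed, with group-sum means and
  variances derived from the pooled normalised mean, the size factors
  and the gene's dispersion.
* **Multiplicity** is Benjamini–Hochberg step-up (`p.adjust`), and DEG
  calls use `|log2FC| >= 1` at `FDR <= 0.1`; infinite fold changes pass
  the magnitude cut. The fold-change cutoff is read as a cutoff on
  magnitude, since both up- and down-regulated genes are reported under
  it.
* The **domesticated-vs-wild** candidate set is the direction-consistent
  intersection of the cultivar-vs-wild and landrace-vs-wild DEG sets.

Calibration is checked two ways. With the generative dispersion supplied,
the conditional test's type-I error at the 5% level sits inside the
binomial 99% CI of nominal on 2,000 null genes — this isolates the
p-value machinery itself. With *estimated* dispersions the maximum
sharing mode is deliberately conservative (roughly half of all null genes
get an inflated dispersion), so the estimated path is asserted to be
not anticonservative rather than exactly nominal; that conservatism is a
property of the method being reproduced, not an accident of this
implementation. Realized FDR on planted effects at 2+2 replicates stays
well under the nominal 10%, and planted |log2FC| = 2 effects at mean 200
are detected with better than 80% power at p < 0.01.

## The synthetic study

`simConfig()` defaults describe the emulated design: three genotype
groups (wild, landrace, cultivar) with two replicate libraries each,
2 x 101 bp paired reads, homoeolog divergence 0.05 substitutions/site,
NB counts with dispersion 0.05, and planted up/down effects expressed as
log2 fold changes applied to both non-reference groups. Subgenome B is
derived from subgenome A's ancestor by iid substitutions, so the per-site
Hamming distance between homoeologs is exactly Binomial(length,
divergence) — the substitution process has a closed-form oracle. Each
transcript is a single-exon gene on its own contig: multi-exon models add
nothing to the arbitration logic and would force a gapped fixture
aligner. Base qualities decline linearly from Q38 to Q22 along the read
with Gaussian jitter (sd 3), chosen so the sliding-window rule trims a
minority of tails. A group pool is treated as a single expression
profile; within-pool heterogeneity between the accessions making up a
real pool is deliberately not modelled.

What the generator does **not** emulate: splicing and indels,
strand-specific chemistry, GC and positional coverage bias, PCR
duplicates, and base-quality miscalibration. Passing tests therefore
demonstrate correctness of the decision rules and inference machinery
under a clean generative model, not robustness to every artefact of real
libraries.

Problem sizes in the tests and acceptance script (tens of genes and a
few hundred read pairs per library for alignment-bound stages; 2,000
genes for count-level inference) were chosen as the smallest sizes at
which the stochastic assertions have comfortable Monte-Carlo margins.
Real-data DEG counts from any particular study are functions of that
study's libraries and are not reproduction targets at this scale.

## qPCR arithmetic

`fitStandardCurve()` fits Ct against log10 relative input and converts
the slope to an amplification efficiency `E = 10^(-1/slope)` (E = 2 is
perfect doubling; a slope of -3.3219 gives exactly 100%).
`relativeQuantification()` computes
`RQ = E_target^(-dCt_target) / E_endo^(-dCt_endo)` with replicate Cts
averaged arithmetically before differencing, per-group efficiencies
applied when curves are available, and a pure `2^(-ddCt)` fallback when
they are not. The endogenous normaliser defaults to *Ubiquitin*. With
E = 2 everywhere the corrected formula reduces exactly to `2^(-ddCt)`
(tested). Published figures of this kind typically do not print slopes or
raw Ct values, so the qPCR module is verified by algebraic identities
(RQ = 1 at zero ddCt, strict monotonicity in treatment Ct, exact
reduction at E = 2) rather than against printed numbers.

## Post-hoc rules

Novel contigs are kept when they have no reference hit or a best identity
of at most 70% — the discard is *strictly above* 70%, so exactly 70% is
kept. The variant filter keeps sites with depth *strictly below* 100,
reading "maximum read depth" as the per-site DP value. N50 is the largest
L such that contigs of length at least L hold half the assembled bases.
Mapping-ratio-vs-distance association is plain Pearson correlation with
a two-sided t-based p value.

## Numerical choices and degenerate inputs

* Printed-style percentages round half-up (`roundHalfUp()`), matching
  table formatting conventions rather than R's banker's rounding.
* `log2FoldChange(0, 0)` is NA and flagged; single zeros give signed
  infinities.
* A count matrix with no all-positive gene has no median-of-ratios
  solution and is rejected with a message suggesting filtering.
* In the NB test, dispersions are floored at 1e-8 and the NB size
  parameter guards against non-positive variance excess (Poisson-like
  genes).
* Standard curves with non-negative slope are flagged invalid rather
  than silently producing efficiencies below 1.
* The fixture aligner reports reads shorter than the seed length as
  unmapped and rejects an empty reference outright.

## Orchestration

`runPipeline()` chains the stages (simulate, trim, align to both
subgenomes, arbitrate, count, test) with per-stage logging, asserts read
conservation at the arbitration boundary (assigned + ties + unmapped =
total pairs), and, when an output directory is configured, writes
FASTA/GTF/TSV artifacts with an MD5 manifest. All randomness derives
from the single seed in the simulation config, so reruns are
bit-identical. Configuration can come from a YAML file
(`pipelineConfig()`); the package's exported functions are the intended
programmatic interface.

## Known limitations

* The fixture aligner is ungapped and exact-seeded; it is a test
  harness, not a mapper, and indel-containing or spliced reads are out
  of scope.
* Arbitration is specified and tested for two subgenomes; the evidence
  structure would generalise to N-way comparisons but no such interface
  is exposed.
* The NB test covers two-group contrasts with replicates; multi-factor
  designs belong to GLM-based tools.
* Efficiency correction uses one mean Ct per gene/group; uncertainty
  propagation across technical replicates is not attempted.
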