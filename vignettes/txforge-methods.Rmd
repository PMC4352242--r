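---
title: "txforge: models, parameters and design decisions"
author: "txforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txforge: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txforge)
```

`txforge` analyzes *de novo* transcriptome assemblies of non-model
species: quality trimming and pair synchronization of the raw reads,
mapping them back to the assembly for coverage-based quality control,
redundancy removal by clustering, coding-region prediction, reciprocal
best-hit (RBH) orthology against a related species, and
tissue-/species-enrichment discovery. Because such species by definition
lack reference data, the package is organized around a simulator that
plants a complete ground truth — ortholog map, tissue assignments,
expression levels, species-specific genes — so that every downstream claim
can be scored against what was actually planted. This vignette documents
the models, defaults and the decisions taken where the design was
genuinely open.

## The synthetic transcriptome

`simConfig()` / `generateTranscriptome()` build a species-A gene
complement with lengths uniform on `lengthRange` and i.i.d. bases. Tissue
structure is deliberately simple: a fraction `tissueSpecificFraction` of
genes per tissue is expressed in that tissue only, and the remainder is
expressed everywhere; per-gene expression levels are log-normal
(meanlog 0, sdlog 1), a standard rough model of bulk expression spread. A
fraction `speciesAOnlyFraction` of genes has no species-B counterpart,
emulating lineage-specific transcripts.

Species B is produced by `evolveOrthologs()` under a Jukes–Cantor
substitution process: each site changes with probability
$\tfrac{3}{4}\!\left(1 - e^{-4d/3}\right)$ and becomes one of the other
three bases uniformly; no indels are introduced by default. The expected
observed identity is therefore $\tfrac{1}{4} + \tfrac{3}{4} e^{-4d/3}$,
which for the default distance $d = 0.09$ substitutions/site gives 0.9152
— the regime of two congeneric fish species whose ortholog identity
distribution centers a little above 91%. Only this single distance is
used by default, because a realistic *distribution* of divergences is not
identifiable from a published histogram; users can evolve subsets at
different distances if they need one.

Sequencing emulates a strand-specific (dUTP) paired-end protocol:
76-bp mates, insert sizes normal around 200 bp (sd 20) truncated to
`[readLength, transcript length]`, fragments drawn per gene with
multinomial weights proportional to expression × length, mate 1 on the
sense strand. Base qualities hold at Q40 over the 5' 60% of the read and
decay linearly to `qualityFloor` (default Q12) over the final 40%, with
per-read jitter; this concentrates low qualities in the 3' tail, as on
real flow cells, and — with the default trimming threshold of Q30 — leaves
the trimmer genuine work while keeping most mates above the 35-bp
retention bound. (A decay spread over the whole read would push typical
cut points below 35 bp and empty the synchronized output, which matches
no real library.) Sequencing errors flip bases uniformly at
`baseErrorRate` (default 0.005). All randomness flows from one integer
seed; reruns are byte-identical.

What the simulator does *not* model: rRNA contamination, PCR duplicates,
indel sequencing errors, isoforms/splicing, composition bias, or a
realistic gene-length distribution. Passing tests on this synthetic data
therefore demonstrates algorithmic correctness under the stated model,
not robustness to every artifact of real libraries.

## Read trimming and pair synchronization

`trimRead()` implements the running-sum 3' rule (BWA's `-q`): scanning
from the 3' end, the area $A(p) = \sum_{i \ge p} (Q_0 - q_i)$ is tracked
and the read is cut at the position maximizing $A$; if no suffix has
positive area the read is untouched, and a uniformly bad read may be
trimmed to length zero. Two details are unspecified in the classical
description and were fixed here: ties in the maximal area keep the
*longest* read (data preservation), and trimming is strictly 3'-sided (no
adapter or 5' logic). The rule is idempotent, which the suite checks,
and is verified against an exhaustive evaluate-every-cut oracle.
`synchronizePairs()` then keeps a pair only when both trimmed mates are at
least `minRetainedLength` (35 bp) — no singletons are ever emitted.

## The read mapper

The internal mapper stands in for heavyweight external aligners at desk
scale. It seeds candidate placements from the two terminal k-mers
(default `k = 31`) of each mate (mate 2 reverse-complemented), verifies
candidates by *ungapped* comparison, and accepts a placement when both
mates stay within `maxMismatchRate` (default 0.05) with consistent
orientation and a non-negative insert. Ungapped verification is a
deliberate simplification: the simulator introduces no indels. Multi-maps
resolve to the fewest-mismatch candidate with a lexicographic tie-break,
so counts are reproducible and independent of read order; an `all-best`
mode credits every tying transcript for sensitivity analyses. Cross-species
mapping (species-B reads on the species-A assembly at ~8.5% divergence)
uses shorter seeds and a laxer cap (`k = 15`, rate 0.12), since the
probability that a 31-mer is substitution-free at that divergence is only
about 6%.

## Assembly QC and clustering

Transcripts with average base coverage strictly below 1 are removed
(`coverageFilter()`); equality is kept. N50 uses the conventional
inclusive definition (largest `L` such that contigs ≥ `L` contain at
least half the bases). Core-gene recovery aligns each core protein
against the predicted peptides with BLOSUM62 local alignment and counts a
gene as recovered at e-value ≤ 10⁻⁶ with alignment spanning more than 70%
of the core gene; at desk scale the core set is synthetic (translations
of planted ORFs), and any user-provided FASTA of real core genes is
accepted.

`clusterTranscripts()` reproduces the greedy incremental procedure of
CD-HIT-EST without its word-filter acceleration: sequences are processed
in decreasing length order (ties by ascending id), each joins the
existing cluster of highest identity if that identity is ≥ 0.90
(inclusive), else founds a new cluster. Identity is computed by
semi-global alignment (shorter sequence end-to-end, free terminal gaps on
the longer) with matches divided by the shorter sequence's length — the
CD-HIT convention. Two open points were fixed: identity ties between
candidate clusters go to the earliest-founded cluster, and the
representative is the founder (longest member). Full dynamic programming
makes the procedure exact but quadratic; it is intended for thousands,
not millions, of sequences, and results can differ from CD-HIT's
heuristics on real data.

## Coding-region prediction

Candidate ORFs (default: complete ATG-to-stop, ≥ 100 codons) are
extracted in all six frames; the 500 longest train the coding model and
per-sequence base-shuffled copies (composition-preserving) train the
noncoding model. The "hexamer" model is an order-5 nucleotide Markov
chain with *codon-phase-specific* transition tables — three 1024 × 4
tables indexed by the phase of the predicted base — plus an initial
5-mer distribution, all with pseudocount 1. The phase-aware choice is a
deliberate design decision: with a single phase-blind chain, the same
region read at forward frame offsets 1 or 2 shares all but one or two
hexamer terms with the proper frame, so the "proper frame must score
highest of the six readings" rule degenerates into a near-coin-flip on
boundary terms and loses all discriminating power. Phase-specific tables
(as in TransDecoder-class predictors) make wrong-offset readings
genuinely unlikely under the coding model, and the reporting rules then
behave as intended.

An ORF is reported iff its log-likelihood ratio is positive, its proper
frame is the strict maximum over the other five readings of the same
region, and it is not eclipsed — fully contained within the span of a
longer reported ORF in a different reading frame (resolved processing
ORFs by decreasing length, then decreasing LLR). Partial (start- or
stop-less) ORFs are excluded by default and can be enabled with
`requireComplete = FALSE`; they are scored identically.

## Orthology and divergence statistics

`localAlign()` is optimal local alignment under affine gaps (match +2,
mismatch −3, gap open 5, extend 2 — classic nucleotide defaults; BLOSUM62
with 11/1 in protein mode). E-values use the Karlin–Altschul form
$E = K m n e^{-\lambda S}$; $\lambda$ is solved exactly from the scoring
scheme under uniform composition ($\lambda \approx 0.634$ for +2/−3) and
$K$ defaults to 0.41 (0.041 protein). These are nominal ungapped
constants: e-values are internally consistent and usable as a cutoff
(default 10⁻⁶) but not comparable to another program's output.

`reciprocalBestHits()` emits `(a, b)` iff each is the other's
highest-scoring accepted hit; ties break by e-value then lexicographic
id, so output is deterministic. Because the scoring is symmetric, one
all-vs-all pass serves both directions. A shared-k-mer prescreen
(`minSharedKmers = 5` shared 13-mers) skips pairs that could not reach
the e-value cutoff anyway: two unrelated 2-kb sequences share fewer than
five 13-mers with overwhelming probability, while genuine orthologs at
≤ 15% divergence share hundreds. The prescreen changes nothing at the
cutoff but reduces the quadratic alignment cost by two orders of
magnitude; `minSharedKmers = 0` forces the exhaustive search, and the
suite verifies both paths. `identityStats()` reports pair count, mean and
median alignment identity over pairs whose alignment covers more than
75% of the subject, mirroring how divergence between two transcript sets
is conventionally summarized.

## Enrichment rules

Tissue enrichment is annotation-based, not differential expression: the
annotated gene sets of samples in the same tissue group are unioned
(ovary and testis merge into "gonad" *before* uniqueness testing — the
alternative order is available by changing the grouping map), a gene is
group-enriched when annotated in that group only, and the shared set is
the intersection of all groups. Species enrichment uses the read-count
rule: at least 8 species-A reads and — under the strict default reading —
zero reads in *each* of the two independent species-B datasets
(`anyDataset = TRUE` gives the laxer at-least-one reading). The threshold
of 8 is configuration, not something the package calibrates. Counts are
raw; no library-size normalization is applied, which is a documented
caveat when libraries differ in depth. GO over-representation is the
hypergeometric upper tail $P(X \ge k)$ per term with Benjamini–Hochberg
adjustment; terms are flat sets (no GO-DAG propagation).

## qPCR statistics

Amplification efficiency comes from the standard-curve slope,
$E = 10^{-1/\text{slope}}$, with a warning outside the plausible
$(1, 2.5]$ range. The efficiency-corrected relative expression ratio is
$E_{target}^{\Delta CP_{target}} / E_{ref}^{\Delta CP_{ref}}$ with each
$\Delta CP$ computed control-minus-treatment from group-mean crossing
points. Significance uses the Wilcoxon–Mann–Whitney test: exact by full
enumeration of rank labelings when the combined sample size is at most
12 (mid-ranks for ties; two-sided p as twice the smaller tail, capped at
1), otherwise the tie-corrected normal approximation without continuity
correction. The exact/approximate switch is part of the operation's
contract, so it is implemented here and cross-checked against
`stats::wilcox.test` in the suite rather than delegated to it.

## Pipeline, determinism, and problem sizes

`runPipeline()` executes the stages in dependency order from a single
`pipelineConfig()`, derives every stage's RNG stream from the master
seed, and records parameters, counts and md5 checksums of all outputs
(relative paths only) in `manifest.yaml`; identical config + seed gives
identical manifests. The *de novo* assembler itself is intentionally not
reimplemented — the pipeline takes either the simulator's truth
transcripts or any user FASTA as the assembly. Coordinates throughout the
package follow the R/Bioconductor convention (1-based, closed intervals).

The validation suite runs at sizes chosen to exercise each method
honestly while staying desk-scale: the divergence-recovery check uses
300 ortholog pairs of 1–3 kb (≈ 600 kb of aligned sequence, giving a
standard error on mean identity well under 0.1 percentage points);
trimming is checked against its exhaustive oracle on 10⁴ reads;
clustering against a brute-force re-execution on 100 instances of up to
30 sequences; coding discrimination on 1 000 planted ORFs and 1 000
shuffled decoys; and the pipeline determinism check runs a 12-gene,
two-tissue configuration twice. The pipeline's demo default lowers the
minimum ORF length to 30 codons because uniformly random transcripts of a
few hundred bases almost never contain 100-codon ORFs; analyses of real
data should keep the 100-codon default.

## Known limitations

- The simulator's i.i.d.-base genes carry no codon structure, so the
  pipeline's ORF stage on simulated data mainly exercises plumbing; the
  coding-model statistics are validated on codon-biased planted ORFs
  instead.
- The mapper is ungapped and will miss indel-bearing reads; real-data use
  should prefer a dedicated aligner and import its counts.
- E-values are nominal (ungapped constants) and not calibrated against
  BLAST.
- Greedy clustering is exact but quadratic; large assemblies need the
  word-filtered tools it emulates.
- Enrichment uses raw counts and flat GO sets, as documented above.
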