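---
title: "lncscout: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncscout: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long non-coding RNAs (lncRNAs) — transcripts longer than 200 nt with no
protein-coding capacity — are most reliably found by genome-guided assembly
of RNA-Seq data followed by aggressive filtering of the assembled
candidates. In compact fungal genomes the question of *what a lncRNA might
do* is then usually approached from two directions: *cis* (what genes sit
next to it, and in what orientation) and *trans* (what genes it could
physically engage, for instance through RNA:DNA:DNA triplexes in promoter
regions), both cross-referenced against co-expression over conditions.

`lncscout` implements that workflow as a set of composable, individually
tested stages. Upstream read processing (trimming, mapping, assembly,
quantification) is deliberately out of scope: the package starts from a
genome FASTA, a reference annotation, an assembled candidate GTF and
count/TPM matrices, which is where analysis decisions — and reproducibility
problems — actually live.

# The filter cascade

Candidates are reduced to a lncRNA set by the intersection of six
independent boolean filters; because the final set is a conjunction, filter
order never matters, and the `filter_report` records which filter(s)
removed each transcript.

| filter | rule | default |
|---|---|---|
| `length_ok` | spliced (exon-sum) length at least the lncRNA cutoff | 200 nt |
| `no_sense_overlap` | no exon overlap with any annotated exon on the same strand | — |
| `noncoding_vote` | unanimous non-coding vote (built-in + external classifiers) | — |
| `known_rna_ok` | no strong hit to structured-RNA databases | RFAM E < 1e-5; RNAcentral identity > 90%, E < 1e-5 |
| `domain_ok` | protein hits recorded; exclusion opt-in | flag-only |
| `expressed` | TPM strictly > threshold in at least one sample | > 1 TPM |

Notes on deliberately asymmetric choices:

* **Antisense overlap does not filter.** Only same-strand exon overlap
  removes a candidate; antisense-exonic lncRNAs are a major recognised
  class and must survive.
* **The expression threshold is strict (`> 1`).** Descriptions of this
  filter differ between "not greater than 1 TPM in any sample" and "< 1 TPM
  in all samples", which disagree at exactly 1; the strict reading is the
  default and the threshold is configurable.
* **Protein-domain hits are flag-only by default.** Real pipelines inspect
  the one or two SWISSPROT/PFAM hits a lncRNA set typically produces rather
  than bulk-excluding; `hit_policy(strict_protein = TRUE)` switches to
  exclusion.
* **A whitelist models manual rescue.** High-identity database hits can be
  stale annotations; whitelisted query ids are exempt from exclusion.

# Coding potential

Published coding-potential classifiers are trained machine-learning tools
that cannot be shipped inside a desk-buildable package. `lncscout`
substitutes a transparent three-feature classifier and keeps the ensemble
logic: external tool labels can be supplied as extra vote columns, and a
transcript is non-coding only if **every** voter says so.

The built-in voter labels a transcript coding when

```
(longest ORF > 100 aa  AND  hexamer score > 0)  OR  Fickett >= 0.95
```

* **ORF**: longest ATG-initiated, stop-terminated reading frame on the
  sense strand (transcripts are stranded), strict `> 100` aa.
* **Hexamer score**: mean log-likelihood ratio of hexamer frequencies under
  a coding table (trained in-frame, step 3, on annotated ORFs) versus a
  non-coding background (all frames). When a transcript has an ORF the
  score is evaluated in-frame on that ORF — the frame the coding table was
  trained on; otherwise over the whole sequence. Add-one smoothing keeps
  every hexamer observable.
* **Fickett TESTCODE**: the classic position/composition statistic with
  the published lookup tables and weights; deterministic,
  case-insensitive, Ns ignored. The 0.95 cutoff and the hexamer cutoff of
  0 are implementation defaults, configurable in `classify_and_vote()`.

Benchmarking (`benchmark_metrics`) treats *coding* as the positive class:
recall = TP/(TP+FN), specificity = TN/(TN+FP), precision = TP/(TP+FP),
balanced accuracy = (recall+specificity)/2, F1 = harmonic mean of precision
and recall; zero-denominator ratios are returned as `NaN` with a warning
rather than silently patched.

# Positional classification

Each lncRNA gets exactly one category relative to its partner coding gene.
Antisense exon overlap wins outright (partner = gene with the largest
overlap); otherwise the partner is the nearest coding gene by span gap
within a 10 kb window (configurable; ties go to the smaller start
coordinate), and orientation plus side decide among
`upstream_sense` / `downstream_sense` (same strand, 5' / 3' of the partner
in partner orientation) and `divergent` / `convergent` (opposite strand,
head-to-head / tail-to-tail). With no gene in the window the call is
`intergenic_unassigned`. Two corner conventions the tests pin down: a
same-strand *exon* overlap is an error (such transcripts should never reach
classification), and a span overlap without exon overlap is sided by
midpoint comparison. Distances are span gaps, 0 when overlapping —
the distance measure between features is nowhere standardised, so the gap
convention is applied uniformly (also in `nearest_neighbors` and pair
labelling).

# Triplex search

Triplex formation is modelled at the motif level: a purine-rich duplex
tract (the TTS) can host a third strand (the TFO, here a lncRNA segment)
via Hoogsteen pairing in one of three canonical motifs:

| motif | TFO alphabet | pairing (TFO:purine strand) | orientation |
|---|---|---|---|
| R | G, A | G:G, A:A | antiparallel |
| Y | C, T/U | C:G, T:A | parallel |
| M | G, T/U | G:G, T:A | antiparallel |

`triplex_params()` carries the search constraints: minimum length 20 nt,
maximum error rate (a single configurable knob, default **0.05**; the
literature this package follows states both 20% and 5% for the same run,
and the stricter value is taken), at most 2 consecutive errors, minimum
guanine fraction 0.20 (measured on the purine strand — i.e. counting triad
positions whose duplex pair is G:C), and merging of overlapping sites.

Window semantics are fully specified so that a brute-force enumeration
oracle can check them: a reported tract/match is a window that starts and
ends on matching positions, satisfies all four constraints, and is
*maximal* (contained in no other valid window); with merging on, chains of
overlapping same-motif windows collapse to the single best window (longest,
then fewest errors, then leftmost), so every reported record itself
satisfies the constraints. Long error runs split the sequence into
independent segments, which keeps the scan near-linear on genomic input.
TTS detection examines both strands as the potential purine strand and is
exactly symmetric under reverse complementation (a property test).

Genomic context uses a strand-independent priority partition
(promoter > exon > intron > intergenic) in which every base has exactly one
class and fractions sum to 1 (to 1e-12). Promoters for the *context map*
are 1000 bp upstream + 250 bp downstream of every transcript's TSS (the TSS
is the first downstream base); promoters for *interaction-pair scope* are
1500/250. The two windows are independent settings on purpose — context
describes the genome, scope links an interaction to a gene. Each
interaction is then labelled with the single highest-priority class its TTS
overlaps, and unique (lncRNA, gene) pairs are extracted per scope
(Promoter, Exon, Gene+Promoter).

# Expression analysis

Transcript counts are summed to gene level and rounded half-away-from-zero.
Normalisation is a documented stand-in for a variance-stabilising
transform: median-of-ratios size factors against a scale-free reference
(geometric mean of the column *proportions*, scaled to a nominal 1e6
library) followed by `log2(count/sf + 1)`. The scale-free reference makes
the transform exactly invariant to rescaling any single sample's library —
an invariant the tests assert bit-sharp — at the cost of anchoring size
factors only up to a dataset-wide constant. Constant rows (quantification
artefacts) are dropped. An externally produced transformed matrix can be
substituted at any point: every downstream function takes a plain matrix.

Correlation is Pearson's r on z-scored rows with two-sided p-values from
the t distribution (n − 2 df). Pair labelling is exclusive with precedence
`Neighbouring` (span gap <= 2 kb) > `Interacting_Promoter` > `Independent`;
the published pair counts this mirrors are only consistent with exclusive
labels, and neighbouring-takes-precedence is the natural reading of
"not neighbouring or predicted to interact". The Exon and Gene+Promoter
scopes are produced as parallel labelings for supplementary-style analyses.
Group summaries stratify by the lncRNA's differential-expression status
(consumed from a DE table: `padj < 0.0005` for growth-rate association via
likelihood-ratio tests, `s-value < 0.005` for pairwise Wald tests —
the GLM fitting itself is out of scope), and report distribution summaries,
a Kolmogorov–Smirnov statistic against the matching Independent group, and
a deliberately simple bimodality indicator: on a fixed 0.25-wide histogram
of r, `1 − density(near 0) / min(mode−, mode+)`. It is a screening
heuristic — values near 1 mean a deep valley between two side modes — not
a significance test.

# Clustering

Growth-rate-associated genes are clustered on *profiles*: per-condition
replicate medians, z-scored per gene. Fuzzy c-means is implemented directly
(Euclidean distance, fuzzifier m = 2 by default, seeded center
initialisation, convergence at center shift < 1e-8 or 1000 iterations)
since no soft-clustering implementation is guaranteed in the runtime
environment; a fixed seed gives bit-identical results. Cluster number is
chosen by inspecting the Dmin curve — the mean over repeated runs of the
minimum pairwise center distance — and is intentionally *not*
auto-selected; the elbow judgement stays with the analyst. Genes whose
maximum membership is below 0.7 stay unassigned.

# The synthetic world

`generate_genome_annotation()` → `plant_triplex_sites()` →
`simulate_expression()` build a fully known ground truth:

* 2 chromosomes x 200 kb at GC 0.41, 60 single/two-exon coding genes with
  ATG...stop ORFs of 150–400 codons drawn from a fixed biased codon table
  (the learnable coding signature), a few ncRNAs.
* 15 planted lncRNAs cycling through the five positional classes. Flank
  lncRNAs are rejection-sampled until genuinely non-coding under the
  built-in classifier; antisense-exonic ones overlap the partner's
  3'-terminal exon by 60–100 bp and extend into redrawn flank sequence —
  a pure reverse complement of biased CDS would (realistically) trip the
  Fickett filter and make the ground truth unusable.
* Five decoys, one per filter: < 200 nt; sense-exon overlap; strong planted
  ORF; all-zero counts (with ~80 features, any nonzero count already
  exceeds 1 TPM, so the expression decoy must be fully silent); and a
  fabricated RFAM hit. A whitelisted high-identity RNAcentral hit on one
  true lncRNA exercises the manual-rescue path.
* Planted TFO/TTS pairs: polypurine tracts (25–35 nt, G >= 0.4) written
  into promoters of genes on another chromosome than their TFO-carrying
  lncRNA (so the planted interactions are trans), with the reversed tract
  (R motif, antiparallel identity pairing) written into the lncRNA.
* Counts: negative binomial (dispersion 0.05) around condition means for
  the design C0.1, 0.025, R3, R6, R10 x 3 replicates (n = 15).
  Growth-associated genes follow a monotone log2FC ramp (|log2FC| 1–3 at
  the slowest growth); correlated (lncRNA, gene) pairs mix a z-scored ramp
  with an orthogonalised quadratic profile at amplitude 1.5 log2 units to
  target Pearson rho = ±0.8; lncRNA baselines (~40) sit below coding
  baselines (~300).

What a green test does establish: coordinate arithmetic, filter logic,
classification rules, triplex window semantics, context priorities, label
precedence, sign and approximate magnitude of planted correlations, and
seeded determinism end to end. What it does not: performance on real
libraries — the generator has no mapping artefacts, no repetitive or
sub-telomeric regions, no isoform ambiguity, no batch effects, and its
noncoding sequence is i.i.d. rather than genomic. Headline counts from real
data (how many lncRNAs a genome yields, how many triplex interactions) are
properties of those data and are not asserted anywhere in the test suite.

# Known limitations

* The triplex search targets motif-level agreement with the established
  tool family, not bit-exact output parity (no thermodynamic scoring, no
  duplicate-handling quirks).
* Fickett tables are the classic published constants; no independent
  reference implementation exists in the build environment, so tests check
  a second, independently coded evaluation rather than an external tool.
* The normalisation is a monotone library-size correction, not a true
  variance-stabilising transform; for publication-grade DE or VST use the
  dedicated external packages and feed the matrix in.
* `maximal_windows` is O(segment^2) within segments delimited by long error
  runs; adversarial inputs (hundreds of kb without three consecutive
  pyrimidines) would be slow, though no genomic sequence looks like that.
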