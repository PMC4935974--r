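---
title: "Models and methods: RBP binding and RNA regulation with rbpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: RBP binding and RNA regulation with rbpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rbpkit implements the integrated analysis used to characterize how an
RNA-binding protein (RBP) — the motivating systems are the ALS-associated
proteins TAF15, FUS and TDP-43 — binds the transcriptome and what that
binding does to RNA metabolism. This vignette documents the models, their
assumptions, the tunable parameters and the numerical decisions, in the
order the pipeline runs them.

## CLIP-seq cluster calling

CLIP-seq yields aligned read intervals marking in vivo protein-RNA
contacts. The package consumes non-redundant aligned reads (PCR
duplicates removed upstream; adapter trimming and alignment are outside
scope) and calls binding clusters in three steps:

1. **Candidate regions** are the maximal intervals of contiguous non-zero
   read coverage within each pre-mRNA span, on the same strand. CLIP
   libraries are stranded, so every overlap operation in the package is
   strand-matched.
2. **Background rates** are reads per nucleotide, computed at two scales:
   transcriptome-wide (reads overlapping any pre-mRNA over the summed
   pre-mRNA lengths) and gene-specific (reads overlapping the gene over
   its span length). The per-nucleotide parameterization makes the
   Poisson mean of a candidate simply rate × length. Reads spanning two
   genes count once transcriptome-wide and once per gene.
3. **Significance**: a candidate with k overlapping reads (≥ 1 nt
   overlap) is significant iff P(X ≥ k) < α/M under *both* rates, with
   X ~ Poisson(rate × length), α = 1e-4 by default, and M the total
   number of candidates tested. The dual test suppresses two failure
   modes at once: highly expressed genes would otherwise litter the
   transcriptome-wide test, while near-silent genes would pass the
   gene-specific test on a couple of reads.

M is the Bonferroni multiplicity unit. Candidates-tested is the standard
choice; a per-gene correction was the plausible alternative, but it makes
the threshold depend on gene count rather than on tests performed.

Assumptions: reads are independent draws from the background (no
crosslink-site or fragment-length structure), and pre-mRNA boundaries are
correct. Both fail gently — pile-up structure inflates candidate counts,
which only makes the Bonferroni correction more conservative.

## Genic region annotation and enrichment

Each gene model carries exons, UTRs and derived introns (span minus
merged exons). The "exon" region class is exonic space minus UTR space,
so exon / 3'UTR / 5'UTR / proximal intron / distal intron partition the
gene body; intronic positions are proximal when closer than 500 nt to an
exon-intron boundary. Clusters are assigned iteratively, exon first, then
3'UTR, 5'UTR, proximal and distal intron; a cluster overlapping no
same-strand gene is `unassigned`. For intronic clusters the 500-nt rule
is evaluated from the nearest cluster edge to the nearest boundary of the
host intron (the measuring point is a package decision; only the 500-nt
constant is externally fixed). A cluster spanning several same-strand
genes counts as a target of each — the conservative choice for target
definition.

Binding preference per region is log2(F_CLIP/F_region): the fraction of
clusters assigned to a class over the fraction of annotated nucleotides
in it. Both fraction vectors sum to 1 by construction (a test asserts
this to 1e-9); a class with clusters but zero annotated space is an
error, not an infinity.

## k-mer motif analysis

Rather than heuristic de novo motif discovery, the package scores the
exhaustive k-mer space (k configurable, default 6): exact, deterministic
and sufficient for all downstream uses of the motif. Cluster sequences
are compared against **region-matched background clusters** — for each
real cluster, one interval of identical length placed uniformly at random
in the annotated space of the same region class — so base-composition
differences between regions cancel. Enrichment per k-mer is

    percent enrichment = 100 × (f_real − f_background) / f_background,

with windows containing masked or ambiguous letters skipped, and k-mers
absent from the background reported as undefined (NA) rather than
infinite. Seed-containing k-mers (e.g. all 6mers containing GGUA) are
compared to the rest with a two-sample two-sided Kolmogorov-Smirnov test.
Positional histograms count motif-start offsets relative to cluster
centers in transcript orientation (±500 nt, 10-nt bins, floor division),
normalized to total matches; motif matching is exact on the sense strand
with IUPAC degeneracy supported.

## RBNS

RBNS selects a random 20-mer RNA pool with a recombinant protein at
0/5/20/80/320 nM; sequence specificity appears as k-mer enrichment

    R = f_pulldown / f_input

with significance at Z ≥ 2, where Z standardizes R over all 4,096 6mers
using the population standard deviation. k-mer counting is restricted to
the random region (flanking primers are excluded by construction).
Analysis uses the concentration with the highest overall enrichment,
defined here as the maximum single-6mer R (the definition is a package
decision; ties break toward the lower concentration, where specific
binding is expected to dominate).

**Motif logos** are built iteratively: take the most enriched significant
6mer, give it weight R − 1, mask every occurrence (the union of
overlapping occurrences) in both pools, recompute enrichments on the
masked reads, repeat. Accepted 6mers are aligned to the seed of an
existing logo at the offset (−5..+5) minimizing mismatches, overhangs
excluded; more than 2 mismatches starts a new logo. PWM columns are
weight-weighted nucleotide frequencies; each logo's proportion is its
share of summed weights.

Two numerical decisions matter here:

- **Stopping rule.** Candidate membership is fixed once, at the initial
  Z ≥ 2 over all 6mers; the masking iteration only orders and weights
  those candidates, ending when none remain or the best remaining
  recomputed R has fallen to 1 (its apparent enrichment fully explained
  by already-masked words). Re-testing significance against the masked
  distribution itself cannot terminate sensibly: the maximum of ~4,096
  standardized values always sits ~3 s.d. above whatever distribution
  remains (and masking depletes pulldown windows faster than input
  windows, drifting all remaining R upward), so that variant consumes
  nearly the whole 6mer space on featureless data. With fixed membership
  the iteration count is bounded by the significant-set size (~100 on a
  pure-noise pool, by construction of Z).
- **Alignment degeneracy.** Because overhangs are excluded from the
  mismatch count, a 1-nt overlap at offset ±5 with a matching letter
  counts as zero mismatches, so in practice almost every accepted 6mer
  joins the first logo. The dominant logo and its PWM around the true
  motif are unaffected (weights R − 1 concentrate on the real signal),
  but multi-logo separation is weak under this alignment rule — a known
  limitation.

## mRNA decay kinetics

Under transcription shutoff, first-order decay gives
N(t) = N(0)·e^(−λt), so ln RPKM is linear in time. Per gene, ordinary
least squares of ln(value) on hours yields λ = −slope,
t1/2 = ln(2)/λ, and R² (the squared correlation — identical to the
regression R² for a simple linear fit). Genes enter downstream analysis
only if λ > 0 and R² > 0.6 (strict), the filter that suppresses genes
whose expression does not actually decay. Numerical choices: zero RPKM
values are replaced by a pseudocount of 0.01 before the log (one zero
tolerated; more makes the series unusable), genes with RPKM ≤ 1 at t = 0
are excluded as not expressed, and fits use unnormalized RPKMs (no
global scaling is applied; none is defined for this design).

The quality control is a within-gene shuffle: time labels of each gene's
values are permuted (simple uniform permutation, identity allowed,
seeded), fits recomputed, and the real and shuffled R² distributions
compared by KS. On decaying data the distributions separate sharply; on
time-independent data they coincide — both behaviors are asserted in the
test suite.

Stability calls compare conditions gene-wise:
log2(t1/2 knockdown / control) > 1 is stabilized, < −1 destabilized,
otherwise unchanged; genes failing the inclusion filter in either
condition are unevaluable rather than silently dropped. Requiring
inclusion in both conditions is a package decision (the alternative —
filtering on one condition only — reports ratios of unreliable fits).

## Gene-set statistics

- Significant DE genes: |log2FC| ≥ log2(1.5) AND adjusted P < 0.05. The
  fold-change inequality is ≥; a "<" here would select the unchanged
  genes, contradicting every downstream use.
- Overlap of two gene sets: hypergeometric upper tail over the expressed
  background (RPKM > 1 in the matched control); subsets are validated,
  not coerced.
- Binding vs regulation: 2×2 Fisher's exact test over the expressed
  universe, two-sided by the conventional rule (sum of tables with
  probability ≤ observed). Base R's `fisher.test`/`phyper` provide the
  distributions; the test suite checks both against full enumeration
  oracles (backgrounds ≤ 15 and tables N ≤ 40).
- Paired log2 changes: OLS of B on A restricted to the both-significant
  intersection (the all-genes mode is also exposed).
- Long-intron comparison: per-gene summed intron length (maximum also
  available), two-sided Wilcoxon rank-sum between sets; intron-less
  genes count 0 and degenerate all-equal comparisons are reported as not
  applicable. The rank-sum test is a package choice; no specific test is
  externally fixed for this comparison.
- Splicing events: |Sep| > 0.5 and q < 0.05, strict as printed, with
  positive Sep marking inclusion.
- Term enrichment: per-term hypergeometric tests with
  Benjamini-Hochberg adjustment across terms; raw P values are kept
  alongside q values since the adjustment is a package addition to the
  bare hypergeometric procedure.

## The synthetic-data generator

Every generator is a pure function of its configuration and seed (same
seed, identical bytes — asserted in tests), and each emits a truth table
sufficient to score the downstream stage without inspecting generator
internals.

- **Genome**: 40 genes laid end to end on one chromosome, alternating
  strands, 2–5 exons of 150–300 nt, introns of 400–2,000 nt, 100/250-nt
  UTRs inside the terminal exons, 10% of genes carrying one 50-kb intron
  (to exercise the long-intron analyses), i.i.d. sequence at 50% GC.
  Null-calibration runs scale to 100 genes (~1 Mb of pre-mRNA).
- **CLIP**: 20,000 reads of 40 nt from a mixture — per-nucleotide weight
  1 across pre-mRNA, plus 50 extra weight units per site nucleotide over
  20 planted 50-nt sites with GGUAAG written at each center (sense
  strand). Enrichment 0 gives the exact uniform null used for
  false-positive calibration.
- **RBNS**: input reads uniform over {A,C,G,U}^20; pulldown at
  concentration c resamples fresh random reads with weight
  1 + a(c) × (motif occurrences, overlaps counted), a(0 nM) = 0,
  defaults a = (0, 1, 4, 10, 6) peaking at 80 nM — a linear-in-count
  weight, the simplest monotone binding model, chosen so the expected R
  is exactly derivable by enumeration (the test suite does this on an
  8-mer analogue and checks the generator against it). 100,000 reads per
  library.
- **Decay**: 500 genes, control half-lives uniform on 3–7 h, times
  0–10 h in 2-h steps (six points spanning ~2 half-lives of the median
  gene), t = 0 abundance log-uniform on 5–500 RPKM, multiplicative
  log-normal noise with σ = 0.1; 5% of genes stabilized ×4 and 5%
  destabilized ×0.25 in the knockdown.
- **DE tables**: 5,000-gene background, 300 significant genes per table
  with 30% shared; shared effects coupled with configurable sign and
  magnitudes ≥ log2(1.5).

What the generator does **not** emulate: sequencing error, crosslink
biochemistry and fragment-length structure in CLIP, position-dependent
nucleotide bias or secondary-structure selection in RBNS, count-level
(mean-variance) noise in RNA-seq, or genome-scale annotation complexity
(overlapping genes, many isoforms). Passing tests therefore demonstrate
that the statistics recover what their models assume at realistic
desk-scale sizes — not that those models are robust to every artifact of
real libraries.

## Problem sizes and runtime

Default sizes (above) keep the full test suite and the acceptance script
in the minutes range on a single core: cluster-null calibration uses 100
seeds of 10,000 reads on the 100-gene genome, RBNS recovery uses 100,000
reads per library with 20 null seeds, decay recovery uses 500 genes.
These are the sizes at which the recovery targets (≥ 95% site recovery,
top-R motif rank, < 10% median half-life error) are asserted.

## Known limitations

- Single-isoform gene models; multi-isoform region conflicts are handled
  only through the union-then-priority rule.
- The logo alignment rule merges most accepted 6mers into one logo (see
  above); interpret per-logo proportions accordingly.
- The KS comparison of seed-containing 6mers is underpowered when the
  background cluster set is small (many 6mers undefined); the paired
  RBNS/CLIP figure-scale analysis needs larger cluster sets than the
  default simulation produces.
- Exact Fisher/hypergeometric P values are conservative and discrete on
  small universes; the null-uniformity test uses large marginals for
  that reason.
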