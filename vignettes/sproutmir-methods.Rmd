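---
title: "Methods: small-RNA profiling and miRNA regulatory networks in tea sprouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA profiling and miRNA regulatory networks in tea sprouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`sproutmir` reimplements, as a tested and reusable pipeline, the
computational analysis of a developmental small-RNA study in tea
(*Camellia sinensis*) sprouts: five tissues sampled down a growing shoot
(bud, first and second leaf, younger and older stem — `Bud, L1, L2, S1, S2`)
with three sequencing libraries each. The stages are:

1. **Preprocessing** — adapter trimming, quality and length filtering,
   collapsing reads to unique *tags* with per-library counts, and annotation
   of structural RNA (rRNA/tRNA/snRNA/snoRNA), sense-strand exon and repeat
   tags, leaving genome-mapped *clean* tags.
2. **miRNA identification** — known miRNAs by Hamming-distance matching
   (at most 2 substitutions) against a mature catalog; novel miRNAs by
   folding genomic flanking windows of unannotated clean tags and applying
   hairpin criteria.
3. **Expression** — TPM normalization (`count / library clean-tag total x
   10^6`), replicate correlation, differential expression, tissue-specific
   classification, trend profiles over ordered stages, and the qPCR
   `2^-ddCT` fold change.
4. **Target prediction** — the plant rule set for ungapped miRNA/mRNA
   duplexes with position-specific mismatch scoring (G:U wobble = 0.5
   mismatch) and a duplex/perfect MFE ratio filter.
5. **Enrichment** — upper-tail hypergeometric tests against a genome
   background, Benjamini–Hochberg FDR per namespace.
6. **Network** — miRNA–mRNA edges by Spearman rho <= -0.5 (p < 0.05),
   mRNA–metabolite edges by Pearson |r| > 0.9 (p < 0.05), and extraction of
   miRNA → TF-mRNA → metabolite triplets.
7. **Synthetic data** — a generator that plants all of the structure the
   pipeline is supposed to recover.

# Tunable parameters and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| adapter-trim mismatches | 1 | subs | deterministic exact-prefix search; no trimmer was prescribed upstream |
| insert length window | 18–30 | nt | the plant sRNA size range retained for tag statistics |
| mean base quality | >= 20 | Phred | conventional Q20 floor; configurable |
| known-match distance | <= 2 | subs | the catalog search allows two mismatches |
| hairpin MFE | <= -18 | kcal/mol | brackets the reported novel-precursor energy range |
| precursor length | 65–400 | nt | brackets the reported precursor length range |
| mature pairing | >= 14 paired, <= 6 consecutive unpaired | bases | standard plant-hairpin plausibility screen |
| DE thresholds | p < 0.05, abs(log2FC) >= 2 | — | the study's stated DEM cutoffs |
| fold-change pseudocount | 0.01 | TPM | avoids infinities for zero groups, preserves ordering |
| trend step fold | 1.5 | ratio | the trend tool's unit convention is not reproducible; 1.5 is a conventional step threshold and configurable |
| presence rule | count >= 1 in >= 2/3 replicates | — | our choice; none was stated |
| enrichment cutoff | q <= 0.05 | BH FDR | the stated "FDR <= 0.05" / "Q value <= 0.05", treated as the same BH threshold |
| network thresholds | rho <= -0.5, abs(r) > 0.9, p < 0.05 | — | the stated filters; note at n = 5, Pearson p < 0.05 alone already implies abs(r) > 0.878, so the 0.9 rule dominates |

# The folding provider

Every energy in this package comes from one pluggable provider. The default
is a Nussinov-style dynamic program minimizing the sum of per-pair energies
GC = -3, AU = -2, GU = -1 kcal/mol with a minimum hairpin loop of 3, and a
deterministic traceback that prefers pairing the 5'-most base. This is
deliberately *not* a nearest-neighbour thermodynamic model: all MFE-derived
rules here are thresholds (hairpin acceptance) or ratios (the 60% duplex
rule), which are well defined as long as one provider is used consistently.
Functions accept a `fold_fun` argument with the same `(structure, mfe)`
contract, so an external thermodynamic engine can be substituted run-wide.
The default provider is verified against exhaustive enumeration of all valid
structures for sequences up to 12 nt, and satisfies `mfe <= 0` and
monotonicity in stem length.

# Target-rule interpretation

The duplex is ungapped and antiparallel; position *i* counts from the miRNA
5' end. Weights: mismatch 1.0, G:U wobble 0.5, Watson–Crick 0. The six
rules: total weight <= 4; no run of >= 3 consecutive non-WC positions
("no more than two adjacent mismatches"); no two consecutive non-WC
positions inside positions 2–12; positions 10–11 strictly Watson–Crick;
weight over positions 1–12 <= 2.5; duplex/perfect MFE ratio >= 60%.
Two readings were genuinely open and are configuration switches:

* whether G:U counts as non-WC inside the adjacency/position rules or only
  in the weighted totals — the strict reading (wobble is non-WC everywhere)
  is the default;
* position counting is taken 5'→3' on the miRNA, the convention of the
  plant target-prediction literature.

Duplex energy of a scored site sums pair energies over the WC/GU positions
only — lost pairing is the penalty; no thermodynamic loop terms. The
consistent-provider requirement makes the 60% ratio meaningful.

# Differential expression

The original study used a count-based DE package we do not reproduce;
following the build contract, replicates are pooled by summation and each
miRNA is tested with a doubled one-sided Fisher exact test on the 2x2 table
(miRNA tags vs remaining tags) x (group A vs B), i.e. twice the smaller
hypergeometric tail, capped at 1. This preserves the study's thresholds
(p < 0.05, |log2FC| >= 2 on group-mean TPM with a 0.01 pseudo-TPM) while
being exactly testable: the p-value is cross-checked against direct
hypergeometric enumeration, and the statistic is antisymmetric under group
exchange and invariant to replicate order. No multiple-testing correction is
applied to DE, matching the study's raw p < 0.05. Note that with library
totals in the millions, the pooled exact test is extremely powerful: tiny
fold changes can be "significant", which is why the |log2FC| >= 2 filter
carries most of the selectivity.

# Trend profiles

For three ordered stage means, a step is +1 when the ratio (with 0.01
pseudocount) is >= 1.5, -1 when <= 1/1.5, else 0. The eight non-flat
signatures are indexed 0–7 in the fixed enumeration
(-1,-1), (-1,0), (-1,+1), (0,-1), (0,+1), (+1,-1), (+1,0), (+1,+1); flat
(0,0) is excluded. Classes: *down* = {(-1,-1), (-1,0), (0,-1)}, *up* =
{(+1,+1), (+1,0), (0,+1)}, *peak* = (+1,-1), *valley* = (-1,+1). The
original short-time-series tool's profile numbering cannot be mapped with
certainty, so class labels — not indices — are the comparable quantities;
the printed per-profile counts are aggregated through exactly this
classifier in the acceptance suite.

# What the synthetic generator emulates — and what it does not

`synthetic_config()` describes the whole toy study; `generate_reference()`
builds a genome with embedded hairpin precursors (one mature per 5' arm, no
star sequence), transcripts carrying planted target sites, a mature catalog,
structural RNA, annotation and TF lookup tables, and mRNA tissue profiles;
`simulate_reads()` draws negative-binomial counts around planted
tissue-profile means and writes 15 adapter-appended FASTQ libraries;
`simulate_metabolites()` makes each linked metabolite an affine transform of
its transcript's tissue profile (slope sign from the link, rescaled into a
5–85 mg/g range so contents stay non-negative) plus Gaussian noise.

Two constructions matter for exactness:

* planted abundances are defined as per-tissue **proportions**, so TPM
  normalization preserves the planted fold steps exactly; the planted trend
  and DE ground truths are therefore derived, not merely intended;
* every planted site is re-scored with the target rules and every planted
  precursor re-folded and checked against the hairpin criteria at
  generation time, so the ground truth is valid by verification.

The generator does **not** emulate sequencing errors, isomiRs, genome
repeat families, multi-locus miRNA families, or realistic transcriptome
complexity. A green recovery test therefore establishes that the pipeline's
logic inverts the generator's stated world — not that it would match a real
study's catalog sizes or mapping rates, which depend on the deposited
libraries and are out of desk-scale reach.

Default noise levels are the stated world: NB dispersion 0.05 (low but
non-zero overdispersion; the zero limit gives exact recovery tests),
metabolite noise 2 mg/g (small against the ~80 mg/g planted dynamic range,
as technical replication of LC-MS quantification typically is), step fold 6
(one planted step = log2FC 2.58, clear of the DE threshold of 2). Exact
trend-signature recovery is asserted in the zero-dispersion limit; at
default dispersion a flat step (true ratio 1.0) occasionally crosses the
1.5-fold threshold, which is sampling noise behaving as designed.

# Numerical choices

* Hypergeometric tails use log-stable `phyper`; tests verify exact
  agreement with enumeration of all draws for backgrounds up to 25.
* The BH step-up is written out (sorted `cummin` of `p * m / j`, capped at
  1) and checked against an independent implementation; FDR is applied per
  namespace since categories are reported separately.
* Spearman p-values use the t-approximation by default; the exhaustive
  permutation null (exact and cheap at n = 5) is available and the two are
  verified to agree on keep/drop decisions at the default thresholds.
* Known-match ties are broken by minimal distance, then lexicographically
  smallest reference id; the fold traceback prefers 5'-most pairing; the
  modal tag length takes the smallest length on ties — all chosen to make
  every output deterministic.
* Coordinates are 1-based inclusive in all user-facing tables.
* Degenerate inputs fail loudly: zero library totals, constant profiles
  (skipped with a message in correlation stages; `NA` in replicate
  correlation), a miRNA whose perfect duplex has zero energy fails the
  ratio rule, hypergeometric bound violations are errors.

# Known limitations

* Exact-substring genome matching (both strands, multi-mapping retained) is
  an index-free desk-scale design; it is quadratic in genome size times tag
  count and not meant for a 3-Gb genome.
* The simplified pair-energy model understates stacking effects; hairpin
  acceptance is calibrated to bracket plausible plant precursors under this
  model, not to reproduce thermodynamic energies.
* The pooled Fisher DE test ignores biological replicate variance
  (replicates are summed); it matches the build contract but is not a
  substitute for a dispersion-modelling DE engine on real data.
* TF annotation is a lookup-table join; the similarity search that produced
  such tables originally is out of scope.
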