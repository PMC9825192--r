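---
title: "Methods: from histone-mark loss to splicing change"
author: "chromsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from histone-mark loss to splicing change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromsplice reimplements, as a tested pipeline over synthetic data with
planted ground truth, an integrative analysis linking knockdown of a
chromatin remodeler to loss of H3K36me3 over gene bodies and, downstream,
to altered alternative splicing. This vignette documents the statistical
models, the parameter choices and their rationale, what the synthetic data
do and do not emulate, and the numerical decisions a maintainer would want
written down.

## Peak harmonization

Peak sets per sample are harmonized with three rules. Narrow-mark peaks
(H3K4me1/2/3, H3K27ac) closer than 350 bp are merged, reading "closer
than" strictly: a gap of exactly 350 bp does not merge, while touching or
overlapping peaks always do; merging is transitive (`merge_close()`).
Broad marks (H3K36me3, H3K27me3) are not merged. Two replicate peaks are
*common* when their overlap is at least 50% of the shorter peak's length
("at least", so equality passes), and the union of their coordinates is
kept; peaks qualifying with several partners collapse by connected
components over the qualifying-pair graph (`common_peaks()`). For three or
more samples, pairwise commonality is folded left-to-right in sample order
(`common_peaks_all()`); only replicate pairs have a canonical order, so the fold order is a declared convention. Blacklisted peaks are
removed whole, never trimmed.

Peak-to-gene assignment conventions vary across annotation tools; the default here is conservative and reproducible: a peak is assigned to every
gene whose span or TSS ± 2 kb window it overlaps, with multi-assignment
allowed and the window configurable.

## Chromatin states

Mark tracks are binarized in 200 bp bins by a Poisson upper tail: a bin is
"on" when `P(X >= c) <= 1e-4` under the genome-wide mean rate, the standard ChromHMM preprocessing, declared in the configuration. A
K = 10 state model is then fit by Baum–Welch on product-Bernoulli
emissions: each state emits the M binary mark calls independently.
Initialization is a seeded k-means on bin patterns for the emissions and
near-uniform jittered transitions; chromosomes are independent sequences,
with the initial distribution applied at each chromosome start. EM stops
at a relative log-likelihood gain below 1e-4 or 200 iterations, and the
log-likelihood trace is retained so monotonicity is testable. The E-step
and Viterbi recursions are implemented in C++ (scaled forward–backward);
K = 1 short-circuits to the closed-form Bernoulli MLE.

Segmentation defaults to per-bin argmax of the posterior
(forward–backward), with Viterbi available; either decoding is defensible for per-bin state calls, and both are tested. State labels are not learned.
`label_states_by_emission()` mirrors manual annotation with a fixed
decision list on the emission matrix — H3K4me3-positive states are
"transcriptional initiation", then H3K36me3 "transcriptional elongation",
H3K27me3 "repressed", H3K4me1/H3K27ac "enhancer", else "quiescent" — at a
presence threshold of 0.25, low enough that weak but genuine signal
states (for example partially covered gene-body edges) label by their
dominant mark. A hand-written YAML map can override the labels.

Per-state, per-mark contrasts count each sample's peaks in each state's
segments (a peak counts once per state however many segments it touches),
express condition totals as percentages of the mark's total over states,
and report control% − knockdown% with an equal-variance two-sample t-test
on the replicate counts. With two replicates per condition the t-test is
reported as computed, with a `low_n` caveat flag rather than being suppressed; when both groups are exactly constant the p-value is 1 (identical
means) or 0 (different), avoiding a spurious error on noiseless input.

## Metagene profiles and effect sizes

ChIP tracks are normalized to input by signal extraction scaling: bins
sorted by ChIP signal, cumulative fractions compared, background defined
by the index maximizing their difference, and scale factors equalizing the
totals over that background. When the difference curve is flat
(proportional tracks) the whole genome is background; a zero-signal input
falls back to total-count scaling with a warning.

Genes enter the metagene only if they pass the stringent filter: span of
at least 2 kb, no other gene within 4 kb (either neighbor closer
disqualifies both; overlap counts as negative distance), and no
opposite-strand gene overlapping the span. Each gene contributes 900
columns of log2((ChIP + 1)/(input + 1)) in 10 bp bins after SES scaling: 200
upstream, the body linearly resampled to 500 (bin-averaging available
behind a flag), 200 downstream, oriented 5′→3′; a pseudocount of 1 per
10 bp bin keeps the ratio finite (a declared choice). Genes
with no nonzero bin are dropped. k-means (k = 3, k-means++ with 10
restarts, seeded) clusters genes by TSS-proximal remodeler enrichment on
the raw log2 profiles — no per-gene scaling, because the clusters of interest separate by enrichment level, which scaling would erase — and cluster ids
are relabeled 1..k by decreasing mean enrichment so they are a function of
the data, not of initialization.

Paired effect sizes use Cohen's d on per-gene differences,
`d = mean(A−B)/sd(A−B)`, the difference-sd denominator implied by
"paired". Confidence intervals use the normal approximation
`SE(d) = sqrt(1/n + d²/(2n))` rather than noncentral-t inversion — simple,
standard, and adequate at n in the hundreds — at a Bonferroni-adjusted
per-bin two-sided level `(1 − 0.99)/n_bins`, so the profile's intervals
hold simultaneously at 99%. Zero-variance bins give signed-infinite d with
missing intervals; exactly identical matrices give d = 0.

## Differential binding

The consensus set is the union-merge of all samples' peaks retained where
at least two distinct samples overlap. The test stage is a documented
simplification of the DiffBind + DESeq2 pair: median-of-ratios
normalization over consensus counts, per-peak method-of-moments dispersion
shrunk toward a parametric trend `a1/mu + a0`, and a Wald test on the
knockdown-vs-control log2 fold change under the NB variance with BH
correction. No outlier filtering or posterior shrinkage is attempted;
acceptance is by simulation calibration, not numeric parity with DESeq2.
Two numerical choices matter: the shrinkage is arithmetic
(`0.1·mom + 0.9·trend`), because a log-scale blend explodes on the many
near-zero moment estimates two replicates produce and was measurably
anti-conservative; and a pseudocount of 0.5 guards the fold change at low
counts. Null calibration is checked at a 2 + 2 design; power on planted
4-fold depletions is checked at a 3-knockdown vs 2-control design,
typical of multi-clone knockdown experiments, with per-sample consensus-peak counts around exp(N(6, 0.5)) —
a 2 + 2 design cannot reach 90% sensitivity at 4-fold and dispersion 0.1
even with oracle dispersion, since the Wald statistic then sits near 4.3
against a BH cutoff near 3.1.

## Alternative splicing

Events are extracted by pairwise transcript comparison within genes, per
the standard seven-type taxonomy: skipped exon (shared flanking
junctions, direct skip junction), retained intron (one transcript's exon
spans two consecutive exons of the other exactly), mutually exclusive
exons (non-overlapping cassettes sharing both flanking junction sites),
alternative 5′/3′ splice sites (junctions sharing one boundary, with the
alternative exons overlapping — strand decides which side is the 5′ one),
and alternative first/last exons (non-overlapping terminal exons sharing
the neighboring internal splice site; overlapping terminal exons that
share no site yield no event). Events are deduplicated by coordinates,
accumulating inclusion and exclusion transcript sets, which are disjoint
by construction. Inclusion conventions: the cassette carrier for SE, the
retention isoform for RI, the transcriptionally proximal cassette for MX,
the longer exonic form for A5/A3, the distal terminal exon for AF/AL.

PSI is inclusion TPM over total event TPM, undefined at zero abundance
and invariant to global TPM scaling. The differential test is empirical:
the null is the pool of absolute between-replicate PSI differences within
condition, stratified into deciles of event abundance
(log10 of total event TPM + 1), and the p-value is the add-one-smoothed
fraction of null values at least as large as the observed
|mean PSI_control − mean PSI_knockdown|. This is a reproducible,
conservative stand-in for the loosely documented interpolation scheme of the standard event-based splicing tool. Significance requires p < 0.05 *and*
|dPSI| > 0.2, the magnitude filter applied to the absolute value since
both signs are reported downstream. Junction-count-based testing is a complementary approach and a declared non-goal here. Because percentage denominators can legitimately be taken over all events or over classified events only, `event_type_summary()` reports percentages over classified events and leaves the denominator choice to the caller.

## RBP motif scanning

Motifs are position probability matrices regularized with a 1e-3
pseudocount and scanned as log-odds against a background distribution
(default: supplied per scan; the generator uses A/T 0.3, C/G 0.2). The
scanning threshold is the stricter of two cutoffs, treating the 95% similarity and 0.001 false-positive-rate settings as one joint rule:
relative score `S_min + 0.95·(S_max − S_min)`, and the smallest score
whose upper-tail probability under iid background is at most 0.001,
computed exactly by dynamic-programming convolution of per-position score
distributions discretized at 0.01 log-odds units (discretization error is
bounded by half a step per position). RNA motifs are applied to
sense-strand DNA with U≡T. Flanks are the 100 nt on each side of every
defining exon, reverse-complemented for minus-strand genes so sequences
read 5′→3′ on the transcribed strand; scanning only the alternative exon's flanks or also the constitutive ones are both found in practice, so all defining exons are scanned, with per-exon role flags.

## AP-MS interactors

Normalizing peptide intensities to an average abundance within each sample can be read per protein or per sample; the default here is global per-sample mean centering (`sample_mean`), because the per-protein reading forces every protein's cross-channel fold
change toward zero, contradicting the downstream computation; the literal
mode is retained behind a flag. Missing intensities are imputed as half
the sample minimum, standard label-free practice. Per peptide, fold
change is mean log2 IP minus mean log2 IgG over replicates; per protein,
the mean of its peptides' fold changes, with a two-tailed Welch t-test on
per-(peptide × replicate) log2 intensities — the observation unit is
declared, with the documented caveat that peptide observations within a
protein are not fully independent. A consequence of per-sample centering
worth knowing: a shift common to *all* peptides of a sample is
unidentifiable by design; enrichment is always relative to the sample's
typical protein. Single-replicate designs use per-peptide differences and
a one-sample t-test. Stringent interactors are significant (p < 0.05,
FC > 0) under both antibodies, with the bait excluded from the reported
set.

## Gene-set statistics

Overlap tests are exact hypergeometric upper tails (one-tailed), with the
odds ratio from the 2×2 table and a Haldane–Anscombe 0.5 correction only
when a cell is zero — the p-value always comes from the uncorrected
table. The default universe is the expressed protein-coding set (gene TPM
strictly above 2 in control means), matching the expressed-gene framing of such analyses; it is configurable. Over-representation over GMT collections BH-corrects across
terms at q < 0.05 and also reports the raw p < 0.01 custom-set rule.

## What the generator emulates, and what it does not

`sim_config()` defaults define the reference study conditions used by the
acceptance suite: 2 chromosomes × 5 Mb, 300 two-isoform genes (each
engineered to carry exactly one event, the seven types cycled), 80%
expressed, 60 remodeler-bound genes of which half lose gene-body
H3K36me3 in knockdown, 80 events shifted by |dPSI| = 0.35 (half placed in
losing genes), 2 ChIP and 3 RNA replicates, lognormal expression
(meanlog log 50, sdlog 0.8), PSI replicate noise 0.02, Poisson tracks at
2.0 per 10 bp bin inside peaks over a 0.2 background and a flat 0.25
input, 400 proteins with 20 interactors shifted 2 log2 units at 0.3 noise,
and a 0.4 motif-planting rate. This scale runs the full pipeline in about
a minute on one CPU; every artifact derives its own RNG stream from the
master seed plus a stable label, so adding an output never perturbs
another.

Architecture choices that make the planted biology recoverable rather
than merely present: peak placement and replicate jitter live on the
200 bp binarization grid (whole-peak shifts, mostly zero); track means
extend 200 bp beyond peak edges, emulating fragment-extension smear, so
segment boundaries do not flicker across replicates; minor
"noise" binding sites are intergenic; and H3K36me3 has two components — an
elongation-coupled body peak (from 1 kb past the TSS to the gene end)
that knockdown removes on losing genes, and a short promoter-proximal
peak retained in knockdown, reflecting initiation-coupled deposition.
That last component is what makes the loss *elongation-state-specific* in
the per-state contrast — the phenomenology this pipeline is built to detect; without it every
H3K36me3 peak lives in elongation states and the percentage difference
degenerates. "Gene body" throughout means the span minus that first
kilobase (`gene_bodies()`).

The generator does not emulate: read-level data (no FASTQ/BAM, tracks are
Poisson bin counts), fragment-length distributions beyond the fixed
200 bp pad, mappability or blacklist artifacts, more than two isoforms
per gene, correlated peptide effects across channels (intensities are iid
around channel means, which is exactly what makes the Welch null hold its
5% size — real AP-MS has peptide-level dependence that the documented
caveat covers), or motif occurrences beyond exact consensus plants.
Passing tests therefore demonstrate correctness of the statistical
machinery and recoverability of planted effects at realistic magnitudes —
not robustness to alignment artifacts, isoform complexity, or
between-laboratory variation in real data.

## Problem sizes and determinism

The test suite runs the end-to-end pipeline at the full reference scale
(50k bins × 6 marks, K = 10), HMM parameter recovery at 50k bins,
interval-algebra oracles on 100 random instances up to 500 intervals, NB
calibration at 10,000 peaks, and motif FPR calibration on 1e5 background
positions — about a minute total. All stochastic entry points take
explicit seeds and restore the caller's RNG state; rerunning any stage
with the same configuration is bit-identical.
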