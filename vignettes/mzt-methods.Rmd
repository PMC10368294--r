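---
title: "Methods: dissecting the maternal-to-zygotic transition from paired poly(A)+ and rRNA-depleted RNA-seq"
author: "mztseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting the maternal-to-zygotic transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztseq)
```

## The observation model

Early embryonic transcriptomes mix three processes that a single poly(A)+
library cannot separate: true abundance changes from zygotic genome
activation, true abundance changes from maternal mRNA degradation, and
poly(A)-tail length changes (cytoplasmic readenylation and deadenylation)
that alter oligo-dT capture without altering abundance. The package's
entire analysis rests on one observation model for a paired design:

* rRNA-depleted counts: `E[k_g] ∝ A_g(t) · len_g`
* poly(A)+ counts: `E[k_g] ∝ A_g(t) · c(L_g(t)) · len_g`

where `A_g(t)` is transcript abundance, `L_g(t)` the poly(A)-tail length in
nt, and `c(L) = L^h / (L^h + K^h)` a Hill-saturating capture probability
(defaults `K = 30` nt, `h = 2`). The Hill form is a smooth, monotone,
two-parameter stand-in for oligo-dT pulldown efficiency: zero for tailless
transcripts (replication-dependent histone mRNA), half-saturated at `K`,
asymptotically complete for long tails. Counts within a library are
compositional: each library is scaled to its sequencing depth, so absolute
abundance is only identified up to normalization — which is exactly why the
downstream analyses work on size-factor-normalized counts (differential
tests) or TPM (threshold screens), never raw counts.

Assumptions worth stating: capture depends on the tail only (no internal
A-stretch priming), both protocols see the same underlying RNA pool (the
libraries are built from splits of the same sample), and gene-level counts
are negative-binomially distributed around their expectations.

## The differential test

Every decision threshold in the pipeline consumes a two-group contrast on
counts. `nb_test()` implements a self-contained negative-binomial test:

1. **Prefilter.** Genes with fewer than `min_total = 10` reads summed over
   the tested samples are flagged and carry no p-value; the BH adjustment
   runs over tested genes only. This also keeps the asymptotic test away
   from the very-low-count regime where a chi-squared reference is
   unreliable.
2. **Normalization.** Median-of-ratios size factors over genes expressed in
   every sample, rescaled to geometric mean 1.
3. **Dispersion.** A single common dispersion maximizing the Cox-Reid
   adjusted profile likelihood over all tested genes (the adjustment
   `0.5·log Σ w_i` per gene/group compensates the plug-in of estimated
   group means). A per-gene option (`dispersion = "moment"`) shrinks
   method-of-moments estimates toward the common value with `prior_df`
   pseudo-degrees of freedom; with one sample per group a configured
   `prior_dispersion` (default 0.1) is used.
4. **Test.** A likelihood-ratio statistic (two group means vs one common
   mean, dispersion held fixed) against chi-squared with 1 df.

A Wald z-statistic with raw method-of-moments dispersions was evaluated
first and rejected: at `n = 3` per group it rejects a true null at roughly
0.08 instead of 0.05 when the dispersion is 0.1 (the moment estimator is
noisy and its error enters the SE multiplicatively), while a t reference
with `n_A + n_B - 2` df over-corrects to below 0.01. The Cox-Reid/LRT
combination is calibrated in both the Poisson and overdispersed regimes —
the acceptance suite asserts the type-I rate at `n = 3` vs 3 inside the
95% binomial interval around 0.05 for dispersions 0 and 0.1.

Fold changes are `log2` ratios of normalized group means floored at 0.5
normalized counts; the floor only prevents division by zero for genes
absent from one condition (a de novo gene has no egg counts) and is not a
general pseudocount. TPM-space screens (oscillation, stability) use an
additive pseudocount of 0.1 TPM instead, a separate, declared choice.

The small tests are likewise self-contained and oracle-checked in the test
suite: Benjamini-Hochberg as the literal step-up, the Wilcoxon signed-rank
test with exact enumeration (via the generating function over the
doubled mid-rank grid) up to 25 non-zero differences and a tie- and
continuity-corrected normal approximation beyond, and the Pearson
chi-squared statistic with `k - 1` df for 2 × k tables (zero expected
cells are an error; callers pool categories).

## Activation calling

Exonic activation at timepoint `t` requires, in the rRNA-depleted contrast
against the egg: adjusted p < 0.05, fold **strictly** above 2, and TPM > 1
at `t`. Poly(A)+ contrasts are refused for activation calling since tail
lengthening masquerades as upregulation there.

Intron signal detects re-activation of genes that already have a maternal
pool. Intron counts are pre-mRNA minus exon counts, clamped at zero
(counting noise at the table level can invert the difference; clamps are
counted and reported). Intronic RPKM uses the summed intron length and the
summed pre-mRNA library size; genes are kept if **any** sample reaches
RPKM ≥ 0.5 — exclusion requires failing everywhere, so a gene active at a
single timepoint stays testable. Exon and intron entries are stacked into
one table (`gene@exon`, `gene@intron`) and tested jointly, so the BH
adjustment spans both entry types; a maternal gene is re-activated when its
intron entry is significantly up.

Per-gene categories use egg TPM gates: de novo zygotic below 0.5, maternal
at or above 1. The gap `[0.5, 1)` with activation evidence is an explicit
`ambiguous` category rather than silently joining either side.
Categorization at `t` uses evidence accumulated up to `t`, making the
per-timepoint category counts monotone in the way stacked-bar summaries
expect, and is total: every gene gets exactly one category per timepoint.

The 10-kb window scan bins gene-level counts by gene-span midpoint, scales
to RPM, and ranks `log2((rpm_t + c)/(rpm_egg + c))` with `c = 0.5` RPM.
Coordinates are parsed from GTF as 1-based inclusive and held 0-based
half-open internally; window tables are emitted in the half-open
convention.

## Clearance analysis

Per protocol, the first timepoint (scanning 2-7 h.p.f. in order) with
adjusted p < 0.05 and a decrease of **at least** 2-fold defines the
first-decrease time. Note the asymmetry, inherited from the source
thresholds: activation is strict (> 2), clearance inclusive (≥ 2); each is
applied where stated. The poly(A)+ time versus rRNA-depleted time matrix
summarizes the program: below-diagonal genes lost poly(A)+ signal before
losing the transcript — deadenylation preceding degradation.
`deadenylation_lead` (rRNA-depleted minus poly(A)+ time, in hours) is
defined only when both timings exist; genes never decreasing occupy a
terminal `never` bin so the matrix layout retains them.

Grouping: genes failing the oscillation filter (> 1.5-fold stage-to-stage
rise, strict, 0.1 TPM pseudocount, poly(A)+ trajectory) are excluded
first — in practice this removes zygotically rising transcripts, which are
not clearance candidates; then early (first poly(A)+ decrease at 2-4
h.p.f.) versus late (≥ 5); maternal genes with no decrease in either
protocol are stable; everything else (e.g. a decrease seen only in the
rRNA-depleted protocol) is excluded as unclassifiable.

The stable maternal reference set demands a poly(A)+ TPM ratio to egg
strictly inside `(1/1.25, 1.25)` at **all** of 4, 5, 6 and 7 h.p.f. and no
significant triptolide-vs-DMSO response (genes prefiltered from that
contrast count as unchanged). With a strict band this tight, even a
well-behaved stable gene is excluded when sampling noise or Benjamini-
Hochberg spillover from the many true triptolide responders catches it;
under the generator's defaults the false-exclusion rate sits just under
10%, dominated by the lowest-expressed maternal genes.

Transcription dependence: per gene, log2 TPM fold changes to egg (0.1
pseudocount) are computed at the treatment timepoint under triptolide and
under DMSO; the per-gene paired differences are tested with the Wilcoxon
signed-rank test across the early- or late-cleared group (at least 5 genes
required). Positive median differences in the rRNA-depleted protocol mean
stabilization — the group's clearance requires zygotic transcription. The
"compared to egg" baseline is the unfertilized egg, not a pool of the
first two timepoints.

## Histone metrics

Class proportions are TPM shares per class per timepoint (replicate means)
against all quantified genes, computed on the rRNA-depleted protocol —
replication-dependent histone mRNA are not polyadenylated and are
invisible to poly(A) selection. Net activation sums, within class, each
gene's RPM increase over a baseline (the max of the first two timepoints,
both pre-activation; a first-only mode covers designs whose second
timepoint already post-dates activation), counting a gene at `t` only
while its RPM is at least 2× baseline — the gate is re-evaluated at each
timepoint (the literal reading; a once-qualified-always-counted variant
would differ only for genes hovering at the gate). Trimmed normalization
uses, as RPM denominator, the summed counts of genes whose totals lie
inside the inclusive 10th-90th percentile band, so a handful of runaway
histone counts cannot deflate everyone else's RPM.

## Stage specificity and GO enrichment

A gene is stage-specific if its stage-mean TPM drops below 1 somewhere,
exceeds 5 somewhere else, and differs significantly from egg at some stage
(poly(A)+ libraries). Peak-stage ties break toward the earliest stage — a
declared convention. Enrichment per GO term is a 2 × k chi-squared test of
annotated/not-annotated across k stage groups (the canonical layout pools
the gastrula timepoints into one group, giving k = 5 and 4 df), BH-adjusted
across tested terms; terms with a zero expected cell are skipped with a
reason rather than fudged. GO maps are inputs: annotation transfer (e.g.
from best protein-database hits at E < 1e-5) happens upstream of this
package. Transcription-factor curation is reduced to a reproducible
filter — DNA-binding GO terms plus an egg-expression floor and a 5-fold
egg-over-later-stages enrichment — in place of manual review.

## Codon adaptation

The reference table counts codon usage over the top-100 egg-expressed
(rRNA-depleted TPM) maternal mRNA without clearance evidence. Unobserved
codons receive a 0.5-count floor before relative adaptiveness
`w_c = f_c / max(f_synonyms)` so every `w` is positive; a family with no
observed member is uninformative and sits at `w = 1` throughout. CAI is
the geometric mean of `w` over a CDS excluding the initiation codon, stop
codons, and the single-codon amino acids Met and Trp, whose `w ≡ 1` would
only dilute the signal — the convention of the classical CAI formulation.
CAI is order-invariant and the CAI of a concatenation lies between the two
parts' values (weighted geometric mean), both asserted as properties.
3'UTRs are emitted only when strictly longer than 20 nt, reverse-
complemented to sense orientation for minus-strand inputs, split into
cleared (foreground) and stable (background) sets for external motif
discovery.

## miRNA discovery and targeting

The homology scan is seed-and-extend: every exact 7-mer of a reference
mature miRNA anchors a full-length ungapped alignment on both strands;
alignments with at most 2 mismatches are reported (any hit sharing one
exact 7-mer is found — with ≤ 2 mismatches over a 22-mer a 7-mer seed is
guaranteed by pigeonhole), and overlapping hits keep the fewest-mismatch
representative. E-value machinery is deliberately replaced by explicit
mismatch counts: they are the operative, reproducible criterion.

Folding is a Nussinov maximum base-pairing dynamic program over
`{AU, UA, GC, CG}` plus G:U wobble, minimum hairpin loop 3, no
pseudoknots, with a deterministic traceback (pair the opening base with the
smallest admissible partner whenever pairing attains the optimum). It
stands in for thermodynamic folding on purpose: it is self-contained and
verifiable against exhaustive enumeration (asserted for all lengths ≤ 12 in
the tests), at the cost of ignoring stacking energetics — users needing
free-energy structures should refold candidates externally. Max-pairing
structures can recruit low-complexity flanks into spurious pairs, one
reason candidate evaluation restricts attention to pairs that involve the
mature sequence: a candidate passes when at least `stem_min = 14` mature
positions pair outside the mature region, with the partner direction
assigning the 5p/3p arm. A register offset relative to a blunt duplex is
recorded as a descriptive annotation of non-canonical processing geometry
and never used to reject — duplicated matures on both arms of one long stem
are reported per hit, not merged.

Candidates must sit in transcripts significantly activated over egg;
triptolide inhibition is annotated, not required, since a small maternal
contribution can coexist with zygotic transcription. Target prediction
anchors the reverse complement of the mature on exact 4-mers, classifies
every position as Watson-Crick, G:U (G opposite U/T, U opposite G), or
mismatch, and reports duplexes with paired fraction ≥ 0.85 — the numeric
surrogate for "extensive complementarity" in the cnidarian, full-length
targeting mode (bilaterian-style 6-8 nt seed matching is out of scope).
Stable-mRNA hits are reported separately as a specificity readout.

## The forward simulator

The generator is first-class code: every analysis above is validated
against its ground truth. Eight gene classes cover the biology the paired
design is meant to resolve: `stable_maternal`, `readenylated` (tail 12 →
70 nt after 0.5-1 h.p.f.), `deadenylated_only` (tail 70 → 10 nt at 2-4
h.p.f., abundance constant), `deadenylated_then_degraded` (tail drop at
2-3, decay from 5-6), `reactivated_maternal` (zygotic production from 4-5
that adds 20% exonic but 2× the gene's maternal abundance in intronic
signal), `de_novo_zygotic` (onset 2-4), `histone_like` (tailless,
intronless, clustered on one scaffold, early burst), `mirna_target`
(maternal, decayed from 5-6 by a zygotically encoded miRNA). Decay is
2^(-1.3) at its onset timepoint and 1.3 log2 units per hour after, floored
at 2% — so degradation is already a called decrease at onset. Late decay
(onset ≥ 5 h.p.f.) is transcription-dependent and suppressed in the
triptolide condition; tail dynamics are maternal and unaffected.
A `triptolide_null` switch generates the inhibited condition with no effect
at all, the null configuration for calibration.

Deliberate calibrations, chosen from the design rather than from data:

* Egg abundances are lognormal within class, normalized so the egg totals
  10^6 units (abundances are expected egg TPM) and so each maternal class
  carries egg mass proportional to its gene count. This makes the
  compositional drift of the libraries a property of the configuration,
  not of the particular seed.
* De novo zygotic amplitudes default to a **mean** of 0.15× the mean
  maternal abundance. The adenylated pool must stay maternal-dominated
  through gastrulation (total poly(A)+ drift within ~10%): a strict
  1.25-fold stability screen is only usable at all under that condition,
  which is also the condition the real embryo satisfies.
* Histone-like amplitudes are solved, not sampled: given every other
  class's trajectory, the class total at the peak timepoint is set to hit
  the configured transcriptome share (default one third), from a maternal
  starting share of 1.8%.
* `nb_dispersion` defaults to 0.005. Each library in the emulated design
  pools on the order of a hundred embryos, which averages out biological
  variability; replicate scatter is then close to Poisson with a small
  overdispersion. Calibration experiments pass dispersions explicitly and
  do not depend on this default.
* Counts are generated at the count-table level (no reads, no alignment);
  each matrix draws from its own seed-derived random stream
  (`sub_seed()`), so adding a matrix never perturbs the others. The exon
  table *is* the rRNA-depleted gene-level table for those samples (one
  sequencing event per library), and the pre-mRNA table adds independent
  intronic draws, making `exon ≤ premRNA` an exact invariant.
* Implanted mature miRNAs are composition-balanced (no base above 40%, no
  run above 5): with G:U wobble allowed, a near-homopolymer mature would
  spuriously "target" a large fraction of any transcriptome, unlike any
  curated miRNA. Re-activated maternal genes are forced multi-exon — the
  class is defined by intron-visible re-activation, and an intronless
  member would be structurally undetectable rather than analytically
  missed.

What the generator does **not** emulate — and therefore what passing tests
do not certify on real data: read-level artifacts (mapping ambiguity,
positional coverage bias, rRNA carryover), dispersion heterogeneity across
genes (the common-dispersion default matches the generator; real data
benefit from the `"moment"` option), partial or graded tail-length
distributions (tails are trajectories of point values, not per-molecule
distributions), isoform structure (one transcript per gene), larval
timepoints (the stage-enrichment 5-group layout arises only with later
stages supplied), and genuinely unannotated transcription (the window scan
is exercised through annotated genes binned by midpoint).

## Orchestration and reproducibility

`pipeline_config()` collects every threshold above with the study defaults;
it round-trips through YAML, and each stage (`simulate`, `de`,
`activation`, `clearance`, `cai`, `mirna`, `histone`, `stages`) reads its
declared inputs from a run directory and writes TSV/FASTA/JSON outputs, so
stages are independently runnable with no hidden state. `run_demo()` runs
everything and writes a manifest (file list with MD5 checksums, config
hash, package version); a rerun with the same seed is byte-identical. A
thin command-line wrapper lives at `inst/scripts/mzt-pipeline.R`
(`--config`, `--outdir`, `--seed`, `--set key=value`, `--log-level`; exit
code 2 for missing inputs, 3 for invalid configuration).

Validation scale: the bundled acceptance experiments run at 2,000 genes,
9 timepoints, 2 replicates per library and 10^6 reads per library — about
a minute of computation — with calibration sub-experiments at 1,000 null
genes and 200 label shuffles. The same quantities are recomputed from
scratch by `scripts/acceptance.R` (see the README).

## Known limitations

The NB test's common dispersion is a deliberate simplification; strongly
heterogeneous dispersions call for the moment-shrinkage option or an
external DE engine. The stability and oscillation screens inherit the
source thresholds' sensitivity to sequencing depth: at low depth the strict
1.25-fold band excludes many truly stable genes. Nussinov folding
maximizes pair count, not stability, and can be fooled by low-complexity
context. Tail length is never estimated in nt — only capture-ratio proxies
are observable in this design. Small-RNA quantification, motif discovery,
annotation transfer and read alignment are out of scope by design; the
package starts from count tables, gene models and sequences.
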