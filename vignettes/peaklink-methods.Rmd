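---
title: "Methods: summit-window integration of chromatin accessibility"
author: "peaklink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summit-window integration of chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaklink)
```

# Scope and model

`peaklink` implements the comparative bookkeeping of a two-condition
chromatin accessibility study: ATAC-seq peaks called separately in a
vehicle- and a ligand-treated condition (the motivating system is
1,25(OH)₂D₃-treated human endometrial stromal cells) are compared at the
summit level, annotated to genomic features and genes, tested for
differential accessibility over a merged region universe, and intersected
with a transcription-factor cistrome and a differential-expression gene
list. Upstream read processing — trimming, alignment, peak calling — is out
of scope; called peaks, summits, and aligned cut-site intervals are the
inputs.

Every analysis operates on one coordinate convention: 0-based, half-open
intervals, as in BED. GTF input (1-based, inclusive) is converted on read
by subtracting 1 from starts, and converted back on write. Two intervals
overlap iff they share at least one base pair; bookended intervals
(`end == start`) do not overlap. This single convention is load-bearing:
every off-by-one ambiguity in the pipeline reduces to it.

## Summit-window overlap classification

Peak summits are single-bp positions of maximal signal. Each summit *s* on
chromosome *c* becomes the fixed window *[s − f, s + f)* with
`summit_flank` f = 100 bp, clipped at chromosome edges, so interior windows
are exactly 200 bp wide with the summit at offset 100. A summit of
condition A is **shared** iff its window intersects ≥ 1 window of condition
B, and **condition-specific** otherwise; the classification is symmetric in
definition but *not* in counts: with asymmetric peak sets, the number of
shared A-summits and shared B-summits may differ (several A-windows can
overlap one B-window). The summary therefore reports, per condition, the
shared and specific counts and the shared percentage of that condition's
own total. Percentages are rounded half-up to two decimals, so a ratio of
80.8559% prints as 80.86.

Overlap between interval sets is colocalization of coordinates; it is
deliberately not interpreted as evidence of a direct regulatory
interaction, and no enrichment statistic (permutation or otherwise) is
attached to it.

## Feature annotation and nearest-TSS assignment

Transcript models carry a strand, an exon list, optional CDS bounds, and
optional explicit UTR intervals; when UTRs are absent but a CDS is present,
they are derived as exon base pairs outside the CDS span, assigned 5′/3′ by
strand. Per transcript the derived feature intervals are:

* promoter: TSS ± `promoter_flank` (2,000 bp each side);
* 5′UTR, 3′UTR: as above;
* exon: all exon bp (coding or not);
* intron: gene span minus exons.

A peak is classified by its **midpoint** `floor((start + end) / 2)`: every
feature interval containing the midpoint is collected, across all
transcripts, and the highest-priority class wins, in the order
promoter > 5′UTR > 3′UTR > exon > intron, with intergenic as the fallback.
Midpoint classification makes the six classes mutually exclusive and
matches the convention of peak-center annotation tools; any-bp overlap
classification would not partition. Three design points were genuinely
open and were fixed as follows:

* **Promoter sidedness.** "Within 2 kb of the TSS" is ambiguous about
  upstream-only versus symmetric. The symmetric TSS ± 2 kb definition is
  used (the common default of peak annotators), and `promoter_flank` is a
  parameter rather than a constant so either reading is available.
* **Anchor.** The region midpoint, not the region edges, anchors both
  classification and TSS distance. For 200 bp summit windows the midpoint
  is the summit itself.
* **Overlapping transcripts.** The winning class and the nearest gene are
  determined independently and may disagree (a peak can sit in gene X's
  intron while gene Y's TSS is closer); both are reported
  (`feature_gene` vs `gene_symbol`).

Gene assignment is by nearest TSS: among transcripts with
|midpoint − TSS| ≤ `tss_range` (100 kb), the minimal absolute distance
wins; ties break by absolute distance, then lexicographic gene symbol,
then transcript id, making the assignment deterministic under any input
order. The reported distance is signed in the transcription direction:
positive downstream of the TSS, negative upstream, regardless of strand.
No TSS in range yields a missing gene, not an error.

## Differential accessibility

The region universe is the union of both conditions' peak intervals merged
with `merge_gap` = 100 bp: intervals whose gap (next start minus previous
end) is ≤ 100 bp are joined — "within 100 bp" is read inclusively, so
touching intervals and intervals exactly 100 bp apart both merge.

The accessibility signal is the Tn5 insertion evidence: the first
`cut_width` = 9 bp of each read 5′ end (both ends for full fragments). No
+4/−5 Tn5 offset is applied — the cut-site definition here is the first 9
bp verbatim — and the extraction function exposes no hidden shift. A
library can be down-sampled to a fixed read count (`downsample_fragments`,
default target 100 million) for workflow parity with depth-normalized
processing; for desk-scale analysis the cheaper equivalent is the built-in
per-sample scaling.

Counts are cut sites overlapping each region by ≥ 1 bp, per sample. A cut
site can in principle touch two regions only if merged regions are closer
than `cut_width`, which the 100 bp merge gap rules out. Normalization
scales each sample's counts to a common total of 10⁷ in-region counts
("counts per 10 million in-universe"); this follows the same logic as
normalizing by read down-sampling — equalizing effective depth — while
being exactly reproducible.

Per region, `y = log2(normalized + 1)` (the pseudocount handles zero-count
regions), the effect is `log2fc = mean(y_treated) − mean(y_vehicle)`, and
the p-value is a two-sided **pooled-variance two-sample t test** on `y`.
The pooled (Student) form rather than Welch–Satterthwaite is a deliberate
choice for the 3-vs-3 replicate design this workflow targets: with n = 3
per group the Welch approximation is markedly conservative (empirical size
≈ 0.034 at nominal 0.05 even on exactly normal, equal-variance data),
whereas the pooled test holds its nominal size (≈ 0.050, reproduced by the
calibration test in this package's suite). The cost is the equal-variance
assumption, reasonable after common scaling and log transform. Degenerate
regions follow fixed conventions rather than producing NaN: identical
values in both groups give p = 1; a nonzero mean difference with zero
within-group variance gives p = 0.

P-values are Benjamini–Hochberg adjusted over all tested regions
(step-up with monotonicity, delegated to `stats::p.adjust`), and regions
are classed increased / decreased / unchanged by
`adj_p < dar_adj_p` (0.05) **and** `|log2fc| ≥ dar_abs_log2fc` (1.0), with
the sign of `log2fc` choosing the direction. The source study does not
state its differential test or thresholds, so its particular DAR counts
(110 increased / 369 decreased) are not a reproduction target; the test,
thresholds, and normalization here are fully specified precisely so that
results from this package are reproducible. A negative-binomial GLM with
dispersion shrinkage (DESeq2/edgeR style) is intentionally out of scope —
at three replicates the simple t on log signal is transparent,
assumption-light, and calibratable against an analytic null.

## Signal profiles

Coverage is the per-bp count of cut-site intervals, run-length encoded per
chromosome. A profile matrix stacks anchors (peak centers or TSSs) as
rows; row *i*, bin *j* is the mean coverage over
*[anchor − flank + (j−1)·b, anchor − flank + j·b)* with `profile_flank` =
2,000 bp and `bin_size` b = 10 bp (400 bins). The flank and bin width are
explicit choices — heatmap tools vary and the motivating figures do not
state a bin size. Bins clipped by a chromosome edge average over the
available bp rather than zero-padding (avoiding artificial edge dips);
anchors outside their chromosome yield NA rows with a warning. With
`strand_aware = TRUE`, minus-strand rows are reversed so transcription
reads left to right; the reversal is an involution. The matrix row order
follows anchor input order, with a stable descending sort by row mean
available for heatmap export. Rendering itself is presentation, not
analysis: the contract is the matrix and mean profile (a base-graphics
plot method is provided for convenience).

## Comparative-Ct quantification

Per measurement ΔCt = Ct(target) − Ct(reference); the group contrast is
ΔΔCt = mean ΔCt(treated) − mean ΔCt(control) and the fold change is
2^−ΔΔCt, so the control group is 1 by construction and each cycle of
difference is a factor of 2. Replicates are aggregated by the mean of
ΔCt values — the conventional reading of the comparative-Ct guideline; the
compact notation sometimes printed for ΔΔCt ("ΔCt,target − ΔCt,reference")
conflicts with the ΔCt definition it accompanies and is resolved here as
treated-minus-control. Per-replicate fold changes (each replicate against
the control mean) are emitted for dispersion display. Amplification
efficiency correction (Pfaffl) and standard curves are out of scope. Ct
values outside 5–40 cycles warn but do not error.

# The synthetic-data generator

The generator emulates the study design — two conditions × 3 replicates,
peaks with summits, a refGene-style annotation with UTRs, a DEG list, a
cistrome — as a pure function of a configuration and a seed: identical
inputs give record-identical outputs, and every emitted file passes the
package's own readers and invariants.

**Placement is slot-based so planted quantities are exactly recoverable.**
Peaks occupy sampled slots on a grid whose pitch exceeds
`peak_width + 2·summit_flank + merge_gap + 300` bp (summits jittered ± 100
bp within their slot). Consequences, by construction: within-condition
summit windows never overlap; condition-specific windows never touch the
other condition's windows; merging never joins two distinct peaks. A
planted `shared_fraction` of summit positions is copied identically into
both conditions, so the overlap classifier recovers
`round(shared_fraction · n_peaks)` exactly — the generator's bookkeeping is
the oracle, not a statistical target. Cistrome peaks are either centered
on a treated summit (certain overlap) or placed at unused slot centers
(certain clearance), making the planted overlap fraction exact as well.

**DEG linkage needs a reserved block.** A DEG is "linked" when some peak's
nearest TSS within `tss_range` is that gene. Guaranteeing *unlinked* genes
is the hard part: on a desk-scale genome nearly every position is within
100 kb of some peak. The generator therefore reserves a contiguous run of
genes (in genomic order) and excludes the run's ± `tss_range` neighbourhood
from peak placement; unlinked DEGs are drawn from the reserve, linked DEGs
from genes the generator verifies as peak-associated by an exhaustive
distance scan (independent of the package's indexed nearest-TSS path).

**Counts are multinomial.** Each sample draws `depth` cut sites; a site
falls in peak *i* with probability proportional to
`peak_width · peak_enrichment` (default 5-fold over background), times
`2^dar_log2fc` for planted differential peaks in treated samples, else
uniformly over the non-peak background. Per-region counts are thus
multinomial, hence marginally binomial — the analytic expectation used by
the count-calibration tests. With `peak_enrichment = 1` and `n_dar = 0`
the generator produces an exact null for type-I checks.

**What it does not emulate:** fragment-length mixtures and nucleosome
periodicity, GC and mappability bias, chromatin domain structure,
overlapping genes and transcript isoforms, and peak-width variation.
Passing tests on this generator validate the *bookkeeping and statistical
machinery* — coordinate handling, classification logic, calibration,
recovery of planted structure — not robustness to the biological artifacts
of real libraries.

# Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `merge_gap` | 100 | bp | peak merging distance (inclusive) |
| `summit_flank` | 100 | bp | half-width of summit windows (200 bp windows) |
| `tss_range` | 100,000 | bp | nearest-TSS search radius |
| `promoter_flank` | 2,000 | bp | promoter half-width around the TSS |
| `profile_flank` | 2,000 | bp | profile half-window |
| `bin_size` | 10 | bp | profile bin width |
| `cut_width` | 9 | bp | read 5′ bp used as the cut-site signal |
| `downsample_n` | 10⁸ | reads | down-sampling target for depth parity |
| `dar_adj_p` | 0.05 | — | adjusted-p threshold for DAR calls |
| `dar_abs_log2fc` | 1.0 | — | effect-size threshold for DAR calls |

Generator defaults are desk-scale: 2 chromosomes × 5 Mb, 300 genes, 2,000
peaks per condition (80% shared), 3 + 3 replicates at 500,000 cut sites
each, 5-fold peak enrichment, 100 planted differential regions at log₂FC 3.
The test suite runs smaller instances of the same constructions (typically
one 1.5–2 Mb chromosome, 150–400 peaks, 2–10 × 10⁴ cut sites per sample;
the brute-force equivalence suites use 1,000 random instances of ≤ 200
intervals; the null calibration uses 2,000 regions × 6 samples × 200
runs) — sizes chosen so each property is measured with comfortable
statistical margin while the whole suite stays interactive.

# Numerical conventions and degenerate inputs

* Percentages in summaries: half-up rounding to two decimals
  (`floor(x·100 + 0.5)/100`), never banker's rounding.
* Empty inputs: merging and overlap of empty sets return empty results;
  overlap summaries of empty sets report zero counts and NA proportions;
  an empty annotation set or an empty qPCR group is an error.
* narrowPeak summit offset −1 maps to a missing summit; a summit offset
  pointing outside its peak is a parse error with the line number, as is
  any malformed line (no record is ever silently dropped).
* Unknown chromosomes are tolerated when no chromosome sizes are supplied
  and rejected when they are, so both synthetic and reference genomes work.
* Gene-symbol comparison in DEG integration is exact and case-sensitive by
  default, with an explicit `case_insensitive` switch; duplicate DEG
  symbols are deduplicated with a warning.
* All randomness (down-sampling, every generator stage) flows through
  locally scoped seeds that restore the caller's RNG state.

# Known limitations

* The differential test assumes approximately equal variances on the log
  scale and ignores count dispersion structure; strongly dispersed real
  data would favour a negative-binomial model, which is out of scope here.
* Nearest-TSS gene assignment is a proximity heuristic; it will misassign
  peaks regulating a distal gene across an intervening TSS, and reports at
  most one gene per peak.
* Condition-specific peak calls conflate biological absence with peak
  caller threshold effects; the classifier reports coordinates, not
  causes.
* The cistrome and DEG integrations are set operations with no
  significance testing attached; observed proportions should be read
  descriptively.
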