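---
title: "Models and methods behind mpsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model, the algorithmic choices, and
the assumptions behind `mpsa`, in the spirit of the methods sections that
accompany quantitative genomics packages. Nothing here states an empirical
result beyond what the package's own test suite and `scripts/acceptance.R`
compute.

## The measurement model

A massively parallel splicing reporter assay places each candidate exon, with
parts of its native introns, between two constitutive exons of a minigene.
Each variant of the exon is tagged with several 8-nt barcodes located
*downstream of the last exon*, so the barcode is present on the mature
transcript whether or not the test exon was included. A 10-nt UMI attached at
reverse transcription marks each original molecule, and paired-end amplicon
sequencing reads out, per molecule, (read 1) the splice junction downstream
of exon 1 and (read 2) the UMI, barcode, and anchoring sequence.

Because the amplicon has fixed structure, each molecule carries an
unambiguous splicing outcome. Percent spliced in for variant $v$ in
condition $c$ is the binomial proportion

$$\Psi(v,c) = 100 \cdot \frac{n_\text{inclusion}}{n_\text{inclusion} + n_\text{skipping}}$$

over UMI-collapsed molecules, and the variant effect is
$\Delta\Psi(v,c) = \Psi(v,c) - \Psi(\text{ref}(v), c)$ against the matched
reference exon in the same condition. With $m$ independent molecules the
standard error of $\hat\Psi$ is $\sqrt{\Psi(100-\Psi)/m}$, which is the
yardstick used throughout the tests (a planted truth must be recovered
within a small multiple of this quantity).

Key assumptions: molecules are sampled independently given the true
$\Psi$; PCR duplicates share a UMI and are collapsed before counting;
molecules spanning unannotated junctions carry no usable inclusion signal
and are excluded from the denominator rather than imputed.

## Library design rules

`design_config()` carries the design constants:

| parameter | default | rationale |
|---|---|---|
| `min_up_flank` | 50 nt | retains the large majority of branchpoints upstream of the 3' splice site |
| `min_down_flank` | 20 nt | covers the 5' splice-site consensus and nearby intronic elements |
| `min_exon_len` / `max_exon_len` | 68 / 97 nt | with both flanks, the insert fits a synthesizable oligo |
| `min_barcodes` | 3 | replicate barcodes make variant-level $\Psi$ robust to single bad barcodes |
| `barcode_len` | 8 nt | $4^8$ words comfortably cover pools of a few thousand variants |
| `fwd_primer` / `rev_primer` | fixed 20-mers | common amplification handles on every oligo |
| `restriction_motifs` | PstI, XbaI, SpeI, MfeI | the two-step cloning layout (PstI/XbaI, then SpeI/MfeI) |
| `max_oligo_len` | 260 nt | synthesis limit; a variant pushing the insert over it is rejected with a named error, never silently truncated |

Two control sequences are derived per exon. The **mutated splice-site
control** rewrites the 3' splice-site AG to TC and the 5' splice-site GT to
CA — four bases in total, nothing else — and should show near-zero inclusion.
The **consensus control** replaces the last 22 nt of the upstream intron with
a 20-nt pyrimidine tract plus AG and the first 6 nt of the downstream intron
with GTAAGT, and should show near-complete inclusion. The pyrimidine tract
composition is not dictated by the biology beyond "pyrimidine"; we use the
alternating 20-mer `TC…TC` because it is deterministic, unambiguous, and
configurable (`design_config(pyrimidine_tract=)`).

Barcodes are drawn from the single parity-check code over $\{A,C,G,T\}^8$
(digit sum divisible by 4), which guarantees pairwise Hamming distance of at
least 2 — one sequencing substitution can never turn one designed barcode
into another — then filtered against all restriction motifs and their
reverse complements, and sampled with the user's seed. The Hamming and motif
constraints go beyond the bare "unique 8-mers" requirement; they are design
hardening, and the distance-2 guarantee is what justifies the *exact-match,
no-rescue* barcode lookup during demultiplexing. Because a barcode junction
with its flanking cassette can still recreate a motif, assembly validates the
whole oligo and swaps in a spare barcode when that happens.

Coordinates follow the input standards: VCF and GTF are 1-based inclusive;
BED is converted from 0-based half-open at the reader. Minus-strand exons
are reverse-complemented at extraction so all downstream logic is
strand-free; variant alleles are complemented at application time. The
variant edit is placed through a per-base genomic-position map, which makes
indel offset bookkeeping automatic; a deletion that would leave a flank
below its minimum re-pads the flank from the genome when one is supplied.

## Plasmid QC

Barcode–variant linkage is verified from merged paired-end plasmid reads.
The merger scans all overlaps of at least `min_overlap` bases, requires a
mismatch fraction of at most `max_mismatch_frac`, takes the overlap with the
most matching bases, and resolves disagreeing bases to the higher-quality
read (ties to read 1).

Each merged read, binned by the exact barcode next to the MfeI–SpeI
cassette, is called against the designed oligos of its exon:

* `expected` — the read's bases across the exon group's designed edit
  positions match the barcode's own variant;
* `other_designed` — they match a *different* designed variant
  (misassignment, e.g. template switching during synthesis or cloning);
* `unrecognized` — best identity against any designed oligo below 90%, or an
  edit-site pattern matching no design;
* `indel_only` — the read aligns to the expected oligo with indels outside
  the designed edit.

Equal-length read/oligo pairs are compared column-wise; anything else goes
through global alignment (match +1, mismatch −1, gap open −2, extend −1).
The scoring constants and the 90% identity floor are package choices — the
assay's fixed amplicon structure makes the calls insensitive to them, and
they are exposed as arguments.

A barcode is dropped when **15% or more** of its reads do not carry the
correct variant. The two natural phrasings of this rule ("kept if more than
85% correct" vs "dropped if at least 15% incorrect") disagree exactly at the
boundary; the package implements the *inclusive-drop* reading
(`frac_incorrect >= 0.15` drops), keeps the threshold configurable, and
pins the boundary with a test. The pool-level **misassignment rate** is
`other_designed` over *all* barcode-assigned reads (the kept-only variant is
also reported), and the **skew ratio** is the 90th over the 10th percentile
of per-barcode depth with percentiles by linear interpolation between
closest ranks (`quantile(type = 7)`, i.e. rank $= 1 + (n-1)p$) — the
percentile convention is a package choice, fixed and tested against a hand
computation.

## Splicing quantification

The published pipeline aligned reads to per-variant references with a
general-purpose spliced aligner. Because the amplicon is fixed-structure,
`mpsa` replaces alignment with **anchored junction classification**: read 1
starts at a known offset inside exon 1, so the `anchor_k` (default 10) bases
after the exon-1 boundary either match the start of the test exon
(inclusion) or the start of exon 3 (skipping), each within `max_mismatch`
(default 1) mismatches. If both or neither match, the molecule spans an
unannotated junction and is discarded from $\Psi$. Equivalence with
alignment is enforced by a test that compares the classifier against
brute-force edit-distance assignment to the two isoform sequences on
simulated reads (perfect agreement error-free; disagreements under
sequencing error must all be the classifier abstaining as `UNANNOTATED`).

Read 2 is accepted only when the exon-3 check sequence and the restriction
site adjacent to the barcode both match at their expected offsets within
`max_anchor_mismatch` (default 1) mismatches, and the 8-mer in the barcode
slot is a designed barcode *exactly* (distance-2 barcodes make a 1-mismatch
rescue tempting; exactness is the conservative choice and is configurable by
table edit). UMI collapse is exact-match, one molecule per (barcode, UMI),
majority vote over the molecule's reads, and exact ties are discarded and
counted — directional or cluster-based UMI collapsing is deliberately out of
scope for fixed-length random UMIs at these depths.

Aggregation is a hierarchy of unweighted means: barcode $\Psi$ (undefined
when a barcode has zero classified molecules; never imputed) → variant
$\Psi$ per condition (mean over kept, defined barcodes) → cell-line mean
over replicates → cross-cell-line mean (`combine_psi`). Pooled-count
$\Psi$ is also reported (`psi_pooled`) for users who prefer it; the
per-replicate-then-average convention is the default because variant-level
replication is the assay's unit of reproducibility.

## Downstream analyses

**Hexamer score deltas.** For an exonic variant, the windowed score change
is the sum of table scores over hexamers *fully inside the exon* that
overlap the variant locus, computed in the variant and the reference exon;
$\Delta$ESE is variant minus reference. The window definition is the package's
own (the field's tables score hexamers, not windows); it was chosen to be
local — only hexamers touching the edit move the score — and antisymmetric
under swapping reference and variant, and both properties are tested.
Hexamers absent from the table contribute 0; intronic variants are flagged
not-applicable. Per-hexamer association reports, for each hexamer, the mean
of signed $\Delta\Psi$ over events ($+\Delta\Psi$ where the hexamer is
gained, $-\Delta\Psi$ where lost).

**Directionality agreement.** Between two conditions, eligibility at
threshold $\tau$ requires $|\Delta\Psi| > \tau$ (strict) in the designated
conditioning condition and a nonzero $\Delta\Psi$ in both; agreement is sign
equality. Exact zeros carry no direction and are excluded. Note the
asymmetry kept on purpose: the agreement thresholds are strict ($>$), while
the conservation contrast below groups *inclusively* ($|\Delta\Psi| \ge 5$) —
both conventions follow how each analysis is ordinarily specified.

**PTC / NMD.** A premature termination codon is called when the first
in-frame stop ends **at least 50 nt** upstream of the transcript's last
exon–exon junction; the boundary (exactly 50) counts as a PTC, and the
distance is configurable. Transcripts without an in-frame stop are flagged
and not PTCs. The NMD regression is ordinary least squares predicting the
control-condition $\Psi$ from the NMD-knockdown $\Psi$ and the PTC flag, on
a seeded train split holding out one third of the records, *stratified by
the PTC flag* so both classes appear in train and test (the bare "1/3 held
out" leaves stratification open; stratifying avoids degenerate splits at
small $n$). The reported comparison is held-out MSE with vs without the PTC
term on the same split. Endogenous-NMD prediction applies the fitted model
with the PTC indicator forced on to annotation-flagged (stop-gained /
frameshift) variants, clamping predicted $\Psi$ to $[0,100]$ and counting
clamps.

**Conservation and external scores.** Group contrasts use the two-sided
Mann–Whitney U test (`wilcox.test`, normal approximation); external
per-variant score tables are inner-joined on variant id (duplicate ids are
an error naming the offender) and summarized by Spearman correlation.

## What the simulator emulates — and what it does not

`simulate_pool` + `simulate_plasmid_fastq` + `simulate_rna_fastq` generate:
random exons with canonical AG/GT boundaries and clean assemblies; reference
$\Psi \sim 100\cdot\mathrm{Beta}(2,2)$; variant effects from a mixture of a
near-null component and a wider $N(0, 20)$ component (shared or independent
across conditions); mutated-control $\Psi \sim 100\cdot\mathrm{Beta}(1,20)$
and consensus-control $\Psi \sim 100\cdot\mathrm{Beta}(20,1)$; log-normal
per-barcode plasmid depth whose default `sdlog` $= \log(5.5)/(z_{0.9}-z_{0.1})$
targets a P90/P10 skew of 5.5; barcode–variant misassignment at 4.59% by
default; per-molecule PCR copy counts $1+\mathrm{Geom}(p)$; and i.i.d.
substitution sequencing errors (0.1% by default). All randomness flows from
one master seed through named substreams (pool / barcodes / truth / plasmid /
rna:condition), so stages re-run independently and reproducibly.

Deliberately not modeled: indel sequencing errors (substitution-only by
default — amplicon data, and it keeps the classifier oracle exact), quality
score variation (constant Q30; no quality model is claimed), UMI collisions
(UMIs are drawn without replacement per barcode; at $4^{10}$ words and
hundreds of molecules collisions are negligible, and guaranteeing
distinctness keeps molecule counts exact for the recovery tests), position-
dependent error profiles, RT template switching, and any NMD kinetics beyond
the linear model above. Passing tests on simulated data therefore
demonstrate the *pipeline's* correctness — demultiplexing, collapsing,
classification, estimation — not robustness to every artifact of real
libraries; the plasmid QC module is the guard against the artifact class
that matters most (wrong barcode–variant linkage).

## Numerical and degenerate-input conventions

* $\Psi$ with zero classified molecules is `NA` and flagged, excluded from
  all means, never imputed; a variant with no surviving barcode is excluded
  and listed.
* UMI vote ties discard the molecule (counted); merge-overlap base ties go
  to read 1.
* $\Delta\Psi$ of a reference row is 0 by construction; a variant whose exon
  lacks a reference value in that condition is excluded and listed.
* Correlation reports require at least 3 finite pairs; contrasts require
  both groups non-empty; `misassignment_rate` with zero assigned reads and a
  skew with fewer than two depths are errors, and a zero 10th percentile is
  an infinite-skew signal (`Inf`), not an error.
* All package errors carry condition subclasses (`mpsa_ref_mismatch`,
  `mpsa_stray_motif`, …) so callers and tests branch on failure modes, not
  message text.

## Problem sizes used by the tests

The test suite and acceptance script size their simulations to be
informative per unit of compute: the design-scale check builds the full
110-exon / 2059-variant pool; $\Psi$ recovery uses 50 exons × (reference + 4
SNVs) × 3 barcodes × 200 molecules (750 barcodes, ≈ 300k read pairs);
control ordering uses 6 exons × 30 molecules × 10 seeds; the NMD comparison
uses $n = 600$ × 20 seeds; classifier-vs-oracle uses 1000 reads; QC recovery
uses 8 exons at depth ≈ 60. These sizes put 3-standard-error recovery bands
in the low percentage points, which is where the interesting failures would
show.

## Known limitations

* The junction classifier assumes the fixed amplicon structure; it does not
  detect cryptic splice sites beyond routing them to `UNANNOTATED`.
* Variant calling on plasmid reads discriminates designed variants of the
  same exon; a chimera between two exons' inserts is `unrecognized`, not
  specially categorized.
* The oligo part order is configurable but the default layout is one
  consistent reading of the two-step cloning design; pools built elsewhere
  should be imported through the pool TSV, whose column contract
  (`validate_pool`) is the real interface.
* Splice-site strength, branchpoint, variant-effect and conservation scores
  are ingested as tables, never computed.
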