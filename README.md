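# mpsa — barcoded minigene splicing reporter assays

`mpsa` implements the computational side of a massively parallel splicing
reporter assay (MPSA): an experiment that measures, for thousands of genetic
variants at once, how each variant changes the inclusion of its exon in the
mature mRNA.

The assay works by cloning each candidate **test exon** — together with at
least 50 nt of upstream intron and at least 20 nt of downstream intron — into
a three-exon minigene reporter between two constitutive exons. Every
variant is tagged with at least three unique 8-nt **barcodes** placed
*downstream* of the last exon, so that transcripts that skip the test exon
remain attributable to their variant. After transfection, RT-PCR with a
10-nt **UMI** (unique molecular identifier) and amplicon sequencing read out
each transcript's splicing outcome.

For a variant *v* in condition *c*, the package computes **percent spliced
in**

&nbsp;&nbsp;&nbsp;&nbsp;Ψ(v, c) = 100 · n_inclusion / (n_inclusion + n_skipping)

over UMI-collapsed molecules, and the variant effect

&nbsp;&nbsp;&nbsp;&nbsp;ΔΨ(v, c) = Ψ(v, c) − Ψ(reference exon of v, c).

## What the package does

* **Library design** (`design_pool`, `extract_test_region`, `apply_variant`,
  `make_mutated_control`, `make_consensus_control`, `generate_barcodes`,
  `assemble_oligo`, `summarize_pool`) — builds the barcoded oligo pool from
  exon annotations (BED6/GTF), a genome FASTA, and a VCF, enforcing the
  design rules (exon length 68–97 nt, flanks ≥ 50/20 nt, ≥ 3 barcodes per
  variant, no stray restriction sites, common primers and PstI/XbaI +
  SpeI/MfeI cloning sites). Each exon also gets a *mutated* splice-site
  control (3'ss AG→TC, 5'ss GT→CA; expected Ψ near 0) and a *consensus*
  control (20-nt pyrimidine tract + AG, 5'ss GTAAGT; expected Ψ near 100).
* **Plasmid QC** (`qc_plasmid`, `merge_pair`, `call_read_variant`,
  `filter_barcodes`, `misassignment_rate`, `skew_ratio`) — verifies from
  paired-end plasmid amplicon reads that each barcode is physically linked to
  its designed variant. Barcodes with ≥ 15% incorrect reads are dropped;
  the pool-level misassignment rate and the P90/P10 depth skew ratio are
  reported.
* **Splicing quantification** (`quantify`, `demux_read2`, `classify_outcome`,
  `collapse_umis`, `compute_psi`, `aggregate_psi`, `delta_psi`) —
  demultiplexes UMI-tagged RNA amplicon pairs by barcode, classifies each
  molecule as inclusion / skipping / unannotated by anchored splice-junction
  comparison against a variant-specific minigene reference, collapses PCR
  duplicates by UMI (majority vote, ties discarded), and tabulates Ψ and ΔΨ
  at barcode and variant level.
* **Downstream analyses** (`eseseq_delta`, `hexamer_association`,
  `directionality_agreement`, `predict_ptc`, `fit_nmd_model`,
  `conservation_contrast`, `external_score_join`) — exonic splicing
  enhancer/silencer hexamer score deltas, cross-condition directionality
  agreement of ΔΨ, premature-termination-codon calls (stop ≥ 50 nt before
  the last exon junction), an NMD regression predicting control-condition Ψ
  from knockdown Ψ plus the PTC flag, Mann-Whitney conservation contrasts,
  and joins against external per-variant score tables.
* **Simulation** (`sim_config`, `simulate_pool`, `simulate_plasmid_fastq`,
  `simulate_rna_fastq`, `end_to_end_check`) — generates design pools and
  FASTQ read sets with known truth (per-barcode depth skew, barcode–variant
  misassignment, PCR duplicates sharing a UMI, substitution errors, control
  Ψ priors at the extremes), so every stage is testable without external
  data.
* **CLI** — `mpsa_run()` / the `inst/exec/mpsa` script expose
  `design`, `qc-plasmid`, `quantify`, `analyze`, `simulate`, and `check`
  subcommands; every run writes a JSON manifest whose read accounting
  reconciles exactly.

## Worked example

Simulate a small study (4 exons, 3 SNVs each, plus reference and both
splice-site controls, 3 barcodes per variant, 80 molecules per barcode), run
plasmid QC, quantify splicing, and compute variant effects:

```r
library(mpsa)

cfg <- sim_config(n_exons = 4, variants_per_exon = 3,
                  molecules_per_barcode = 80, depth_meanlog = log(40))
sim <- simulate_pool(cfg, seed = 42)
summarize_pool(sim$pool)
#> pool: 72 oligos, 24 variants (12 excluding reference/controls), 4 exons
#>   barcodes/variant 3-3; exon length 68-85; min flanks 50/20 nt
#>   design rules satisfied

pl <- simulate_plasmid_fastq(sim, seed = 42)
qc <- qc_plasmid(pl$r1, pl$r2, sim$pool)
qc
#> plasmid QC: 3255 pairs, 3190 assigned; 69/72 barcodes kept
#>   misassignment rate 0.0455; skew ratio 4.46

rna <- simulate_rna_fastq(sim, "cond1", seed = 42)
q <- quantify(rna$r1, rna$r2, sim$pool, condition = "cond1",
              kept_barcodes = qc$kept)
q
#> splicing quantification: 11600 pairs -> 5592 molecules over 69 barcodes (24 variants)

d <- delta_psi(q$variant_psi, sim$pool)
head(d[order(-abs(d$delta_psi)),
       c("variant_id", "variant_class", "psi", "ref_psi", "delta_psi")], 5)
#>    variant_id     variant_class   psi ref_psi delta_psi
#> 13 ex003_cons control_consensus 97.91    16.9      81.0
#> 2   ex001_mut   control_mutated  1.22    80.5     -79.3
#> 19 ex004_cons control_consensus 99.60    31.3      68.3
#> 8   ex002_mut   control_mutated 17.65    83.4     -65.7
#> 11  ex002_v02               SNV 34.88    83.4     -48.5
```

The simulation planted a misassignment rate of 4.59% (recovered 4.55%) and a
log-normal depth skew. The strongest variant effects are the designed
splice-site controls — the mutated controls collapse toward Ψ ≈ 0, the
consensus controls rise toward Ψ ≈ 100 — with a strong exonic SNV next.
Against the planted truth, the largest variant-level Ψ error in this run is
7.6 percentage points, consistent with binomial counting noise at ~240
molecules per variant.

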