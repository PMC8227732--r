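---
title: "Methods: long-read amplicon splice-variant discovery with nanosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read amplicon splice-variant discovery with nanosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosplice)
```

# Problem setting and model

`nanosplice` analyses targeted amplicon sequencing of a *single gene* with
long reads. Because one read can span the transcript from an alternative
first exon to the terminal exon, the observable unit is the complete
**exon chain** of a transcript, not an assembly of short fragments. The
pipeline's data model reflects that:

* a `gene_model` holds the exons, the annotated transcript chains, the
  initiation/termination codons and the protein-domain intervals of one
  gene on one contig and strand;
* a read contributes a chain of **aligned blocks** (maximal gap-free
  reference intervals); consecutive blocks are separated by splice
  junctions;
* a transcript variant is an exon-id chain such as
  `E1a-E2-E3-E5-E6-E7-E8-E9`.

Assumptions built into the method:

1. **Spliced alignments are given.** Input is SAM/BAM from any spliced
   aligner. Only `N` CIGAR operations separate blocks; deletions (`D`) are
   treated as alignment noise within a block.
2. **Primary alignments only.** Secondary/supplementary records are
   ignored; an amplicon design gives one locus, so chimeras are out of
   scope.
3. **Splice-site fidelity beats base-level fidelity.** Long-read indel
   noise jitters junction coordinates by a few nt, but true junctions
   coincide with annotated splice sites far more often than chance, so
   junction ends are *snapped* to annotated sites within a window, and only
   what cannot be snapped is considered a cryptic-site candidate.
4. **Full-length reads define isoforms.** Only reads whose alignment
   starts near the start of an annotated first exon and ends near the end
   of the terminal exon are collapsed into the isoform catalogue — for
   targeted PCR, primers sit in the terminal exons, so incomplete reads
   are artefacts, not evidence of shorter isoforms.

# Coordinate convention

All genomic coordinates are **1-based, closed intervals**, the native
convention of SAM, GTF and the Bioconductor ranges stack used throughout
(`GenomicRanges`, `GenomicAlignments`, `Biostrings`). A junction is the
pair (donor, acceptor) = (last base of the upstream exon, first base of
the downstream exon). Using the ecosystem's own convention removes an
entire class of off-by-one conversions at every package boundary; BED12
output is converted by `rtracklayer` at the file boundary only.

# Stage parameters and their defaults

| parameter | default | role | rationale |
|---|---|---|---|
| `w` | 12 nt | snap / cluster window | generous for long-read jitter at splice sites, yet far smaller than the shortest exon (92 nt), so windows of neighbouring sites cannot collide |
| `min_support` | 5 reads | junction / novel-exon floor | suppresses junction artefacts created by coincident indel clusters |
| `min_frac` | 1e-4 | junction support fraction | with deep amplicon runs an absolute floor alone is meaningless; the smallest real junction classes sit orders of magnitude above 0.01% |
| `min_isoform_support` | 3 reads | variant floor | a chain seen three times with identical junctions is unlikely to be a compound error |
| `t` | 30 nt | full-length terminal window | tolerates ragged read ends while rejecting truncated molecules |
| `boundary_tol` | 12 nt | block-to-exon matching | same scale as `w`; applied after snapping, so internal boundaries are usually exact |
| `d_nmd` | 50 nt | NMD rule | the canonical 50-nt boundary: a stop more than 50 nt upstream of the last exon–exon junction marks an NMD candidate (strict inequality; a stop in the final exon never qualifies) |
| `min_orf_aa` | 50 aa | ORF scan floor | used only when no initiation anchor is present |
| `p_sub`, `p_ins`, `p_del` | 0.03, 0.02, 0.03 | simulator error rates | nanopore-era per-base error regime (~8% total) |

Snapping chooses, among candidate (donor, acceptor) site pairs within `w`,
the pair minimising the total shift, breaking ties in favour of annotated
junction pairs, then `GT..AG` pairs, then the smaller coordinates — a
deterministic, order-free rule.

Junction classification is three-valued: `annotated` (pair used by an
annotated transcript), `novel_combination` (both sites annotated, pair
new), `cryptic` (at least one un-annotated site). Cryptic *exons* are
called from internal blocks that overlap no annotated exon, clustered
within `w`, and reported with per-cluster **modal** start/end — the mode,
unlike the mean, is insensitive to the heavy-tailed indel jitter and
recovers exact boundaries once a majority of reads vote correctly.

# ORF calling by anchors

Initiation and termination codons are located by 15-nt **anchor
subsequences** taken from the annotated transcript, not by genome
coordinates. This makes the caller applicable to plain cDNA sequences
(e.g. deposited variant sequences, via `orf_from_fasta()`) where exon
coordinates are unknown. Priority: annotated start anchor, then the
designated alternative starts in exons 3 and 4, then a longest-ORF scan;
anchors match exactly first, then with one mismatch. A prediction is
PTC-flagged when its stop codon lies upstream of the annotated
termination anchor. Domain presence uses an exact amino-acid substring
rule against the annotated protein: any skip, insertion or frameshift
that disturbs a domain's sequence marks it absent, with no coordinate
arithmetic.

# The synthetic fixture

`elf3_fixture()` generates a fully synthetic locus mirroring the targeted
gene's architecture: alternative first exons of 120 and 234 bp differing
only in 5' UTR, exons 2–9, introns of 300 nt (all `GT..AG`), a 156-nt
cryptic exon (N1) hidden between exons 7 and 8 and a 92-nt one (N2)
between exons 8 and 9, a 371-aa protein with the five domains mapped onto
exons as PNT (exons 2–3), TAD (exon 4), SAR (exon 6), AT_hook (exon 7)
and ETS (exons 8–9).

The sequence is *frame-engineered* so that the reference catalogue of 27
variants behaves qualitatively like the real gene's:

* exon-2's coding part and exons 3–7 are multiples of 3, so single
  cassette skips preserve the reading frame;
* exon 8 is **not** a multiple of 3 while exon 8 + N2 is — skipping exon 8
  and inserting N2 therefore shift translation into one common alternative
  frame in exon 9, for which a single downstream stop codon is planted
  (variants with these frameshifts terminate in the final exon and escape
  NMD);
* N1 is a multiple of 3 and carries an in-frame premature stop, making its
  carrier the one PTC/NMD-candidate variant;
* apart from three planted initiation codons (annotated start in exon 2,
  alternatives in exons 3 and 4) the locus contains **no ATG at any
  offset**, and every exon terminus is fixed to `C` so neither start nor
  stop codons can straddle a splice junction — variants lacking all three
  anchors provably have no ORF.

These constraints are validated by `elf3_fixture_config()`; violating
overrides are rejected rather than silently accepted. Within the
constraints, all non-architectural lengths are arbitrary.

# What the simulator does and does not emulate

`simulate_reads()` draws reads multinomially from a transcript mixture and
applies an i.i.d. per-base error model (deletion, else substitution;
single-base insertions between template bases), logging every error
position. `emit_oracle_alignments()` then writes the *exact* spliced
alignment of each read — `N` gaps precisely at the source introns, `I`/`D`
at the simulated indels — playing the role of a perfectly calibrated
aligner. This separates concerns: the pipeline is tested against sequence
noise, while aligner-specific artefacts (soft-clipping, splice-motif
scoring, homopolymer compression) are deliberately out of scope. Error
rates are i.i.d., so position-dependent error profiles are not modelled;
`truncation_rate` produces the incomplete molecules that the full-length
filter must reject. All randomness flows from a single seed; identical
configurations give byte-identical FASTQ/SAM output.

# Problem sizes

The default reproduction simulates 4,050 reads (150 per catalogue chain)
over a ~5.4-kb locus; the full pipeline runs in well under a minute.
Junction tabulation and assembly are linear in the number of aligned
blocks, so runs of 10^5–10^6 reads remain desk-scale.

# Limitations

* One gene, one contig, one strand per run; no multi-sample batching.
* Intron retention is counted but retained-intron isoforms are not
  catalogued.
* Abundance estimates are raw read-support counts; no length or PCR bias
  correction is attempted, so support is comparable within a run only.
* The domain substring rule detects any sequence disruption but cannot
  distinguish a missing domain from a minimally mutated one; for the
  engineered catalogue the two coincide.
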