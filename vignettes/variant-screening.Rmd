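---
title: "Screening VCFs for known phenotype-associated variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening VCFs for known phenotype-associated variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfscreen)
```

## What the package computes

`vcfscreen` answers two questions a veterinary diagnostic lab asks of a
sequenced animal:

1. **Which known phenotype-associated variants does this animal carry, and
   in what zygosity?** The sample's VCF is matched, locus by locus, against
   a catalogue of variants of interest (VOI), each with a chromosome,
   position, gene, inheritance pattern, phenotype and the breeds in which
   the genotype–phenotype association is established.
2. **How genetically diverse is this individual relative to the rest of
   its cohort?** Measured as the within-individual average heterozygosity
   over a shared set of loci.

Both computations are deliberately simple; the value of the package is in
doing them in a standardized, fully transparent way — every catalogue
locus is accounted for in exactly one output table, and a locus that could
not be genotyped is reported as such rather than omitted.

## Zygosity model

Only the GT subfield of the VCF is consumed. `/` and `|` separators are
treated identically: phase is recorded but plays no role, since none of
the downstream rules depend on it. Allele indices are resolved against
REF/ALT into allele strings, and a genotype is classified as:

* `HOM_REF` / `HOM_NONREF` — two equal called alleles, equal / not equal
  to REF;
* `HET` — two different called alleles. Multi-allelic sites are *not*
  split into biallelic records; a `1/2` genotype is heterozygous with two
  non-reference alleles. Splitting would require normalization decisions
  (left-alignment, allele atomization) that add no information here,
  because matching is by position and zygosity is computed on resolved
  allele strings.
* `HEMI_REF` / `HEMI_NONREF` — haploid genotypes (single index; chrY,
  mitochondria, male X depending on the caller). Reports label these
  "Hemizygous".
* `NO_CALL` — any genotype with a missing index, *including half-calls*
  like `./1`. A half-call asserts one allele but leaves the genotype — and
  hence any zygosity-based advice — undetermined, so the binary
  call/no-call framing is the safe clinical choice.

## The five report tables and the no-call policy

For one sample and one clean catalogue, every VOI row lands in exactly one
of three variant tables:

| table | contents |
|---|---|
| priority | non-reference or no-call loci whose VOI breeds contain the sample's breed |
| other_breed | non-reference or no-call loci recorded for other breeds |
| hom_ref | loci where the sample is homozygous (or hemizygous) reference |

Two further tables give breeding advice for every non-reference hit, keyed
by (inheritance pattern, homozygous/heterozygous class); hemizygous
non-reference calls use the homozygous class, since a single defective
allele is fully expressed. The advice strings are fixed texts, total over
all inheritance values: an unknown or blank inheritance pattern yields an
explicit "not able to provide breeding advice" row rather than no row.
Sex is never inferred from the VCF; the sex-conditional advice phrasings
("If animal is female: ...") are kept verbatim, and an optional `--sex`
flag only annotates the report header.

No-call transparency is a hard invariant: a VOI locus with a missing
genotype (`MISSING_GT`) or absent from the VCF entirely
(`ABSENT_FROM_VCF`) still appears, with the verbatim allele text "A call
could not be made for this sample at this given locus". The two statuses
are rendered with the same user-facing text but kept distinct in the
`locus_status` column because they have different debugging implications
(caller dropout vs. a locus outside the capture design).

Routing is by breed string match — case-insensitive, whitespace-normalized,
exact. Fuzzy breed matching was rejected deliberately: in a clinical
report, a variant silently "matched" to the wrong breed is worse than one
conservatively routed to the other-breed table. Locus matching is by
chromosome + position only (1-based throughout); a VOI reference allele
that disagrees with the VCF REF is flagged in an `allele_mismatch` column
but never changes routing, since allele concordance is a QC concern, not a
filtering key.

## Catalogue quality control

`qc_voi()` applies three checks, in order:

1. rows missing chromosome, position, gene or assembly are dropped
   (they cannot be matched);
2. if the user states the VCF's assembly, rows recorded against a
   different assembly label are excluded — compared by exact string
   equality after trimming and case folding. No alias table
   ("CanFam3.1" vs "canFam4" style families are a curation question, not
   something to guess at);
3. if a reference FASTA is given, the base at each retained position is
   compared case-insensitively against the *first base* of the row's
   reference allele — first base only, because VCF-style indel REF
   strings begin with the anchor base. Mismatches are retained and
   flagged, never dropped: the correct action is manual curation (a
   common real failure mode is a variant annotated on the wrong
   chromosome), and dropping would hide exactly the rows that need
   attention. Rows on chromosomes absent from the FASTA are reported
   unverifiable.

QC is idempotent: a second pass over a clean table drops nothing new.

## Exon/intron localization

Transcripts come from BED12 (0-based, half-open); blocks are converted to
1-based inclusive exon intervals with
`exon_start = chromStart + blockStart + 1`,
`exon_end = exon_start + blockSize − 1`. The BED parser is strict —
blockCount must match the size/start lists, blocks must stay inside
chromEnd — and reports the offending line number, because a silently
mis-parsed annotation produces plausible-looking but wrong exon numbers.
Exon and intron indices are reported in *transcription order*: on the `−`
strand exon 1 is the genomically last exon, matching how clinical reports
and HGVS-style descriptions number exons. A variant hitting several
transcripts gets one annotation entry per transcript. Positions inside a
VOI gene's span but outside all its transcripts are labelled
"outside transcripts" and keep the catalogue's gene symbol.

## Average heterozygosity

For sample $i$, $He_i = n_{het,i} / n_n$, where $n_n$ is the number of
loci called (diploid, both alleles present) in **every** sample of the
multi-sample VCF and $n_{het,i}$ counts the shared loci at which sample
$i$'s two alleles differ. Restricting to the shared set makes $n_n$
identical across samples, so the estimates are comparable; the shared set
shrinks as samples are added, which is the accepted cost. Loci that are
haploid in any sample are excluded from the shared set — a haploid call
cannot be heterozygous, and keeping such loci would deflate He for the
affected sample only. Multi-allelic heterozygotes (`1/2`) count as
heterozygous, since the two alleles differ. He is computed as an exact
ratio of integer counts and formatted to 15 decimal places in tables; an
empty shared set is an explicit error (He undefined), not a `NaN`.

Charts are written as static PNGs in four annotation variants
(unannotated; all samples labeled; sample of interest highlighted;
maximum-He sample highlighted, ties broken by table order and noted in the
log), with a sub-folder per sample. File paths are printed rather than
opening a browser.

## The fixture generator

`generate_fixtures()` emulates the screening inputs: a multi-sample VCF of
biallelic SNVs on a few short synthetic contigs (60 kb by default), a
canonical-schema VOI table drawn from those loci, a BED12 with one
three-exon transcript per VOI gene placed so the locus falls in exon 2, a
reference FASTA consistent with every REF base, and a chromosome-name map.
Genotypes are independent per-locus-per-sample draws: missing with
probability `missing_rate` (default 0.1, a plausible exome no-call rate),
heterozygous with probability `het_rate` (default 0.3) otherwise, and the
remaining mass split evenly between the two homozygotes. Ground truth —
shared-locus count, per-sample He, filter partition sizes, QC defect
counts, extra-variant counts — is recorded by direct bookkeeping *during*
generation, before any parser runs, which is what makes it an oracle.
Defects can be planted on request: rows with a blank position, rows
recorded against a different assembly, and rows whose reference allele is
corrupted relative to the FASTA.

What the generator does **not** emulate: linkage disequilibrium,
population structure, indels and multi-allelic sites, genotype-quality
annotations, or non-uniform missingness. Tests passing on fixtures
therefore demonstrate the bookkeeping and the rules, not robustness to
messy real-world VCFs; the parsers are exercised on standard formats, so
the main residual risk on real data is upstream caller idiosyncrasy.

The bundled worked example (`labrador_example()`) is a hand-written
one-sample bundle reproducing a typical screen of a yellow Labrador
retriever — five genotyped sites, three of them breed-matched (COL11A2,
MC1R, ATP7A), one no-call (FGF5), one recorded for another breed — with
genuine canFam3 coordinates. It ships no FASTA because nothing in the
screening path needs one.

## Numerical and interface choices

* Coordinates are 1-based everywhere internally; BED input is converted
  at the parser boundary.
* Report row order is catalogue input order; two runs on identical inputs
  produce byte-identical TSV table bodies (timestamps are confined to the
  combined report's metadata block).
* The OMIA header preset lives in a packaged TSV
  (`inst/extdata/omia_header_map.tsv`) rather than in code, because an
  external export dialect is exactly the kind of thing that changes;
  users can fall back to `source = "USER"` with an explicit `column_map`.
* FILTER is carried through and displayed but never used to exclude
  records: the screening question is "what did the caller report at this
  locus", and silently applying caller-side filters would reintroduce the
  hidden-information problem the no-call policy exists to prevent.
* The CLI returns exit status 0/1/2 (success / data error / usage error)
  from an exported function, with the installed script a four-line
  wrapper, so the shell surface is testable in-process.

## Problem sizes

The test suite runs entirely on generated fixtures: the diversity and
partition sweeps use 22 bundles spanning 2–8 samples, 50–500 loci and
missingness 0–0.3; localization is verified position-by-position over
full transcript spans (a few kb) on both strands. The whole suite
completes in well under a minute on a single CPU.

## Known limitations

* No liftover: catalogue rows on another assembly are excluded, not
  converted.
* No variant normalization: an indel represented differently in the VCF
  and the catalogue will not match by position alone and will surface as
  an allele mismatch flag at best.
* Compound heterozygosity and gene–gene interactions (e.g. a protective
  variant in one gene masking another) are interpretation, not
  computation; the report presents the genotypes side by side.
* He is observed heterozygosity only; no allele-frequency, F-statistics
  or kinship estimates.
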