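# vcfscreen

Clinical screening of VCF files for known phenotype-associated variants in
domestic animals, with standardized reporting, Mendelian breeding advice
and genetic-diversity monitoring.

## The problem

Whole-exome and whole-genome sequencing are entering routine veterinary
diagnostics, but most variant-interpretation tooling is human-centric and
assumes databases that do not exist for dogs, cats, horses or livestock.
What a veterinary diagnostic lab actually needs is simpler and different:
given a sample's VCF and a catalogue of *already known* phenotype-associated
variants (for example an [OMIA](https://omia.org) export), report — in a
standardized, clinician-readable form — which of those variants the animal
carries, in which zygosity, whether the association is established in the
animal's breed, and what that means for breeding. Because selective
breeding has left many breeds with dangerously low genetic diversity, the
same data should also yield a per-individual diversity estimate.

`vcfscreen` implements that workflow as an R package plus a small CLI:

* **VCF model** — parse a (multi-sample) VCF v4.x, report its file
  attributes, harmonize chromosome names (`1` vs `chr1`), extract
  single-sample views.
* **VOI catalogue** — parse a variants-of-interest table (OMIA dialect or
  user-defined), with quality control: incomplete rows are dropped, rows
  recorded against another genome assembly are excluded, and reference
  bases are checked against a FASTA (mismatches are *flagged*, never
  silently removed).
* **Annotation** — build transcript/exon models from a UCSC-style BED12
  file and localize every hit to an exon or intron in transcription order.
* **Filtering** — call zygosity at each catalogue locus and partition the
  hits into the priority table (non-reference, known to segregate in the
  breed), the other-breed table, and the homozygous-reference table, plus
  two breeding-advice tables keyed by inheritance pattern. Loci that could
  not be genotyped are reported with an explicit no-call text — never
  hidden, because "no call" must not be mistaken for "not carried".
* **Diversity** — per-sample average heterozygosity
  `He = n_het / n_shared`, where `n_shared` counts only loci called in
  *every* sample of the multi-sample VCF, so the denominator (and hence
  the estimate) is comparable across samples.
* **Reporting** — five standardized HTML tables plus one combined,
  self-contained report, with TSV mirrors of every table.
* **Fixtures** — a deterministic generator of coherent VCF + VOI + BED12 +
  FASTA bundles with known ground truth, for testing without downloads.

## Worked example

The package bundles a worked example: a healthy, yellow, female Labrador
retriever screened against a five-variant catalogue.

```r
library(vcfscreen)

d   <- tempfile()
ex  <- labrador_example(d)
vcf <- read_vcf(ex$vcf, verbose = FALSE)
voi <- qc_voi(parse_voi(ex$voi), assembly = "canFam3")$voi
ann <- build_annotation(ex$bed, gene_map = ex$gene_map)

res <- filter_variants(extract_sample(vcf, "dog1"), voi,
                       annotations = ann, breed = "Labrador retriever")
print(res)
#> Variant screening result for sample 'dog1' (breed: Labrador retriever)
#>   priority (segregating in breed): 3
#>   other breeds:                    2
#>   homozygous reference:            0
#>   advice rows (hom/het):           2/2

res$priority[, c("chrom", "pos", "gene", "zygosity")]
#>   chrom      pos    gene   zygosity
#> 1 chr12 22652874 COL11A2        HET
#> 2  chr5 63694334    MC1R HOM_NONREF
#> 3  chrX 60279238   ATP7A        HET
```

The three priority hits are the clinically actionable core: the dog is a
carrier of the recessive COL11A2 skeletal-dysplasia variant (no phenotype,
but essential for mate selection), homozygous for the recessive MC1R
variant (hence the yellow coat), and heterozygous at the X-linked ATP7A
locus. Two further hits (an FGF5 no-call and a second MC1R variant) are
not known to segregate in the Labrador retriever and are reported
separately for careful interpretation. `render_report(res, out_dir = ...)`
writes the five HTML tables and the combined report;
`heterozygosity(vcf)` adds the per-sample diversity summary.

The same pipeline is available from the shell:

```sh
Rscript inst/scripts/vcfscreen scan --vcf dog1.vcf --voi voi.tsv \
    --bed annotation.bed --breed "Labrador retriever" --sample dog1 \
    --out report_dir --with-diversity
```

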