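source_header	canonical
Chromosome	chrom
Chr	chrom
Chr.	chrom
Position	pos
Location	pos
g. or m.	pos
Gene	gene
Reference allele	ref_allele
Ref allele	ref_allele
Variant allele	var_allele
Alt allele	var_allele
Allele	var_allele
Inheritance	inheritance
Mode of inheritance	inheritance
Phenotype	phenotype
Phene	phenotype
Phenotype(s)	phenotype
Breed	breeds
Breeds	breeds
Breed(s)	breeds
Genome assembly	assembly
Assembly	assembly
Reference Sequence	assembly
Species	species
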