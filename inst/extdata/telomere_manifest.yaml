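# Provenance of the packaged telomere-length / osteoarthritis instrument panel.
source: >
  Published table of 20 sentinel SNPs associated with leukocyte telomere length
  at genome-wide significance (p < 5e-8) in a European-ancestry GWAS
  meta-analysis of up to 78,592 individuals, with their per-allele effects on
  total osteoarthritis from the UK Biobank osteoarthritis GWAS
  (10,083 cases / 40,425 controls, 50,508 individuals).
files:
  exposure: telomere_tl.tsv      # per-SD-of-TL additive effects
  outcome: telomere_oa.tsv       # log-odds of total osteoarthritis
  ld: telomere_ld_synthetic.tsv  # see note below
  exclusions: telomere_exclusions.tsv
sample_sizes:
  exposure_n: 78592   # headline meta-analysis size; per-SNP N not published
  outcome_n: 50508
  outcome_cases: 10083
removal_annotations:
  rs2853677: "r2 > 0.05"              # LD with rs7705526 (both TERT, 1,220 bp apart)
  rs73624724: "body fat percentage"   # confounder association (RTEL1)
notes:
  - The published table prints the rs55749605 position with a malformed digit
    grouping ("0,1,232,093"); it is transcribed here as 101,232,093
    (SENP7, chromosome 3).
  - The pairwise r2 between rs7705526 and rs2853677 was not published, only
    that it exceeds 0.05. The shipped LD table carries a SYNTHETIC
    representative value of 0.50; any value above the 0.05 pruning threshold
    produces the identical 19-SNP set because greedy pruning keeps the SNP
    with the smaller exposure p-value (rs7705526).
  - The three chromosome-20 SNPs (rs75691080, rs34978822, rs73624724) fall
    within one pruning window but were all retained as independent sentinel
    variants, i.e. pairwise r2 <= 0.05; the LD table carries SYNTHETIC
    representative values of 0.01 for these pairs. Any value at or below the
    threshold gives the identical instrument set.
  - Effect alleles are shared between the two files; betas in both files are
    reported for the same effect allele, so harmonization flips nothing.
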