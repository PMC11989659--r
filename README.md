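# abca4cohort

Variant interpretation and genotype–phenotype analysis for clinical cohorts
with **ABCA4-associated Stargardt disease (STGD1)**, the most common
inherited macular dystrophy. STGD1 is autosomal recessive: disease follows
from biallelic loss of the ABCA4 photoreceptor lipid transporter, and the
residual function encoded by a patient's *pair* of alleles — not any single
variant — drives phenotype severity. Study groups therefore summarize each
patient's genotype into the Fujinami groups

* **A** — two or more missense / in-frame alleles (most residual function),
* **B** — one deleterious (null) allele plus one or more missense / in-frame
  alleles,
* **C** — two or more deleterious alleles (least residual function),

where a *deleterious (null)* allele is one expected to abolish the gene
product under the ACMG very-strong (PVS1-class) logic: nonsense, frameshift,
canonical ±1/2 splice site, initiation-codon loss, or exonic deletion.
Non-canonical intronic alleles are promoted to deleterious only on in-silico
splice evidence — a SpliceAI delta score ≥ 0.2 on any gain/loss channel, or,
within a functional splice site, a MaxEntScan score difference
ΔMaxEnt = MaxEnt(variant) − MaxEnt(reference) < 0 — or on a reported prior
association with a severe phenotype.

Phenotype severity is graded from five clinical criteria (age of onset,
best-corrected visual acuity in the better eye on the logMAR scale, fundus
appearance type, fundus-autofluorescence type, ERG type): **mild** needs ≥ 2
of {onset > 15 y, BCVA < 0.78, type-1 labels}, **severe** needs ≥ 2 of
{onset < 10 y, BCVA > 1.0, type-3 labels}, anything else is **moderate**.
All inequalities are strict. Low-vision acuities are mapped to fixed logMAR
values (counting fingers → 1.98, hand motion → 2.28).

The package is aimed at inherited-retinal-disease researchers who have a
per-patient phenotype table and an HGVS-annotated variant table and want the
whole chain — HGVS parsing, consequence typing, splice-rule calls, allele
grading, genotype grouping, severity grading, cohort statistics — as tested,
scriptable functions rather than spreadsheet arithmetic. An 18-patient
reference cohort ships as plain-text fixtures, and a seeded synthetic-cohort
generator with planted labels supports end-to-end validation.

## Worked example

```r
library(abca4cohort)

# one variant end to end
v <- variant_descriptor(cdna_hgvs = "c.6006-3C>A")
v
#> <variant> c.6006-3C>A  [near_splice_intronic]

p <- splice_prediction(acceptor_loss = 0.42, maxent_delta = -3.702)
call_splice_effect(p, in_functional_site = TRUE)
#> <splice_call> loss_of_site (acceptor_loss 0.42)

# a heterozygous null plus a heterozygous missense is group B
assign_genotype_group(c("deleterious", "non_deleterious"), c("het", "het"))$group
#> [1] "B"

to_logmar("FC/40cm")   # counting fingers at 40 cm
#> [1] 1.98

classify_severity(onset = 7, better = 1.30, af = 1)$klass
#> [1] "severe"      # onset < 10 and BCVA > 1.0: two severe hits

# the full pipeline on the packaged 18-patient reference cohort
ref <- load_reference_cohort()
res <- run_pipeline(ref$patients, ref$variants, ref$splice)
res$summary
#> <cohort_summary> 18 patients
#>   onset: adult mean 44.3 (n=6), child mean 9.6 (n=12), late-onset n=4
#>   mean logMAR OD 0.96, OS 0.92
#>   groups A/B/C: 5/6/7; severity mild/moderate/severe: 4/5/6 of 15 evaluable
#>   distinct variants 30 (novel 8)
```

Reading the summary: six patients had adult onset (mean 44.3 years) and
twelve childhood/adolescent onset (mean 9.6 years); four meet the
late-onset definition (onset ≥ 45 y). Mean right-eye acuity is 0.96 logMAR.
Five patients carry two mild alleles (group A), six one null plus a mild
allele (B), and seven two null alleles (C); of the fifteen patients with
evaluable phenotype data, 4 are mild, 5 moderate, and 6 severe (40.0%).
Thirty distinct ABCA4 variants were observed, eight of them novel.
`res$summary$group_stats` adds per-group onset and all-eye BCVA statistics
(group B mean 0.878 logMAR over 12 eyes, group C 1.113 over 14 eyes),
`res$summary$crosstab` the genotype × severity table, and `res$audit` the
per-allele classification rationale. `reference_discrepancy_report(res$summary)`
lists the few quantities whose published rounded values do not recompute
exactly from the tabulated data.

A thin command-line front end with `parse-variants`, `splice-call`, `group`,
`severity`, `summarize`, `simulate`, and `validate` subcommands is installed
at `system.file("cli", "abca4cohort-cli.R", package = "abca4cohort")`.

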