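# irdx — exome-based molecular diagnosis of inherited retinal dystrophies

Inherited retinal dystrophies (IRD — retinitis pigmentosa, cone–rod
dystrophy, Leber congenital amaurosis, achromatopsia, Usher syndrome and
related disorders) are extremely heterogeneous Mendelian diseases: some 300
genes, all inheritance patterns, and a large load of private mutations.
`irdx` implements, as a reusable and tested R package, the diagnostic
workflow a whole-exome-sequencing (WES) laboratory applies to such cohorts.
It is aimed at statistical/clinical genetics developers who want every step
of the decision process — filtering, inheritance modelling, evidence
weighting, diagnosis — to be explicit, parameterized and testable.

## The method

For each family, annotated variants pass a three-stage prioritization
cascade:

1. **Frequency** — keep records with ExAC-style population frequency
   AF = AC/AN ≤ 0.01 (inclusive; alleles absent from the reference are
   kept, AF := 0).
2. **Consequence** — keep null (nonsense, frameshift, canonical splice),
   missense, splice-region and exonic copy-number alleles;
   literature-reported pathogenic alleles (e.g. deep-intronic) are
   whitelisted through.
3. **Consensus prediction** — a missense allele must be called damaging by
   ≥ 2 of 4 tools (PolyPhen-2, SIFT, MutationTaster, CADD ≥ 15; a
   categorical call overrides the tool's numeric score).

Surviving alleles are assembled into candidate genotypes that comply with a
Mendelian model — dominant (AD), recessive homozygous (AR hom), compound
heterozygous in trans (AR comphet), X-linked (XL) — against the pedigree,
with a cosegregation verdict (consistent / inconsistent / unavailable).
Each allele then receives ACMG/AMP-style evidence codes:

| code | strength | trigger |
|------|----------|---------|
| PVS1 | very strong | null allele, loss-of-function disease mechanism |
| PS3  | strong   | functional (wet-lab) support for the gene/allele |
| PM3 (tiered) | strong / moderate / supporting | recessive allele in trans with a PVS1-Pathogenic / reported-or-P/LP / co-candidate allele |
| PM2  | moderate | AF below the rarity ceiling (10⁻⁴ dominant, 10⁻³ recessive) or absent |
| PP1  | supporting | consistent cosegregation |
| PP3  | supporting | ≥ 2 damaging in-silico calls |
| PP5  | supporting | previously reported pathogenic |
| BA1  | stand-alone benign | AF > 5% |

Codes combine by the standard rules into Pathogenic / Likely Pathogenic /
VUS / Benign, plus **VGUS** — a clearly disruptive, cosegregating variant in
a gene whose disease role is still uncertain.  A family is **solved** when a
complete, cosegregation-compatible genotype in a credible gene carries only
P/LP alleles; **candidate** when the best genotype involves VUS/VGUS
alleles, an unsupported candidate gene, or non-penetrant carriers; otherwise
**unsolved**.

Structural evidence is handled by three dedicated callers: exon read-depth
ratios against control exomes (heterozygous deletion ≤ 0.65, duplication
≥ 1.35, ≥ 2 consecutive exons), MLPA probe ratios (deletion < 0.7,
duplication > 1.3, strict), and trio-SNP deletion inference (mother and
child homozygous for different alleles is impossible under diploid
transmission and maps a breakpoint interval).

A synthetic-cohort generator (`simulateCohort`) emulates the cohort the
workflow was built for — 33 families (14 simplex / 4 dominant /
14 recessive / 1 X-linked), ~300-gene panel, per-patient modifier-allele
loads of 0.3 known and 5.25 predicted-damaging heterozygous recessive
alleles, noisy predictors and coverage — with a full ground-truth table, so
every stage can be validated end to end.

## Worked example

```r
library(irdx)

res <- runTable1Pipeline(loadTable1Cohort())
res$summary
#> CohortSummary: 33 families | solved 18 (55%) | candidate 10 (30%) | unsolved 5

res$mismatches[, c("family", "gene", "acmg_class", "printed_class", "evidence")]
#>    family    gene       acmg_class printed_class                    evidence
#> 10  55ORG C2orf71 LikelyPathogenic    Pathogenic                    PVS1+PM2
#> 39  62ORG   SCLT1             VGUS    Pathogenic PVS1+PM2+PM3_supporting+PP1

countNovelMutations()
#> $novel_known_genes
#> [1] 21
#> $new_candidate_genes
#> [1] 4
```

The summary reproduces the published cohort outcome: 18 of 33 families with
a secure diagnosis (55% strict yield), 10 with a plausible candidate (an
additional 30%), 5 undiagnosed.  Per-variant ACMG classes agree with the
published classification for 39 of the 41 table entries; the two
disagreements are printed with their derived evidence codes (the published
per-variant criteria are not fully reconstructable, so the engine logs
rather than forces them).

A simulation round-trip with known truth:

```r
sim <- simulateCohort(simConfig(seed = 1, predictor_sensitivity = 1,
                                predictor_specificity = 1))
out <- analyzeCohort(sim)
out$recovery          # 1: every planted causal genotype recovered
```

## Package layout

- `R/` — domain classes (pedigree, panel, candidate genotype, evidence,
  reports), prioritization, ACMG engine, CNV/MLPA/trio-SNP callers, cohort
  summaries, the simulator.
- `inst/extdata/` — the cohort fixture (families, variant table, gene
  panel) as TSV.
- `vignettes/ird-diagnosis.Rmd` — the methods vignette: model,
  parameters, design decisions, limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent brute-force oracles.
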