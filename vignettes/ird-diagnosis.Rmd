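---
title: "Exome-based diagnosis of inherited retinal dystrophies: methods and design"
author: "irdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome-based diagnosis of inherited retinal dystrophies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdx)
```

## The diagnostic model

`irdx` operationalizes the workflow a WES laboratory applies to a cohort of
families with inherited retinal dystrophies.  Its central assumption is the
standard one for rare Mendelian disease: the causal genotype is a rare,
functionally severe configuration of alleles in a disease-relevant gene
that complies with an inheritance model in the family.  The pipeline makes
every step of that assumption explicit:

1. **Rarity.**  Population frequency is taken as ExAC-style
   `AC/AN`.  A variant is retained when its frequency is at most `af_max`
   (default 0.01, boundary inclusive).  Alleles absent from the reference
   population are treated as frequency 0.  Alleles whose position is *not
   covered* in the reference are distinct from absent ones: their frequency
   is unknown, so they pass the rarity filter (they cannot be excluded) but
   earn no rarity evidence later.  A record with `AN = 0` is degenerate and
   treated as absent, with a warning.
2. **Severity.**  Retained consequence classes are nonsense, frameshift,
   canonical-splice, splice-region, missense and exonic
   deletions/duplications.  Synonymous, deep-intronic and unclassified
   records are removed — except literature-reported pathogenic alleles,
   which a whitelist carries through regardless of annotation class (this
   is how a known pathogenic deep-intronic allele survives).
3. **Computational consensus.**  A missense variant must be called damaging
   by at least `min_positive_predictors` (default 2) of PolyPhen-2, SIFT,
   MutationTaster and CADD.  When a tool reports both a categorical call
   and a score, the call wins: published annotation tables show
   combinations such as a "Tolerated" call next to a borderline score, and
   the call is what the annotator asserted.  Score fallbacks are
   PolyPhen-2 ≥ 0.85, SIFT ≤ 0.05, MutationTaster ≥ 0.5 and CADD ≥ 15.
   CADD has no categorical call; 15 is a common screening threshold for
   rare-disease work.  Null and copy-number alleles bypass the consensus
   test — their severity does not rest on missense predictors.  A missense
   record with all four tools missing fails the test, with a warning,
   rather than passing silently.

The filters commute (frequency and consequence are independent
record-level predicates), which the test suite asserts on random record
sets.

## Inheritance models and cosegregation

Candidate genotypes are assembled per gene against the pedigree:

* **AD** — one heterozygous allele carried by every genotyped affected and,
  under complete penetrance, absent from every genotyped unaffected.
* **AR hom** — homozygous in all affecteds, never homozygous in
  unaffecteds, and heterozygous in genotyped parents of affecteds.
* **AR comphet** — exactly two distinct heterozygous alleles of one gene in
  all affecteds, never co-carried by an unaffected, and in trans whenever
  parental genotypes phase them (a pair attributable to a single parent is
  discarded as cis; an unphaseable pair is kept and flagged).
* **XL** — chrX alleles hemizygous in affected males (homozygous females
  are compatible), with genotyped mothers of affected males carrying the
  allele; chrY is ignored.

Simplex families are evaluated under all four models: a sporadic case is
usually recessive, but a substantial minority turn out dominant or
X-linked, so assuming recessiveness would miss them.

Cosegregation is a three-valued verdict.  With at most one genotyped
member it is *unavailable* — and deliberately non-blocking for diagnosis,
because a proband-only family with a homozygous null in an established
gene is still a secure diagnosis.  It is *inconsistent* when a genotyped
unaffected relative carries the complete causal genotype; under the
default complete-penetrance mode such genotypes are never proposed for
dominant families, while the `incomplete` mode keeps them but forces the
inconsistent verdict, which caps the family at *candidate* status.  This
reproduces the situation of dominant pedigrees where reported mutations
appear in unaffected carriers and the phenotype tracks a second,
independently segregating allele.

## Evidence derivation and class combination

Each allele of a candidate genotype receives ACMG/AMP-style codes
(PVS1, PS3, PM2, PM3, PP1, PP3, PP5, BA1) and the codes combine by the
standard rules into Pathogenic, Likely Pathogenic, VUS or Benign, plus the
workflow's own VGUS label.  Three derivation choices deserve comment, as
the design here was genuinely open:

**PM2 ceilings differ by inheritance context.**  Rarity evidence uses a
strict ceiling of 10⁻⁴ for dominant/X-linked candidates and 10⁻³ for
recessive ones.  Recessive pathogenic alleles circulate in the population
as unaffected carriers, so well-established recessive founder alleles
reach frequencies near 10⁻³; a single ceiling at 10⁻⁴ would deny rarity
evidence to textbook pathogenic recessive alleles, while 10⁻³ still sits
an order of magnitude under the 1% screening bound.

**PM3 is tiered by how secure the trans allele is.**  For a compound
heterozygote, being in trans with a pathogenic allele is moderate evidence
by the standard; the package grades it: *strong* when the trans allele is
itself Pathogenic via PVS1 (a secure null), *moderate* when the trans
allele is Pathogenic/Likely Pathogenic or literature-reported pathogenic,
and *supporting* when the trans allele is merely the other surviving
co-candidate.  Tiers are assigned in a second pass from classes computed
without PM3, so the procedure is well-defined and needs no iteration to a
fixed point.  Homozygotes receive no PM3 — an allele cannot support
itself through its own second copy.

**VGUS expresses gene-level, not allele-level, uncertainty.**  In a gene
of uncertain disease relevance (association `candidate_gene`) without
functional support, an allele that would classify Pathogenic/Likely
Pathogenic is reported as VGUS when disruptive and VUS when missense; an
allele that would be VUS but forms a complete, cosegregating causal
genotype with predictor or null support is also labelled VGUS.  Functional
support (PS3) lifts the gene out of this demotion — which is exactly the
role a cilia-formation assay plays for a new candidate gene.  With this
mapping the shipped cohort reproduces 39 of its 41 printed per-variant
classes; the two disagreements (a homozygous frameshift printed Pathogenic
where PVS1+PM2 alone combine to Likely Pathogenic, and a candidate-gene
splice allele printed Pathogenic where the gene-level demotion yields
VGUS) are logged with their evidence codes rather than forced, because the
published table's exact per-variant criteria are not reconstructable from
the text.

Contradictory evidence (BA1 together with PVS1) collapses to VUS with a
conflict flag instead of trusting either side.

## Structural-variant evidence

*Exon depth ratios.*  Depths are normalized per sample by the sample's
median depth over designated control genes (mirroring the use of a nearby
unaffected gene as internal control), and the per-exon statistic is the
normalized case depth over the mean normalized control depth.  A
heterozygous deletion is called at ratio ≤ 0.65 and a duplication at
≥ 1.35 over at least `min_exons = 2` consecutive exons: the thresholds sit
midway between the expected heterozygous copy states (0.5 and 1.5) and the
diploid ratio of 1, and the two-exon minimum reflects the resolution of
capture data — a single discordant exon is within noise, and the
rearrangements this evidence targets span multiple exons.  Exons with zero
control depth are masked, not imputed.  When deletion and duplication runs
both qualify, the longer run wins (tie-break toward deletion).

*MLPA.*  Probe ratios call deletion under 0.7 and duplication over 1.3,
both strict, so a ratio of exactly 0.7 or 1.3 is normal copy number; the
call is a monotone step function of the ratio.

*Trio-SNP deletion inference.*  Over ordered SNPs in a suspected region, a
heterozygous call in either individual proves two copies; mother and child
homozygous for *different* alleles is impossible under diploid transmission
and supports hemizygosity on distinct retained haplotypes; identical
homozygotes and missing calls are uninformative.  The breakpoint interval
runs from the non-deleted loci immediately flanking the maximal
deletion-compatible run; fine-mapping of breakpoints by flank-homology
alignment is out of scope.

## The synthetic cohort: what it emulates, and what it does not

`simulateCohort()` generates cohorts with the statistical structure the
analysis assumes, with ground truth.  Defaults are the study conditions the
package targets: 33 families split 14 simplex / 4 dominant / 14 recessive /
1 X-linked; an 18/10/5 solved/candidate/unsolved expectation; a ~300-gene
panel with a small set of candidate genes; per-patient modifier loads of
Poisson(0.3) known pathogenic and Poisson(5.25) predicted-damaging
heterozygous recessive alleles; predictor error of 0.9 sensitivity / 0.8
specificity per tool, independent across tools (which makes the 2-of-4
consensus meaningfully noisy); exon-depth noise at CV 10% and MLPA ratio
noise at SD 0.05.  Rare-allele frequencies mix a 60% "absent" point mass
with a log-uniform tail — spanning the range from private alleles to
reported recessive alleles near 2×10⁻³ — with planted causal alleles drawn
from a pathogenic spectrum truncated at 10⁻³.  Background variation is
generated as synonymous, deep-intronic and *common* missense records: the
classes the cascade is designed to remove.  Modifier alleles are placed in
distinct, purely recessive established genes, where a heterozygous carrier
allele can never constitute a candidate genotype on its own — which is
what makes them modifiers.

Consequences of these choices: under noiseless settings (perfect
predictors, penetrance 1) the pipeline must recover every planted genotype
and reproduce every expected status exactly, and the test suite asserts
both.  What passing these tests does *not* show about real data: the
generator plants no benign rare missense that sneaks past real predictors,
no annotation errors, no pipeline-upstream artifacts (alignment,
variant-calling), no linkage structure between variants, and its pedigrees
are small nuclear families.  Real cohorts will therefore produce more
borderline candidate genotypes than the simulation; the generator measures
the decision logic, not the noise floor of annotation tools.

Determinism is a contract: the cohort, including all emitted files, is a
byte-reproducible function of the configuration (which carries a mandatory
seed).

## Problem sizes and numerical choices in the test suite

The suite exercises the compound-heterozygote selector against a
brute-force pair-enumeration oracle on 1000 random genes of up to 10
variants; the evidence combiner against a literal rule-table oracle over
all 1024 evidence subsets; the trio-deletion flags against an exhaustive
diploid-transmission oracle over all genotype pairs; recovery on a
noiseless 33-family cohort and a 200-family cohort under default predictor
noise (threshold 90%); CNV detection on 200 noisy replicates of a planted
two-exon deletion (threshold 95% exact-range recovery) and 1000 CNV-free
genes (false-positive rate at most 1%).  These sizes keep the full suite
around a minute while giving the stochastic checks comfortable margins
over their thresholds.

Degenerate inputs are handled explicitly rather than defensively: empty
VCF bodies yield empty tables; an empty coverage target is an error; a
negative MLPA ratio is an error; unknown PED phenotype codes map to
"unknown" with a warning; a pedigree member missing from a VCF header is a
hard error naming the member.

## Known limitations

* The ACMG engine implements only the codes the diagnostic decisions here
  require; hotspot (PM1), de-novo (PS2), same-residue (PM5) and the benign
  BP codes are out of scope, as are de novo, mosaic, digenic and imprinting
  models.
* Annotation is an input, never computed: the package does not run
  predictors, does not lift over coordinates, and does not read BAM/CRAM.
* The depth-ratio caller reports single-exon events as normal; true
  single-exon CNVs are below its stated resolution.
* The cohort fixture identifies variants by gene and HGVS string; genomic
  coordinates in it are synthetic placeholders, and the five undiagnosed
  families are synthetic ids (the source table only lists diagnosed and
  candidate families).
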