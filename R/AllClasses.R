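#' @import methods
NULL

## Controlled vocabularies shared across the package ------------------------

.ZYGOSITY <- c("hom_ref", "het", "hom_alt", "hemizygous", "missing")

.CONSEQUENCES <- c("nonsense", "frameshift", "canonical_splice",
                   "noncanonical_splice_region", "missense", "synonymous",
                   "deep_intronic", "exonic_deletion", "exonic_duplication",
                   "other")

## consequences treated as "clearly disruptive" (null-like) alleles
.DISRUPTIVE <- c("nonsense", "frameshift", "canonical_splice",
                 "exonic_deletion", "exonic_duplication")

.MODELS <- c("AD", "AR_hom", "AR_comphet", "XL")

.ACMG_CLASSES <- c("Pathogenic", "LikelyPathogenic", "VUS", "VGUS", "Benign")

.COSEG <- c("consistent", "inconsistent", "unavailable")

## Evidence codes and their default strengths.  PM3 is tiered by how secure
## the trans allele is, hence the three PM3 codes.
.ACMG_STRENGTH <- c(
  PVS1            = "very_strong",
  PS3             = "strong",
  PM3_strong      = "strong",
  PM2             = "moderate",
  PM3             = "moderate",
  PM3_supporting  = "supporting",
  PP1             = "supporting",
  PP3             = "supporting",
  PP5_reported    = "supporting",
  BA1             = "stand_alone_benign"
)

## Columns a variant table must carry.  A variant table is a plain
## data.frame: one row per decomposed alt allele.
.VARIANT_COLS <- c("id", "chrom", "pos", "ref", "alt", "gene", "consequence",
                   "hgvs", "exac_ac", "exac_an", "exac_status", "reported",
                   "pp2_call", "pp2_score", "sift_call", "sift_score",
                   "mt_call", "mt_score", "cadd")

#' Pedigree of one family
#'
#' Holds the members of a single family: identifiers, sex, affection status
#' and parent links, plus a consanguinity flag.  Validity enforces acyclic
#' parentage and that referenced parents exist as members.
#'
#' @slot familyId single family identifier.
#' @slot members data.frame with columns \code{id}, \code{father},
#'   \code{mother} (\code{NA} for founders), \code{sex} (\code{"male"},
#'   \code{"female"}, \code{"unknown"}) and \code{affected}
#'   (\code{"affected"}, \code{"unaffected"}, \code{"unknown"}).
#' @slot consanguineous logical flag.
#' @exportClass FamilyPedigree
setClass("FamilyPedigree",
  representation(familyId = "character",
                 members = "data.frame",
                 consanguineous = "logical"))

setValidity("FamilyPedigree", function(object) {
  m <- object@members
  need <- c("id", "father", "mother", "sex", "affected")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id))
    return("duplicated member ids")
  for (p in c(m$father, m$mother))
    if (!is.na(p) && !p %in% m$id)
      return(sprintf("parent '%s' is not a member", p))
  if (!all(m$affected %in% c("affected", "unaffected", "unknown")))
    return("affected must be affected/unaffected/unknown")
  ## acyclicity: walking up parent links must terminate
  for (start in m$id) {
    seen <- character(); cur <- start
    while (length(cur)) {
      if (cur %in% seen) return("cyclic parentage")
      seen <- c(seen, cur)
      i <- match(cur, m$id)
      cur <- m$father[i]
      if (is.na(cur)) break
    }
  }
  TRUE
})

#' Gene panel
#'
#' The prioritized gene set: per gene its disease-association tier, the
#' inheritance modes it supports, whether loss of function is an established
#' disease mechanism, and whether functional (wet-lab) support exists.
#'
#' @slot genes data.frame with columns \code{gene}, \code{association}
#'   (\code{established_IRD}, \code{established_syndromic},
#'   \code{candidate_gene}), \code{modes} (comma-separated subset of
#'   AD/AR/XL), \code{lof_mechanism}, \code{functional_support}.
#' @exportClass GenePanel
setClass("GenePanel", representation(genes = "data.frame"))

setValidity("GenePanel", function(object) {
  g <- object@genes
  need <- c("gene", "association", "modes", "lof_mechanism",
            "functional_support")
  if (!all(need %in% names(g)))
    return(paste("panel must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene)) return("duplicated gene symbols")
  ok <- g$association %in% c("established_IRD", "established_syndromic",
                             "candidate_gene")
  if (!all(ok)) return("unknown association tier")
  modes <- strsplit(g$modes, ",", fixed = TRUE)
  if (!all(unlist(modes) %in% c("AD", "AR", "XL")))
    return("modes must be a comma-separated subset of AD,AR,XL")
  TRUE
})

#' ACMG/AMP evidence set for one allele
#'
#' A set of evidence codes; each code carries a fixed strength
#' (very_strong, strong, moderate, supporting, stand_alone_benign).
#'
#' @slot codes character vector of evidence codes.
#' @exportClass AcmgEvidence
setClass("AcmgEvidence", representation(codes = "character"))

setValidity("AcmgEvidence", function(object) {
  bad <- setdiff(object@codes, names(.ACMG_STRENGTH))
  if (length(bad)) return(paste("unknown evidence codes:",
                                paste(bad, collapse = ", ")))
  if (anyDuplicated(object@codes)) return("duplicated evidence codes")
  TRUE
})

#' Candidate genotype for one family under one inheritance model
#'
#' The unit that gets classified and diagnosed: one or two alleles in a
#' single gene that together comply with a Mendelian model in the family.
#'
#' @slot familyId family identifier.
#' @slot gene gene symbol.
#' @slot model one of AD, AR_hom, AR_comphet, XL.
#' @slot alleles data.frame of variant rows (one or, for compound
#'   heterozygotes, two), including a \code{zygosity} column for the proband.
#' @slot cosegregation consistent/inconsistent/unavailable.
#' @slot phased for compound heterozygotes, TRUE when parental genotypes
#'   confirm the trans configuration, FALSE when phase is unknown.
#' @slot evidence list of AcmgEvidence, one per allele (filled by
#'   \code{classifyCandidate}).
#' @slot classes character vector of ACMG classes, one per allele.
#' @exportClass CandidateGenotype
setClass("CandidateGenotype",
  representation(familyId = "character", gene = "character",
                 model = "character", alleles = "data.frame",
                 cosegregation = "character", phased = "logical",
                 evidence = "list", classes = "character"))

setValidity("CandidateGenotype", function(object) {
  if (!object@model %in% .MODELS) return("unknown inheritance model")
  if (!object@cosegregation %in% .COSEG) return("unknown cosegregation state")
  n <- nrow(object@alleles)
  if (object@model == "AR_comphet" && n != 2)
    return("AR_comphet requires exactly two distinct alleles")
  if (object@model != "AR_comphet" && n != 1)
    return("single-allele models require exactly one allele")
  if (length(object@classes) && !all(object@classes %in% .ACMG_CLASSES))
    return("unknown ACMG class")
  TRUE
})

#' Copy-number call from exon read-depth ratios
#'
#' @slot gene gene symbol.
#' @slot state het_deletion / duplication / normal.
#' @slot exonRange integer first/last affected exon (length 0 when normal).
#' @slot ratios per-exon case/control normalized depth ratios (NA = masked).
#' @slot supportingExons number of consecutive exons supporting the call.
#' @exportClass CnvCall
setClass("CnvCall",
  representation(gene = "character", state = "character",
                 exonRange = "integer", ratios = "numeric",
                 supportingExons = "integer"))

setValidity("CnvCall", function(object) {
  if (!object@state %in% c("het_deletion", "duplication", "normal"))
    return("state must be het_deletion/duplication/normal")
  if (any(object@ratios < 0, na.rm = TRUE)) return("ratios must be >= 0")
  if (length(object@exonRange) == 2 &&
      object@exonRange[2] < object@exonRange[1])
    return("exonRange must be ordered")
  TRUE
})

#' Deletion evidence from ordered trio SNP genotypes
#'
#' @slot loci data.frame with columns \code{locus}, \code{pos},
#'   \code{mother}, \code{child}, \code{flag} (deletion_supporting /
#'   non_deleted / uninformative).
#' @slot breakpointInterval numeric length-2 interval (positions of the
#'   flanking non-deleted loci; NA where unbounded), or NAs when no
#'   deletion-supporting locus exists.
#' @exportClass DeletionEvidence
setClass("DeletionEvidence",
  representation(loci = "data.frame", breakpointInterval = "numeric"))

#' Per-family diagnostic report
#'
#' @slot familyId family identifier.
#' @slot status solved / candidate / unsolved.
#' @slot causative the causative (or best candidate) CandidateGenotype, or
#'   NULL.
#' @slot candidates list of all classified CandidateGenotype objects.
#' @slot modifiers data.frame of modifier alleles (heterozygous rare
#'   predicted-pathogenic or known recessive alleles outside the causative
#'   genotype), with an \code{acmg_class} column.
#' @slot notes character notes.
#' @exportClass FamilyReport
setClass("FamilyReport",
  representation(familyId = "character", status = "character",
                 causative = "ANY", candidates = "list",
                 modifiers = "data.frame", notes = "character"))

setValidity("FamilyReport", function(object) {
  if (!object@status %in% c("solved", "candidate", "unsolved"))
    return("status must be solved/candidate/unsolved")
  TRUE
})

#' Cohort-level diagnostic summary
#'
#' @slot nFamilies cohort size.
#' @slot nSolved,nCandidate,nUnsolved family counts by status.
#' @slot pctSolved,pctCandidate exact percentages (not rounded).
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(nFamilies = "integer", nSolved = "integer",
                 nCandidate = "integer", nUnsolved = "integer",
                 pctSolved = "numeric", pctCandidate = "numeric"))

setValidity("CohortSummary", function(object) {
  if (object@nSolved + object@nCandidate + object@nUnsolved !=
      object@nFamilies)
    return("status counts must sum to the cohort size")
  TRUE
})
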