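#' Construct an AcmgEvidence set
#'
#' @param codes character vector of evidence codes (a subset of
#'   PVS1, PS3, PM2, PM3, PM3_strong, PM3_supporting, PP1, PP3,
#'   PP5_reported, BA1).
#' @return an \linkS4class{AcmgEvidence}.
#' @export
acmgEvidence <- function(codes = character())
  new("AcmgEvidence", codes = unique(as.character(codes)))

## how secure is the trans allele of a compound heterozygote?
.TRANS_STATUS <- c("none", "candidate", "reported", "plp",
                   "pvs1_pathogenic")

#' Derive ACMG/AMP evidence codes for one allele
#'
#' Evidence is derived from the allele's annotations, the gene's panel
#' entry, the family-level cosegregation status and (for compound
#' heterozygotes) how secure the trans allele is:
#' \itemize{
#'   \item PVS1: null allele (nonsense, frameshift, canonical splice,
#'     exonic deletion/duplication) in a gene where loss of function is an
#'     established disease mechanism.
#'   \item PM2: frequency below the rarity ceiling for the inheritance
#'     context (dominant/X-linked 1e-4, recessive 1e-3 by default) or
#'     absent from the reference population.  An allele whose position is
#'     not covered in the reference has unknown frequency and earns no PM2.
#'   \item PM3 (recessive compound heterozygotes only, tiered by the trans
#'     allele): \code{PM3_strong} when the trans allele is
#'     PVS1-Pathogenic, \code{PM3} (moderate) when it is
#'     Pathogenic/Likely Pathogenic or literature-reported pathogenic,
#'     \code{PM3_supporting} when it is merely a surviving co-candidate.
#'     Homozygotes earn no PM3 (self-support would be circular).
#'   \item PP1: cosegregation with disease is consistent in the family.
#'   \item PP3: missense/splice-region allele with a positive consensus of
#'     in-silico predictors.
#'   \item PS3: functional (wet-lab) support recorded for the gene.
#'   \item PP5_reported: previously reported as pathogenic.
#'   \item BA1: frequency above 5\% (stand-alone benign).
#' }
#'
#' @param variant one-row variant data.frame.
#' @param panelEntry list for the gene as returned by
#'   \code{\link{geneInfo}}.
#' @param model inheritance model of the candidate (AD, AR_hom,
#'   AR_comphet, XL), or NA for a stand-alone allele (the rarity ceiling
#'   then follows the gene's inheritance modes).
#' @param cosegregation consistent/inconsistent/unavailable.
#' @param transStatus for AR_comphet alleles, one of \code{"none"},
#'   \code{"candidate"}, \code{"reported"}, \code{"plp"},
#'   \code{"pvs1_pathogenic"} describing the trans allele.
#' @param config a \code{\link{prioritizationConfig}}.
#' @return an \linkS4class{AcmgEvidence}.
#' @export
deriveEvidence <- function(variant, panelEntry, model = NA,
                           cosegregation = "unavailable",
                           transStatus = "none",
                           config = prioritizationConfig()) {
  stopifnot(nrow(variant) == 1L, transStatus %in% .TRANS_STATUS)
  codes <- character()
  csq <- variant$consequence
  if (csq %in% .DISRUPTIVE && isTRUE(panelEntry$lof_mechanism))
    codes <- c(codes, "PVS1")

  af <- alleleFrequency(variant)
  recessive <- if (!is.na(model)) model %in% c("AR_hom", "AR_comphet")
    else "AR" %in% strsplit(panelEntry$modes, ",", fixed = TRUE)[[1]]
  ceiling <- if (recessive) config$pm2_af_recessive else config$pm2_af_dominant
  if (!is.na(af) && af > 0.05) codes <- c(codes, "BA1")
  else if (!is.na(af) && af < ceiling) codes <- c(codes, "PM2")

  if (identical(model, "AR_comphet"))
    codes <- c(codes, switch(transStatus,
                             pvs1_pathogenic = "PM3_strong",
                             plp = "PM3",
                             reported = "PM3",
                             candidate = "PM3_supporting",
                             none = NULL))

  if (identical(cosegregation, "consistent")) codes <- c(codes, "PP1")

  if (csq %in% c("missense", "noncanonical_splice_region") &&
      countPositivePredictors(variant) >= config$min_positive_predictors)
    codes <- c(codes, "PP3")

  if (isTRUE(panelEntry$functional_support)) codes <- c(codes, "PS3")
  if (identical(variant$reported, "reported_pathogenic"))
    codes <- c(codes, "PP5_reported")
  acmgEvidence(codes)
}

#' Combine ACMG evidence into a variant class
#'
#' Implements the standard evidence-combining rules over the derived
#' codes.  With \code{p} = PVS1 present, \code{s}/\code{m}/\code{u} the
#' counts of strong/moderate/supporting codes:
#' \itemize{
#'   \item Pathogenic: \code{p} with (>= 1 strong, or >= 2 moderate, or
#'     1 moderate + 1 supporting, or >= 2 supporting); or >= 2 strong; or
#'     1 strong with (>= 3 moderate, or 2 moderate + >= 2 supporting, or
#'     1 moderate + >= 4 supporting).
#'   \item Likely Pathogenic: \code{p} + 1 moderate; 1 strong + 1-2
#'     moderate; 1 strong + >= 2 supporting; >= 3 moderate; 2 moderate +
#'     >= 2 supporting; 1 moderate + >= 4 supporting.
#'   \item BA1 alone: Benign.  BA1 together with PVS1 is contradictory:
#'     VUS with a conflict attribute.
#'   \item otherwise VUS.
#' }
#'
#' In a gene of uncertain disease relevance (association
#' \code{candidate_gene}) without functional support (no PS3), the class is
#' post-filtered: a would-be Pathogenic/Likely Pathogenic allele becomes
#' VGUS when disruptive and VUS when missense; a would-be VUS allele that
#' is part of a complete cosegregating causal genotype (PP1) and is
#' disruptive or predictor-supported (PP3) becomes VGUS.  VGUS — a clearly
#' disruptive variant in a gene whose disease role is uncertain — is an
#' output label of this workflow, not an ACMG standard class.
#'
#' @param evidence an \linkS4class{AcmgEvidence}.
#' @param association the gene's association tier.
#' @param disruptive is the allele a null/copy-number (disruptive) allele?
#' @return a single character class (Pathogenic, LikelyPathogenic, VUS,
#'   VGUS, Benign), with attribute \code{conflict = TRUE} when
#'   contradictory evidence was collapsed to VUS.
#' @export
combineEvidence <- function(evidence, association = "established_IRD",
                            disruptive = FALSE) {
  codes <- evidenceCodes(evidence)
  str <- .ACMG_STRENGTH[codes]
  p <- "PVS1" %in% codes
  s <- sum(str == "strong")
  m <- sum(str == "moderate")
  u <- sum(str == "supporting")
  ba1 <- "BA1" %in% codes

  if (ba1 && p)
    return(structure("VUS", conflict = TRUE))
  if (ba1) return("Benign")

  cls <- if ((p && (s >= 1 || m >= 2 || (m == 1 && u >= 1) || u >= 2)) ||
             s >= 2 ||
             (s == 1 && (m >= 3 || (m == 2 && u >= 2) ||
                         (m == 1 && u >= 4)))) "Pathogenic"
  else if ((p && m >= 1) ||
           (s == 1 && m >= 1) || (s == 1 && u >= 2) ||
           m >= 3 || (m == 2 && u >= 2) || (m == 1 && u >= 4))
    "LikelyPathogenic"
  else "VUS"

  if (association == "candidate_gene" && !"PS3" %in% codes) {
    if (cls %in% c("Pathogenic", "LikelyPathogenic"))
      cls <- if (disruptive) "VGUS" else "VUS"
    else if (cls == "VUS" && "PP1" %in% codes &&
             (disruptive || "PP3" %in% codes))
      cls <- "VGUS"
  }
  cls
}

## trans-allele status from its base class (classified without PM3) and
## reported status
.transStatusOf <- function(baseClass, basePvs1, reported) {
  if (identical(baseClass, "Pathogenic") && basePvs1) "pvs1_pathogenic"
  else if (baseClass %in% c("Pathogenic", "LikelyPathogenic")) "plp"
  else if (identical(reported, "reported_pathogenic")) "reported"
  else "candidate"
}

#' Classify all alleles of a candidate genotype
#'
#' Two-pass procedure: every allele is first classified without PM3 (its
#' base class); for compound heterozygotes the partner's base class and
#' reported status then set the PM3 tier, and the final class is computed
#' with PM3 included.
#'
#' @param candidate a \linkS4class{CandidateGenotype}.
#' @param panel a \linkS4class{GenePanel}.
#' @param config a \code{\link{prioritizationConfig}}.
#' @return the candidate with \code{evidence} and \code{classes} filled.
#' @export
classifyCandidate <- function(candidate, panel,
                              config = prioritizationConfig()) {
  entry <- geneInfo(panel, candidate@gene)
  al <- candidate@alleles
  n <- nrow(al)
  base <- lapply(seq_len(n), function(i)
    deriveEvidence(al[i, , drop = FALSE], entry, candidate@model,
                   candidate@cosegregation, "none", config))
  baseCls <- vapply(seq_len(n), function(i)
    combineEvidence(base[[i]], entry$association,
                    al$consequence[i] %in% .DISRUPTIVE), character(1))

  if (candidate@model == "AR_comphet") {
    ## class used for PM3 must be the unfiltered combining-rule class
    rawCls <- vapply(seq_len(n), function(i)
      combineEvidence(base[[i]]), character(1))
    ev <- lapply(seq_len(n), function(i) {
      j <- if (i == 1L) 2L else 1L
      ts <- .transStatusOf(rawCls[j], "PVS1" %in% evidenceCodes(base[[j]]),
                           al$reported[j])
      deriveEvidence(al[i, , drop = FALSE], entry, candidate@model,
                     candidate@cosegregation, ts, config)
    })
    cls <- vapply(seq_len(n), function(i)
      combineEvidence(ev[[i]], entry$association,
                      al$consequence[i] %in% .DISRUPTIVE), character(1))
  } else {
    ev <- base
    cls <- baseCls
  }
  candidate@evidence <- ev
  candidate@classes <- cls
  candidate
}

#' Classify a stand-alone allele (outside any candidate genotype)
#'
#' Used for modifier alleles: heterozygous reported-pathogenic or rare
#' predicted-pathogenic alleles in panel genes outside the causative
#' genotype.
#'
#' @param variant one-row variant data.frame.
#' @param panel a \linkS4class{GenePanel}.
#' @param cosegregation cosegregation status of the allele, if assessed.
#' @param config a \code{\link{prioritizationConfig}}.
#' @return list with elements \code{evidence} and \code{class}.
#' @export
classifyVariant <- function(variant, panel, cosegregation = "unavailable",
                            config = prioritizationConfig()) {
  entry <- geneInfo(panel, variant$gene)
  ev <- deriveEvidence(variant, entry, NA, cosegregation, "none", config)
  list(evidence = ev,
       class = combineEvidence(ev, entry$association,
                               variant$consequence %in% .DISRUPTIVE))
}
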