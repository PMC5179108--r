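#' Aggregate classified candidates into a per-family diagnosis
#'
#' A family is \code{solved} when some classified candidate genotype (i)
#' lies in an established disease gene, or in a candidate gene with
#' functional support (PS3), (ii) is complete for its inheritance model
#' (two alleles for compound heterozygotes, one otherwise), (iii) has
#' cosegregation consistent or unavailable (an unavailable cosegregation
#' does not block a diagnosis), and (iv) has every causal allele
#' Pathogenic or Likely Pathogenic.  A family is \code{candidate} when
#' candidates exist but the best one carries a VUS/VGUS allele, lies in a
#' candidate gene without functional support, or cosegregates
#' inconsistently (incomplete penetrance).  Otherwise the family is
#' \code{unsolved}.
#'
#' @param candidates list of classified \linkS4class{CandidateGenotype}.
#' @param panel a \linkS4class{GenePanel}.
#' @param modifiers data.frame of modifier alleles (may carry an
#'   \code{acmg_class} column); stored in the report.
#' @param familyId family identifier (defaults to the candidates' family).
#' @return a \linkS4class{FamilyReport}.
#' @export
diagnoseFamily <- function(candidates, panel,
                           modifiers = data.frame(),
                           familyId = NULL) {
  if (is.null(familyId)) {
    if (!length(candidates))
      stop("familyId must be given when there are no candidates")
    familyId <- candidates[[1]]@familyId
  }
  isSolved <- function(cg) {
    entry <- geneInfo(panel, cg@gene)
    credible <- entry$association != "candidate_gene" ||
      isTRUE(entry$functional_support)
    complete <- nrow(cg@alleles) == if (cg@model == "AR_comphet") 2L else 1L
    credible && complete &&
      cg@cosegregation %in% c("consistent", "unavailable") &&
      length(cg@classes) > 0 &&
      all(cg@classes %in% c("Pathogenic", "LikelyPathogenic"))
  }
  solved <- vapply(candidates, isSolved, logical(1))
  status <- if (any(solved)) "solved"
            else if (length(candidates)) "candidate"
            else "unsolved"
  causative <- if (any(solved)) candidates[[which(solved)[1]]]
               else if (length(candidates)) {
                 ## best candidate: most severe worst-allele class
                 rank <- c(Pathogenic = 1, LikelyPathogenic = 2, VGUS = 3,
                           VUS = 4, Benign = 5)
                 worst <- vapply(candidates, function(cg)
                   max(rank[cg@classes]), numeric(1))
                 candidates[[which.min(worst)]]
               } else NULL
  notes <- if (!is.null(causative) &&
               causative@cosegregation == "inconsistent")
    "cosegregation inconsistent: unaffected carriers (incomplete penetrance?)"
  else character()
  new("FamilyReport", familyId = familyId, status = status,
      causative = causative, candidates = candidates,
      modifiers = modifiers, notes = notes)
}
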