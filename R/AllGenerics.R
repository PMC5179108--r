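#' @rdname FamilyPedigree-class
#' @param x,object an object.
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

#' @rdname FamilyReport-class
#' @export
setGeneric("diagnosisStatus", function(x) standardGeneric("diagnosisStatus"))

#' @rdname FamilyReport-class
#' @export
setGeneric("causativeGenotype",
           function(x) standardGeneric("causativeGenotype"))

#' @rdname GenePanel-class
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname GenePanel-class
#' @param gene gene symbol.
#' @export
setGeneric("geneInfo", function(x, gene) standardGeneric("geneInfo"))

#' @rdname AcmgEvidence-class
#' @export
setGeneric("evidenceCodes", function(x) standardGeneric("evidenceCodes"))

#' @rdname AcmgEvidence-class
#' @export
setGeneric("evidenceStrengths",
           function(x) standardGeneric("evidenceStrengths"))

#' @rdname CandidateGenotype-class
#' @export
setGeneric("inheritanceModel",
           function(x) standardGeneric("inheritanceModel"))

#' @rdname CandidateGenotype-class
#' @export
setGeneric("alleleTable", function(x) standardGeneric("alleleTable"))

#' @rdname CandidateGenotype-class
#' @export
setGeneric("acmgClasses", function(x) standardGeneric("acmgClasses"))

#' @rdname CandidateGenotype-class
#' @export
setGeneric("cosegregation", function(x) standardGeneric("cosegregation"))

#' @rdname CnvCall-class
#' @export
setGeneric("cnvState", function(x) standardGeneric("cnvState"))

## ---- methods -------------------------------------------------------------

#' @rdname FamilyPedigree-class
#' @export
setMethod("familyId", "FamilyPedigree", function(x) x@familyId)

#' @rdname CandidateGenotype-class
#' @export
setMethod("familyId", "CandidateGenotype", function(x) x@familyId)

#' @rdname FamilyReport-class
#' @export
setMethod("familyId", "FamilyReport", function(x) x@familyId)

#' @rdname FamilyReport-class
#' @export
setMethod("diagnosisStatus", "FamilyReport", function(x) x@status)

#' @rdname FamilyReport-class
#' @export
setMethod("causativeGenotype", "FamilyReport", function(x) x@causative)

#' @rdname GenePanel-class
#' @export
setMethod("panelGenes", "GenePanel", function(x) x@genes$gene)

#' @rdname GenePanel-class
#' @export
setMethod("geneInfo", "GenePanel", function(x, gene) {
  i <- match(gene, x@genes$gene)
  if (is.na(i)) stop(sprintf("gene '%s' is not in the panel", gene))
  as.list(x@genes[i, ])
})

#' @rdname AcmgEvidence-class
#' @export
setMethod("evidenceCodes", "AcmgEvidence", function(x) x@codes)

#' @rdname AcmgEvidence-class
#' @export
setMethod("evidenceStrengths", "AcmgEvidence",
          function(x) .ACMG_STRENGTH[x@codes])

#' @rdname CandidateGenotype-class
#' @export
setMethod("inheritanceModel", "CandidateGenotype", function(x) x@model)

#' @rdname CandidateGenotype-class
#' @export
setMethod("alleleTable", "CandidateGenotype", function(x) x@alleles)

#' @rdname CandidateGenotype-class
#' @export
setMethod("acmgClasses", "CandidateGenotype", function(x) x@classes)

#' @rdname CandidateGenotype-class
#' @export
setMethod("cosegregation", "CandidateGenotype", function(x) x@cosegregation)

#' @rdname CnvCall-class
#' @export
setMethod("cnvState", "CnvCall", function(x) x@state)

## ---- show methods --------------------------------------------------------

setMethod("show", "FamilyPedigree", function(object) {
  m <- object@members
  cat(sprintf("FamilyPedigree '%s': %d members (%d affected)%s\n",
              object@familyId, nrow(m), sum(m$affected == "affected"),
              if (isTRUE(object@consanguineous)) ", consanguineous" else ""))
})

setMethod("show", "GenePanel", function(object) {
  g <- object@genes
  cat(sprintf("GenePanel: %d genes (%d established, %d candidate)\n",
              nrow(g), sum(g$association != "candidate_gene"),
              sum(g$association == "candidate_gene")))
})

setMethod("show", "AcmgEvidence", function(object) {
  if (!length(object@codes)) { cat("AcmgEvidence: (none)\n"); return() }
  cat("AcmgEvidence:",
      paste(sprintf("%s[%s]", object@codes, .ACMG_STRENGTH[object@codes]),
            collapse = " "), "\n")
})

setMethod("show", "CandidateGenotype", function(object) {
  cat(sprintf("CandidateGenotype %s | %s | %s | %d allele(s) | coseg %s\n",
              object@familyId, object@gene, object@model,
              nrow(object@alleles), object@cosegregation))
  if (length(object@classes))
    cat("  classes:", paste(object@classes, collapse = " + "), "\n")
})

setMethod("show", "CnvCall", function(object) {
  if (object@state == "normal")
    cat(sprintf("CnvCall %s: normal\n", object@gene))
  else
    cat(sprintf("CnvCall %s: %s exons %d-%d (%d supporting)\n",
                object@gene, object@state, object@exonRange[1],
                object@exonRange[2], object@supportingExons))
})

setMethod("show", "DeletionEvidence", function(object) {
  n <- table(factor(object@loci$flag,
                    levels = c("deletion_supporting", "non_deleted",
                               "uninformative")))
  cat(sprintf(paste0("DeletionEvidence: %d loci ",
                     "(%d deletion-supporting, %d non-deleted, ",
                     "%d uninformative)\n"),
              nrow(object@loci), n[1], n[2], n[3]))
  bp <- object@breakpointInterval
  if (!all(is.na(bp)))
    cat(sprintf("  breakpoint interval: (%s, %s)\n",
                ifelse(is.na(bp[1]), "-inf", format(bp[1])),
                ifelse(is.na(bp[2]), "+inf", format(bp[2]))))
})

setMethod("show", "FamilyReport", function(object) {
  cat(sprintf("FamilyReport %s: %s\n", object@familyId, object@status))
  if (!is.null(object@causative)) {
    cg <- object@causative
    cat(sprintf("  causative: %s (%s) %s\n", cg@gene, cg@model,
                paste(cg@classes, collapse = " + ")))
  }
  if (nrow(object@modifiers))
    cat(sprintf("  modifiers: %d allele(s)\n", nrow(object@modifiers)))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf(paste0("CohortSummary: %d families | solved %d (%d%%) | ",
                     "candidate %d (%d%%) | unsolved %d\n"),
              object@nFamilies, object@nSolved, round(object@pctSolved),
              object@nCandidate, round(object@pctCandidate),
              object@nUnsolved))
})
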