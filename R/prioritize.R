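#' Prioritization configuration
#'
#' Tunable parameters of the three-stage prioritization cascade.
#'
#' @param af_max maximum population allele frequency; the boundary is
#'   inclusive (frequency <= af_max is kept).  Default 0.01.
#' @param retained_consequences consequence classes that pass the
#'   consequence filter.
#' @param min_positive_predictors minimum number of in-silico tools calling
#'   a missense variant damaging (default 2 of the 4 tools).
#' @param reported_pathogenic_whitelist keep literature-reported pathogenic
#'   alleles regardless of consequence class (covers reported deep-intronic
#'   alleles).  Default TRUE.
#' @param penetrance_mode \code{"complete"} (dominant candidates must be
#'   absent from unaffected relatives) or \code{"incomplete"} (unaffected
#'   carriers are tolerated but force cosegregation to inconsistent).
#' @param pm2_af_dominant,pm2_af_recessive PM2 rarity ceilings (strict
#'   upper bounds) used during evidence derivation for dominant/X-linked
#'   and recessive candidates respectively.
#' @return a list of class \code{PrioritizationConfig}.
#' @export
prioritizationConfig <- function(af_max = 0.01,
                                 retained_consequences = c(
                                   "nonsense", "frameshift",
                                   "canonical_splice",
                                   "noncanonical_splice_region", "missense",
                                   "exonic_deletion", "exonic_duplication"),
                                 min_positive_predictors = 2L,
                                 reported_pathogenic_whitelist = TRUE,
                                 penetrance_mode = c("complete",
                                                     "incomplete"),
                                 pm2_af_dominant = 1e-4,
                                 pm2_af_recessive = 1e-3) {
  penetrance_mode <- match.arg(penetrance_mode)
  stopifnot(af_max > 0, af_max <= 1,
            min_positive_predictors >= 1L, min_positive_predictors <= 4L,
            all(retained_consequences %in% .CONSEQUENCES))
  structure(list(af_max = af_max,
                 retained_consequences = retained_consequences,
                 min_positive_predictors = as.integer(min_positive_predictors),
                 reported_pathogenic_whitelist = reported_pathogenic_whitelist,
                 penetrance_mode = penetrance_mode,
                 pm2_af_dominant = pm2_af_dominant,
                 pm2_af_recessive = pm2_af_recessive),
            class = c("PrioritizationConfig", "list"))
}

#' Filter variants by population allele frequency
#'
#' Keeps records whose ExAC-style frequency is lower than or equal to
#' \code{af_max} (inclusive boundary).  Records absent from the reference
#' population are always kept, as are records whose frequency is unknown
#' (position not covered).
#'
#' @param variants variant data.frame.
#' @param config a \code{\link{prioritizationConfig}}.
#' @return the filtered data.frame.
#' @export
filterByFrequency <- function(variants, config = prioritizationConfig()) {
  if (!nrow(variants)) return(variants)
  af <- alleleFrequency(variants)
  keep <- is.na(af) | af <= config$af_max
  variants[keep, , drop = FALSE]
}

#' Filter variants by consequence class
#'
#' Keeps null, missense, frameshift, splicing and exonic copy-number
#' records; literature-reported pathogenic alleles are whitelisted through
#' regardless of consequence when the whitelist is enabled.  Records with a
#' missing or \code{"other"} consequence are removed (with a message).
#'
#' @inheritParams filterByFrequency
#' @return the filtered data.frame.
#' @export
filterByConsequence <- function(variants, config = prioritizationConfig()) {
  if (!nrow(variants)) return(variants)
  csq <- variants$consequence
  keep <- !is.na(csq) & csq %in% config$retained_consequences
  if (config$reported_pathogenic_whitelist)
    keep <- keep | (!is.na(variants$reported) &
                    variants$reported == "reported_pathogenic")
  dropped <- which(!keep & (is.na(csq) | csq == "other"))
  if (length(dropped))
    message(length(dropped),
            " record(s) with missing/'other' consequence removed")
  variants[keep, , drop = FALSE]
}

## per-tool positivity; when both a categorical call and a score are
## present the call wins (the published table shows calls such as
## "Tolerated" alongside scores like 0.06)
.predictorPositive <- function(variants) {
  pp2 <- ifelse(!is.na(variants$pp2_call),
                variants$pp2_call %in% c("Probably D.", "Possibly D."),
                ifelse(!is.na(variants$pp2_score),
                       variants$pp2_score >= 0.85, NA))
  sift <- ifelse(!is.na(variants$sift_call),
                 variants$sift_call == "Damaging",
                 ifelse(!is.na(variants$sift_score),
                        variants$sift_score <= 0.05, NA))
  mt <- ifelse(!is.na(variants$mt_call),
               variants$mt_call == "Disease C.",
               ifelse(!is.na(variants$mt_score),
                      variants$mt_score >= 0.5, NA))
  cadd <- ifelse(!is.na(variants$cadd), variants$cadd >= 15, NA)
  cbind(polyphen2 = pp2, sift = sift, mutationtaster = mt, cadd = cadd)
}

#' Count positive in-silico predictors
#'
#' @param variants variant data.frame.
#' @return integer vector: number of tools (PolyPhen2, SIFT,
#'   MutationTaster, CADD) calling each record damaging; tools with neither
#'   score nor call contribute nothing.
#' @export
countPositivePredictors <- function(variants) {
  pos <- .predictorPositive(variants)
  as.integer(rowSums(pos, na.rm = TRUE))
}

#' Consensus in-silico pathogenicity test
#'
#' A missense variant passes when at least
#' \code{min_positive_predictors} of the four tools give a positive score
#' or call.  Null, frameshift, splicing and copy-number records bypass the
#' test (vacuously TRUE).  A missense record with all four tools missing
#' fails, with a warning.
#'
#' @inheritParams filterByFrequency
#' @return logical vector, one element per record.
#' @export
consensusPathogenicity <- function(variants,
                                   config = prioritizationConfig()) {
  if (!nrow(variants)) return(logical())
  needsTest <- variants$consequence %in% "missense"
  pos <- .predictorPositive(variants)
  nTools <- rowSums(!is.na(pos))
  n <- as.integer(rowSums(pos, na.rm = TRUE))
  out <- rep(TRUE, nrow(variants))
  out[needsTest] <- n[needsTest] >= config$min_positive_predictors
  blind <- needsTest & nTools == 0L
  if (any(blind)) {
    warning("missense record(s) with all predictors missing fail the ",
            "consensus test: ", paste(variants$id[blind], collapse = ", "))
    out[blind] <- FALSE
  }
  out
}

#' Run the full prioritization cascade on a variant table
#'
#' Frequency filter, consequence filter, then the consensus prediction
#' filter on missense records.  The first two filters commute; the
#' consensus filter only ever removes missense/splice-region records.
#'
#' @inheritParams filterByFrequency
#' @return the prioritized data.frame.
#' @export
prioritizeVariants <- function(variants, config = prioritizationConfig()) {
  v <- filterByConsequence(filterByFrequency(variants, config), config)
  if (!nrow(v)) return(v)
  keep <- consensusPathogenicity(v, config) |
    (!is.na(v$reported) & v$reported == "reported_pathogenic" &
       config$reported_pathogenic_whitelist)
  v[keep, , drop = FALSE]
}

## ---- inheritance-model genotype selection --------------------------------

.isCarrier <- function(z) z %in% c("het", "hom_alt", "hemizygous")

.newCandidate <- function(fam, gene, model, alleles, coseg = "unavailable",
                          phased = NA)
  new("CandidateGenotype", familyId = fam, gene = gene, model = model,
      alleles = alleles, cosegregation = coseg, phased = phased,
      evidence = list(), classes = character())

#' Select candidate genotypes under a Mendelian inheritance model
#'
#' Given prioritized variants with per-member zygosity calls, returns every
#' genotype configuration in a panel gene that complies with the requested
#' model:
#' \describe{
#'   \item{AD}{one heterozygous allele carried by all genotyped affecteds
#'     and absent from genotyped unaffecteds (unless
#'     \code{penetrance_mode = "incomplete"}, in which case unaffected
#'     carriers are tolerated and cosegregation is forced to inconsistent).}
#'   \item{AR_hom}{homozygous-alt in all affecteds, not homozygous in any
#'     unaffected; genotyped parents of affecteds must be heterozygous.}
#'   \item{AR_comphet}{exactly two distinct heterozygous alleles in the
#'     same gene in all affecteds, in trans whenever parental genotypes
#'     phase them, never co-occurring in an unaffected.}
#'   \item{XL}{chrX alleles hemizygous in affected males (heterozygous or
#'     homozygous females are compatible), with genotyped mothers of
#'     affected males carrying the allele; unaffected males must not carry
#'     it.}
#' }
#' Simplex families (a single genotyped affected) are usually evaluated
#' under all four models; see \code{\link{analyzeFamily}}.
#'
#' @param variants prioritized variant data.frame.
#' @param genotypes zygosity matrix (variants x samples; rownames are
#'   variant ids).
#' @param pedigree a \linkS4class{FamilyPedigree}.
#' @param panel a \linkS4class{GenePanel}; only panel genes whose
#'   inheritance modes include the model's mode are considered.
#' @param model one of \code{"AD"}, \code{"AR_hom"}, \code{"AR_comphet"},
#'   \code{"XL"}.
#' @param config a \code{\link{prioritizationConfig}}.
#' @return list of \linkS4class{CandidateGenotype} (with cosegregation
#'   already assessed via \code{\link{checkCosegregation}}).
#' @export
candidateGenotypes <- function(variants, genotypes, pedigree, panel,
                               model = c("AD", "AR_hom", "AR_comphet", "XL"),
                               config = prioritizationConfig()) {
  model <- match.arg(model)
  if (!nrow(variants)) return(list())
  bad <- setdiff(colnames(genotypes), pedigree@members$id)
  if (length(bad))
    stop("genotype sample(s) not in pedigree: ", paste(bad, collapse = ", "))
  if (!identical(rownames(genotypes), variants$id))
    genotypes <- genotypes[variants$id, , drop = FALSE]
  aff <- intersect(.affectedIds(pedigree), colnames(genotypes))
  una <- intersect(.unaffectedIds(pedigree), colnames(genotypes))
  if (!length(aff)) return(list())
  fam <- pedigree@familyId

  onX <- variants$chrom %in% c("chrX", "X")
  onY <- variants$chrom %in% c("chrY", "Y")
  mode <- c(AD = "AD", AR_hom = "AR", AR_comphet = "AR", XL = "XL")[model]
  inScope <- vapply(variants$gene, function(g)
    !is.na(g) && .geneHasMode(panel, g, mode), logical(1))
  inScope <- inScope & !onY & if (model == "XL") onX else !onX

  out <- list()
  addCg <- function(gene, alleleIdx, phased = NA) {
    alleles <- variants[alleleIdx, , drop = FALSE]
    alleles$zygosity <- genotypes[alleleIdx, aff[1]]
    cg <- .newCandidate(fam, gene, model, alleles, phased = phased)
    cg@cosegregation <- checkCosegregation(cg, pedigree, genotypes, config)
    out[[length(out) + 1L]] <<- cg
  }

  zrow <- function(i) stats::setNames(genotypes[i, ], colnames(genotypes))
  if (model == "AD") {
    for (i in which(inScope)) {
      z <- zrow(i)
      if (!all(z[aff] %in% c("het", "hom_alt"))) next
      if (config$penetrance_mode == "complete" &&
          any(.isCarrier(z[una]))) next
      addCg(variants$gene[i], i)
    }
  } else if (model == "AR_hom") {
    for (i in which(inScope)) {
      z <- zrow(i)
      if (!all(z[aff] == "hom_alt")) next
      if (any(z[una] == "hom_alt")) next
      parents <- intersect(unique(unlist(lapply(aff, .parentsOf,
                                                ped = pedigree))),
                           colnames(genotypes))
      if (length(parents) && !all(genotypes[i, parents] == "het")) next
      addCg(variants$gene[i], i)
    }
  } else if (model == "AR_comphet") {
    for (g in unique(variants$gene[inScope])) {
      gi <- which(inScope & variants$gene == g)
      hetAll <- gi[vapply(gi, function(i)
        all(genotypes[i, aff] == "het"), logical(1))]
      if (length(hetAll) < 2L) next
      for (a in seq_along(hetAll)) for (b in seq_len(a - 1L)) {
        i <- hetAll[b]; j <- hetAll[a]
        ## an unaffected member must not carry both alleles
        if (length(una) && any(.isCarrier(genotypes[i, una]) &
                               .isCarrier(genotypes[j, una]))) next
        ph <- .comphetPhase(i, j, aff, pedigree, genotypes)
        if (identical(ph, "cis")) next
        addCg(g, c(i, j), phased = identical(ph, "trans"))
      }
    }
  } else {                                            # XL
    males <- pedigree@members$id[pedigree@members$sex == "male"]
    for (i in which(inScope)) {
      z <- zrow(i)
      affM <- intersect(aff, males)
      affF <- setdiff(aff, males)
      if (length(affM) &&
          !all(z[affM] %in% c("hemizygous", "hom_alt"))) next
      if (length(affF) && !all(z[affF] %in% c("het", "hom_alt"))) next
      if (!length(affM) && !length(affF)) next
      unaM <- intersect(una, males)
      if (any(z[unaM] %in% c("hemizygous", "hom_alt"))) next
      mothers <- intersect(
        unique(vapply(affM, function(a) {
          p <- .parentsOf(pedigree, a); unname(p["mother"])
        }, character(1))), colnames(genotypes))
      mothers <- mothers[!is.na(mothers)]
      if (length(mothers) && !all(.isCarrier(z[mothers]))) next
      addCg(variants$gene[i], i)
    }
  }
  out
}

## phase a het pair from parental genotypes: "trans", "cis" or "unknown"
.comphetPhase <- function(i, j, aff, pedigree, genotypes) {
  verdict <- "unknown"
  for (child in aff) {
    p <- .parentsOf(pedigree, child)
    p <- p[p %in% colnames(genotypes)]
    if (length(p) < 2L) next
    c1 <- .isCarrier(genotypes[i, p])
    c2 <- .isCarrier(genotypes[j, p])
    ## each allele attributable to exactly one parent?
    if (sum(c1) == 1L && sum(c2) == 1L)
      return(if (which(c1) == which(c2)) "cis" else "trans")
  }
  verdict
}

#' Assess cosegregation of a candidate genotype in the family
#'
#' \code{unavailable} when no informative relative is genotyped (only one
#' genotyped member); \code{inconsistent} when a genotyped unaffected
#' relative carries the full causal genotype (a dominant het carrier, a
#' recessive homozygote or double-het, a hemizygous male); \code{consistent}
#' otherwise.
#'
#' @param candidate a \linkS4class{CandidateGenotype}.
#' @param pedigree a \linkS4class{FamilyPedigree}.
#' @param genotypes zygosity matrix.
#' @param config a \code{\link{prioritizationConfig}}.
#' @return one of \code{"consistent"}, \code{"inconsistent"},
#'   \code{"unavailable"}.
#' @export
checkCosegregation <- function(candidate, pedigree, genotypes,
                               config = prioritizationConfig()) {
  if (ncol(genotypes) <= 1L) return("unavailable")
  una <- intersect(.unaffectedIds(pedigree), colnames(genotypes))
  ids <- candidate@alleles$id
  carriesFull <- function(s) {
    z <- genotypes[ids, s]
    switch(candidate@model,
           AD = .isCarrier(z),
           AR_hom = z == "hom_alt",
           AR_comphet = all(.isCarrier(z)),
           XL = z %in% c("hemizygous", "hom_alt"))
  }
  if (length(una) && any(vapply(una, carriesFull, logical(1))))
    return("inconsistent")
  "consistent"
}
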