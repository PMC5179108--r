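#' Simulation configuration
#'
#' Defines the study conditions a simulated cohort emulates.  Defaults
#' mirror the published cohort: 33 families (14 simplex, 4 dominant, 14
#' recessive, 1 X-linked), a panel of around 300 genes, and per-patient
#' modifier-allele rates of 0.3 known pathogenic recessive alleles and
#' 5.25 rare predicted-pathogenic alleles (Poisson means).
#'
#' @param seed mandatory integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @param n_families number of families; must equal \code{sum(model_mix)}.
#' @param model_mix named integer vector: families per structure
#'   (simplex / AD / AR / XL).
#' @param status_mix named proportions of expected diagnostic statuses
#'   (solved / candidate / unsolved); scaled to \code{n_families}.
#' @param panel_size synthetic panel size (default 300 genes).
#' @param n_candidate_genes genes of uncertain disease relevance in the
#'   panel.
#' @param background_per_gene expected background (non-causal,
#'   non-modifier) variants per panel gene per patient; background records
#'   are synonymous, deep-intronic or common missense — variation the
#'   prioritization cascade is designed to remove.
#' @param af_absent_frac fraction of rare alleles absent from the
#'   reference population; the remainder draw a log-uniform frequency.
#' @param af_range log-uniform frequency range of background variation.
#' @param causal_af_range log-uniform frequency range of planted causal
#'   alleles (pathogenic spectrum).
#' @param causal_common_frac fraction of planted causal alleles forced to
#'   a frequency above 1\% (they are then removed by the frequency filter;
#'   useful to probe filter behaviour against truth).
#' @param predictor_sensitivity,predictor_specificity per-tool error model
#'   for in-silico predictors, independent across the four tools; set both
#'   to 1 for noiseless predictions.
#' @param modifier_known_mean,modifier_predicted_mean Poisson means of the
#'   per-patient modifier-allele counts.
#' @param penetrance penetrance of dominant genotypes; below 1, unaffected
#'   carriers appear in dominant pedigrees.
#' @param cnv_fraction fraction of solved families whose causal null
#'   allele is an exonic deletion with simulated coverage/MLPA evidence.
#' @param coverage_cv multiplicative coefficient of variation of exon
#'   depths.
#' @param mlpa_sd standard deviation of MLPA probe ratios.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed,
                      n_families = 33L,
                      model_mix = c(simplex = 14L, AD = 4L, AR = 14L,
                                    XL = 1L),
                      status_mix = c(solved = 18, candidate = 10,
                                     unsolved = 5),
                      panel_size = 300L,
                      n_candidate_genes = 8L,
                      background_per_gene = 0.01,
                      af_absent_frac = 0.6,
                      af_range = c(1e-6, 5e-2),
                      causal_af_range = c(1e-6, 1e-3),
                      causal_common_frac = 0,
                      predictor_sensitivity = 0.9,
                      predictor_specificity = 0.8,
                      modifier_known_mean = 0.3,
                      modifier_predicted_mean = 5.25,
                      penetrance = 1,
                      cnv_fraction = 3 / 33,
                      coverage_cv = 0.1,
                      mlpa_sd = 0.05) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (sum(model_mix) != n_families)
    stop("infeasible config: model_mix must sum to n_families")
  stopifnot(penetrance >= 0, penetrance <= 1, panel_size >= 30,
            all(status_mix >= 0), background_per_gene >= 0,
            causal_common_frac >= 0, causal_common_frac <= 1)
  structure(as.list(environment()), class = c("SimConfig", "list"))
}

.logUnif <- function(n, range)
  exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a synthetic gene panel
#'
#' Synthetic genes on a miniature contig set (chr1-22, chrX), with
#' inheritance modes, association tiers, a loss-of-function-mechanism flag
#' and exon counts.  Uses the current RNG state.
#'
#' @param panel_size number of genes.
#' @param n_candidate_genes number of candidate (uncertain-relevance)
#'   genes, placed last.
#' @return a \linkS4class{GenePanel} whose table also carries synthetic
#'   \code{chrom}, \code{start} and \code{n_exons} columns.
#' @export
makeSyntheticPanel <- function(panel_size = 300L, n_candidate_genes = 8L) {
  n <- as.integer(panel_size)
  gene <- sprintf("G%04d", seq_len(n))
  modes <- sample(c("AR", "AD", "XL", "AR,AD"), n, replace = TRUE,
                  prob = c(0.60, 0.20, 0.08, 0.12))
  assoc <- rep("established_IRD", n)
  assoc[sample(which(modes != "XL"), round(0.15 * n))] <-
    "established_syndromic"
  cand <- seq.int(n - n_candidate_genes + 1L, n)
  assoc[cand] <- "candidate_gene"
  modes[cand] <- "AR"                       # recessive new candidates
  chrom <- ifelse(modes == "XL", "chrX",
                  paste0("chr", rep_len(1:22, n)))
  g <- data.frame(gene = gene, association = assoc, modes = modes,
                  lof_mechanism = stats::runif(n) < 0.9,
                  functional_support = FALSE,
                  chrom = chrom,
                  start = 1000000L + seq_len(n) * 100000L,
                  n_exons = sample(1:30, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  genePanel(g)
}

## ---- pedigree structures -------------------------------------------------

.simPedigree <- function(fam, structure, probandSex, penetrance) {
  m <- switch(structure,
    simplex = data.frame(id = "P1", father = NA, mother = NA,
                         sex = probandSex, affected = "affected"),
    AD = data.frame(
      id = c("F1", "M1", "C1", "C2"),
      father = c(NA, NA, "F1", "F1"), mother = c(NA, NA, "M1", "M1"),
      sex = c("male", "female", probandSex, "female"),
      affected = c("affected", "unaffected", "affected", "unaffected")),
    AR = data.frame(
      id = c("F1", "M1", "C1", "C2"),
      father = c(NA, NA, "F1", "F1"), mother = c(NA, NA, "M1", "M1"),
      sex = c("male", "female", probandSex, "male"),
      affected = c("unaffected", "unaffected", "affected", "unaffected")),
    XL = data.frame(
      id = c("F1", "M1", "C1"),
      father = c(NA, NA, "F1"), mother = c(NA, NA, "M1"),
      sex = c("male", "female", "male"),
      affected = c("unaffected", "unaffected", "affected")))
  m[] <- lapply(m, as.character)
  familyPedigree(fam, m)
}

## genotype vector (one value per member) for a planted allele
.plantZygosity <- function(ped, kind, allele = 1L, penetrance = 1) {
  ids <- ped@members$id
  z <- stats::setNames(rep("hom_ref", length(ids)), ids)
  one <- length(ids) == 1L
  proband <- if (one) ids[1] else "C1"
  switch(kind,
    AR_hom = {
      z[proband] <- "hom_alt"
      if (!one) { z[c("F1", "M1")] <- "het"
        z["C2"] <- sample(c("het", "hom_ref"), 1) }
    },
    AR_comphet = {
      z[proband] <- "het"
      if (!one) {
        z[if (allele == 1L) "F1" else "M1"] <- "het"
        ## the unaffected sib may carry at most one allele
        if (allele == 1L && stats::runif(1) < 0.5) z["C2"] <- "het"
      }
    },
    AD = {
      z[proband] <- "het"
      if (!one) {
        z["F1"] <- "het"
        if (penetrance < 1 && stats::runif(1) > penetrance)
          z["C2"] <- "het"                   # non-penetrant carrier
      }
    },
    XL = {
      z[proband] <- "hemizygous"
      if (!one) z["M1"] <- "het"
    })
  z
}

## sample one element (safe for length-1 pools)
.pick <- function(x) x[sample.int(length(x), 1L)]

## Mendelian gene drop of a single founder het allele
.geneDrop <- function(ped) {
  m <- ped@members
  z <- stats::setNames(rep("hom_ref", nrow(m)), m$id)
  founders <- m$id[is.na(m$father) & is.na(m$mother)]
  z[sample(founders, 1)] <- "het"
  ## children inherit from a carrier parent with probability 1/2
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(m))) {
      if (!is.na(m$father[i]) && z[m$id[i]] == "hom_ref") {
        fromF <- z[m$father[i]] != "hom_ref" && stats::runif(1) < 0.5
        fromM <- z[m$mother[i]] != "hom_ref" && stats::runif(1) < 0.5
        if (fromF || fromM) { z[m$id[i]] <- "het"; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  z
}

## draw the four predictor outputs for one record
.simPredictions <- function(pathogenic, csq, sens, spec) {
  out <- list(pp2_call = NA_character_, pp2_score = NA_real_,
              sift_call = NA_character_, sift_score = NA_real_,
              mt_call = NA_character_, mt_score = NA_real_,
              cadd = NA_real_)
  if (csq %in% c("synonymous", "deep_intronic")) return(out)
  if (csq %in% .DISRUPTIVE) {               # table-style null annotation
    out$mt_call <- "Disease C."; out$mt_score <- 1
    return(out)
  }
  pos <- stats::runif(4) < if (pathogenic) sens else 1 - spec
  out$pp2_call <- if (pos[1]) "Probably D." else "Benign"
  out$pp2_score <- if (pos[1]) stats::runif(1, 0.9, 1)
                   else stats::runif(1, 0, 0.4)
  out$sift_call <- if (pos[2]) "Damaging" else "Tolerated"
  out$sift_score <- if (pos[2]) stats::runif(1, 0, 0.05)
                    else stats::runif(1, 0.2, 1)
  out$mt_call <- if (pos[3]) "Disease C." else "Polymorphism"
  out$mt_score <- if (pos[3]) stats::runif(1, 0.95, 1)
                  else stats::runif(1, 0, 0.3)
  out$cadd <- if (pos[4]) stats::runif(1, 15, 40)
              else stats::runif(1, 0, 14.9)
  out
}

.simAf <- function(n, config, causal = FALSE, common = FALSE) {
  if (common) return(.logUnif(n, c(2e-2, 0.5)))
  range <- if (causal) config$causal_af_range else config$af_range
  ifelse(stats::runif(n) < config$af_absent_frac, 0, .logUnif(n, range))
}

#' Simulate a cohort with known ground truth
#'
#' Generates, deterministically from the configuration seed, a cohort of
#' families with pedigrees, annotated variant tables and per-member
#' zygosity calls: planted causal genotypes satisfying their inheritance
#' model, per-patient modifier alleles at the configured Poisson rates,
#' background variation the prioritization cascade removes, in-silico
#' predictor outputs drawn from the per-tool error model, and (for a
#' configurable fraction of solved families) an exonic deletion with
#' simulated coverage and MLPA evidence.  The returned truth table records
#' every planted genotype and the expected diagnostic status.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir optional directory: when given, per-family VCF/PED and
#'   annotation TSVs, the panel, and the truth table are written there.
#' @return list (class \code{SimulatedCohort}) with elements
#'   \code{families} (each: \code{pedigree}, \code{variants},
#'   \code{genotypes}, \code{coverage}, \code{mlpa}), \code{panel},
#'   \code{truth} (data.frame) and \code{config}.
#' @export
simulateCohort <- function(config, dir = NULL) {
  set.seed(config$seed)
  panel <- makeSyntheticPanel(config$panel_size, config$n_candidate_genes)
  pg <- panel@genes
  estAR <- pg$gene[grepl("AR", pg$modes) & pg$association != "candidate_gene"]
  estARlof <- intersect(estAR, pg$gene[pg$lof_mechanism])
  estAD <- pg$gene[grepl("AD", pg$modes) & pg$association != "candidate_gene" &
                   pg$lof_mechanism]
  estXL <- pg$gene[pg$modes == "XL" & pg$lof_mechanism]
  candG <- pg$gene[pg$association == "candidate_gene" & pg$lof_mechanism]
  modPool <- pg$gene[pg$modes == "AR" & pg$association != "candidate_gene"]

  structures <- sample(rep(names(config$model_mix), config$model_mix))
  nStatus <- round(config$status_mix / sum(config$status_mix) *
                   config$n_families)
  nStatus[1] <- config$n_families - sum(nStatus[-1])
  statuses <- sample(rep(names(nStatus), nStatus))
  ## X-linked family structures need a plantable X model
  statuses[structures == "XL" & statuses == "unsolved"] <- "solved"

  fams <- sprintf("FAM%03d", seq_len(config$n_families))
  posCounter <- stats::setNames(rep(0L, nrow(pg)), pg$gene)
  newVariant <- function(gene, csq, pathogenic, af, reported = "novel") {
    posCounter[gene] <<- posCounter[gene] + 1L
    i <- match(gene, pg$gene)
    pos <- pg$start[i] + posCounter[gene] * 10L
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    pred <- .simPredictions(pathogenic, csq, config$predictor_sensitivity,
                            config$predictor_specificity)
    an <- 121000L
    data.frame(id = .variantId(pg$chrom[i], pos, ref, alt),
               chrom = pg$chrom[i], pos = pos, ref = ref, alt = alt,
               gene = gene, consequence = csq,
               hgvs = sprintf("%s:c.%d%s>%s", gene, posCounter[gene] * 10L,
                              ref, alt),
               exac_ac = if (af == 0) NA_integer_
                         else max(1L, as.integer(round(af * an))),
               exac_an = if (af == 0) NA_integer_ else an,
               exac_status = if (af == 0) "absent" else "observed",
               reported = reported,
               pp2_call = pred$pp2_call, pp2_score = pred$pp2_score,
               sift_call = pred$sift_call, sift_score = pred$sift_score,
               mt_call = pred$mt_call, mt_score = pred$mt_score,
               cadd = pred$cadd, stringsAsFactors = FALSE)
  }

  families <- list(); truthRows <- list()
  nCnvLeft <- round(config$cnv_fraction * sum(statuses == "solved"))

  for (fi in seq_along(fams)) {
    fam <- fams[fi]; structure <- structures[fi]; status <- statuses[fi]
    ## underlying inheritance model (simplex cases are mostly recessive,
    ## with a minority of dominant/X-linked mutations, as observed)
    model <- switch(structure,
      simplex = sample(c("AR_hom", "AR_comphet", "AD", "XL"), 1,
                       prob = c(0.5, 0.3, 0.1, 0.1)),
      AD = "AD",
      AR = sample(c("AR_hom", "AR_comphet"), 1),
      XL = "XL")
    probandSex <- if (model == "XL") "male" else sample(c("male", "female"), 1)
    ped <- .simPedigree(fam, structure, probandSex, config$penetrance)
    ids <- ped@members$id

    vrows <- list(); zrows <- list(); plantedIds <- character()
    cnv <- FALSE; coverage <- NULL; mlpa <- NULL
    addRow <- function(v, z) {
      vrows[[length(vrows) + 1L]] <<- v
      zrows[[length(zrows) + 1L]] <<- z[ids]
    }

    causalGene <- NA_character_
    if (status != "unsolved") {
      ## candidate-gene (VGUS-style) plants only fit recessive models
      vgusStyle <- status == "candidate" &&
        model %in% c("AR_hom", "AR_comphet") && stats::runif(1) < 0.3
      plantNull <- status == "solved" || vgusStyle
      useCnv <- status == "solved" && model %in% c("AD", "AR_comphet") &&
        nCnvLeft > 0L
      pool <- switch(model,
        AD = estAD, XL = estXL,
        if (vgusStyle) candG else if (status == "solved") estARlof
        else estAR)
      if (useCnv) {           # coverage evidence needs a multi-exon gene
        multi <- intersect(pool, pg$gene[pg$n_exons >= 4L])
        if (length(multi)) pool <- multi else useCnv <- FALSE
      }
      causalGene <- .pick(pool)
      common <- stats::runif(1) < config$causal_common_frac
      af1 <- if (common) .logUnif(1, c(1.1e-2, 5e-2))
             else .simAf(1, config, causal = TRUE)
      csq1 <- if (!plantNull) "missense"
              else if (useCnv) "exonic_deletion"
              else .pick(c("nonsense", "frameshift", "canonical_splice"))
      v1 <- newVariant(causalGene, csq1, pathogenic = TRUE, af = af1,
                       reported = "novel")
      if (model == "AR_comphet") {
        z1 <- .plantZygosity(ped, "AR_comphet", 1L)
        addRow(v1, z1)
        ## second allele: a reported missense for solved families, a novel
        ## missense otherwise
        v2 <- newVariant(causalGene, "missense", pathogenic = TRUE,
                         af = .simAf(1, config, causal = TRUE),
                         reported = if (status == "solved")
                           "reported_pathogenic" else "novel")
        addRow(v2, .plantZygosity(ped, "AR_comphet", 2L))
        plantedIds <- c(v1$id, v2$id)
      } else {
        addRow(v1, .plantZygosity(ped, model, penetrance = config$penetrance))
        plantedIds <- v1$id
      }
      if (useCnv) {
        cnv <- TRUE; nCnvLeft <- nCnvLeft - 1L
        nEx <- pg$n_exons[match(causalGene, pg$gene)]
        first <- sample.int(nEx - 1L, 1L)
        delRange <- first:min(first + sample.int(3L, 1L), nEx)
        coverage <- simulateCoverageMatrix(nEx, planted = range(delRange),
                                           state = "het_deletion",
                                           cv = config$coverage_cv)
        ratios <- rep(1, nEx)
        ratios[delRange] <- 0.5
        mlpa <- data.frame(exon = seq_along(ratios),
                           ratio = pmax(0, ratios + stats::rnorm(
                             length(ratios), 0, config$mlpa_sd)))
        mlpa$call <- mlpaCall(mlpa$ratio)
      }
    }

    ## modifier alleles: per-proband counts at the configured Poisson
    ## rates, each in a distinct purely recessive established gene (a
    ## heterozygous carrier allele never forms a candidate on its own)
    nKnown <- stats::rpois(1, config$modifier_known_mean)
    nPred <- stats::rpois(1, config$modifier_predicted_mean)
    modGenes <- sample(setdiff(modPool, causalGene), nKnown + nPred)
    for (k in seq_len(nKnown + nPred)) {
      known <- k <= nKnown
      v <- newVariant(modGenes[k], "missense", pathogenic = TRUE,
                      af = if (known) .logUnif(1, c(1e-5, 1e-3))
                           else .simAf(1, config, causal = TRUE),
                      reported = if (known) "reported_pathogenic" else "novel")
      z <- stats::setNames(rep("hom_ref", length(ids)), ids)
      proband <- if ("C1" %in% ids) "C1" else ids[1]
      z[proband] <- "het"
      if (all(c("F1", "M1") %in% ids)) {
        z[sample(c("F1", "M1"), 1)] <- "het"
        if ("C2" %in% ids && stats::runif(1) < 0.5) z["C2"] <- "het"
      }
      addRow(v, z)
    }

    ## background variation: removed by the cascade by construction
    nBg <- stats::rpois(1, config$background_per_gene * nrow(pg))
    if (nBg > 0) for (b in seq_len(nBg)) {
      csq <- sample(c("synonymous", "deep_intronic", "missense"), 1,
                    prob = c(0.4, 0.3, 0.3))
      v <- newVariant(sample(pg$gene, 1), csq, pathogenic = FALSE,
                      af = .simAf(1, config, common = csq == "missense"))
      addRow(v, .geneDrop(ped))
    }

    variants <- .completeVariants(do.call(rbind, vrows))
    genotypes <- do.call(rbind, zrows)
    dimnames(genotypes) <- list(variants$id, ids)
    families[[fam]] <- list(pedigree = ped, variants = variants,
                            genotypes = genotypes, coverage = coverage,
                            mlpa = mlpa)
    truthRows[[fam]] <- data.frame(
      family = fam, structure = structure, model =
        if (status == "unsolved") NA_character_ else model,
      gene = causalGene,
      allele_ids = paste(plantedIds, collapse = ","),
      cnv = cnv, expected_status = status, stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  out <- structure(list(families = families, panel = panel, truth = truth,
                        config = config), class = "SimulatedCohort")
  if (!is.null(dir)) writeSimulatedCohort(out, dir)
  out
}

#' Simulate an exon coverage matrix for one gene
#'
#' A case sample and \code{nControls} control samples over \code{nExons}
#' exons; per-exon baseline depths vary around \code{depth}, multiplicative
#' noise has coefficient of variation \code{cv}, and the case sample
#' carries the planted state (half depth for a heterozygous deletion, 1.5x
#' for a duplication) over the planted exon range.
#'
#' @param nExons number of exons.
#' @param planted NULL or integer c(first, last) affected exons.
#' @param state "het_deletion" or "duplication".
#' @param cv multiplicative noise CV.
#' @param nControls number of control samples.
#' @param depth mean per-exon depth.
#' @return numeric matrix (exons x samples) with columns \code{case},
#'   \code{ctrl1}, ...
#' @export
simulateCoverageMatrix <- function(nExons, planted = NULL,
                                   state = c("het_deletion", "duplication"),
                                   cv = 0.1, nControls = 3L, depth = 100) {
  state <- match.arg(state)
  base <- depth * stats::runif(nExons, 0.5, 1.5)
  cols <- c("case", paste0("ctrl", seq_len(nControls)))
  m <- sapply(cols, function(s) {
    d <- base
    if (s == "case" && !is.null(planted)) {
      idx <- planted[1]:planted[2]
      d[idx] <- d[idx] * if (state == "het_deletion") 0.5 else 1.5
    }
    d * pmax(0, stats::rnorm(nExons, 1, cv))
  })
  dimnames(m) <- list(NULL, cols)
  m
}

#' Write a simulated cohort to plain-text files
#'
#' Emits, per family, \code{<fam>.vcf}, \code{<fam>.ped} and
#' \code{<fam>_annotations.tsv}, plus cohort-level \code{panel.tsv},
#' \code{truth.tsv}, and coverage/MLPA TSVs for families with a planted
#' exonic deletion.  Output is byte-deterministic given the configuration.
#'
#' @param sim a \code{SimulatedCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  for (fam in names(sim$families)) {
    f <- sim$families[[fam]]
    writeFamilyVcf(f$variants, f$genotypes,
                   file.path(dir, paste0(fam, ".vcf")))
    writePedigree(f$pedigree, file.path(dir, paste0(fam, ".ped")))
    ann <- f$variants[, setdiff(names(f$variants),
                                c("chrom", "pos", "ref", "alt"))]
    wt(ann, file.path(dir, paste0(fam, "_annotations.tsv")))
    if (!is.null(f$coverage))
      wt(as.data.frame(f$coverage),
         file.path(dir, paste0(fam, "_coverage.tsv")))
    if (!is.null(f$mlpa))
      wt(f$mlpa, file.path(dir, paste0(fam, "_mlpa.tsv")))
  }
  wt(sim$panel@genes, file.path(dir, "panel.tsv"))
  wt(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Analyze one family end to end
#'
#' Prioritization cascade, candidate-genotype selection under all four
#' inheritance models, two-pass ACMG classification, modifier annotation,
#' and diagnosis.
#'
#' @param variants annotated variant data.frame.
#' @param genotypes zygosity matrix (variants x members).
#' @param pedigree a \linkS4class{FamilyPedigree}.
#' @param panel a \linkS4class{GenePanel}.
#' @param config a \code{\link{prioritizationConfig}}.
#' @param models inheritance models to evaluate.
#' @return a \linkS4class{FamilyReport}.
#' @export
analyzeFamily <- function(variants, genotypes, pedigree, panel,
                          config = prioritizationConfig(),
                          models = c("AD", "AR_hom", "AR_comphet", "XL")) {
  prior <- prioritizeVariants(variants, config)
  genotypes <- genotypes[prior$id, , drop = FALSE]
  candidates <- list()
  for (m in models)
    candidates <- c(candidates,
                    candidateGenotypes(prior, genotypes, pedigree, panel,
                                       m, config))
  candidates <- lapply(candidates, classifyCandidate, panel = panel,
                       config = config)
  proband <- intersect(.affectedIds(pedigree), colnames(genotypes))[1]
  causalIds <- unique(unlist(lapply(candidates,
                                    function(cg) cg@alleles$id)))
  inCausal <- prior$id %in% causalIds
  het <- genotypes[, proband] == "het"
  nPos <- countPositivePredictors(prior)
  isMod <- !inCausal & het &
    ((!is.na(prior$reported) & prior$reported == "reported_pathogenic") |
       nPos >= config$min_positive_predictors)
  modifiers <- prior[isMod, , drop = FALSE]
  if (nrow(modifiers))
    modifiers$acmg_class <- vapply(seq_len(nrow(modifiers)), function(i)
      classifyVariant(modifiers[i, , drop = FALSE], panel,
                      config = config)$class, character(1))
  diagnoseFamily(candidates, panel, modifiers,
                 familyId = pedigree@familyId)
}

#' Analyze a simulated cohort against its ground truth
#'
#' Runs \code{\link{analyzeFamily}} on every simulated family and compares
#' the outcome with the truth table.
#'
#' @param sim a \code{SimulatedCohort}.
#' @param config a \code{\link{prioritizationConfig}}.
#' @return list with \code{reports} (named list of
#'   \linkS4class{FamilyReport}), \code{evaluation} (data.frame: family,
#'   expected and observed status, status_match, planted-genotype
#'   recovered flag) and \code{recovery} (fraction of planted causal
#'   genotypes recovered among families with a planted genotype whose
#'   alleles survive the filters).
#' @export
analyzeCohort <- function(sim, config = prioritizationConfig()) {
  reports <- list(); evalRows <- list()
  for (fam in names(sim$families)) {
    f <- sim$families[[fam]]
    rep <- analyzeFamily(f$variants, f$genotypes, f$pedigree, sim$panel,
                         config)
    reports[[fam]] <- rep
    tr <- sim$truth[sim$truth$family == fam, ]
    planted <- if (nzchar(tr$allele_ids))
      strsplit(tr$allele_ids, ",", fixed = TRUE)[[1]] else character()
    recovered <- if (!length(planted)) NA else
      any(vapply(rep@candidates, function(cg)
        identical(cg@model, tr$model) && identical(cg@gene, tr$gene) &&
          setequal(cg@alleles$id, planted), logical(1)))
    evalRows[[fam]] <- data.frame(
      family = fam, expected_status = tr$expected_status,
      observed_status = diagnosisStatus(rep),
      status_match = tr$expected_status == diagnosisStatus(rep),
      recovered = recovered, stringsAsFactors = FALSE)
  }
  evaluation <- do.call(rbind, evalRows)
  rownames(evaluation) <- NULL
  list(reports = reports, evaluation = evaluation,
       recovery = mean(evaluation$recovered, na.rm = TRUE))
}
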