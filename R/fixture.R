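#' Load the published 33-family cohort fixture
#'
#' A machine-readable transcription of the published cohort's
#' mutation table: 33 families (28 with classified variants in four table
#' sections A-D, plus 5 undiagnosed families carried as synthetic
#' placeholders with no variant rows), 41 classified variant rows (40
#' distinct mutations; one USH2A allele recurs in two families), and 18
#' families flagged with a secure genetic diagnosis.  Decimal commas of the
#' printed table were normalized to decimal points at transcription time;
#' per-tool categorical predictor calls are carried verbatim.
#'
#' Genomic coordinates are synthetic placeholders (the printed table
#' identifies variants by HGVS only); the HGVS string carries variant
#' identity.  Validation fails loudly on any count mismatch.
#'
#' @param dir directory holding the fixture TSVs; defaults to the copies
#'   installed with the package.
#' @return list with elements \code{families} (data.frame: family, section,
#'   disease, model, secure_diagnosis, synthetic), \code{variants}
#'   (data.frame: one row per classified table entry, with predictor
#'   scores/calls, ExAC counts, cosegregation, role and the printed ACMG
#'   class) and \code{panel} (a \linkS4class{GenePanel}).
#' @export
loadTable1Cohort <- function(dir = system.file("extdata", package = "irdx")) {
  fam <- utils::read.delim(file.path(dir, "table1_families.tsv"),
                           stringsAsFactors = FALSE)
  var <- utils::read.delim(file.path(dir, "table1_variants.tsv"),
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  panel <- loadGenePanel(file.path(dir, "table1_panel.tsv"))

  ## assign synthetic coordinates: identity lives in gene + HGVS
  genes <- sort(unique(var$gene))
  chrom <- ifelse(genes == "RPGR", "chrX",
                  paste0("chr", (match(genes, genes) %% 22) + 1))
  var$chrom <- chrom[match(var$gene, genes)]
  var$pos <- 1000000L + seq_len(nrow(var)) * 1000L
  var$ref <- "N"
  var$alt <- "A"
  var$id <- .variantId(var$chrom, var$pos, var$ref, var$alt)
  var$hgvs <- ifelse(is.na(var$hgvs_p), var$hgvs_c,
                     paste(var$hgvs_c, var$hgvs_p))

  ## --- validation: fail loudly on any count mismatch -----------------
  if (nrow(fam) != 33L)
    stop("fixture must contain exactly 33 families, found ", nrow(fam))
  if (anyDuplicated(fam$family)) stop("duplicated family ids in fixture")
  if (nrow(var) != 41L)
    stop("fixture must contain exactly 41 classified variant rows, found ",
         nrow(var))
  if (length(unique(paste(var$gene, var$hgvs_c))) != 40L)
    stop("fixture must contain exactly 40 distinct mutations")
  if (sum(fam$secure_diagnosis) != 18L)
    stop("fixture must flag exactly 18 secure diagnoses, found ",
         sum(fam$secure_diagnosis))
  if (!all(var$family %in% fam$family))
    stop("variant rows reference unknown families")
  if (!all(var$gene %in% panelGenes(panel)))
    stop("variant rows reference genes missing from the panel")
  if (!all(var$consequence %in% .CONSEQUENCES))
    stop("unknown consequence class in fixture")
  if (!all(var$cosegregation %in% .COSEG))
    stop("unknown cosegregation state in fixture")
  with5 <- fam$family[fam$synthetic]
  if (length(with5) != 5L || any(with5 %in% var$family))
    stop("fixture must carry exactly 5 undiagnosed placeholder families ",
         "with no variant rows")

  list(families = fam, variants = .completeVariants(var), panel = panel)
}
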