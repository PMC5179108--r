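#' Variant tables
#'
#' Variants are carried as plain data.frames with one row per decomposed
#' alt allele and a stable \code{id} of the form \code{chrom:pos:ref:alt}.
#' Annotation columns (gene, consequence, ExAC counts, predictor scores and
#' calls, reported status) are never computed by this package: they are
#' inputs, read from the VCF INFO field or from a sidecar TSV.
#'
#' @name variant-tables
NULL

.variantId <- function(chrom, pos, ref, alt)
  sprintf("%s:%d:%s:%s", chrom, as.integer(pos), ref, alt)

.emptyVariants <- function() {
  df <- data.frame(id = character(), chrom = character(), pos = integer(),
                   ref = character(), alt = character(), gene = character(),
                   consequence = character(), hgvs = character(),
                   exac_ac = integer(), exac_an = integer(),
                   exac_status = character(), reported = character(),
                   pp2_call = character(), pp2_score = numeric(),
                   sift_call = character(), sift_score = numeric(),
                   mt_call = character(), mt_score = numeric(),
                   cadd = numeric(), stringsAsFactors = FALSE)
  df
}

## fill missing annotation columns with NAs so downstream code can rely on
## the full column set
.completeVariants <- function(df) {
  tmpl <- .emptyVariants()
  for (cn in names(tmpl))
    if (!cn %in% names(df)) df[[cn]] <- tmpl[[cn]][NA_integer_][seq_len(nrow(df))]
  if (!"exac_status" %in% names(df) || all(is.na(df$exac_status)))
    df$exac_status <- ifelse(is.na(df$exac_ac), "absent", "observed")
  df[, union(names(tmpl), names(df))]
}

#' Allele frequency from ExAC-style counts
#'
#' Frequency is \code{exac_ac / exac_an}.  \code{exac_status == "absent"}
#' (not present in the reference population) maps to frequency 0;
#' \code{"not_covered"} (position not covered, so the frequency is unknown)
#' maps to NA.  An observed record with \code{exac_an == 0} is treated as
#' absent, with a warning.
#'
#' @param variants a variant data.frame.
#' @return numeric vector of frequencies in [0, 1], NA when unknown.
#' @export
alleleFrequency <- function(variants) {
  af <- rep(NA_real_, nrow(variants))
  st <- variants$exac_status
  af[st == "absent"] <- 0
  obs <- which(st == "observed")
  an0 <- obs[!is.na(variants$exac_an[obs]) & variants$exac_an[obs] == 0]
  if (length(an0)) {
    warning("exac_an == 0 treated as absent for ",
            paste(variants$id[an0], collapse = ", "))
    af[an0] <- 0
    obs <- setdiff(obs, an0)
  }
  af[obs] <- variants$exac_ac[obs] / variants$exac_an[obs]
  af
}

## zygosity of one decomposed alt allele from a VCF GT string
.gtToZygosity <- function(gt, altIndex) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".")) return("missing")
  al <- as.integer(al)
  hits <- sum(al == altIndex)
  if (length(al) == 1L)        # haploid call (male X/Y)
    return(if (hits == 1L) "hemizygous" else "hom_ref")
  if (hits == 2L) "hom_alt" else if (hits == 1L) "het" else "hom_ref"
}

#' Read a per-family multi-sample VCF
#'
#' Parses a VCF 4.2 file via \code{VariantAnnotation::readVcf}, decomposes
#' multi-allelic sites into one record per alt allele, and maps the GT field
#' of every pedigree member to a zygosity call (haploid calls become
#' \code{hemizygous}).  Annotations come from the INFO field (\code{AC},
#' \code{AN} when present) and/or a sidecar annotation TSV keyed by variant
#' id.
#'
#' @param path VCF file path.
#' @param pedigree a \linkS4class{FamilyPedigree}; every member must appear
#'   in the VCF sample header (hard error naming the member otherwise).
#' @param annotations optional sidecar annotation data.frame or TSV path
#'   with an \code{id} column.
#' @return list with elements \code{variants} (data.frame, one row per alt
#'   allele) and \code{genotypes} (zygosity matrix, variants x samples).
#' @export
readFamilyVcf <- function(path, pedigree, annotations = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  missing <- setdiff(pedigree@members$id, samples)
  if (length(missing))
    stop(sprintf("pedigree member(s) missing from VCF header: %s",
                 paste(missing, collapse = ", ")))
  samples <- pedigree@members$id
  if (nrow(vcf) == 0L)
    return(list(variants = .emptyVariants(),
                genotypes = matrix(character(), 0, length(samples),
                                   dimnames = list(NULL, samples))))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  info <- VariantAnnotation::info(vcf)

  rows <- list(); zyg <- list()
  for (i in seq_len(nrow(vcf))) {
    alts <- as.character(altList[[i]])
    for (k in seq_along(alts)) {
      id <- .variantId(chrom[i], pos[i], ref[i], alts[k])
      ac <- an <- NA_integer_
      if ("AC" %in% names(info)) {
        aci <- info$AC[[i]]
        if (length(aci) >= k) ac <- as.integer(aci[k])
      }
      if ("AN" %in% names(info)) an <- as.integer(info$AN[[i]])
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, chrom = chrom[i], pos = pos[i], ref = ref[i],
                   alt = alts[k], exac_ac = ac, exac_an = an,
                   stringsAsFactors = FALSE)
      zyg[[length(zyg) + 1L]] <-
        vapply(gt[i, samples], .gtToZygosity, character(1), altIndex = k)
    }
  }
  variants <- do.call(rbind, rows)
  genotypes <- do.call(rbind, zyg)
  dimnames(genotypes) <- list(variants$id, samples)

  if (!is.null(annotations)) {
    if (is.character(annotations))
      annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
    keep <- setdiff(names(annotations), names(variants))
    variants <- cbind(variants,
                      annotations[match(variants$id, annotations$id), keep,
                                  drop = FALSE])
  }
  variants <- .completeVariants(variants)
  rownames(variants) <- NULL
  list(variants = variants, genotypes = genotypes)
}

#' Write a variant table and zygosity matrix as a VCF 4.2 file
#'
#' The inverse of \code{\link{readFamilyVcf}} for the simple biallelic
#' records this package emits: positions, alleles and genotypes round-trip.
#' ExAC counts, when present, are written as INFO AC/AN.
#'
#' @param variants variant data.frame.
#' @param genotypes zygosity matrix (variants x samples).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFamilyVcf <- function(variants, genotypes, path) {
  samples <- colnames(genotypes)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gtMap <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
             hemizygous = "1", missing = "./.")
  o <- order(variants$chrom, variants$pos, variants$alt)
  body <- vapply(o, function(i) {
    info <- if (!is.na(variants$exac_ac[i]) && !is.na(variants$exac_an[i]))
      sprintf("AC=%d;AN=%d", variants$exac_ac[i], variants$exac_an[i])
    else "."
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", info, "GT",
            gtMap[genotypes[i, ]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
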