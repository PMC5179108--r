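#' CNV-calling configuration
#'
#' Depth-ratio thresholds sit midway between the expected heterozygous
#' copy states (0.5, 1.5) and the diploid ratio 1.0; a call requires at
#' least two consecutive supporting exons (single-exon events are reported
#' as normal: they are below the resolution this evidence supports).
#'
#' @param del_ratio_max maximum case/control ratio supporting a
#'   heterozygous deletion (default 0.65).
#' @param dup_ratio_min minimum ratio supporting a duplication (default
#'   1.35).
#' @param min_exons minimum run of consecutive supporting exons (default 2).
#' @return a list of class \code{CnvConfig}.
#' @export
cnvConfig <- function(del_ratio_max = 0.65, dup_ratio_min = 1.35,
                      min_exons = 2L) {
  stopifnot(del_ratio_max < 1, dup_ratio_min > 1, min_exons >= 1L)
  structure(list(del_ratio_max = del_ratio_max,
                 dup_ratio_min = dup_ratio_min,
                 min_exons = as.integer(min_exons)),
            class = c("CnvConfig", "list"))
}

#' Per-sample normalization factors from control genes
#'
#' Each sample's factor is its median exon depth over designated control
#' genes (mirroring the use of a nearby unaffected gene as coverage
#' control).
#'
#' @param coverage long data.frame with columns \code{gene}, \code{exon}
#'   and one numeric column per sample, or a list of per-gene depth
#'   matrices (exons x samples).
#' @param controlGenes character vector of control gene names.
#' @return named numeric vector of per-sample factors.
#' @export
sampleNormFactors <- function(coverage, controlGenes) {
  if (is.data.frame(coverage)) {
    sub <- coverage[coverage$gene %in% controlGenes, , drop = FALSE]
    depths <- as.matrix(sub[, setdiff(names(sub), c("gene", "exon")),
                            drop = FALSE])
  } else {
    depths <- do.call(rbind, coverage[controlGenes])
  }
  apply(depths, 2, stats::median)
}

#' Call exon-level copy-number changes from read-depth ratios
#'
#' Depths are normalized per sample (by \code{normFactors}, typically the
#' sample's median depth over control genes), the per-exon ratio is the
#' normalized case depth over the mean normalized control depth, and a
#' heterozygous deletion (duplication) is called when at least
#' \code{min_exons} consecutive exons fall at or below
#' \code{del_ratio_max} (at or above \code{dup_ratio_min}).  Exons with a
#' zero control depth are masked with a warning.  When both states have
#' qualifying runs the longer run wins.
#'
#' @param depths numeric matrix of mean exon depths (exons in genomic
#'   order x samples) for one gene.
#' @param case case sample name (column of \code{depths}).
#' @param controls control sample names (>= 1).
#' @param gene gene symbol for the call.
#' @param normFactors named per-sample normalization factors; default 1
#'   (depths already normalized).
#' @param config a \code{\link{cnvConfig}}.
#' @return a \linkS4class{CnvCall}.
#' @export
exonRatioCnv <- function(depths, case, controls, gene = "gene",
                         normFactors = NULL, config = cnvConfig()) {
  stopifnot(case %in% colnames(depths), all(controls %in% colnames(depths)),
            length(controls) >= 1L)
  if (is.null(normFactors))
    normFactors <- stats::setNames(rep(1, ncol(depths)), colnames(depths))
  norm <- sweep(depths, 2, normFactors[colnames(depths)], "/")
  ctrl <- rowMeans(norm[, controls, drop = FALSE])
  masked <- apply(depths[, controls, drop = FALSE] == 0, 1, any)
  if (any(masked))
    warning(sum(masked), " exon(s) masked (zero control depth)")
  ratio <- ifelse(masked, NA_real_, norm[, case] / ctrl)

  bestRun <- function(flag) {
    r <- rle(flag & !is.na(flag))
    if (!any(r$values & r$lengths >= config$min_exons))
      return(NULL)
    ok <- which(r$values & r$lengths >= config$min_exons)
    best <- ok[which.max(r$lengths[ok])]
    first <- sum(r$lengths[seq_len(best - 1)]) + 1L
    c(first, first + r$lengths[best] - 1L)
  }
  del <- bestRun(ratio <= config$del_ratio_max)
  dup <- bestRun(ratio >= config$dup_ratio_min)
  pick <- function(range, state)
    new("CnvCall", gene = gene, state = state,
        exonRange = as.integer(range), ratios = unname(ratio),
        supportingExons = as.integer(range[2] - range[1] + 1L))
  if (!is.null(del) && (is.null(dup) ||
                        diff(del) >= diff(dup))) pick(del, "het_deletion")
  else if (!is.null(dup)) pick(dup, "duplication")
  else new("CnvCall", gene = gene, state = "normal", exonRange = integer(),
           ratios = unname(ratio), supportingExons = 0L)
}

#' Interpret MLPA probe ratios
#'
#' A probe supports a deletion when the sample/control ratio is under 0.7
#' and a duplication when it is over 1.3 (both strict); anything else is
#' normal copy number.
#'
#' @param ratio numeric vector of normalized probe ratios (>= 0).
#' @return character vector: deletion / normal / duplication.
#' @export
mlpaCall <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0)) stop("ratios must be >= 0")
  ifelse(ratio < 0.7, "deletion", ifelse(ratio > 1.3, "duplication",
                                         "normal"))
}

#' Infer a heterozygous deletion from ordered trio SNP genotypes
#'
#' Over an ordered set of biallelic SNPs in the suspected region, a locus
#' where either individual is heterozygous implies two copies
#' (non-deleted); a locus where mother and child are homozygous for
#' different alleles is impossible under diploid transmission and supports
#' hemizygosity on distinct retained haplotypes (deletion-supporting);
#' anything else (same homozygote, missing call) is uninformative.  The
#' breakpoint interval runs from the non-deleted loci immediately flanking
#' the maximal run of deletion-supporting/uninformative loci that contains
#' at least one deletion-supporting locus (NA where the run reaches the
#' end of the typed region).
#'
#' @param snps data.frame with columns \code{locus}, \code{pos} (ordered,
#'   increasing), \code{mother}, \code{child}; genotypes as strings like
#'   \code{"A/G"} (\code{NA} or \code{"./."} = missing).
#' @return a \linkS4class{DeletionEvidence}.
#' @export
trioDeletionScan <- function(snps) {
  stopifnot(all(c("locus", "pos", "mother", "child") %in% names(snps)),
            !is.unsorted(snps$pos))
  alleles <- function(gt) {
    if (is.na(gt) || gt %in% c("./.", ".")) return(NULL)
    strsplit(gt, "[/|]")[[1]]
  }
  flag <- vapply(seq_len(nrow(snps)), function(i) {
    m <- alleles(snps$mother[i]); c <- alleles(snps$child[i])
    if (is.null(m) || is.null(c)) return("uninformative")
    mHet <- length(unique(m)) > 1L; cHet <- length(unique(c)) > 1L
    if (mHet || cHet) return("non_deleted")
    if (m[1] != c[1]) "deletion_supporting" else "uninformative"
  }, character(1))
  loci <- data.frame(locus = snps$locus, pos = snps$pos,
                     mother = snps$mother, child = snps$child, flag = flag,
                     stringsAsFactors = FALSE)

  bp <- c(NA_real_, NA_real_)
  if (any(flag == "deletion_supporting")) {
    r <- rle(flag != "non_deleted")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cand <- which(r$values & vapply(seq_along(r$values), function(k)
      any(flag[starts[k]:ends[k]] == "deletion_supporting"), logical(1)))
    best <- cand[which.max(r$lengths[cand])]
    lo <- starts[best]; hi <- ends[best]
    bp <- c(if (lo > 1L) snps$pos[lo - 1L] else NA_real_,
            if (hi < nrow(snps)) snps$pos[hi + 1L] else NA_real_)
  }
  new("DeletionEvidence", loci = loci, breakpointInterval = bp)
}
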