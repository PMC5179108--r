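#' Load a gene panel from a TSV file
#'
#' The panel TSV has columns \code{gene}, \code{association}
#' (established_IRD / established_syndromic / candidate_gene), \code{modes}
#' (comma-separated subset of AD,AR,XL), \code{lof_mechanism} and
#' \code{functional_support} (logical).
#'
#' @param path panel TSV path.
#' @return a \linkS4class{GenePanel}.
#' @export
loadGenePanel <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(gene = "character",
                                        association = "character",
                                        modes = "character",
                                        lof_mechanism = "logical",
                                        functional_support = "logical"))
  genePanel(g)
}

#' Construct a GenePanel from a data.frame
#'
#' @param genes data.frame with the panel columns (see
#'   \code{\link{loadGenePanel}}).
#' @return a \linkS4class{GenePanel}.
#' @export
genePanel <- function(genes) {
  rownames(genes) <- NULL
  new("GenePanel", genes = genes)
}

## internal: does `gene` support inheritance mode `mode` ("AD","AR","XL")?
.geneHasMode <- function(panel, gene, mode) {
  i <- match(gene, panel@genes$gene)
  if (is.na(i)) return(FALSE)
  mode %in% strsplit(panel@genes$modes[i], ",", fixed = TRUE)[[1]]
}

.inPanel <- function(panel, gene) gene %in% panel@genes$gene
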