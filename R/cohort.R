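#' Coverage summary of a sequencing target
#'
#' @param depths numeric vector of per-base (or per-interval, weighted
#'   equally) depths over the target.
#' @return list with \code{median} depth, \code{C10} and \code{C30}: the
#'   percentage of targeted bases covered by at least 10 and 30 reads.
#' @export
coverageSummary <- function(depths) {
  if (!length(depths)) stop("empty coverage target")
  if (any(depths < 0)) stop("negative depths")
  list(median = stats::median(depths),
       C10 = 100 * mean(depths >= 10),
       C30 = 100 * mean(depths >= 30))
}

#' Per-patient carrier burden of additional IRD alleles
#'
#' Counts, per patient and excluding the causative genotype of the family,
#' (a) heterozygous known pathogenic recessive alleles in panel genes and
#' (b) heterozygous unreported alleles predicted pathogenic by at least two
#' in-silico algorithms, plus the cohort means of both.
#'
#' @param variants data.frame of per-patient panel-gene variants with
#'   columns \code{patient}, \code{id}, \code{gene}, \code{zygosity},
#'   \code{reported} and the predictor columns.
#' @param panel a \linkS4class{GenePanel}.
#' @param causativeIds variant ids of causative alleles, excluded from the
#'   counts.
#' @param patients optional character vector of patient ids defining the
#'   denominator (patients without extra alleles count zero).
#' @param config a \code{\link{prioritizationConfig}}.
#' @return list with \code{per_patient} (data.frame: patient,
#'   known_het_recessive, rare_predicted_pathogenic),
#'   \code{mean_known} and \code{mean_predicted}.
#' @export
carrierBurden <- function(variants, panel, causativeIds = character(),
                          patients = NULL,
                          config = prioritizationConfig()) {
  v <- variants[!variants$id %in% causativeIds & variants$zygosity == "het",
                , drop = FALSE]
  recessiveGene <- vapply(v$gene, function(g)
    .inPanel(panel, g) && .geneHasMode(panel, g, "AR"), logical(1))
  nPos <- countPositivePredictors(v)
  af <- alleleFrequency(v)
  rare <- is.na(af) | af <= config$af_max
  known <- recessiveGene & v$reported == "reported_pathogenic"
  predicted <- recessiveGene & v$reported == "novel" & rare &
    nPos >= config$min_positive_predictors
  if (is.null(patients)) patients <- sort(unique(variants$patient))
  perPatient <- data.frame(
    patient = patients,
    known_het_recessive =
      as.integer(table(factor(v$patient[known], levels = patients))),
    rare_predicted_pathogenic =
      as.integer(table(factor(v$patient[predicted], levels = patients))))
  list(per_patient = perPatient,
       mean_known = mean(perPatient$known_het_recessive),
       mean_predicted = mean(perPatient$rare_predicted_pathogenic))
}

#' Cohort-level diagnostic yield
#'
#' @param reports list of \linkS4class{FamilyReport} (one per family;
#'   duplicated family ids are an error).
#' @return a \linkS4class{CohortSummary}; percentages are exact (display
#'   rounding is left to \code{show}).
#' @export
cohortYield <- function(reports) {
  ids <- vapply(reports, familyId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate family id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  st <- vapply(reports, diagnosisStatus, character(1))
  n <- length(st)
  ns <- sum(st == "solved"); nc <- sum(st == "candidate")
  new("CohortSummary", nFamilies = as.integer(n), nSolved = as.integer(ns),
      nCandidate = as.integer(nc),
      nUnsolved = as.integer(n - ns - nc),
      pctSolved = if (n) 100 * ns / n else 0,
      pctCandidate = if (n) 100 * nc / n else 0)
}
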