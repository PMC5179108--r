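#' Construct a FamilyPedigree
#'
#' @param familyId family identifier.
#' @param members data.frame with columns \code{id}, \code{father},
#'   \code{mother}, \code{sex}, \code{affected}.  Parent ids referenced but
#'   not listed are added as founders of unknown sex/phenotype, with a
#'   warning.
#' @param consanguineous logical.
#' @return a \linkS4class{FamilyPedigree}.
#' @export
familyPedigree <- function(familyId, members, consanguineous = FALSE) {
  members$father[members$father %in% c("0", "")] <- NA
  members$mother[members$mother %in% c("0", "")] <- NA
  implied <- setdiff(c(members$father, members$mother), c(members$id, NA))
  if (length(implied)) {
    warning(sprintf("creating implicit founder(s): %s",
                    paste(implied, collapse = ", ")))
    members <- rbind(members,
                     data.frame(id = implied, father = NA_character_,
                                mother = NA_character_, sex = "unknown",
                                affected = "unknown",
                                stringsAsFactors = FALSE))
  }
  rownames(members) <- NULL
  new("FamilyPedigree", familyId = as.character(familyId),
      members = members, consanguineous = isTRUE(consanguineous))
}

#' Read a PLINK 6-column PED file
#'
#' Columns: family, individual, father, mother, sex (1 = male, 2 = female,
#' other = unknown), phenotype (1 = unaffected, 2 = affected, other =
#' unknown with a warning).  A parent id that is not listed as an individual
#' becomes an implicit founder (with a warning).
#'
#' @param path PED file path.
#' @return a \linkS4class{FamilyPedigree}; if the file contains several
#'   family ids, a named list of them.
#' @export
readPedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  if (!nrow(ped)) stop("empty PED file: ", path)
  sex <- c(`1` = "male", `2` = "female")[ped$sex]
  sex[is.na(sex)] <- "unknown"
  aff <- c(`1` = "unaffected", `2` = "affected")[ped$phenotype]
  if (anyNA(aff))
    warning("unknown phenotype code(s) mapped to 'unknown'")
  aff[is.na(aff)] <- "unknown"
  members <- data.frame(id = ped$id, father = ped$father,
                        mother = ped$mother, sex = sex, affected = aff,
                        stringsAsFactors = FALSE)
  fams <- split(seq_len(nrow(ped)), ped$family)
  out <- lapply(names(fams),
                function(f) familyPedigree(f, members[fams[[f]], ]))
  names(out) <- names(fams)
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a FamilyPedigree as a PLINK 6-column PED file
#'
#' @param pedigree a \linkS4class{FamilyPedigree}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePedigree <- function(pedigree, path) {
  m <- pedigree@members
  sex <- c(male = "1", female = "2", unknown = "0")[m$sex]
  phe <- c(unaffected = "1", affected = "2", unknown = "0")[m$affected]
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", pedigree@familyId, m$id,
                   ifelse(is.na(m$father), "0", m$father),
                   ifelse(is.na(m$mother), "0", m$mother), sex, phe)
  writeLines(lines, path)
  invisible(path)
}

## internal helpers ---------------------------------------------------------

.members <- function(ped) ped@members

.affectedIds <- function(ped) ped@members$id[ped@members$affected == "affected"]

.unaffectedIds <- function(ped)
  ped@members$id[ped@members$affected == "unaffected"]

.parentsOf <- function(ped, id) {
  i <- match(id, ped@members$id)
  stats::na.omit(c(father = ped@members$father[i],
                   mother = ped@members$mother[i]))
}

.sexOf <- function(ped, id) ped@members$sex[match(id, ped@members$id)]
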