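# Independent oracles and small fixture builders used across the suite.

# build a one-row (or n-row) variant data.frame with sensible defaults
mkVar <- function(id = "v1", chrom = "chr1", pos = 100L, ref = "A",
                  alt = "G", gene = "GENE1", consequence = "missense",
                  hgvs = NA, exac_ac = NA, exac_an = NA,
                  exac_status = "absent", reported = "novel",
                  pp2_call = NA, pp2_score = NA, sift_call = NA,
                  sift_score = NA, mt_call = NA, mt_score = NA,
                  cadd = NA) {
  data.frame(id = id, chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = alt, gene = gene, consequence = consequence,
             hgvs = as.character(hgvs), exac_ac = as.integer(exac_ac),
             exac_an = as.integer(exac_an), exac_status = exac_status,
             reported = reported, pp2_call = as.character(pp2_call),
             pp2_score = as.numeric(pp2_score),
             sift_call = as.character(sift_call),
             sift_score = as.numeric(sift_score),
             mt_call = as.character(mt_call),
             mt_score = as.numeric(mt_score), cadd = as.numeric(cadd),
             stringsAsFactors = FALSE)
}

mkPanel <- function(genes = "GENE1", association = "established_IRD",
                    modes = "AR", lof = TRUE, functional = FALSE) {
  genePanel(data.frame(gene = genes,
                       association = rep_len(association, length(genes)),
                       modes = rep_len(modes, length(genes)),
                       lof_mechanism = rep_len(lof, length(genes)),
                       functional_support = rep_len(functional,
                                                    length(genes)),
                       stringsAsFactors = FALSE))
}

mkTrio <- function(fam = "F1", childSex = "female",
                   childAffected = "affected", extraSib = FALSE) {
  m <- data.frame(
    id = c("F1", "M1", "C1", if (extraSib) "C2"),
    father = c(NA, NA, "F1", if (extraSib) "F1"),
    mother = c(NA, NA, "M1", if (extraSib) "M1"),
    sex = c("male", "female", childSex, if (extraSib) "male"),
    affected = c("unaffected", "unaffected", childAffected,
                 if (extraSib) "unaffected"),
    stringsAsFactors = FALSE)
  familyPedigree(fam, m)
}

# ---- brute-force compound-heterozygote oracle -----------------------------
# Enumerates every unordered pair of variants and applies the comphet rule
# directly: same autosomal gene with recessive mode, both alleles het in all
# genotyped affecteds, never co-carried by a genotyped unaffected, and not
# provably in cis from parental genotypes.
carrierO <- function(z) z %in% c("het", "hom_alt", "hemizygous")

bruteForceComphet <- function(variants, genotypes, pedigree, panel) {
  members <- pedigree@members
  aff <- intersect(members$id[members$affected == "affected"],
                   colnames(genotypes))
  una <- intersect(members$id[members$affected == "unaffected"],
                   colnames(genotypes))
  pairs <- list()
  n <- nrow(variants)
  if (n < 2 || !length(aff)) return(pairs)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    g <- variants$gene[i]
    if (is.na(g) || !identical(g, variants$gene[j])) next
    gi <- geneInfo(panel, g)
    if (!grepl("AR", gi$modes)) next
    if (variants$chrom[i] %in% c("chrX", "chrY", "X", "Y")) next
    if (!all(genotypes[i, aff] == "het") ||
        !all(genotypes[j, aff] == "het")) next
    if (length(una) && any(carrierO(genotypes[i, una]) &
                           carrierO(genotypes[j, una]))) next
    cis <- FALSE
    for (child in aff) {
      k <- match(child, members$id)
      par <- c(members$father[k], members$mother[k])
      par <- par[!is.na(par) & par %in% colnames(genotypes)]
      if (length(par) < 2) next
      c1 <- carrierO(genotypes[i, par]); c2 <- carrierO(genotypes[j, par])
      if (sum(c1) == 1 && sum(c2) == 1 && which(c1) == which(c2))
        cis <- TRUE
    }
    if (cis) next
    pairs[[length(pairs) + 1]] <- sort(c(variants$id[i], variants$id[j]))
  }
  pairs
}

# ---- diploid-transmission oracle for the trio deletion scan ---------------
# A locus proves two copies when either individual is heterozygous; it is
# deletion-supporting when both calls are homozygous and no maternal allele
# can have been transmitted to the child under diploidy; otherwise it is
# uninformative.
oracleTrioFlag <- function(mother, child) {
  parse <- function(gt) {
    if (is.na(gt) || gt %in% c("./.", ".")) return(NULL)
    strsplit(gt, "[/|]")[[1]]
  }
  m <- parse(mother); c <- parse(child)
  if (is.null(m) || is.null(c)) return("uninformative")
  if (length(unique(m)) > 1 || length(unique(c)) > 1) return("non_deleted")
  transmissionPossible <- length(intersect(m, c)) > 0
  if (!transmissionPossible) "deletion_supporting" else "uninformative"
}

# ---- literal ACMG combining-table oracle ----------------------------------
# Independent enumeration of the published combining rules, pattern by
# pattern, over code strengths.
oracleCombine <- function(codes) {
  strength <- c(PVS1 = "vs", PS3 = "s", PM3_strong = "s", PM2 = "m",
                PM3 = "m", PM3_supporting = "p", PP1 = "p", PP3 = "p",
                PP5_reported = "p", BA1 = "ba")
  st <- strength[codes]
  vs <- "PVS1" %in% codes
  s <- sum(st == "s"); m <- sum(st == "m"); p <- sum(st == "p")
  if ("BA1" %in% codes) {
    if (vs) return("VUS")                  # contradictory evidence
    return("Benign")
  }
  pathogenic <- (vs && s >= 1) || (vs && m >= 2) ||
    (vs && m == 1 && p >= 1) || (vs && p >= 2) ||
    (s >= 2) ||
    (s == 1 && m >= 3) || (s == 1 && m == 2 && p >= 2) ||
    (s == 1 && m == 1 && p >= 4)
  if (pathogenic) return("Pathogenic")
  likely <- (vs && m >= 1) ||
    (s == 1 && (m == 1 || m == 2)) || (s == 1 && p >= 2) ||
    (m >= 3) || (m == 2 && p >= 2) || (m == 1 && p >= 4)
  if (likely) return("LikelyPathogenic")
  "VUS"
}

# random comphet scenario with up to `maxVar` variants in one recessive gene
randomComphetCase <- function(maxVar = 10, parentsTyped = NA) {
  nV <- sample(2:maxVar, 1)
  ped <- mkTrio(extraSib = sample(c(TRUE, FALSE), 1))
  ids <- slot(ped, "members")$id
  typed <- "C1"
  if (is.na(parentsTyped)) parentsTyped <- sample(c(TRUE, FALSE), 1)
  if (parentsTyped) typed <- c(typed, "F1", "M1")
  if ("C2" %in% ids && sample(c(TRUE, FALSE), 1)) typed <- c(typed, "C2")
  v <- do.call(rbind, lapply(seq_len(nV), function(k)
    mkVar(id = sprintf("v%02d", k), pos = 100L + k, gene = "GENE1",
          consequence = "missense")))
  z <- matrix(sample(c("hom_ref", "het", "hom_alt"),
                     nV * length(typed), replace = TRUE,
                     prob = c(0.4, 0.45, 0.15)),
              nrow = nV, dimnames = list(v$id, typed))
  list(variants = v, genotypes = z, pedigree = ped)
}
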