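test_that("frequency filter keeps rare and absent records with an inclusive boundary", {
  cfg <- prioritizationConfig()
  ush <- mkVar(id = "ush", exac_ac = 95L, exac_an = 121178L,
               exac_status = "observed")
  absent <- mkVar(id = "abs")
  expect_equal(filterByFrequency(rbind(ush, absent), cfg)$id,
               c("ush", "abs"))

  an <- 1e6L
  sweep <- do.call(rbind, lapply(c(0.0099, 0.01, 0.0101), function(f)
    mkVar(id = sprintf("f%g", f), exac_ac = as.integer(f * an),
          exac_an = an, exac_status = "observed")))
  expect_equal(filterByFrequency(sweep, cfg)$id, c("f0.0099", "f0.01"))

  ## fine boundary sweep: kept iff frequency <= af_max exactly
  fr <- seq(0.001, 0.02, by = 0.0005)
  grid <- do.call(rbind, lapply(seq_along(fr), function(i)
    mkVar(id = sprintf("g%d", i), exac_ac = as.integer(round(fr[i] * an)),
          exac_an = an, exac_status = "observed")))
  kept <- filterByFrequency(grid, cfg)$id
  expect_setequal(kept, grid$id[alleleFrequency(grid) <= cfg$af_max])
})

test_that("a zero ExAC denominator is treated as absent with a warning", {
  v <- mkVar(id = "v0", exac_ac = 0L, exac_an = 0L,
             exac_status = "observed")
  expect_warning(af <- alleleFrequency(v), "exac_an == 0")
  expect_equal(af, 0)
  suppressWarnings(expect_equal(nrow(filterByFrequency(v)), 1L))
})

test_that("consequence filter retains null/missense/splice and whitelists reported alleles", {
  cfg <- prioritizationConfig()
  v <- rbind(mkVar(id = "syn", consequence = "synonymous"),
             mkVar(id = "fs", consequence = "frameshift"),
             mkVar(id = "deep", consequence = "deep_intronic",
                   reported = "reported_pathogenic"),
             mkVar(id = "deep2", consequence = "deep_intronic"))
  expect_equal(filterByConsequence(v, cfg)$id, c("fs", "deep"))
  ## whitelist off: the reported deep-intronic allele goes too
  cfg2 <- prioritizationConfig(reported_pathogenic_whitelist = FALSE)
  expect_equal(filterByConsequence(v, cfg2)$id, "fs")
  expect_message(filterByConsequence(mkVar(consequence = "other"), cfg),
                 "removed")
})

test_that("frequency and consequence filters commute on random record sets", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    v <- do.call(rbind, lapply(seq_len(n), function(i) {
      obs <- runif(1) < 0.7
      mkVar(id = sprintf("v%d", i),
            consequence = sample(c("missense", "synonymous", "frameshift",
                                   "deep_intronic", "other"), 1),
            exac_ac = if (obs) sample.int(5000L, 1) else NA,
            exac_an = if (obs) 100000L else NA,
            exac_status = if (obs) "observed" else "absent",
            reported = sample(c("novel", "reported_pathogenic"), 1,
                              prob = c(0.8, 0.2)))
    }))
    a <- suppressMessages(filterByConsequence(filterByFrequency(v)))
    b <- suppressMessages(filterByFrequency(filterByConsequence(v)))
    expect_equal(a$id, b$id)
  }
})

test_that("consensus prediction requires two positive tools, with calls overriding scores", {
  cfg <- prioritizationConfig()
  ## four positives: PolyPhen2 call, SIFT score 0, MutationTaster call,
  ## CADD 28.01
  abca4 <- mkVar(pp2_call = "Probably D.", pp2_score = 0.961,
                 sift_call = "Damaging", sift_score = 0,
                 mt_call = "Disease C.", mt_score = 1, cadd = 28.01)
  expect_equal(countPositivePredictors(abca4), 4L)
  expect_true(consensusPathogenicity(abca4, cfg))

  ## the SIFT call "Tolerated" wins over its score of 0.06: three positives
  phyh <- mkVar(pp2_call = "Probably D.", pp2_score = 1,
                sift_call = "Tolerated", sift_score = 0.06,
                mt_call = "Disease C.", mt_score = 1, cadd = 22.7)
  expect_equal(countPositivePredictors(phyh), 3L)
  expect_true(consensusPathogenicity(phyh, cfg))

  allNeg <- mkVar(pp2_call = "Benign", sift_call = "Tolerated",
                  mt_call = "Polymorphism", cadd = 3)
  expect_false(consensusPathogenicity(allNeg, cfg))

  ## null records bypass the test; blind missense records fail, warning
  expect_true(consensusPathogenicity(mkVar(consequence = "frameshift"),
                                     cfg))
  expect_warning(ok <- consensusPathogenicity(mkVar(), cfg),
                 "predictors missing")
  expect_false(ok)
})

test_that("all 16 positive/negative predictor combinations follow the >=2 rule", {
  cfg <- prioritizationConfig()
  for (mask in 0:15) {
    bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    v <- mkVar(pp2_call = if (bits[1]) "Probably D." else "Benign",
               sift_call = if (bits[2]) "Damaging" else "Tolerated",
               mt_call = if (bits[3]) "Disease C." else "Polymorphism",
               cadd = if (bits[4]) 25 else 5)
    expect_identical(consensusPathogenicity(v, cfg), sum(bits) >= 2,
                     label = sprintf("mask %d", mask))
  }
})

test_that("compound-het, homozygous, dominant and X-linked genotype selection", {
  panel <- mkPanel(c("USH2A", "RPGR", "CRX"),
                   modes = c("AR", "XL", "AD"))
  ped <- mkTrio()
  v <- rbind(mkVar(id = "a", gene = "USH2A", pos = 1L),
             mkVar(id = "b", gene = "USH2A", pos = 2L))
  z <- matrix(c("het", "hom_ref", "het",
                "hom_ref", "het", "het"), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("F1", "M1", "C1")))
  cg <- candidateGenotypes(v, z, ped, panel, "AR_comphet")
  expect_length(cg, 1L)
  expect_setequal(alleleTable(cg[[1]])$id, c("a", "b"))
  expect_true(slot(cg[[1]], "phased"))       # one allele per parent: trans

  ## both alleles from the same parent: cis, rejected
  zc <- z; zc["b", ] <- c("het", "hom_ref", "het")
  expect_length(candidateGenotypes(v, zc, ped, panel, "AR_comphet"), 0L)

  ## a single het in a recessive gene is no candidate
  expect_length(candidateGenotypes(v[1, ], z[1, , drop = FALSE], ped,
                                   panel, "AR_hom"), 0L)
  expect_length(candidateGenotypes(v[1, ], z[1, , drop = FALSE], ped,
                                   panel, "AR_comphet"), 0L)

  ## hemizygous indel in an X-linked gene in an affected male
  pedM <- familyPedigree("FX", data.frame(
    id = "P1", father = NA_character_, mother = NA_character_,
    sex = "male", affected = "affected", stringsAsFactors = FALSE))
  vx <- mkVar(id = "x", chrom = "chrX", gene = "RPGR",
              consequence = "frameshift")
  zx <- matrix("hemizygous", 1, 1, dimnames = list("x", "P1"))
  cgx <- candidateGenotypes(vx, zx, pedM, panel, "XL")
  expect_length(cgx, 1L)
  expect_equal(inheritanceModel(cgx[[1]]), "XL")
  expect_equal(cosegregation(cgx[[1]]), "unavailable")

  ## dominant: unaffected carrier blocks the candidate under complete
  ## penetrance, and is kept but flagged inconsistent under incomplete
  vd <- mkVar(id = "d", gene = "CRX", consequence = "frameshift")
  zd <- matrix(c("hom_ref", "het", "het"), 1,
               dimnames = list("d", c("F1", "M1", "C1")))
  expect_length(candidateGenotypes(vd, zd, ped, panel, "AD"), 0L)
  cfgInc <- prioritizationConfig(penetrance_mode = "incomplete")
  cgd <- candidateGenotypes(vd, zd, ped, panel, "AD", cfgInc)
  expect_length(cgd, 1L)
  expect_equal(cosegregation(cgd[[1]]), "inconsistent")
})

test_that("candidate genotypes never invent alleles outside the input", {
  set.seed(7)
  panel <- mkPanel("GENE1", modes = "AR,AD")
  for (rep in 1:10) {
    case <- randomComphetCase()
    for (model in c("AD", "AR_hom", "AR_comphet")) {
      cgs <- candidateGenotypes(case$variants, case$genotypes,
                                case$pedigree, panel, model)
      for (cg in cgs)
        expect_true(all(alleleTable(cg)$id %in% case$variants$id))
    }
  }
})

test_that("comphet selection equals the brute-force pair oracle on random genes", {
  set.seed(11)
  panel <- mkPanel("GENE1")
  for (rep in 1:60) {
    case <- randomComphetCase()
    got <- candidateGenotypes(case$variants, case$genotypes,
                              case$pedigree, panel, "AR_comphet")
    gotPairs <- lapply(got, function(cg) sort(alleleTable(cg)$id))
    expPairs <- bruteForceComphet(case$variants, case$genotypes,
                                  case$pedigree, panel)
    expect_setequal(vapply(gotPairs, paste, "", collapse = "+"),
                    vapply(expPairs, paste, "", collapse = "+"))
  }
})

test_that("cosegregation is unavailable/inconsistent/consistent as the rule dictates", {
  panel <- mkPanel("GENE1", modes = "AR,AD")
  ## proband-only: unavailable
  case <- randomComphetCase()
  solo <- mkVar(id = "s1", gene = "GENE1", consequence = "frameshift")
  pedSolo <- familyPedigree("FS", data.frame(
    id = "P1", father = NA_character_, mother = NA_character_,
    sex = "male", affected = "affected", stringsAsFactors = FALSE))
  zs <- matrix("het", 1, 1, dimnames = list("s1", "P1"))
  cg <- candidateGenotypes(solo, zs, pedSolo, panel, "AD")[[1]]
  expect_equal(cosegregation(cg), "unavailable")

  ## six-member pedigree: exhaustive genotype assignments against the rule
  m <- data.frame(id = c("F1", "M1", "C1", "C2", "C3", "C4"),
                  father = c(NA, NA, rep("F1", 4)),
                  mother = c(NA, NA, rep("M1", 4)),
                  sex = c("male", "female", rep("female", 4)),
                  affected = c("unaffected", "unaffected", "affected",
                               "affected", "unaffected", "unaffected"),
                  stringsAsFactors = FALSE)
  ped6 <- familyPedigree("F6", m)
  v <- mkVar(id = "h", gene = "GENE1")
  states <- c("hom_ref", "het", "hom_alt")
  for (zC3 in states) for (zC4 in states) {
    z <- matrix(c("het", "het", "hom_alt", "hom_alt", zC3, zC4), 1,
                dimnames = list("h", m$id))
    cg <- new("CandidateGenotype", familyId = "F6", gene = "GENE1",
              model = "AR_hom", alleles = cbind(v, zygosity = "hom_alt"),
              cosegregation = "unavailable", phased = NA,
              evidence = list(), classes = character())
    got <- checkCosegregation(cg, ped6, z)
    exp <- if (zC3 == "hom_alt" || zC4 == "hom_alt") "inconsistent"
           else "consistent"
    expect_equal(got, exp, label = sprintf("C3=%s C4=%s", zC3, zC4))
  }
})
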