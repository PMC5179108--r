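test_that("evidence derivation reproduces canonical cases", {
  panelEst <- geneInfo(mkPanel("GUCY2D"), "GUCY2D")
  ## homozygous frameshift, absent from controls, cosegregating
  fs <- mkVar(gene = "GUCY2D", consequence = "frameshift",
              mt_call = "Disease C.", mt_score = 1)
  ev <- deriveEvidence(fs, panelEst, "AR_hom", "consistent")
  expect_setequal(evidenceCodes(ev), c("PVS1", "PM2", "PP1"))

  ## functionally supported homozygous missense at 33/121314 with
  ## cosegregation and 3 positive predictors
  panelFun <- geneInfo(mkPanel("CEP250", association = "candidate_gene",
                               functional = TRUE), "CEP250")
  a609v <- mkVar(gene = "CEP250", exac_ac = 33L, exac_an = 121314L,
                 exac_status = "observed", pp2_call = "Probably D.",
                 sift_call = "Damaging", mt_call = "Neutral", cadd = 20.6)
  ev2 <- deriveEvidence(a609v, panelFun, "AR_hom", "consistent")
  expect_setequal(evidenceCodes(ev2), c("PS3", "PM2", "PP1", "PP3"))

  ## common variant: stand-alone benign only
  common <- mkVar(gene = "GUCY2D", exac_ac = 20000L, exac_an = 100000L,
                  exac_status = "observed", consequence = "missense")
  ev3 <- deriveEvidence(common, panelEst, "AR_hom", "unavailable")
  expect_identical(evidenceCodes(ev3), "BA1")

  ## unknown frequency (position not covered) earns no PM2
  nc <- mkVar(gene = "GUCY2D", consequence = "deep_intronic",
              exac_status = "not_covered", reported = "reported_pathogenic")
  ev4 <- deriveEvidence(nc, panelEst, "AR_comphet", "consistent", "plp")
  expect_false("PM2" %in% evidenceCodes(ev4))
  expect_true(all(c("PM3", "PP1", "PP5_reported") %in% evidenceCodes(ev4)))
})

test_that("PM2 rarity ceilings differ between recessive and dominant contexts", {
  entry <- geneInfo(mkPanel("USH2A"), "USH2A")
  v <- mkVar(gene = "USH2A", exac_ac = 95L, exac_an = 121178L,
             exac_status = "observed")  # ~7.8e-4
  expect_true("PM2" %in% evidenceCodes(
    deriveEvidence(v, entry, "AR_comphet", "consistent")))
  expect_false("PM2" %in% evidenceCodes(
    deriveEvidence(v, entry, "AD", "consistent")))
})

test_that("combining rules match the printed classes of canonical evidence sets", {
  expect_equal(combineEvidence(acmgEvidence(c("PVS1", "PM2", "PP1"))),
               "Pathogenic")
  ## candidate-gene missense with cosegregation and predictor support
  expect_equal(combineEvidence(acmgEvidence(c("PM2", "PP1", "PP3")),
                               association = "candidate_gene",
                               disruptive = FALSE), "VGUS")
  ## the same evidence in an established gene stays VUS
  expect_equal(combineEvidence(acmgEvidence(c("PM2", "PP1", "PP3"))),
               "VUS")
  ## disruptive candidate-gene allele that would be Pathogenic
  expect_equal(combineEvidence(acmgEvidence(c("PVS1", "PM2", "PP1")),
                               association = "candidate_gene",
                               disruptive = TRUE), "VGUS")
  ## contradictory evidence collapses to VUS with a conflict flag
  conflict <- combineEvidence(acmgEvidence(c("PVS1", "BA1")))
  expect_equal(as.character(conflict), "VUS")
  expect_true(attr(conflict, "conflict"))
  expect_equal(combineEvidence(acmgEvidence("BA1")), "Benign")
})

test_that("every evidence subset matches the literal combining-table oracle", {
  codes <- names(irdx:::.ACMG_STRENGTH)
  for (mask in 0:(2^length(codes) - 1)) {
    sel <- codes[bitwAnd(mask, 2^(seq_along(codes) - 1)) > 0]
    got <- as.character(combineEvidence(acmgEvidence(sel)))
    expect_equal(got, oracleCombine(sel),
                 label = paste(sel, collapse = "+"))
  }
})

test_that("adding pathogenic-direction evidence never moves the class toward benign", {
  rank <- c(Pathogenic = 4, LikelyPathogenic = 3, VUS = 2, Benign = 1)
  codes <- setdiff(names(irdx:::.ACMG_STRENGTH), "BA1")
  set.seed(3)
  for (rep in 1:200) {
    sel <- sample(codes, sample.int(length(codes) - 1, 1))
    extra <- sample(setdiff(codes, sel), 1)
    before <- rank[as.character(combineEvidence(acmgEvidence(sel)))]
    after <- rank[as.character(combineEvidence(acmgEvidence(c(sel,
                                                              extra))))]
    expect_gte(after, before)
  }
})

test_that("two-pass classification upgrades PM3 from the trans allele", {
  panel <- mkPanel("CRB1")
  nonsense <- mkVar(id = "n", gene = "CRB1", consequence = "nonsense",
                    exac_ac = 2L, exac_an = 121386L,
                    exac_status = "observed",
                    reported = "reported_pathogenic")
  missense <- mkVar(id = "m", gene = "CRB1", pp2_call = "Probably D.",
                    sift_call = "Damaging", mt_call = "Disease C.",
                    cadd = 15.2)
  al <- rbind(nonsense, missense); al$zygosity <- "het"
  cg <- new("CandidateGenotype", familyId = "2ORG", gene = "CRB1",
            model = "AR_comphet", alleles = al,
            cosegregation = "unavailable", phased = NA,
            evidence = list(), classes = character())
  cg <- classifyCandidate(cg, panel)
  expect_equal(acmgClasses(cg), c("Pathogenic", "LikelyPathogenic"))
  expect_true("PM3_strong" %in% evidenceCodes(slot(cg, "evidence")[[2]]))

  ## a merely co-candidate trans allele contributes supporting PM3, which
  ## still lifts a null allele to Pathogenic
  missense2 <- mkVar(id = "m2", gene = "CRB1", pp2_call = "Possibly D.",
                     sift_call = "Damaging", mt_call = "Disease C.",
                     cadd = 25)
  al2 <- rbind(mkVar(id = "n2", gene = "CRB1", consequence = "nonsense"),
               missense2)
  al2$zygosity <- "het"
  cg2 <- new("CandidateGenotype", familyId = "65ORG", gene = "CRB1",
             model = "AR_comphet", alleles = al2,
             cosegregation = "unavailable", phased = NA,
             evidence = list(), classes = character())
  cg2 <- classifyCandidate(cg2, panel)
  expect_equal(acmgClasses(cg2)[1], "Pathogenic")
  expect_true("PM3_supporting" %in%
                evidenceCodes(slot(cg2, "evidence")[[1]]))
  expect_equal(acmgClasses(cg2)[2], "VUS")
})

test_that("family diagnosis follows the solved/candidate/unsolved rules", {
  panel <- mkPanel(c("GUCY2D", "ABCA4", "PDE6B"),
                   modes = c("AR", "AR", "AD"))
  mk <- function(gene, model, classes, coseg) {
    n <- length(classes)
    al <- do.call(rbind, lapply(seq_len(n), function(i)
      mkVar(id = sprintf("%s%d", gene, i), gene = gene)))
    al$zygosity <- if (model == "AR_hom") "hom_alt" else "het"
    cg <- new("CandidateGenotype", familyId = "F", gene = gene,
              model = model, alleles = al, cosegregation = coseg,
              phased = NA, evidence = list(), classes = classes)
    cg
  }
  ## homozygous Pathogenic in an established gene, cosegregating: solved
  rep1 <- diagnoseFamily(list(mk("GUCY2D", "AR_hom", "Pathogenic",
                                 "consistent")), panel)
  expect_equal(diagnosisStatus(rep1), "solved")

  ## LikelyPathogenic + VUS compound het: candidate
  rep2 <- diagnoseFamily(list(mk("ABCA4", "AR_comphet",
                                 c("LikelyPathogenic", "VUS"),
                                 "consistent")), panel)
  expect_equal(diagnosisStatus(rep2), "candidate")

  ## zero candidates: unsolved
  rep3 <- diagnoseFamily(list(), panel, familyId = "F")
  expect_equal(diagnosisStatus(rep3), "unsolved")

  ## Pathogenic dominant allele with inconsistent cosegregation
  ## (incomplete penetrance): candidate, with a note
  rep4 <- diagnoseFamily(list(mk("PDE6B", "AD", "Pathogenic",
                                 "inconsistent")), panel)
  expect_equal(diagnosisStatus(rep4), "candidate")
  expect_match(slot(rep4, "notes"), "penetrance")

  ## unavailable cosegregation does not block a diagnosis
  rep5 <- diagnoseFamily(list(mk("GUCY2D", "AR_hom", "LikelyPathogenic",
                                 "unavailable")), panel)
  expect_equal(diagnosisStatus(rep5), "solved")
})
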