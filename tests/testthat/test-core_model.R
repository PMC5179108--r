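test_that("PED round trip preserves a trio and maps phenotype codes", {
  ped_file <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1\tF1\t0\t0\t1\t1",
               "F1\tM1\t0\t0\t2\t1",
               "F1\tC1\tF1\tM1\t2\t2"), ped_file)
  ped <- readPedigree(ped_file)
  expect_s4_class(ped, "FamilyPedigree")
  m <- slot(ped, "members")
  expect_equal(nrow(m), 3L)
  expect_equal(m$father[m$id == "C1"], "F1")
  expect_equal(m$mother[m$id == "C1"], "M1")
  expect_equal(m$affected[m$id == "C1"], "affected")
  expect_equal(m$affected[m$id == "F1"], "unaffected")

  out <- withr::local_tempfile(fileext = ".ped")
  writePedigree(ped, out)
  expect_identical(readPedigree(out), ped)
})

test_that("founder-only PED parses and unknown phenotype codes warn", {
  ped_file <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F2\tA\t0\t0\t1\t9", "F2\tB\t0\t0\t2\t1"), ped_file)
  expect_warning(ped <- readPedigree(ped_file), "unknown phenotype")
  m <- slot(ped, "members")
  expect_true(all(is.na(m$father)))
  expect_equal(m$affected[m$id == "A"], "unknown")
})

test_that("a parent id not listed becomes an implicit founder that round-trips", {
  ped_file <- withr::local_tempfile(fileext = ".ped")
  writeLines("F3\tC1\tF1\tM1\t2\t2", ped_file)
  expect_warning(ped <- readPedigree(ped_file), "implicit founder")
  m <- slot(ped, "members")
  expect_setequal(m$id, c("C1", "F1", "M1"))
  out <- withr::local_tempfile(fileext = ".ped")
  writePedigree(ped, out)
  ## the implicit founders round-trip with their unknown phenotype intact
  back <- suppressWarnings(readPedigree(out))
  expect_identical(slot(back, "members")[order(m$id), ],
                   m[order(m$id), ])
})

test_that("cyclic parentage is rejected", {
  m <- data.frame(id = c("A", "B"), father = c("B", "A"),
                  mother = c(NA, NA), sex = c("male", "male"),
                  affected = c("affected", "unaffected"),
                  stringsAsFactors = FALSE)
  expect_error(familyPedigree("F", m), "cyclic")
})

.writeVcf <- function(lines, samples = "S1") {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               lines), path)
  path
}

.soloPed <- function(id = "S1")
  familyPedigree("F1", data.frame(id = id, father = NA_character_,
                                  mother = NA_character_, sex = "female",
                                  affected = "affected",
                                  stringsAsFactors = FALSE))

test_that("a single het SNV yields one record with the printed ExAC fraction", {
  path <- .writeVcf("chr1\t100\t.\tA\tT\t.\tPASS\tAC=2;AN=121386\tGT\t0/1")
  res <- readFamilyVcf(path, .soloPed())
  expect_equal(nrow(res$variants), 1L)
  expect_equal(unname(res$genotypes[1, "S1"]), "het")
  expect_equal(alleleFrequency(res$variants), 2 / 121386,
               tolerance = 1e-15)
})

test_that("an empty VCF body yields an empty record set", {
  path <- .writeVcf(character())
  res <- readFamilyVcf(path, .soloPed())
  expect_equal(nrow(res$variants), 0L)
})

test_that("tri-allelic sites decompose into per-alt records matching the genotype table", {
  path <- .writeVcf(
    c("chr1\t500\t.\tA\tC,T\t.\tPASS\t.\tGT\t1/2\t0/1\t2/2"),
    samples = c("S1", "S2", "S3"))
  ped <- familyPedigree("F1", data.frame(
    id = c("S1", "S2", "S3"), father = NA_character_,
    mother = NA_character_, sex = "female",
    affected = c("affected", "unaffected", "unaffected"),
    stringsAsFactors = FALSE))
  res <- readFamilyVcf(path, ped)
  expect_equal(res$variants$alt, c("C", "T"))
  ## manual decomposition of GTs 1/2, 0/1, 2/2 per alt allele
  expect_equal(unname(res$genotypes["chr1:500:A:C", ]),
               c("het", "het", "hom_ref"))
  expect_equal(unname(res$genotypes["chr1:500:A:T", ]),
               c("het", "hom_ref", "hom_alt"))
})

test_that("a pedigree member absent from the VCF header is a named hard error", {
  path <- .writeVcf("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1")
  ped <- familyPedigree("F1", data.frame(
    id = c("S1", "S9"), father = NA_character_, mother = NA_character_,
    sex = "female", affected = "affected", stringsAsFactors = FALSE))
  expect_error(readFamilyVcf(path, ped), "S9")
})

test_that("VCF write/read round-trip preserves positions, alleles and genotypes", {
  v <- rbind(mkVar(id = "chr2:10:G:A", chrom = "chr2", pos = 10L,
                   ref = "G", alt = "A", exac_ac = 5L, exac_an = 1000L,
                   exac_status = "observed"),
             mkVar(id = "chrX:99:T:C", chrom = "chrX", pos = 99L,
                   ref = "T", alt = "C"))
  z <- matrix(c("het", "hom_alt", "hemizygous", "hom_ref"), 2, 2,
              dimnames = list(v$id, c("S1", "S2")))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeFamilyVcf(v, z, path)
  ped <- familyPedigree("F1", data.frame(
    id = c("S1", "S2"), father = NA_character_, mother = NA_character_,
    sex = c("female", "male"), affected = "affected",
    stringsAsFactors = FALSE))
  res <- readFamilyVcf(path, ped)
  o <- match(v$id, res$variants$id)
  expect_equal(res$variants$pos[o], v$pos)
  expect_equal(res$variants$ref[o], v$ref)
  expect_equal(res$variants$alt[o], v$alt)
  expect_equal(res$genotypes[v$id, ], z)
  expect_equal(res$variants$exac_ac[o], v$exac_ac)
})

test_that("the cohort fixture validates, is stable on reload, and matches printed rows", {
  co <- loadTable1Cohort()
  expect_equal(nrow(co$families), 33L)
  expect_equal(sum(co$families$secure_diagnosis), 18L)
  expect_equal(nrow(co$variants), 41L)
  expect_identical(loadTable1Cohort(), co)

  r58 <- co$variants[co$variants$family == "58ORG", ]
  expect_equal(r58$gene, "GUCY2D")
  expect_equal(r58$consequence, "frameshift")
  expect_equal(r58$zygosity, "hom_alt")
  expect_equal(r58$exac_status, "absent")

  r66 <- co$variants[co$variants$family == "66ORG", ]
  expect_equal(r66$gene, "SEMA6B")
  expect_equal(geneInfo(co$panel, "SEMA6B")$association, "candidate_gene")

  ## printed allele fractions reproduce to high relative precision
  crb1 <- co$variants[co$variants$gene == "CRB1" &
                        co$variants$family == "2ORG" &
                        co$variants$exac_status == "observed", ]
  expect_equal(alleleFrequency(crb1), 2 / 121386, tolerance = 1e-12)
})
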