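test_that("a hand-written VCF parses to the expected dosages", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "an1", "an2", "an3"), collapse = "\t"),
           paste(c("1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
                   "0/0", "0/1", "1/1"), collapse = "\t"),
           paste(c("1", "200", "snp2", "C", "T", ".", "PASS", ".", "GT",
                   "./.", "1|1", "0/0"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  g <- readGenotypes(f, "vcf")
  expect_equal(unname(dosages(g)[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(dosages(g)[, "snp2"]), c(NA, 2, 0))
  expect_equal(snpInfo(g)$pos, c(100L, 200L))

  # multi-allelic sites are refused
  bad <- sub("\tT\t", "\tT,G\t", vcf[5])
  writeLines(c(vcf[1:4], bad), f)
  expect_error(readGenotypes(f, "vcf"), "biallelic")
})

test_that("VCF and raw writers round-trip through the readers", {
  spec <- smallSpec(seed = 2, nPerLine = 20, nF1 = 10, nSnps = 30,
                    nQtl = 10, missingRate = 0.05)
  g <- simulatePopulation(spec, pseudoEbv = FALSE)$genotypes
  fv <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypes(g, fv, "vcf")
  g2 <- readGenotypes(fv, lines = lineOf(g))
  expect_identical(dosages(g2), dosages(g))
  expect_identical(lineOf(g2), lineOf(g))
  expect_equal(snpInfo(g2), snpInfo(g))

  fr <- withr::local_tempfile(fileext = ".txt")
  writeGenotypes(g, fr, "raw")
  g3 <- readGenotypes(fr, "raw")
  expect_identical(dosages(g3), dosages(g))
  expect_identical(lineOf(g3), lineOf(g))

  # real-valued (imputed) dosages only fit the raw dialect
  gi <- imputeMissing(g, mode = "mean")
  expect_error(writeGenotypes(gi, fv, "vcf"), "integer")
  writeGenotypes(gi, fr, "raw")
  expect_equal(dosages(readGenotypes(fr, "raw")), dosages(gi),
               tolerance = 1e-12)
})

test_that("pedigree and trait CSVs round-trip with validation", {
  ped <- Pedigree(data.frame(id = c("p1", "p2", "k"), sire = c(NA, NA, "p1"),
                             dam = c(NA, NA, "p2"), line = "A"))
  f <- withr::local_tempfile(fileext = ".csv")
  writePedigree(ped, f)
  expect_identical(pedigreeTable(readPedigree(f)), pedigreeTable(ped))

  # reliability bound enforced on read
  ft <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,line,ebv,r2", "a,A,1.0,1.2"), ft)
  expect_error(readTraits(ft), "0, 1")

  tr <- TraitRecords(data.frame(id = c("a", "b"), line = "A",
                                ebv = c(1.5, -2), r2 = c(0.4, 0.9)))
  writeTraits(tr, ft)
  expect_equal(traitRecords(readTraits(ft)), traitRecords(tr))
})

test_that("alignDatasets intersects and reports dropped animals", {
  d <- matrix(0:1, 10, 4,
              dimnames = list(paste0("a", 1:10), paste0("s", 1:4)))
  g <- GenotypeData(d, line = "A")
  ped <- Pedigree(data.frame(id = paste0("a", 1:10), sire = NA, dam = NA,
                             line = "A"))
  tr <- TraitRecords(data.frame(id = c(paste0("a", 1:7), paste0("x", 1:3)),
                                line = "A", ebv = 0, r2 = 0.5))
  al <- alignDatasets(g, ped, tr)
  expect_identical(animalIds(al$genotypes), paste0("a", 1:7))
  expect_identical(animalIds(al$traits), paste0("a", 1:7))
  expect_equal(al$report[c("nKept", "nGenotypeOnly", "nTraitOnly")],
               list(nKept = 7L, nGenotypeOnly = 3L, nTraitOnly = 3L))

  # identical sets: nothing dropped
  tr2 <- TraitRecords(data.frame(id = paste0("a", 1:10), line = "A",
                                 ebv = 0, r2 = 0.5))
  expect_equal(alignDatasets(g, ped, tr2)$report$nGenotypeOnly, 0L)
  trX <- TraitRecords(data.frame(id = "zzz", line = "A", ebv = 0, r2 = 0.5))
  expect_error(alignDatasets(g, ped, trX), "no animal")
})

test_that("population specs load from YAML and simulations export to files", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nPerLine: 40", "nF1: 20", "nSnps: 60", "nQtl: 10",
               "h2: 0.25", "rhoPbCb: 0.5", "seed: 3",
               "lines: [DL, LW]"), fy)
  spec <- readPopulationSpec(fy)
  expect_equal(spec@nPerLine, 40L)
  expect_equal(spec@lines, c("DL", "LW"))
  expect_equal(spec@h2, 0.25)
  writeLines("nopeField: 1", fy)
  expect_error(readPopulationSpec(fy), "unknown population spec")

  spec2 <- smallSpec(seed = 5, nPerLine = 25, nF1 = 10, nSnps = 40,
                     nQtl = 8, missingRate = 0.02)
  sim <- simulatePopulation(spec2)
  d <- withr::local_tempdir()
  writeSimulation(sim, d)
  expect_true(all(file.exists(file.path(d, c("genotypes.vcf",
                                             "pedigree.csv", "traits.csv",
                                             "truth.csv",
                                             "line_freqs.csv")))))
  g <- readGenotypes(file.path(d, "genotypes.vcf"),
                     lines = lineOf(sim$genotypes))
  expect_identical(dosages(g), dosages(sim$genotypes))
  tru <- read.csv(file.path(d, "truth.csv"))
  expect_equal(tru$effectPb, unname(sim$truth$qtlEffectsPb))
})
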