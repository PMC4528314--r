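test_that("founder simulation honors a degenerate MAF interval and HW heterozygosity", {
  spec <- smallSpec(founderMafRange = c(0.5, 0.5), nFounders = 100,
                    nSnps = 50, nQtl = 20)
  f <- simulateFounders(spec)
  expect_true(all(f$freqs == 0.5))

  # binomial sampling oracle: mean heterozygosity 2pq at p = 0.3
  spec2 <- smallSpec(founderMafRange = c(0.3, 0.3), nFounders = 2000,
                     nSnps = 1000, seed = 4)
  d <- dosages(simulateFounders(spec2)$genotypes)
  het <- mean(d == 1)
  se <- sqrt(0.42 * 0.58 / length(d))
  expect_lt(abs(het - 2 * 0.3 * 0.7), 3 * se)
})

test_that("identical spec and seed give identical founders", {
  a <- simulateFounders(smallSpec(seed = 9))
  b <- simulateFounders(smallSpec(seed = 9))
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_false(identical(dosages(a$genotypes),
                         dosages(simulateFounders(smallSpec(seed = 10))$genotypes)))
})

test_that("drift matches Wright-Fisher expectations", {
  p0 <- runif(400, 0.2, 0.5)
  # zero generations: frequencies unchanged
  d0 <- driftLines(p0, generations = 0, effectiveSize = 50, seed = 1)
  expect_identical(d0$freqs[1, ], p0)
  expect_identical(d0$freqs[2, ], p0)

  # realized Fst vs 1 - (1 - 1/(2Ne))^t, thousands of independent SNP
  # replicates; tolerance three Monte-Carlo standard errors of the mean
  Ne <- 50; t <- 10
  p0 <- runif(5000, 0.2, 0.5)
  dl <- driftLines(p0, t, Ne, seed = 2)
  fexp <- 1 - (1 - 1 / (2 * Ne))^t
  perSnp <- apply(dl$freqs, 2, var) / mean(p0 * (1 - p0))
  se <- sd(perSnp) / sqrt(length(perSnp))
  expect_lt(abs(dl$fst - fexp), 3 * se)

  # drift is unbiased: mean frequency change ~ 0
  dchg <- colMeans(dl$freqs) - p0
  expect_lt(abs(mean(dchg)), 3 * sd(dchg) / sqrt(length(dchg)))
})

test_that("realized Fst is non-decreasing in drift generations", {
  fst <- sapply(c(5, 15, 30), function(t) {
    mean(sapply(1:20, function(s)
      driftLines(runif(300, 0.2, 0.5), t, 60, seed = s)$fst))
  })
  expect_true(all(diff(fst) > 0))
})

test_that("F1 cross transmits one gamete per parent", {
  # fixed opposite homozygotes force heterozygous offspring
  dA <- matrix(2, 5, 4, dimnames = list(paste0("s", 1:5), paste0("m", 1:4)))
  dB <- matrix(0, 5, 4, dimnames = list(paste0("d", 1:5), paste0("m", 1:4)))
  cr <- makeF1(GenotypeData(dA, "A"), GenotypeData(dB, "B"), 20, seed = 3)
  expect_true(all(dosages(cr$genotypes) == 1))
  expect_true(all(cr$pedigree$sire %in% rownames(dA)))
  expect_true(all(cr$pedigree$dam %in% rownames(dB)))
  expect_true(all(cr$pedigree$line == "F1"))

  # allele frequency oracle: F1 freq ~ (pA + pB)/2
  spec <- smallSpec(nFounders = 400, nSnps = 600, seed = 5)
  dl <- driftLines(runif(600, 0.2, 0.5), 10, 50, nPerLine = 300, seed = 5)
  cr2 <- makeF1(dl$genotypes$A, dl$genotypes$B, 1500, seed = 6)
  pF1 <- colMeans(dosages(cr2$genotypes)) / 2
  pExp <- (dl$freqs[1, ] + dl$freqs[2, ]) / 2
  dev <- pF1 - pExp
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
  expect_error(makeF1(dl$genotypes$A[, character(0)], dl$genotypes$B, 5),
               "empty|SNP")
})

test_that("QTL effects honor the purebred-crossbred correlation", {
  spec <- smallSpec(nQtl = 500, nSnps = 600, rhoPbCb = 1, seed = 11)
  d <- matrix(rbinom(200 * 600, 2, 0.4), 200, 600,
              dimnames = list(paste0("a", 1:200), paste0("s", 1:600)))
  lines <- setNames(rep(c("A", "B"), 100), rownames(d))
  e1 <- assignEffects(d, lines, spec)
  expect_equal(cor(e1$truth$qtlEffectsPb, e1$truth$qtlEffectsCb), 1)

  spec9 <- smallSpec(nQtl = 500, nSnps = 600, rhoPbCb = 0.9, seed = 12)
  e9 <- assignEffects(d, lines, spec9)
  r <- cor(e9$truth$qtlEffectsPb, e9$truth$qtlEffectsCb)
  se <- (1 - 0.9^2) / sqrt(500)
  expect_lt(abs(r - 0.9), 3 * se)

  # phenotype = TBV + noise: regression of phenotype on TBV ~ 1
  tbv <- e9$truth$tbvPb
  fitSlope <- biasSlope(tbv, e9$phenotypes, direction = "obsOnPred")
  seSlope <- sqrt((1 - 0.3) / (length(tbv) * var(tbv)))
  expect_lt(abs(fitSlope - 1), 3 * seSlope)

  expect_error(assignEffects(d, lines, smallSpec(h2 = 0)), "h2")
})

test_that("TBVs are an exact dot product of dosage and stored effects", {
  spec <- smallSpec(seed = 21, nPerLine = 80, nF1 = 40, nSnps = 300,
                    nQtl = 60, missingRate = 0)
  sim <- simulatePopulation(spec, pseudoEbv = FALSE)
  tr <- sim$truth
  d <- dosages(sim$genotypes)
  ids <- rownames(d)
  expect_equal(unname(drop(d[, tr$qtlIds] %*% tr$qtlEffectsPb)) -
                 tr$interceptPb,
               unname(tr$tbvPb[ids]), tolerance = 1e-12)
  expect_equal(unname(drop(d[, tr$qtlIds] %*% tr$qtlEffectsCb)) -
                 tr$interceptCb,
               unname(tr$tbvCb[ids]), tolerance = 1e-12)
  expect_length(tr$qtlEffectsPb, spec@nQtl)
  expect_length(tr$qtlEffectsCb, spec@nQtl)
})

test_that("the full generator is deterministic and keeps its variance bookkeeping", {
  spec <- smallSpec(seed = 31, nPerLine = 500, nF1 = 200, nSnps = 400,
                    nQtl = 100, pedGenerations = 1)
  a <- simulatePopulation(spec)
  b <- simulatePopulation(spec)
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(traitRecords(a$traits), traitRecords(b$traits))

  # var(TBV)/var(phenotype) ~ h2 within each purebred line (n >= 1000
  # phenotyped animals across lines)
  lin <- lineOf(a$pedigree)[names(a$phenotypes)]
  for (l in c("A", "B")) {
    ids <- names(a$phenotypes)[lin == l]
    ratio <- var(a$truth$tbvPb[ids]) / var(a$phenotypes[ids])
    expect_lt(abs(ratio - spec@h2), 0.06)  # ~3 MC SEs at n = 500
  }

  # pedigree structure: every F1 has a line-A sire and line-B dam
  ptab <- pedigreeTable(a$pedigree)
  lo <- lineOf(a$pedigree)
  f1 <- ptab[ptab$line == "F1", ]
  expect_true(all(lo[f1$sire] == "A"))
  expect_true(all(lo[f1$dam] == "B"))
})
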