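# Synthetic multi-line population generator.
#
# The generator produces the data structure the rest of the pipeline
# assumes: two purebred lines whose allele frequencies have diverged by
# Wright-Fisher drift, a recent pedigree within each line (so pedigree-based
# prediction has information to work with), an F1 cross between the lines,
# and a trait whose purebred and crossbred expressions are controlled by
# correlated QTL effect vectors.

#' Simulate founder genotypes in Hardy-Weinberg proportions
#'
#' Founder allele frequencies are drawn uniformly on the spec's
#' `founderMafRange` (the drawn value is the minor-allele frequency) and
#' each genotype is two independent allele draws, so sites are in
#' Hardy-Weinberg proportions with no missing calls.
#'
#' @param spec a [PopulationSpec-class].
#' @return list with `genotypes` (a [GenotypeData-class] of `nFounders`
#'   animals) and `freqs` (the founder allele-frequency vector).
#' @export
simulateFounders <- function(spec) {
  stopifnot(is(spec, "PopulationSpec"))
  methods::validObject(spec)
  withSeed(spec@seed, {
    p <- runif(spec@nSnps, spec@founderMafRange[1], spec@founderMafRange[2])
    g <- drawHardyWeinberg(spec@nFounders, p,
                           ids = paste0("F", seq_len(spec@nFounders)),
                           snpIds = defaultSnpIds(spec@nSnps),
                           line = "founder")
    list(genotypes = g, freqs = p)
  })
}

defaultSnpIds <- function(m) sprintf("snp%05d", seq_len(m))

# n animals drawn at HW proportions from frequency vector p.
drawHardyWeinberg <- function(n, p, ids, snpIds, line) {
  m <- length(p)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m,
              dimnames = list(ids, snpIds))
  GenotypeData(d, line = line)
}

#' Drift line allele frequencies by Wright-Fisher resampling
#'
#' Each line starts at the founder frequencies and evolves independently for
#' `generations` rounds of binomial resampling of `2 * effectiveSize`
#' gametes. Line genotypes are then drawn at the final frequencies. The
#' realized Fst is the mean across SNPs of the between-line variance of
#' frequencies divided by the mean founder heterozygosity term p0*q0; its
#' expectation is `1 - (1 - 1/(2*Ne))^t`.
#'
#' @param founderFreqs founder allele-frequency vector.
#' @param generations number of drift generations (>= 0).
#' @param effectiveSize effective population size Ne (>= 2).
#' @param lines character vector of line labels.
#' @param nPerLine animals to draw per line at the final frequencies.
#' @param seed integer seed.
#' @return list with `freqs` (lines x SNPs matrix), `genotypes` (list of
#'   [GenotypeData-class] per line) and `fst` (realized Fst, NA for a single
#'   line or zero founder diversity).
#' @export
driftLines <- function(founderFreqs, generations, effectiveSize,
                       lines = c("A", "B"), nPerLine = 0L, seed = 1L) {
  stopifnot(generations >= 0, effectiveSize >= 2)
  withSeed(seed, {
    L <- length(lines)
    m <- length(founderFreqs)
    p <- matrix(rep(founderFreqs, each = L), L, m,
                dimnames = list(lines, NULL))
    ng <- 2L * as.integer(effectiveSize)
    for (g in seq_len(generations))
      p[] <- rbinom(L * m, ng, p) / ng
    genos <- NULL
    if (nPerLine > 0) {
      genos <- lapply(lines, function(l)
        drawHardyWeinberg(nPerLine, p[l, ],
                          ids = paste0(l, seq_len(nPerLine)),
                          snpIds = defaultSnpIds(m), line = l))
      names(genos) <- lines
    }
    list(freqs = p, genotypes = genos,
         fst = realizedFst(p, founderFreqs))
  })
}

# Between-line frequency variance standardized by founder p0*q0.
realizedFst <- function(lineFreqs, founderFreqs) {
  het <- mean(founderFreqs * (1 - founderFreqs))
  if (nrow(lineFreqs) < 2 || het <= 0) return(NA_real_)
  v <- apply(lineFreqs, 2, var)
  mean(v) / het
}

#' Cross two purebred parent sets into an F1 generation
#'
#' Each offspring receives one gamete from a named sire in the first parent
#' set and one from a named dam in the second. SNPs assort independently
#' (no linkage); at each SNP the transmitted allele is a Bernoulli draw with
#' probability dosage/2.
#'
#' @param sires,dams [GenotypeData-class] objects sharing the same SNP set.
#' @param nOffspring number of F1 animals.
#' @param seed integer seed.
#' @param ids offspring ids (default `F1_1`, `F1_2`, ...).
#' @return list with `genotypes` (the F1 [GenotypeData-class]) and
#'   `pedigree` (data.frame of id/sire/dam/line rows, line `"F1"`).
#' @export
makeF1 <- function(sires, dams, nOffspring, seed = 1L, ids = NULL) {
  if (ncol(dosages(sires)) != ncol(dosages(dams)) ||
      !identical(snpIds(sires), snpIds(dams)))
    stop("sire and dam sets must share the same SNP set")
  if (nrow(dosages(sires)) == 0 || nrow(dosages(dams)) == 0)
    stop("empty parent set")
  withSeed(seed, {
    if (is.null(ids)) ids <- paste0("F1_", seq_len(nOffspring))
    sid <- sample(animalIds(sires), nOffspring, replace = TRUE)
    did <- sample(animalIds(dams), nOffspring, replace = TRUE)
    d <- meiosis(dosages(sires), sid) + meiosis(dosages(dams), did)
    dimnames(d) <- list(ids, snpIds(sires))
    list(genotypes = GenotypeData(d, line = "F1",
                                  chrom = snpInfo(sires)$chrom,
                                  pos = snpInfo(sires)$pos),
         pedigree = data.frame(id = ids, sire = sid, dam = did,
                               line = "F1"))
  })
}

# One gamete per offspring from each parent row (no linkage).
meiosis <- function(parentDosage, parentIds) {
  pm <- parentDosage[parentIds, , drop = FALSE] / 2
  matrix(rbinom(length(pm), 1L, pm), nrow(pm), ncol(pm))
}

#' Assign correlated QTL effects and simulate phenotypes
#'
#' A random subset of `nQtl` SNPs is declared causal and each receives a
#' pair of allele-substitution effects (purebred, crossbred) drawn from a
#' zero-mean bivariate normal with correlation `rhoPbCb`. True breeding
#' values are dosage-times-effect dot products, rescaled so the mean
#' within-line additive variance equals `h2` on a unit phenotypic-variance
#' scale; the crossbred scaling uses the F1 animals (or the purebreds when
#' no F1 is present). Phenotypes are line mean + context-appropriate TBV +
#' independent normal noise with variance `1 - h2`.
#'
#' @param dosage complete animals x SNPs dosage matrix with dimnames.
#' @param lines named line label per animal; animals labelled `"F1"` express
#'   the crossbred trait, all others the purebred trait.
#' @param spec a [PopulationSpec-class] (uses `nQtl`, `h2`, `rhoPbCb`,
#'   `lineMeans`).
#' @param seed integer seed (defaults to the spec's).
#' @param qtlIds optional fixed set of causal SNP ids.
#' @return list with elements `truth` (qtl ids, scaled effect vectors,
#'   intercepts making `tbv = dosage[, qtl] %*% effects - intercept` an exact
#'   identity, and both TBV contexts for every animal) and `phenotypes`
#'   (named vector).
#' @export
assignEffects <- function(dosage, lines, spec, seed = NULL, qtlIds = NULL) {
  h2 <- spec@h2
  if (h2 <= 0 && spec@nQtl > 0)
    stop("h2 = 0 is incompatible with a genetic signal (nQtl > 0)")
  if (is.null(seed)) seed <- deriveSeed(spec@seed, 7L)
  withSeed(seed, {
    if (is.null(qtlIds))
      qtlIds <- sort(sample(colnames(dosage), spec@nQtl))
    M <- dosage[, qtlIds, drop = FALSE]
    uPb <- rnorm(spec@nQtl)
    uCb <- spec@rhoPbCb * uPb +
      sqrt(max(0, 1 - spec@rhoPbCb^2)) * rnorm(spec@nQtl)
    isF1 <- lines == "F1"
    rawPb <- drop(M %*% uPb)
    rawCb <- drop(M %*% uCb)
    pbVar <- meanWithinLineVar(rawPb, lines[!isF1], subset = !isF1)
    cbVar <- if (any(isF1)) var(rawCb[isF1]) else
      meanWithinLineVar(rawCb, lines, subset = !isF1)
    if (!is.finite(pbVar) || pbVar <= 0 || !is.finite(cbVar) || cbVar <= 0)
      stop("degenerate genetic variance; increase nQtl or founder diversity")
    sPb <- sqrt(h2 / pbVar)
    sCb <- sqrt(h2 / cbVar)
    effPb <- sPb * uPb
    effCb <- sCb * uCb
    interceptPb <- mean(rawPb[!isF1]) * sPb
    interceptCb <- if (any(isF1)) mean(rawCb[isF1]) * sCb else
      mean(rawCb[!isF1]) * sCb
    tbvPb <- drop(M %*% effPb) - interceptPb
    tbvCb <- drop(M %*% effCb) - interceptCb
    names(tbvPb) <- names(tbvCb) <- rownames(dosage)
    tbv <- ifelse(isF1, tbvCb, tbvPb)
    mu <- spec@lineMeans[lines]
    if (anyNA(mu)) stop("lineMeans missing for line(s): ",
                        paste(unique(lines[is.na(mu)]), collapse = ", "))
    y <- drop(mu) + tbv + rnorm(length(tbv), 0, sqrt(max(0, 1 - h2)))
    names(y) <- rownames(dosage)
    list(truth = list(qtlIds = qtlIds, qtlEffectsPb = effPb,
                      qtlEffectsCb = effCb, interceptPb = interceptPb,
                      interceptCb = interceptCb, tbvPb = tbvPb,
                      tbvCb = tbvCb),
         phenotypes = y)
  })
}

meanWithinLineVar <- function(x, lines, subset = TRUE) {
  x <- x[subset]; lines <- lines[subset]
  v <- tapply(x, lines, var)
  mean(v[!is.na(v)])
}

#' Simulate a complete two-line + F1 breeding data set
#'
#' Runs the full generator: founder panel, per-line Wright-Fisher drift,
#' a recent pedigree of `pedGenerations` generations within each line
#' (half-sib family structure: roughly one sire per eight matings), an F1
#' cross whose purebred parents sit `gapGenerations` generations behind the
#' genotyped nucleus animals, correlated purebred/crossbred QTL effects,
#' phenotypes, and pseudo-EBVs with per-animal reliabilities obtained by
#' solving the pedigree-based mixed model on the simulated phenotypes
#' (reliability = 1 - PEV/sigma2a). Genotype calls are finally masked
#' missing at the spec's `missingRate`.
#'
#' @param spec a [PopulationSpec-class].
#' @param pseudoEbv run the pedigree-BLUP pseudo-EBV step (the most
#'   expensive stage); set `FALSE` when only genotypes/phenotypes/truth are
#'   needed, in which case `traits` and `evaluation` are `NULL`.
#' @return a list of class `SimulatedPopulation` with elements
#'   `genotypes` ([GenotypeData-class] of genotyped purebred + F1 animals),
#'   `pedigree` ([Pedigree-class], including ungenotyped ancestors),
#'   `traits` ([TraitRecords-class] with pseudo-EBV and reliability),
#'   `phenotypes` (named vector over all phenotyped animals),
#'   `truth` (QTL effects, TBVs, line frequencies, realized Fst), and
#'   `evaluation` (line-effect estimates and variance components used for
#'   the pseudo-EBV step).
#' @export
simulatePopulation <- function(spec, pseudoEbv = TRUE) {
  stopifnot(is(spec, "PopulationSpec"))
  methods::validObject(spec)
  withSeed(spec@seed, {
    m <- spec@nSnps
    snps <- defaultSnpIds(m)
    p0 <- runif(m, spec@founderMafRange[1], spec@founderMafRange[2])
    ng <- 2L * spec@effectiveSize
    lineFreq <- matrix(rep(p0, each = 2), 2, m,
                       dimnames = list(spec@lines, snps))
    for (g in seq_len(spec@driftGenerations))
      lineFreq[] <- rbinom(2 * m, ng, lineFreq) / ng

    nBase <- max(40L, ceiling(spec@nPerLine / 3))
    ped <- list(); doseAll <- list(); lineAll <- list()
    genoIds <- character(); f1ParentPool <- list()
    f1Gen <- max(0L, spec@pedGenerations - spec@gapGenerations)
    for (l in spec@lines) {
      prevIds <- paste0(l, "_g0_", seq_len(nBase))
      prevDose <- matrix(rbinom(nBase * m, 2L, rep(lineFreq[l, ], each = nBase)),
                         nBase, m, dimnames = list(prevIds, snps))
      ped[[length(ped) + 1L]] <- data.frame(
        id = prevIds, sire = NA_character_, dam = NA_character_, line = l)
      doseAll[[length(doseAll) + 1L]] <- prevDose
      if (f1Gen == 0L) f1ParentPool[[l]] <- prevIds
      for (g in seq_len(spec@pedGenerations)) {
        nOff <- spec@nPerLine
        ids <- paste0(l, "_g", g, "_", seq_len(nOff))
        nSire <- max(2L, ceiling(length(prevIds) / 8))
        sireCand <- prevIds[seq_len(nSire)]
        damCand <- prevIds[-seq_len(nSire)]
        sid <- sample(sireCand, nOff, replace = TRUE)
        did <- sample(damCand, nOff, replace = TRUE)
        dose <- meiosis(prevDose, sid) + meiosis(prevDose, did)
        dimnames(dose) <- list(ids, snps)
        ped[[length(ped) + 1L]] <- data.frame(id = ids, sire = sid,
                                              dam = did, line = l)
        doseAll[[length(doseAll) + 1L]] <- dose
        if (g == f1Gen) f1ParentPool[[l]] <- ids
        prevIds <- ids; prevDose <- dose
      }
      genoIds <- c(genoIds, prevIds)
    }
    dose <- do.call(rbind, doseAll)
    pedDf <- do.call(rbind, ped)

    if (spec@nF1 > 0) {
      poolA <- f1ParentPool[[spec@lines[1]]]
      poolB <- f1ParentPool[[spec@lines[2]]]
      nSireA <- max(2L, ceiling(length(poolA) / 8))
      cross <- makeF1(subsetGenotypeData(dose, poolA[seq_len(nSireA)],
                                         spec@lines[1], snps),
                      subsetGenotypeData(dose, poolB[-seq_len(
                        max(2L, ceiling(length(poolB) / 8)))], spec@lines[2],
                        snps),
                      spec@nF1, seed = deriveSeed(spec@seed, 3L))
      dose <- rbind(dose, dosages(cross$genotypes))
      pedDf <- rbind(pedDf, cross$pedigree)
      genoIds <- c(genoIds, cross$pedigree$id)
    }
    pedigree <- Pedigree(pedDf)
    lineOfAll <- setNames(pedDf$line, pedDf$id)

    # trait architecture + phenotypes over all pedigreed animals
    eff <- assignEffects(dose, lineOfAll[rownames(dose)], spec,
                         seed = deriveSeed(spec@seed, 7L))

    # pseudo-EBVs: pedigree BLUP on phenotypes of generation >= 1 animals
    traits <- NULL
    evaluation <- NULL
    s2a <- spec@h2; s2e <- 1 - spec@h2
    if (pseudoEbv) {
      phenoIds <- pedDf$id[!(is.na(pedDf$sire) & is.na(pedDf$dam))]
      A <- buildA(pedigree, subset = phenoIds)
      # multi-parity record means: first-parity residual plus extra draws
      nPar <- sample(spec@parityRange[1]:spec@parityRange[2],
                     length(phenoIds), replace = TRUE)
      isF1p <- lineOfAll[phenoIds] == "F1"
      tbvCtx <- ifelse(isF1p, eff$truth$tbvCb[phenoIds],
                       eff$truth$tbvPb[phenoIds])
      muCtx <- spec@lineMeans[lineOfAll[phenoIds]]
      e1 <- eff$phenotypes[phenoIds] - muCtx - tbvCtx
      extra <- rnorm(length(phenoIds), 0,
                     sqrt(pmax(0, (nPar - 1) * (1 - spec@h2))))
      yEval <- setNames(muCtx + tbvCtx + (e1 + extra) / nPar, phenoIds)
      fit <- solveBlup(yEval, A,
                       weights = setNames(as.numeric(nPar), phenoIds),
                       lines = lineOfAll[phenoIds],
                       sigma2a = s2a, sigma2e = s2e)
      # trait records for every evaluated animal (parents included, so
      # parent-adjusted deregression can see their EBVs), not only the
      # genotyped generation
      r2 <- pmin(0.99, pmax(1e-6, fit$reliability[phenoIds]))
      traits <- TraitRecords(data.frame(
        id = phenoIds, line = lineOfAll[phenoIds],
        ebv = fit$gHat[phenoIds], r2 = r2, row.names = NULL))
      evaluation <- list(mu = fit$beta[1],
                         lineEffects = lineEffectsFromFit(
                           fit, unique(lineOfAll[phenoIds])),
                         sigma2a = s2a, sigma2e = s2e,
                         records = data.frame(id = phenoIds,
                                              parities = nPar,
                                              recordMean = unname(yEval)))
    }

    gdose <- dose[genoIds, , drop = FALSE]
    if (spec@missingRate > 0) {
      nMiss <- rbinom(1L, length(gdose), spec@missingRate)
      gdose[sample(length(gdose), nMiss)] <- NA
    }
    chrom <- rep(as.character(seq_len(18)), length.out = m)
    pos <- as.integer(seq_len(m) * 1000L)
    genotypes <- GenotypeData(gdose, line = lineOfAll[genoIds],
                              chrom = chrom, pos = pos)

    f1Freq <- if (spec@nF1 > 0) colMeans(lineFreq) else NULL
    truth <- c(eff$truth,
               list(founderFreqs = setNames(p0, snps), lineFreqs = lineFreq,
                    f1Freqs = f1Freq, realizedFst = realizedFst(lineFreq, p0)))
    structure(list(genotypes = genotypes, pedigree = pedigree,
                   traits = traits, phenotypes = eff$phenotypes,
                   truth = truth, evaluation = evaluation),
              class = "SimulatedPopulation")
  })
}

subsetGenotypeData <- function(dose, ids, line, snps) {
  GenotypeData(dose[ids, , drop = FALSE], line = line)
}

# Named per-line fixed-effect estimates (reference line = 0).
lineEffectsFromFit <- function(fit, lines) {
  lv <- sort(unique(lines))
  eff <- setNames(numeric(length(lv)), lv)
  for (l in lv[-1]) {
    nm <- paste0("line", l)
    if (nm %in% names(fit$beta)) eff[l] <- fit$beta[nm]
  }
  eff
}

#' @export
print.SimulatedPopulation <- function(x, ...) {
  cat("SimulatedPopulation:", length(animalIds(x$genotypes)),
      "genotyped animals,", length(animalIds(x$pedigree)),
      "pedigree records,", length(snpIds(x$genotypes)), "SNPs\n")
  cat("  realized Fst:", round(x$truth$realizedFst, 4), "\n")
  invisible(x)
}

#' Read a PopulationSpec from a YAML file
#'
#' The file holds any subset of [populationSpec()]'s arguments by name,
#' e.g. `nPerLine: 1200` or `lines: [DL, LW]`; omitted fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a [PopulationSpec-class].
#' @export
readPopulationSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(populationSpec))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown population spec field(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$lineMeans)) cfg$lineMeans <- unlist(cfg$lineMeans)
  do.call(populationSpec, cfg)
}

#' Export a simulated population to standard files
#'
#' Writes `genotypes.vcf` (raw calls, `./.` for missing), `pedigree.csv`,
#' `traits.csv`, a `truth.csv` sidecar with the causal SNPs and their
#' scaled purebred/crossbred effects (the test oracle for dot-product
#' reconstruction of TBVs), and `line_freqs.csv` with the drifted per-line
#' allele frequencies.
#'
#' @param sim a `SimulatedPopulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypes(sim$genotypes, file.path(dir, "genotypes.vcf"), "vcf")
  writePedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  if (!is.null(sim$traits))
    writeTraits(sim$traits, file.path(dir, "traits.csv"))
  tr <- sim$truth
  utils::write.csv(data.frame(qtl = tr$qtlIds,
                              effectPb = tr$qtlEffectsPb,
                              effectCb = tr$qtlEffectsCb),
                   file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  lf <- data.frame(snp = colnames(tr$lineFreqs), t(tr$lineFreqs))
  utils::write.csv(lf, file.path(dir, "line_freqs.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
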