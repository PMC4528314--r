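# Replicated training/validation prediction scenarios: within-population,
# multi-population, across-population, and purebred-to-crossbred.

#' Prediction accuracy
#'
#' Pearson correlation between predictions (GEBV/EBV) and the validation
#' responses (DEBV). Returns `NA` (an explicit undefined-accuracy signal,
#' distinct from 0) when either vector has zero variance.
#'
#' @param pred,obs equal-length paired vectors, length >= 3.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
predictionAccuracy <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 3) stop("need at least 3 pairs")
  if (sd(pred) == 0 || sd(obs) == 0) return(NA_real_)
  cor(pred, obs)
}

#' Dispersion bias (regression slope)
#'
#' Ordinary-least-squares slope. The default regresses the validation
#' responses on the predictions (`obsOnPred`, slope < 1 means
#' over-dispersed predictions); the reverse direction is also available
#' since both conventions appear in the literature.
#'
#' @param pred,obs equal-length paired vectors, length >= 3.
#' @param direction `"obsOnPred"` (default) or `"predOnObs"`.
#' @return the slope, or `NA` when the regressor has zero variance.
#' @export
biasSlope <- function(pred, obs, direction = c("obsOnPred", "predOnObs")) {
  direction <- match.arg(direction)
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 3) stop("need at least 3 pairs")
  x <- if (direction == "obsOnPred") pred else obs
  y <- if (direction == "obsOnPred") obs else pred
  if (sd(x) == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Define a prediction scenario
#'
#' @param id scenario label.
#' @param trainingLines named vector giving the training sample size per
#'   line: a number, or `"all"` for every eligible animal of that line.
#' @param validationLine line supplying the validation set.
#' @param validationSize number of validation animals sampled per
#'   replicate, or `"all"` (then typically `nReplicates = 1`).
#' @param nReplicates number of random training/validation replicates.
#' @param matrixKind `"auto"` (genomic: across-population centering when
#'   more than one line is analyzed, VanRaden otherwise), or one of
#'   `"genomic_within"`, `"genomic_across"`, `"pedigree"`.
#' @param group scenario group label (free text).
#' @param seed base seed; replicate seeds are derived deterministically, so
#'   two runs of the same spec sample identical sets.
#' @return a `ScenarioSpec` (list).
#' @export
scenarioSpec <- function(id, trainingLines, validationLine,
                         validationSize = 50, nReplicates = 20,
                         matrixKind = "auto", group = "", seed = 1L) {
  structure(list(id = as.character(id), trainingLines = trainingLines,
                 validationLine = validationLine,
                 validationSize = validationSize,
                 nReplicates = as.integer(nReplicates),
                 matrixKind = matrixKind, group = group,
                 seed = as.integer(seed)),
            class = "ScenarioSpec")
}

#' Run one replicated prediction scenario
#'
#' Per replicate: sample the validation set from the validation line, then
#' the training sets per line (never overlapping the validation animals),
#' build the requested relationship matrix over training plus validation,
#' estimate variance components on the training data by REML (or use
#' supplied ones), solve the mixed model with the validation responses
#' removed, and score accuracy and slope on the validation set. A line
#' fixed effect is included whenever the training set spans more than one
#' line. Undefined accuracies (zero-variance predictions) are excluded from
#' the summary means and counted.
#'
#' @param spec a [scenarioSpec()].
#' @param genotypes complete [GenotypeData-class] (after QC/imputation).
#' @param traits deregressed [TraitRecords-class] (needs `debv`, `weight`).
#' @param pedigree a [Pedigree-class] (needed for `matrixKind =
#'   "pedigree"`).
#' @param varComponents `"reml"` to re-estimate on each training set, or
#'   `"fixed"` with `sigma2a`/`sigma2e` supplied.
#' @param sigma2a,sigma2e variance components for `varComponents = "fixed"`.
#' @param model label stored in the result (e.g. `"gblup"`, `"pedblup"`).
#' @return a [ScenarioResult-class].
#' @export
runScenario <- function(spec, genotypes, traits, pedigree = NULL,
                        varComponents = c("reml", "fixed"),
                        sigma2a = NULL, sigma2e = NULL, model = "gblup") {
  varComponents <- match.arg(varComponents)
  if (varComponents == "fixed" && (is.null(sigma2a) || is.null(sigma2e)))
    stop("fixed variance components require sigma2a and sigma2e")
  tr <- traitRecords(traits)
  if (!all(c("debv", "weight") %in% names(tr)))
    stop("traits must be deregressed first (need debv and weight)")
  gid <- animalIds(genotypes)
  tr <- tr[tr$id %in% gid, , drop = FALSE]
  byLine <- split(tr$id, tr$line)
  if (!spec$validationLine %in% names(byLine))
    stop("no eligible animals in validation line ", spec$validationLine)
  debv <- setNames(tr$debv, tr$id)
  wts <- setNames(tr$weight, tr$id)
  lin <- setNames(tr$line, tr$id)

  reps <- vector("list", spec$nReplicates)
  for (r in seq_len(spec$nReplicates)) {
    rseed <- deriveSeed(spec$seed, r)
    reps[[r]] <- withSeed(rseed, {
      pool <- byLine[[spec$validationLine]]
      vIds <- if (identical(spec$validationSize, "all")) pool
              else sample(pool, spec$validationSize)
      if (length(vIds) < 3) stop("validation set smaller than 3")
      tIds <- character(0)
      for (l in names(spec$trainingLines)) {
        if (!l %in% names(byLine)) stop("no eligible animals in line ", l)
        avail <- setdiff(byLine[[l]], vIds)
        sz <- spec$trainingLines[[l]]
        tIds <- c(tIds, if (identical(sz, "all")) avail
                  else sample(avail, as.integer(sz)))
      }
      stopifnot(length(intersect(tIds, vIds)) == 0)  # never leak responses
      all <- c(tIds, vIds)
      kind <- spec$matrixKind
      if (kind == "auto")
        kind <- if (length(unique(lin[all])) > 1) "genomic_across"
                else "genomic_within"
      K <- switch(kind,
        pedigree = {
          if (is.null(pedigree)) stop("pedigree matrix requested without a pedigree")
          buildA(pedigree, subset = all)
        },
        genomic_within = buildG(dosages(genotypes)[all, , drop = FALSE]),
        genomic_across = buildGAcross(dosages(genotypes)[all, , drop = FALSE],
                                      lines = lin[all]))
      fixedLines <- if (length(unique(lin[tIds])) > 1) lin else NULL
      y <- debv[tIds]
      if (varComponents == "reml") {
        vc <- remlUnivariate(y, K, weights = wts[tIds], lines = fixedLines)
        s2a <- vc$sigma2a; s2e <- vc$sigma2e
      } else {
        s2a <- sigma2a; s2e <- sigma2e
      }
      fit <- solveBlup(y, K, weights = wts[tIds], lines = fixedLines,
                       sigma2a = s2a, sigma2e = s2e)
      pred <- fit$gebv[vIds]
      data.frame(replicate = r, seed = rseed,
                 accuracy = predictionAccuracy(pred, debv[vIds]),
                 slope = biasSlope(pred, debv[vIds]),
                 slopeRev = biasSlope(pred, debv[vIds],
                                      direction = "predOnObs"),
                 nTrain = length(tIds), nValidation = length(vIds),
                 meanTrainR2 = mean(tr$r2[tr$id %in% tIds]),
                 sigma2a = s2a, sigma2e = s2e, matrixKind = kind)
    })
  }
  rdf <- do.call(rbind, reps)
  okAcc <- rdf$accuracy[!is.na(rdf$accuracy)]
  summary <- list(
    meanAccuracy = if (length(okAcc)) mean(okAcc) else NA_real_,
    sdAccuracy = if (nrow(rdf) > 1 && length(okAcc) > 1) sd(okAcc)
                 else NA_real_,
    meanSlope = mean(rdf$slope, na.rm = TRUE),
    meanSlopeRev = mean(rdf$slopeRev, na.rm = TRUE),
    nUndefined = sum(is.na(rdf$accuracy)))
  methods::new("ScenarioResult", id = spec$id, replicates = rdf,
               summary = summary, matrixKind = rdf$matrixKind[1],
               model = model)
}

# Are two sets of animals connected through shared pedigree ancestry?
linesConnected <- function(ped, idsX, idsY) {
  tab <- pedigreeTable(ped)
  sire <- setNames(tab$sire, tab$id)
  dam <- setNames(tab$dam, tab$id)
  closure <- function(ids) {
    seen <- character(0)
    frontier <- ids
    while (length(frontier)) {
      seen <- union(seen, frontier)
      par <- unique(c(sire[frontier], dam[frontier]))
      frontier <- setdiff(par[!is.na(par)], seen)
    }
    seen
  }
  length(intersect(closure(intersect(idsX, tab$id)),
                   closure(intersect(idsY, tab$id)))) > 0
}

#' Materialize the standard 17-scenario suite
#'
#' Builds the full set of scenario specifications for a two-line + F1 data
#' set, in four groups: within-population (3: each line predicts a held-out
#' subset of itself), multi-population (4: both purebred lines added to the
#' training data, with and without the F1 and with equalized training
#' sizes), across-population (4: one purebred line predicts the other,
#' full and reduced training), and purebred-to-crossbred (6: single and
#' combined purebred training predicting all F1, full and equalized
#' sizes). Replicated scenarios hold out `validationSize` animals per
#' replicate; single-replicate scenarios validate on the entire other
#' population.
#'
#' @param nA,nB,nF1 eligible animal counts per line.
#' @param lines labels of the two purebred lines.
#' @param f1 label of the crossbred line.
#' @param validationSize held-out animals per replicate for within/multi
#'   scenarios.
#' @param nReplicates replicates for the replicated scenarios.
#' @param equalizedSize per-line training size for the equalized scenarios;
#'   default one third of the smaller purebred line. Reduced
#'   single-line trainings use twice this size.
#' @param seed master seed; per-scenario seeds are derived from it.
#' @return named list of [scenarioSpec()] objects (`"s1"` ... `"s17"`).
#' @export
scenarioSuiteSpecs <- function(nA, nB, nF1, lines = c("A", "B"), f1 = "F1",
                               validationSize = 50, nReplicates = 20,
                               equalizedSize = NULL, seed = 1L) {
  A <- lines[1]; B <- lines[2]
  if (is.null(equalizedSize)) equalizedSize <- round(min(nA, nB) / 3)
  s <- equalizedSize
  f1Train <- max(nF1 - validationSize, 3)
  sp <- function(idx, tl, vl, vs, nr, grp)
    scenarioSpec(as.character(idx), tl, vl, vs, nr, group = grp,
                 seed = deriveSeed(seed, idx))
  specs <- list(
    sp(1, setNames(list("all"), A), A, validationSize, nReplicates, "within"),
    sp(2, setNames(list("all"), B), B, validationSize, nReplicates, "within"),
    sp(3, setNames(list("all"), f1), f1, validationSize, nReplicates, "within"),
    sp(4, setNames(list("all", "all"), c(A, B)), A, validationSize,
       nReplicates, "multi"),
    sp(5, setNames(list("all", "all"), c(A, B)), B, validationSize,
       nReplicates, "multi"),
    sp(6, setNames(list("all", "all", "all"), c(A, B, f1)), f1,
       validationSize, nReplicates, "multi"),
    sp(7, setNames(list(f1Train, f1Train, "all"), c(A, B, f1)), f1,
       validationSize, nReplicates, "multi"),
    sp(8, setNames(list("all"), A), B, "all", 1, "across"),
    sp(9, setNames(list(2 * s), A), B, "all", nReplicates, "across"),
    sp(10, setNames(list("all"), B), A, "all", 1, "across"),
    sp(11, setNames(list(2 * s), B), A, "all", nReplicates, "across"),
    sp(12, setNames(list("all", "all"), c(A, B)), f1, "all", 1, "pb2cb"),
    sp(13, setNames(list(s, s), c(A, B)), f1, "all", nReplicates, "pb2cb"),
    sp(14, setNames(list("all"), A), f1, "all", 1, "pb2cb"),
    sp(15, setNames(list(2 * s), A), f1, "all", nReplicates, "pb2cb"),
    sp(16, setNames(list("all"), B), f1, "all", 1, "pb2cb"),
    sp(17, setNames(list(2 * s), B), f1, "all", nReplicates, "pb2cb"))
  names(specs) <- paste0("s", 1:17)
  specs
}

#' Run the full scenario suite
#'
#' Runs every scenario with GBLUP and, where the training and validation
#' populations are related through the pedigree, also with PED-BLUP;
#' pedigree-based prediction is skipped (with the reason recorded) when a
#' training line is unrelated to the validation line, since the pedigree
#' then carries no information across them.
#'
#' @param genotypes,traits,pedigree the aligned, QC'd, deregressed data.
#' @param lines,f1 line labels.
#' @param validationSize,nReplicates,equalizedSize passed to
#'   [scenarioSuiteSpecs()].
#' @param varComponents,sigma2a,sigma2e passed to [runScenario()].
#' @param models which of `"gblup"`, `"pedblup"` to run.
#' @param seed master seed.
#' @return list with `results` (list of [ScenarioResult-class]), `skipped`
#'   (data.frame of skipped model runs with reasons) and `summary` (one row
#'   per scenario x model, shaped like a results table: sizes, mean
#'   training reliability, accuracy, SD, slopes).
#' @export
runScenarioSuite <- function(genotypes, traits, pedigree,
                             lines = c("A", "B"), f1 = "F1",
                             validationSize = 50, nReplicates = 20,
                             equalizedSize = NULL,
                             varComponents = "reml", sigma2a = NULL,
                             sigma2e = NULL,
                             models = c("gblup", "pedblup"), seed = 1L) {
  tr <- traitRecords(traits)
  gid <- animalIds(genotypes)
  elig <- split(tr$id[tr$id %in% gid], tr$line[tr$id %in% gid])
  cnt <- function(l) if (l %in% names(elig)) length(elig[[l]]) else 0L
  specs <- scenarioSuiteSpecs(cnt(lines[1]), cnt(lines[2]), cnt(f1),
                              lines = lines, f1 = f1,
                              validationSize = validationSize,
                              nReplicates = nReplicates,
                              equalizedSize = equalizedSize, seed = seed)
  conn <- list()
  connected <- function(lx, ly) {
    key <- paste(sort(c(lx, ly)), collapse = "|")
    if (is.null(conn[[key]]))
      conn[[key]] <<- if (lx == ly) TRUE else
        linesConnected(pedigree, elig[[lx]], elig[[ly]])
    conn[[key]]
  }
  results <- list()
  skipped <- data.frame(scenario = character(), model = character(),
                        reason = character())
  for (nm in names(specs)) {
    spc <- specs[[nm]]
    for (mdl in models) {
      if (mdl == "pedblup") {
        unrel <- names(spc$trainingLines)[!vapply(
          names(spc$trainingLines), connected, logical(1),
          ly = spc$validationLine)]
        if (length(unrel)) {
          skipped <- rbind(skipped, data.frame(
            scenario = spc$id, model = mdl,
            reason = paste0("training line(s) ",
                            paste(unrel, collapse = ","),
                            " not related to ", spc$validationLine,
                            " according to the pedigree")))
          next
        }
      }
      spcM <- spc
      if (mdl == "pedblup") spcM$matrixKind <- "pedigree"
      results[[paste0(nm, "_", mdl)]] <-
        runScenario(spcM, genotypes, traits, pedigree,
                    varComponents = varComponents, sigma2a = sigma2a,
                    sigma2e = sigma2e, model = mdl)
    }
  }
  list(results = results, skipped = skipped,
       summary = suiteSummary(results, specs))
}

# One row per scenario x model, numeric columns rounded for stable output.
suiteSummary <- function(results, specs) {
  rows <- lapply(results, function(res) {
    s <- res@summary
    data.frame(scenario = res@id,
               group = specs[[paste0("s", res@id)]]$group,
               model = res@model, matrixKind = res@matrixKind,
               nReplicates = nrow(res@replicates),
               nTrain = round(mean(res@replicates$nTrain)),
               nValidation = round(mean(res@replicates$nValidation)),
               meanTrainR2 = round(mean(res@replicates$meanTrainR2), 4),
               accuracy = round(s$meanAccuracy, 4),
               accuracySD = round(s$sdAccuracy, 4),
               slope = round(s$meanSlope, 4),
               slopeRev = round(s$meanSlopeRev, 4),
               nUndefined = s$nUndefined)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(as.integer(out$scenario), out$model), ]
}
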