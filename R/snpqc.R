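# Marker and individual quality control, and single-site imputation.

#' Per-SNP quality statistics
#'
#' Call rate, allele frequency, minor-allele frequency, and the 1-df
#' Hardy-Weinberg goodness-of-fit chi-square `sum((obs - exp)^2 / exp)`
#' over the three genotype classes, computed from non-missing calls pooled
#' across all animals. Monomorphic SNPs get chi-square 0 (they are caught
#' by the MAF filter instead).
#'
#' @param g a [GenotypeData-class] with integer (unimputed) dosages.
#' @return data.frame with one row per SNP: `id`, `chrom`, `callRate`,
#'   `freq`, `maf`, `hweChi2`.
#' @export
snpStats <- function(g) {
  d <- dosages(g)
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
    stop("QC statistics need raw integer dosages")
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0)) stop("SNP with no observed calls: ",
                           colnames(d)[which(nObs == 0)[1]])
  p <- colMeans(d, na.rm = TRUE) / 2
  data.frame(id = colnames(d), chrom = snpInfo(g)$chrom,
             callRate = nObs / nrow(d), freq = p, maf = pmin(p, 1 - p),
             hweChi2 = .hweChi2(d), row.names = NULL)
}

# 1-df goodness-of-fit chi-square per SNP column; NA when no calls.
.hweChi2 <- function(d) {
  nObs <- colSums(!is.na(d))
  n2 <- colSums(d == 2, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n0 <- nObs - n1 - n2
  p <- ifelse(nObs > 0, (2 * n2 + n1) / (2 * nObs), NA_real_)
  q <- 1 - p
  e0 <- nObs * q^2; e1 <- nObs * 2 * p * q; e2 <- nObs * p^2
  ifelse(is.na(p) | p <= 0 | p >= 1, ifelse(is.na(p), NA_real_, 0),
         (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
}

#' Marker quality-control filters
#'
#' Removes a SNP when its call rate is below `callRateMin`, its
#' minor-allele frequency is below `mafMin`, its Hardy-Weinberg chi-square
#' exceeds `hweChi2Max`, or its chromosome is in `excludeChroms` (sex
#' chromosomes and unmapped markers by default). All filters are evaluated
#' on the input, so the operation is idempotent.
#'
#' @param g a [GenotypeData-class].
#' @param callRateMin,mafMin,hweChi2Max filter thresholds.
#' @param excludeChroms chromosome labels to drop.
#' @return list with `genotypes` (filtered) and `report` (a `QCReport`
#'   list: the per-SNP statistics with removal flags, per-filter counts,
#'   and the thresholds used).
#' @export
snpFilters <- function(g, callRateMin = 0.95, mafMin = 0.01,
                       hweChi2Max = 600, excludeChroms = c("X", "Y", "0")) {
  st <- snpStats(g)
  # per-line HWE chi-square kept as a diagnostic: the filter itself pools
  # lines, and the extreme threshold makes Wahlund inflation immaterial
  lin <- lineOf(g)
  if (length(unique(lin)) > 1) {
    d <- dosages(g)
    for (l in unique(lin))
      if (sum(lin == l) >= 2)
        st[[paste0("hweChi2.", l)]] <- .hweChi2(d[lin == l, , drop = FALSE])
  }
  st$failCallRate <- st$callRate < callRateMin
  st$failMaf <- st$maf < mafMin
  st$failHwe <- st$hweChi2 > hweChi2Max
  st$failChrom <- st$chrom %in% excludeChroms | is.na(st$chrom)
  st$removed <- st$failCallRate | st$failMaf | st$failHwe | st$failChrom
  if (all(st$removed))
    stop("all SNPs removed; review the QC thresholds")
  keep <- st$id[!st$removed]
  report <- structure(list(
    scope = "snp",
    snpStats = st,
    nInput = nrow(st), nRemoved = sum(st$removed), nRetained = length(keep),
    counts = c(callRate = sum(st$failCallRate), maf = sum(st$failMaf),
               hwe = sum(st$failHwe), chrom = sum(st$failChrom)),
    thresholds = list(callRateMin = callRateMin, mafMin = mafMin,
                      hweChi2Max = hweChi2Max,
                      excludeChroms = excludeChroms)), class = "QCReport")
  list(genotypes = g[keep, ], report = report)
}

#' Individual missingness filter
#'
#' Removes animals whose fraction of missing genotype calls strictly
#' exceeds `missingMax` (an animal exactly at the threshold is retained).
#' Applied after the SNP filters in the standard pipeline; the order is
#' recorded in the report.
#'
#' @param g a [GenotypeData-class].
#' @param missingMax maximum tolerated missing fraction.
#' @return list with `genotypes` and `report`.
#' @export
individualFilter <- function(g, missingMax = 0.05) {
  d <- dosages(g)
  miss <- rowMeans(is.na(d))
  removed <- miss > missingMax
  if (all(removed)) stop("all animals removed; review missingMax")
  report <- structure(list(
    scope = "animal",
    animalStats = data.frame(id = rownames(d), missingRate = miss,
                             removed = removed, row.names = NULL),
    nInput = nrow(d), nRemoved = sum(removed), nRetained = sum(!removed),
    thresholds = list(missingMax = missingMax)), class = "QCReport")
  list(genotypes = g[, !removed], report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report (", x$scope, "): ", x$nRemoved, " of ", x$nInput,
      " removed, ", x$nRetained, " retained\n", sep = "")
  if (!is.null(x$counts)) {
    cat("  per-filter counts (a record may fail several):\n")
    for (nm in names(x$counts)) cat("   ", nm, ":", x$counts[[nm]], "\n")
  }
  invisible(x)
}

#' Impute remaining missing genotypes
#'
#' Single-site statistical imputation: `mode = "mean"` fills each missing
#' call with the expected dosage `2p` (real-valued); `mode = "draw"`
#' samples a genotype from Hardy-Weinberg proportions at `p`. With
#' `perLine = TRUE` (the default, matching line-structured frequencies) `p`
#' is estimated within the animal's line, falling back to the pooled
#' frequency for a line with no observed calls at that SNP.
#'
#' @param g a QC-filtered [GenotypeData-class].
#' @param mode `"mean"` or `"draw"`.
#' @param perLine estimate frequencies within line.
#' @param seed seed for draw mode.
#' @return a complete [GenotypeData-class] (no missing entries).
#' @export
imputeMissing <- function(g, mode = c("mean", "draw"), perLine = TRUE,
                          seed = NULL) {
  mode <- match.arg(mode)
  d <- dosages(g)
  if (!anyNA(d)) return(g)
  lin <- lineOf(g)
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0))
    stop("cannot impute SNP with all calls missing: ",
         colnames(d)[which(nObs == 0)[1]])
  pooled <- colMeans(d, na.rm = TRUE) / 2
  fillFreq <- matrix(rep(pooled, each = nrow(d)), nrow(d), ncol(d))
  if (perLine && length(unique(lin)) > 1) {
    for (l in unique(lin)) {
      rows <- lin == l
      pl <- colMeans(d[rows, , drop = FALSE], na.rm = TRUE) / 2
      pl[is.nan(pl)] <- pooled[is.nan(pl)]  # line has no calls at this SNP
      fillFreq[rows, ] <- rep(pl, each = sum(rows))
    }
  }
  idx <- which(is.na(d))
  withSeed(seed, {
    d[idx] <- if (mode == "mean") 2 * fillFreq[idx]
              else rbinom(length(idx), 2L, fillFreq[idx])
  })
  out <- g
  SummarizedExperiment::assay(out, "dosage") <- t(d)
  methods::validObject(out)
  out
}

#' Run the standard QC pipeline
#'
#' SNP filters, then the individual missingness filter, then imputation.
#'
#' @param g a [GenotypeData-class].
#' @param callRateMin,mafMin,hweChi2Max,excludeChroms passed to
#'   [snpFilters()].
#' @param missingMax passed to [individualFilter()].
#' @param imputeMode,perLine,seed passed to [imputeMissing()].
#' @return list with `genotypes` (complete, filtered) and `reports` (list
#'   of the SNP and animal QC reports, in application order).
#' @export
runQC <- function(g, callRateMin = 0.95, mafMin = 0.01, hweChi2Max = 600,
                  excludeChroms = c("X", "Y", "0"), missingMax = 0.05,
                  imputeMode = "mean", perLine = TRUE, seed = NULL) {
  s <- snpFilters(g, callRateMin, mafMin, hweChi2Max, excludeChroms)
  a <- individualFilter(s$genotypes, missingMax)
  gg <- imputeMissing(a$genotypes, mode = imputeMode, perLine = perLine,
                      seed = seed)
  list(genotypes = gg, reports = list(snp = s$report, animal = a$report))
}
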