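#' @import methods
#' @useDynLib crossblup, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor var sd rbinom rnorm runif optimize setNames pnorm
#'   complete.cases coef lm
#' @importFrom utils read.table write.table head
NULL

#' SNP dosage data for one or more genetic lines
#'
#' `GenotypeData` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a single assay
#' `"dosage"` holding allele dosages (SNPs in rows, animals in columns).
#' Entries count copies of the alternate (or A1) allele, so raw calls are in
#' \{0, 1, 2\} with `NA` for missing; after mean imputation real-valued
#' dosages in \[0, 2\] are permitted. Row metadata carries the chromosome and
#' position of each SNP; column metadata carries each animal's line label.
#'
#' @section Accessors:
#' [dosages()] returns the animals-by-SNPs dosage matrix (the orientation
#' used for relationship matrices), [animalIds()], [snpIds()], [lineOf()],
#' and [snpInfo()] return the identifiers and metadata.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "dosage"))
    msg <- c(msg, "must carry exactly one assay named 'dosage'")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && (min(bad) < 0 || max(bad) > 2))
      msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "animal ids (colnames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"line" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'line' column")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'pos' columns")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, animals in rows and SNPs in columns, with
#'   rownames (animal ids) and colnames (SNP ids); entries in \[0, 2\] or
#'   `NA` for missing.
#' @param line character vector of line labels, one per animal (recycled if
#'   length 1).
#' @param chrom,pos SNP metadata vectors, one entry per SNP. Defaults label
#'   every SNP chromosome `"1"` with consecutive positions.
#' @return a [GenotypeData-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(c("a1", "a2", "a3"), c("s1", "s2")))
#' g <- GenotypeData(d, line = "A")
#' dosages(g)
#' @export
GenotypeData <- function(dosage, line, chrom = NULL, pos = NULL) {
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage matrix must have animal rownames and SNP colnames")
  storage.mode(dosage) <- "double"
  n_snp <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", n_snp)
  if (is.null(pos)) pos <- seq_len(n_snp)
  line <- rep_len(as.character(line), nrow(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosage)),
    rowData = S4Vectors::DataFrame(chrom = as.character(chrom),
                                   pos = as.integer(pos),
                                   row.names = colnames(dosage)),
    colData = S4Vectors::DataFrame(line = line,
                                   row.names = rownames(dosage)))
  methods::new("GenotypeData", se)
}

#' Pedigree with line labels
#'
#' Holds animal/sire/dam/line records in topological order (every parent
#' precedes its offspring). Unknown parents are `NA`. The constructor
#' re-orders rows as needed and refuses pedigrees in which an animal is its
#' own ancestor.
#'
#' @slot id,sire,dam,line parallel character vectors, one entry per animal.
#' @export
setClass("Pedigree",
         representation(id = "character", sire = "character",
                        dam = "character", line = "character"))

setValidity("Pedigree", function(object) {
  msg <- character()
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@line) != n)
    msg <- c(msg, "id, sire, dam and line must have equal length")
  if (anyDuplicated(object@id))
    msg <- c(msg, paste("duplicated animal id:",
                        object@id[duplicated(object@id)][1L]))
  pos <- seq_len(n)
  names(pos) <- object@id
  for (p in c("sire", "dam")) {
    par <- slot(object, p)
    known <- !is.na(par) & par %in% object@id
    if (any(pos[par[known]] >= pos[which(known)])) {
      msg <- c(msg, "pedigree is not topologically ordered")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree
#'
#' Accepts records in any order; rows are topologically sorted so parents
#' precede offspring. Parents coded `NA`, `""` or `"0"` are treated as
#' unknown. Parents that appear only as sire/dam (never as an animal row)
#' are kept as references without records of their own.
#'
#' @param x data.frame with columns `id`, `sire`, `dam`, `line` (extra
#'   columns ignored).
#' @return a [Pedigree-class] object.
#' @export
Pedigree <- function(x) {
  x <- as.data.frame(x)
  need <- c("id", "sire", "dam", "line")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  id <- as.character(x$id)
  clean <- function(v) {
    v <- as.character(v)
    v[is.na(v) | v == "" | v == "0"] <- NA_character_
    v
  }
  sire <- clean(x$sire); dam <- clean(x$dam)
  ord <- pedigreeTopoSort(id, sire, dam)
  methods::new("Pedigree", id = id[ord], sire = sire[ord], dam = dam[ord],
               line = as.character(x$line)[ord])
}

# Kahn's algorithm over the parent->offspring DAG; errors with the cycle.
pedigreeTopoSort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n); names(idx) <- id
  parents <- function(i) {
    p <- c(sire[i], dam[i])
    idx[p[!is.na(p) & p %in% id]]
  }
  indeg <- vapply(idx, function(i) length(parents(i)), integer(1))
  children <- vector("list", n)
  for (i in idx) for (p in parents(i))
    children[[p]] <- c(children[[p]], i)
  queue <- idx[indeg == 0L]
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    cyc <- id[setdiff(idx, out)]
    stop("pedigree contains a cycle involving: ",
         paste(cyc, collapse = " -> "))
  }
  out
}

#' Per-animal trait records: EBV, reliability, and deregressed proofs
#'
#' A thin S4 container around a per-animal table with columns `id`, `line`,
#' `ebv`, `r2` (reliability in (0, 1]) and, once deregression has been run,
#' `debv` and `weight`. The `debv` and `weight` columns are present or
#' absent together.
#'
#' @slot records the data.frame described above.
#' @export
setClass("TraitRecords", representation(records = "data.frame"))

setValidity("TraitRecords", function(object) {
  r <- object@records
  msg <- character()
  need <- c("id", "line", "ebv", "r2")
  if (!all(need %in% names(r)))
    return(paste("records need columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$id))
    msg <- c(msg, "duplicated animal id in trait records")
  if (any(!is.finite(r$r2)) || any(r$r2 <= 0) || any(r$r2 > 1))
    msg <- c(msg, "reliabilities r2 must lie in (0, 1]")
  if (xor("debv" %in% names(r), "weight" %in% names(r)))
    msg <- c(msg, "debv and weight must be present together")
  if ("weight" %in% names(r) && any(r$weight <= 0, na.rm = TRUE))
    msg <- c(msg, "weights must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct TraitRecords
#' @param x data.frame with columns `id`, `line`, `ebv`, `r2` and optionally
#'   `debv` and `weight`.
#' @return a [TraitRecords-class] object.
#' @export
TraitRecords <- function(x) {
  x <- as.data.frame(x)
  x$id <- as.character(x$id)
  x$line <- as.character(x$line)
  methods::new("TraitRecords", records = x)
}

#' Additive relationship matrix (pedigree or genomic)
#'
#' Symmetric animals-by-animals matrix of additive relationships: the
#' pedigree numerator relationship matrix A, a VanRaden genomic matrix G, or
#' an across-population G in which each animal's genotypes are centered with
#' its own line's allele frequencies.
#'
#' @slot values symmetric numeric matrix with animal-id dimnames.
#' @slot kind one of `"pedigree"`, `"genomic_within"`, `"genomic_across"`.
#' @slot centerFreqs for genomic kinds, the per-SNP allele frequencies used
#'   for centering (a vector, or a per-line list for the across kind).
#' @slot scaling list of scaling constants (e.g. the 2*sum(p*q) denominator).
#' @export
setClass("RelationshipMatrix",
         representation(values = "matrix", kind = "character",
                        centerFreqs = "list", scaling = "list"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else if (max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v))))
    msg <- c(msg, "matrix must be symmetric")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "dimnames must carry matching animal ids")
  if (!object@kind %in% c("pedigree", "genomic_within", "genomic_across"))
    msg <- c(msg, "unknown relationship kind")
  if (object@kind == "pedigree" && nrow(v) && min(diag(v)) < 1 - 1e-8)
    msg <- c(msg, "pedigree diagonal must be >= 1")
  if (length(msg)) msg else TRUE
})

RelationshipMatrix <- function(values, kind, centerFreqs = list(),
                               scaling = list()) {
  values <- (values + t(values)) / 2  # tidy float asymmetry
  methods::new("RelationshipMatrix", values = values, kind = kind,
               centerFreqs = centerFreqs, scaling = scaling)
}

#' Parameters of the synthetic multi-line population generator
#'
#' Bundles every knob of the simulator: founder panel size, drift, the two
#' purebred lines and optional F1 cross, trait architecture (heritability,
#' purebred-crossbred genetic correlation) and the seed. See
#' [populationSpec()] for defaults and units.
#'
#' @export
setClass("PopulationSpec",
         representation(nFounders = "integer", nSnps = "integer",
                        nQtl = "integer", founderMafRange = "numeric",
                        driftGenerations = "integer", effectiveSize = "integer",
                        lines = "character", nPerLine = "integer",
                        nF1 = "integer", pedGenerations = "integer",
                        gapGenerations = "integer",
                        parityRange = "integer",
                        lineMeans = "numeric", h2 = "numeric",
                        rhoPbCb = "numeric", missingRate = "numeric",
                        seed = "integer"))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@nQtl > object@nSnps) msg <- c(msg, "nQtl must be <= nSnps")
  r <- object@founderMafRange
  if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 0.5)
    msg <- c(msg, "founderMafRange must be an interval within [0, 0.5]")
  if (object@h2 < 0 || object@h2 > 1) msg <- c(msg, "h2 must be in [0, 1]")
  if (abs(object@rhoPbCb) > 1) msg <- c(msg, "|rhoPbCb| must be <= 1")
  if (object@effectiveSize < 2) msg <- c(msg, "effectiveSize must be >= 2")
  if (object@driftGenerations < 0) msg <- c(msg, "driftGenerations must be >= 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(object@lines) < 2) msg <- c(msg, "need at least two purebred lines")
  pr <- object@parityRange
  if (length(pr) != 2 || pr[1] < 1 || pr[1] > pr[2])
    msg <- c(msg, "parityRange must be an integer interval with min >= 1")
  if (length(msg)) msg else TRUE
})

#' Specify a synthetic two-line + F1 population
#'
#' Defaults describe a desk-scale breeding structure: two purebred lines of
#' 1,200 genotyped sows each plus 290 F1 crossbreds, genotyped at 5,000 SNPs
#' of which 500 are causal, with the lines diverged by 30 generations of
#' drift at effective size 100.
#'
#' @param nFounders founder haplotype pool size per line.
#' @param nSnps,nQtl number of SNPs and of causal loci among them.
#' @param founderMafRange interval in \[0, 0.5\] for founder minor-allele
#'   frequencies.
#' @param driftGenerations,effectiveSize Wright-Fisher drift applied to each
#'   line's allele frequencies before the pedigreed generations.
#' @param lines labels of the two purebred lines.
#' @param nPerLine genotyped animals per purebred line.
#' @param nF1 genotyped F1 crossbred animals (0 for none).
#' @param pedGenerations pedigreed generations within each line (>= 1); the
#'   last generation carries the genotyped animals.
#' @param gapGenerations ungenotyped generations separating the F1's purebred
#'   parents from the genotyped purebred animals (the crossbreds need not be
#'   offspring of the genotyped nucleus animals).
#' @param parityRange integer interval; each phenotyped sow contributes a
#'   number of own (parity) records drawn uniformly from this range, which
#'   enter the pseudo-EBV evaluation as a weighted record mean. Repeated
#'   records are what push reliabilities into the range seen in sow data
#'   and make each EBV own-information dominated.
#' @param lineMeans per-line trait means, trait units; names must cover
#'   `lines` and `"F1"` when `nF1 > 0`.
#' @param h2 narrow-sense heritability of the simulated trait.
#' @param rhoPbCb genetic correlation between purebred and crossbred
#'   expression of the trait, in \[-1, 1\].
#' @param missingRate fraction of genotype calls set missing at random.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return a [PopulationSpec-class] object.
#' @export
populationSpec <- function(nFounders = 400L, nSnps = 5000L, nQtl = 500L,
                           founderMafRange = c(0.05, 0.5),
                           driftGenerations = 30L, effectiveSize = 100L,
                           lines = c("A", "B"), nPerLine = 1200L, nF1 = 290L,
                           pedGenerations = 2L, gapGenerations = 1L,
                           parityRange = c(2L, 6L),
                           lineMeans = NULL, h2 = 0.3, rhoPbCb = 0.9,
                           missingRate = 0.01, seed = 1L) {
  if (is.null(lineMeans)) {
    lineMeans <- setNames(seq_along(lines) - 1, lines)
    if (nF1 > 0) lineMeans <- c(lineMeans, F1 = mean(lineMeans))
  }
  methods::new("PopulationSpec",
               nFounders = as.integer(nFounders), nSnps = as.integer(nSnps),
               nQtl = as.integer(nQtl),
               founderMafRange = as.numeric(founderMafRange),
               driftGenerations = as.integer(driftGenerations),
               effectiveSize = as.integer(effectiveSize),
               lines = as.character(lines), nPerLine = as.integer(nPerLine),
               nF1 = as.integer(nF1),
               pedGenerations = as.integer(pedGenerations),
               gapGenerations = as.integer(gapGenerations),
               parityRange = as.integer(parityRange),
               lineMeans = lineMeans, h2 = as.numeric(h2),
               rhoPbCb = as.numeric(rhoPbCb),
               missingRate = as.numeric(missingRate), seed = as.integer(seed))
}

#' Result of one replicated prediction scenario
#'
#' @slot id scenario identifier.
#' @slot replicates data.frame with one row per replicate: `accuracy`
#'   (Pearson correlation of predictions with validation DEBVs), `slope`
#'   (OLS slope of DEBV on prediction), `slopeRev` (the reverse regression),
#'   training and validation sizes, and the replicate seed.
#' @slot summary list with `meanAccuracy`, `sdAccuracy` (NA when a single
#'   replicate), `meanSlope`, `nUndefined` (replicates with zero-variance
#'   predictions, excluded from the means).
#' @slot matrixKind,model relationship matrix kind and model label used.
#' @export
setClass("ScenarioResult",
         representation(id = "character", replicates = "data.frame",
                        summary = "list", matrixKind = "character",
                        model = "character"))

setValidity("ScenarioResult", function(object) {
  r <- object@replicates
  if (nrow(r) && any(abs(r$accuracy) > 1 + 1e-12, na.rm = TRUE))
    return("|accuracy| must be <= 1")
  TRUE
})
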