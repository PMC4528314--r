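# Pedigree and genomic relationship matrices.

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds Wright's numerator relationship matrix A by the tabular method:
#' processing animals in topological order, `a_ij = 0.5 * (a_{j,sire(i)} +
#' a_{j,dam(i)})` for previously processed j, and `a_ii = 1 +
#' 0.5 * a_{sire(i),dam(i)}`; unknown parents contribute zero. Parents that
#' appear only as sire/dam are included as founders, so relationships
#' through ungenotyped ancestors are fully propagated even when a subset is
#' requested.
#'
#' @param ped a [Pedigree-class].
#' @param subset animal ids for which to return the (sub)matrix; default all
#'   pedigree animals.
#' @return a [RelationshipMatrix-class] of kind `"pedigree"`.
#' @export
buildA <- function(ped, subset = NULL) {
  stopifnot(is(ped, "Pedigree"))
  tab <- pedigreeTable(ped)
  extra <- setdiff(c(tab$sire, tab$dam), c(tab$id, NA))
  if (length(extra))
    tab <- rbind(data.frame(id = extra, sire = NA_character_,
                            dam = NA_character_, line = NA_character_), tab)
  n <- nrow(tab)
  idx <- seq_len(n); names(idx) <- tab$id
  si <- ifelse(is.na(tab$sire), 0L, idx[tab$sire])
  di <- ifelse(is.na(tab$dam), 0L, idx[tab$dam])
  A <- .tabularA(as.integer(si), as.integer(di))
  dimnames(A) <- list(tab$id, tab$id)
  if (!is.null(subset)) {
    missing <- setdiff(subset, tab$id)
    if (length(missing))
      stop("animals absent from pedigree: ",
           paste(head(missing, 5), collapse = ", "))
    A <- A[subset, subset, drop = FALSE]
  }
  RelationshipMatrix(A, kind = "pedigree")
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i * q_i))` where Z is the dosage matrix centered
#' by twice the allele frequency at each SNP. With observed frequencies the
#' centered columns sum to zero across animals, so every row of G sums to
#' zero; G is invariant to flipping any SNP's allele coding.
#'
#' @param g a complete (no missing dosages) [GenotypeData-class], or a plain
#'   animals x SNPs matrix with dimnames.
#' @param freqs per-SNP allele frequencies used for centering and scaling;
#'   default observed frequencies of the analyzed animals.
#' @return a [RelationshipMatrix-class] of kind `"genomic_within"`.
#' @export
buildG <- function(g, freqs = NULL) {
  M <- if (is(g, "GenotypeData")) dosages(g) else g
  if (anyNA(M)) stop("missing dosages; run imputeMissing() first")
  if (is.null(freqs)) freqs <- colMeans(M) / 2
  den <- 2 * sum(freqs * (1 - freqs))
  if (den <= 0)
    stop("2*sum(p*q) is zero: all SNPs monomorphic at the centering frequencies")
  Z <- sweep(M, 2L, 2 * freqs)
  G <- tcrossprod(Z) / den
  RelationshipMatrix(G, kind = "genomic_within",
                     centerFreqs = list(freqs = freqs),
                     scaling = list(denominator = den))
}

#' Across-population genomic relationship matrix
#'
#' Accounts for allele-frequency differences between lines by centering
#' each animal's genotypes with its own line's frequencies. With
#' `denominator = "blockwise"` (default) the (line j, line k) block is
#' scaled by `sqrt(d_j * d_k)` where `d_l = 2 * sum(p_l * q_l)`, so each
#' within-line diagonal block equals that line's own VanRaden matrix
#' exactly. `denominator = "pooled"` divides everything by a single
#' `2 * sum(p * q)` from the pooled observed frequencies.
#'
#' F1 frequencies default to the observed F1 frequencies when at least 30
#' F1 animals are present, otherwise to the mean of the parental line
#' frequencies (requires `parentLines`).
#'
#' @param g complete [GenotypeData-class] with at least two lines (or a
#'   matrix plus `lines`).
#' @param lines named line label per animal (taken from `g` when omitted).
#' @param denominator `"blockwise"` or `"pooled"`.
#' @param freqs optional named list of per-line frequency vectors; required
#'   for lines with fewer than 2 animals.
#' @param parentLines for an `"F1"` line, the two purebred parent lines
#'   used for the frequency fallback; default the two non-F1 lines.
#' @return a [RelationshipMatrix-class] of kind `"genomic_across"` (or
#'   `"genomic_within"` when only one line is present, in which case the
#'   result equals [buildG()]).
#' @export
buildGAcross <- function(g, lines = NULL,
                         denominator = c("blockwise", "pooled"),
                         freqs = NULL, parentLines = NULL) {
  denominator <- match.arg(denominator)
  M <- if (is(g, "GenotypeData")) dosages(g) else g
  if (is.null(lines) && is(g, "GenotypeData")) lines <- lineOf(g)
  lines <- lines[rownames(M)]
  if (anyNA(M)) stop("missing dosages; run imputeMissing() first")
  lv <- unique(lines)
  if (length(lv) < 2) return(buildG(M))
  if (is.null(parentLines)) parentLines <- setdiff(lv, "F1")
  lineFreq <- list()
  for (l in lv) {
    if (!is.null(freqs) && !is.null(freqs[[l]])) {
      lineFreq[[l]] <- freqs[[l]]
    } else {
      rows <- lines == l
      if (l == "F1" && sum(rows) < 30 && length(parentLines) == 2) {
        pf <- lapply(parentLines, function(pl) {
          if (!is.null(freqs) && !is.null(freqs[[pl]])) freqs[[pl]]
          else colMeans(M[lines == pl, , drop = FALSE]) / 2
        })
        lineFreq[[l]] <- (pf[[1]] + pf[[2]]) / 2
      } else if (sum(rows) < 2) {
        stop("line '", l, "' has fewer than 2 animals; supply its frequencies")
      } else {
        lineFreq[[l]] <- colMeans(M[rows, , drop = FALSE]) / 2
      }
    }
  }
  Z <- M
  for (l in lv)
    Z[lines == l, ] <- sweep(M[lines == l, , drop = FALSE], 2L,
                             2 * lineFreq[[l]])
  if (denominator == "blockwise") {
    d <- vapply(lineFreq, function(p) 2 * sum(p * (1 - p)), numeric(1))
    if (any(d <= 0)) stop("a line has zero heterozygosity 2*sum(p*q)")
    sc <- sqrt(d[lines])
    G <- tcrossprod(Z / sc)
    scaling <- list(denominator = "blockwise", d = d)
  } else {
    pbar <- colMeans(M) / 2
    den <- 2 * sum(pbar * (1 - pbar))
    if (den <= 0) stop("pooled 2*sum(p*q) is zero")
    G <- tcrossprod(Z) / den
    scaling <- list(denominator = "pooled", d = den)
  }
  RelationshipMatrix(G, kind = "genomic_across",
                     centerFreqs = lineFreq, scaling = scaling)
}

#' Split a training set by mean relatedness to a validation set
#'
#' Scores each training animal by its mean relationship to all validation
#' animals and returns the most- and least-related halves (or another
#' fraction). Ties are broken by the order in which training ids are
#' supplied, so the split is deterministic.
#'
#' @param K a [RelationshipMatrix-class] (or plain symmetric matrix with id
#'   dimnames) covering both sets.
#' @param trainingIds,validationIds disjoint animal id vectors present in K.
#' @param fraction fraction (by count, floor) assigned to the most-related
#'   half.
#' @return list with `mostRelated`, `leastRelated` (id vectors) and
#'   `scores` (named mean-relationship scores).
#' @export
meanRelatednessSplit <- function(K, trainingIds, validationIds,
                                 fraction = 0.5) {
  V <- if (is(K, "RelationshipMatrix")) as.matrix(K) else K
  if (length(intersect(trainingIds, validationIds)))
    stop("training and validation sets overlap")
  missing <- setdiff(c(trainingIds, validationIds), rownames(V))
  if (length(missing))
    stop("ids absent from relationship matrix: ",
         paste(head(missing, 5), collapse = ", "))
  scores <- rowMeans(V[trainingIds, validationIds, drop = FALSE])
  ord <- order(-scores, seq_along(scores))
  nMost <- floor(fraction * length(trainingIds) + 1e-9)
  list(mostRelated = trainingIds[ord[seq_len(nMost)]],
       leastRelated = trainingIds[ord[-seq_len(nMost)]],
       scores = scores)
}
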