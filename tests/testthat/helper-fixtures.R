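# Shared fixtures and independent oracles.

# Independent oracle for additive relationships: recursive coancestry
# (Malecot kinship), memoized; a different algorithm from the tabular method.
kinshipOracle <- function(ped) {
  tab <- pedigreeTable(ped)
  idx <- seq_len(nrow(tab)); names(idx) <- tab$id
  sire <- tab$sire; dam <- tab$dam
  memo <- new.env()
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    si <- if (is.na(sire[j]) || !sire[j] %in% tab$id) 0 else idx[[sire[j]]]
    di <- if (is.na(dam[j]) || !dam[j] %in% tab$id) 0 else idx[[dam[j]]]
    v <- if (i == j) 0.5 * (1 + f(si, di)) else 0.5 * (f(i, si) + f(i, di))
    memo[[key]] <- v
    v
  }
  n <- nrow(tab)
  A <- matrix(0, n, n, dimnames = list(tab$id, tab$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# Random valid pedigree of up to nMax animals (parents always earlier).
randomPedigree <- function(n, seed) {
  withr::with_seed(seed, {
    id <- paste0("a", seq_len(n))
    sire <- dam <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (i >= 3 && runif(1) < 0.7) {
        pars <- sample(id[seq_len(i - 1)], 2)
        sire[i] <- pars[1]; dam[i] <- pars[2]
      }
    }
    Pedigree(data.frame(id = id, sire = sire, dam = dam, line = "A"))
  })
}

# Joint-covariance conditional-mean oracle for the animal model: GLS fixed
# effects, then E[g | y] through the covariance; PEV from the conditional
# variance. Completely independent of the mixed-model-equations route.
glsBlupOracle <- function(y, K, w, lines, sigma2a, sigma2e) {
  ids <- rownames(K)
  rec <- names(y)
  X <- crossblup:::fixedDesign(rec, if (is.null(lines)) NULL else lines[rec])
  V <- K[rec, rec] * sigma2a + diag(sigma2e / w, length(rec))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - drop(X %*% b)
  gh <- sigma2a * K[, rec] %*% Vi %*% resid
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  pev <- diag(sigma2a * K - sigma2a^2 * K[, rec] %*% P %*% K[rec, ])
  list(beta = drop(b), gHat = setNames(drop(gh), ids),
       pev = setNames(pev, ids))
}

# Random small BLUP fixture on a genomic relationship matrix.
randomBlupFixture <- function(seed, q = 10, n = 8) {
  withr::with_seed(seed, {
    M <- matrix(rbinom(q * 300, 2, runif(300, .1, .9)), q, 300,
                dimnames = list(paste0("an", seq_len(q)), NULL))
    K <- as.matrix(buildG(M)) + diag(0.05, q, q)
    dimnames(K) <- list(rownames(M), rownames(M))
    rec <- rownames(M)[seq_len(n)]
    list(K = K,
         y = setNames(rnorm(n), rec),
         w = setNames(runif(n, 0.5, 3), rec),
         lines = setNames(rep(c("A", "B"), length.out = q), rownames(M)),
         s2a = runif(1, 0.2, 0.8), s2e = runif(1, 0.2, 0.8))
  })
}

# Small population specs used across tests (sizes chosen for runtime).
smallSpec <- function(seed = 1, ...) {
  args <- list(nFounders = 150, nSnps = 700, nQtl = 120, nPerLine = 150,
               nF1 = 80, driftGenerations = 20, effectiveSize = 60,
               pedGenerations = 2, h2 = 0.3, rhoPbCb = 0.8, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(populationSpec, args)
}

# The standard analysis chain up to scenario-ready data.
prepScenarioData <- function(spec) {
  sim <- simulatePopulation(spec)
  qc <- runQC(sim$genotypes, imputeMode = "mean")
  dr <- deregress(sim$traits, sim$pedigree, h2 = spec@h2,
                  mode = "parent_adjusted")
  dr <- addBackLineEffect(dr, sim$evaluation$lineEffects[
    unique(traitRecords(dr)$line)])
  al <- alignDatasets(qc$genotypes, sim$pedigree, dr)
  list(sim = sim, geno = al$genotypes, traits = al$traits,
       ped = sim$pedigree)
}
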