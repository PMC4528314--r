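test_that("tabular A reproduces textbook cases", {
  ped <- Pedigree(data.frame(
    id = c("p1", "p2", "s1", "s2", "x"),
    sire = c(NA, NA, "p1", "p1", "s1"),
    dam = c(NA, NA, "p2", "p2", "s2"), line = "A"))
  A <- as.matrix(buildA(ped))
  expect_equal(A["s1", "p1"], 0.5)          # offspring-parent
  expect_equal(A["s1", "s2"], 0.5)          # full sibs
  expect_equal(A["x", "x"], 1.25)           # offspring of full sibs, F = 1/4
  expect_equal(diag(A)[c("p1", "p2")], c(p1 = 1, p2 = 1))
  # subset keeps full ancestral recursion
  As <- as.matrix(buildA(ped, subset = c("x", "s1")))
  expect_equal(As["x", "s1"], A["x", "s1"])
  expect_error(buildA(ped, subset = "nope"), "absent")
})

test_that("tabular A equals the recursive-kinship oracle on random pedigrees", {
  for (seed in 1:30) {
    ped <- randomPedigree(sample(4:8, 1), seed)
    expect_equal(as.matrix(buildA(ped)), kinshipOracle(ped),
                 tolerance = 1e-12)
  }
})

test_that("VanRaden G matches the hand-computed example and its identities", {
  d <- matrix(c(0, 2, 2, 0), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  G <- as.matrix(buildG(d))
  expect_equal(G, matrix(c(2, -2, -2, 2), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))))

  set.seed(3)
  M <- matrix(rbinom(40 * 500, 2, runif(500, .1, .9)), 40, 500,
              dimnames = list(paste0("a", 1:40), paste0("s", 1:500)))
  G2 <- as.matrix(buildG(M))
  # observed-frequency centering: every row sums to zero
  expect_lt(max(abs(rowSums(G2))), 1e-10)
  # allele-flip invariance
  flip <- sample(500, 120)
  Mf <- M; Mf[, flip] <- 2 - Mf[, flip]
  expect_lt(max(abs(as.matrix(buildG(Mf)) - G2)), 1e-10)
  # duplicated animals give identical rows and equal diagonals
  Md <- rbind(M, dup = M[1, ])
  rownames(Md) <- c(rownames(M), "dup")
  Gd <- as.matrix(buildG(Md))
  expect_equal(unname(Gd["dup", ]), unname(Gd["a1", ]))
  expect_equal(Gd["dup", "dup"], Gd["a1", "a1"])
  # monomorphic panel is an error
  expect_error(buildG(matrix(2, 3, 4, dimnames = list(letters[1:3],
                                                      LETTERS[1:4]))),
               "monomorphic")
})

test_that("mean G diagonal approaches 1 under Hardy-Weinberg sampling", {
  set.seed(8)
  p <- runif(4000, 0.1, 0.5)
  M <- matrix(rbinom(300 * 4000, 2, rep(p, each = 300)), 300, 4000,
              dimnames = list(paste0("a", 1:300), NULL))
  colnames(M) <- paste0("s", seq_len(ncol(M)))
  expect_lt(abs(mean(diag(as.matrix(buildG(M)))) - 1), 0.03)
})

test_that("across-population G keeps per-line VanRaden blocks and symmetry", {
  set.seed(4)
  pA <- runif(400, .1, .9)
  pB <- pmin(.95, pmax(.05, pA + runif(400, -.3, .3)))
  dA <- matrix(rbinom(30 * 400, 2, rep(pA, each = 30)), 30, 400)
  dB <- matrix(rbinom(30 * 400, 2, rep(pB, each = 30)), 30, 400)
  M <- rbind(dA, dB)
  dimnames(M) <- list(c(paste0("A", 1:30), paste0("B", 1:30)),
                      paste0("s", 1:400))
  lines <- setNames(rep(c("A", "B"), each = 30), rownames(M))
  Gx <- buildGAcross(M, lines = lines)
  expect_equal(kinshipKind(Gx), "genomic_across")
  V <- as.matrix(Gx)
  # blockwise scaling: each within-line block is that line's own VanRaden G
  expect_equal(V[1:30, 1:30], as.matrix(buildG(M[1:30, ])),
               tolerance = 1e-12)
  expect_equal(V[31:60, 31:60], as.matrix(buildG(M[31:60, ])),
               tolerance = 1e-12)
  expect_lt(max(abs(V - t(V))), 1e-12)
  expect_true(all(is.finite(V)))

  # single line degenerates to plain VanRaden
  G1 <- buildGAcross(M[1:30, ], lines = lines[1:30])
  expect_equal(as.matrix(G1), as.matrix(buildG(M[1:30, ])))

  # pooled denominator recorded in metadata
  Gp <- buildGAcross(M, lines = lines, denominator = "pooled")
  expect_equal(Gp@scaling$denominator, "pooled")

  # small F1 group: frequencies fall back to the parental-line mean
  M2 <- rbind(M, F1a = rbinom(400, 2, (pA + pB) / 2),
              F1b = rbinom(400, 2, (pA + pB) / 2))
  lines2 <- c(lines, F1a = "F1", F1b = "F1")
  Gf <- buildGAcross(M2, lines = lines2)
  expect_equal(Gf@centerFreqs$F1,
               (Gf@centerFreqs$A + Gf@centerFreqs$B) / 2)
  expect_true(all(is.finite(as.matrix(Gf))))

  # a 1-animal line without supplied frequencies is an error
  expect_error(buildGAcross(M2[c(1:30, 61), ],
                            lines = lines2[c(1:30, 61)]),
               "fewer than 2")
})

test_that("A and G agree entrywise on simulated pedigreed data", {
  spec <- smallSpec(seed = 6, nSnps = 2000, nQtl = 200, nPerLine = 120,
                    nF1 = 60, missingRate = 0)
  sim <- simulatePopulation(spec, pseudoEbv = FALSE)
  ids <- animalIds(sim$genotypes)
  G <- as.matrix(buildGAcross(sim$genotypes))
  A <- as.matrix(buildA(sim$pedigree, subset = ids))
  expect_gt(cor(c(A), c(G)), 0.8)
})

test_that("mean-relatedness split ranks by mean kinship with stable ties", {
  K <- diag(4); dimnames(K) <- list(letters[1:4], letters[1:4])
  K["a", "d"] <- K["d", "a"] <- 0.5
  sp <- meanRelatednessSplit(K, trainingIds = c("a", "b"),
                             validationIds = "d")
  expect_identical(sp$mostRelated, "a")
  expect_identical(sp$leastRelated, "b")

  # ten animals with scores 0.1..1.0 -> top five by score
  n <- 11
  K2 <- diag(n)
  K2[1:10, 11] <- K2[11, 1:10] <- seq(0.1, 1, 0.1)
  ids <- c(paste0("t", 1:10), "v")
  dimnames(K2) <- list(ids, ids)
  sp2 <- meanRelatednessSplit(K2, paste0("t", 1:10), "v")
  expect_setequal(sp2$mostRelated, paste0("t", 6:10))

  # all-equal scores: the first half in supplied order is "most"
  K3 <- diag(5); K3[1:4, 5] <- K3[5, 1:4] <- 0.25
  dimnames(K3) <- list(c(paste0("t", 1:4), "v"), c(paste0("t", 1:4), "v"))
  sp3 <- meanRelatednessSplit(K3, paste0("t", 1:4), "v")
  expect_identical(sp3$mostRelated, c("t1", "t2"))

  expect_error(meanRelatednessSplit(K3, c("t1", "v"), "v"), "overlap")
})
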