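test_that("solveBlup matches the joint-covariance conditional-mean oracle", {
  for (seed in 1:5) {
    fx <- randomBlupFixture(seed)
    fit <- solveBlup(fx$y, fx$K, weights = fx$w, lines = fx$lines,
                     sigma2a = fx$s2a, sigma2e = fx$s2e)
    o <- glsBlupOracle(fx$y, fx$K, fx$w, fx$lines, fx$s2a, fx$s2e)
    expect_equal(unname(fit$beta), unname(o$beta), tolerance = 1e-8)
    expect_equal(fit$gHat, o$gHat, tolerance = 1e-8)
    expect_equal(fit$pev, o$pev, tolerance = 1e-8)
    # PEV never exceeds the additive variance; reliabilities in [0, 1]
    expect_true(all(fit$pev <= fx$s2a * max(diag(fx$K)) + 1e-10))
    expect_true(all(fit$reliability >= -1e-10 & fit$reliability <= 1 + 1e-10))
  }
})

test_that("BLUP limits behave: shrinkage to the mean and isolated animals", {
  fx <- randomBlupFixture(99)
  # variance ratio -> 0: all g -> 0, mu -> weighted mean
  fit0 <- solveBlup(fx$y, fx$K, weights = fx$w, sigma2a = 1e-10,
                    sigma2e = 1)
  expect_lt(max(abs(fit0$gHat)), 1e-6)
  expect_equal(unname(fit0$beta[1]), weighted.mean(fx$y, fx$w),
               tolerance = 1e-6)

  # an animal unrelated to every record gets gHat 0, gebv = fixed part
  K <- diag(5); dimnames(K) <- list(letters[1:5], letters[1:5])
  K[1:4, 1:4] <- 0.4; diag(K) <- 1
  y <- setNames(rnorm(4), letters[1:4])
  fit <- solveBlup(y, K, sigma2a = .5, sigma2e = .5)
  expect_equal(unname(fit$gHat["e"]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$gebv["e"]), unname(fit$beta[1]))

  expect_error(solveBlup(setNames(1:3, c("a", "b", "zz")), K,
                         sigma2a = .5, sigma2e = .5), "present in K")
})

test_that("weighted residuals sum to zero with observed-frequency G", {
  set.seed(12)
  M <- matrix(rbinom(30 * 800, 2, runif(800, .2, .8)), 30, 800,
              dimnames = list(paste0("a", 1:30), NULL))
  colnames(M) <- paste0("s", seq_len(800))
  G <- buildG(M)
  y <- setNames(rnorm(30), rownames(M))
  w <- setNames(runif(30, .5, 2), rownames(M))
  fit <- solveBlup(y, G, weights = w, sigma2a = .4, sigma2e = .6)
  resid <- y - fit$gebv[names(y)]
  expect_lt(abs(sum(w * resid)), 1e-6)
})

test_that("EM-REML has a non-decreasing restricted log-likelihood", {
  set.seed(2)
  n <- 80
  M <- matrix(rbinom(n * 300, 2, .3), n, 300,
              dimnames = list(paste0("a", 1:n), NULL))
  colnames(M) <- paste0("s", 1:300)
  K <- buildG(M)
  y <- setNames(rnorm(n), paste0("a", 1:n))
  f <- remlUnivariate(y, K, method = "em", maxIter = 5000)
  expect_true(all(diff(f$loglikTrace) > -1e-7))
  # the AI route lands on the same optimum
  fa <- remlUnivariate(y, K, method = "ai")
  expect_equal(fa$h2, f$h2, tolerance = 5e-3)
})

test_that("univariate REML recovers h2 and shrinks toward truth with n", {
  est <- function(n, h2, seed) {
    withr::with_seed(seed, {
      m <- 1200
      p <- runif(m, .1, .5)
      M <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
                  dimnames = list(paste0("a", 1:n), NULL))
      colnames(M) <- paste0("s", 1:m)
      G <- as.matrix(buildG(M))
      L <- chol(G + diag(1e-6, n))
      g <- drop(crossprod(L, rnorm(n))) * sqrt(h2)
      y <- setNames(g + rnorm(n, 0, sqrt(1 - h2)), rownames(M))
      remlUnivariate(y, G)$h2
    })
  }
  err200 <- mean(abs(sapply(1:4, function(s) est(200, 0.4, s)) - 0.4))
  err1000 <- mean(abs(sapply(1:4, function(s) est(1000, 0.4, s)) - 0.4))
  expect_lt(err1000, err200 + 0.02)
  expect_lt(err1000, 0.08)

  # pure-noise null: h2 estimated near zero
  null <- mean(sapply(1:4, function(s) {
    withr::with_seed(100 + s, {
      M <- matrix(rbinom(300 * 800, 2, .4), 300, 800,
                  dimnames = list(paste0("a", 1:300), NULL))
      colnames(M) <- paste0("s", 1:800)
      y <- setNames(rnorm(300), rownames(M))
      remlUnivariate(y, buildG(M))$h2
    })
  }))
  expect_lt(null, 0.1)
})

test_that("GBLUP and PED-BLUP coincide when G numerically equals A", {
  ped <- randomPedigree(8, 5)
  A <- buildA(ped)
  y <- setNames(rnorm(6), animalIds(ped)[1:6])
  fA <- solveBlup(y, A, sigma2a = .4, sigma2e = .6)
  fG <- solveBlup(y, as.matrix(A), sigma2a = .4, sigma2e = .6)
  expect_equal(fA$gHat, fG$gHat, tolerance = 1e-12)
  expect_equal(fA$pev, fG$pev, tolerance = 1e-12)
})

test_that("bivariate REML with a diagonal constraint matches the univariate fits", {
  set.seed(31)
  ped <- rbind(data.frame(id = paste0("p", 1:30), sire = NA, dam = NA,
                          line = "A"),
               data.frame(id = paste0("x", 1:120),
                          sire = sample(paste0("p", 1:10), 120, TRUE),
                          dam = sample(paste0("p", 11:30), 120, TRUE),
                          line = "A"),
               data.frame(id = paste0("f", 1:120),
                          sire = sample(paste0("p", 1:10), 120, TRUE),
                          dam = sample(paste0("p", 11:30), 120, TRUE),
                          line = "F1"))
  P <- Pedigree(ped)
  A <- as.matrix(buildA(P, subset = c(paste0("x", 1:120), paste0("f", 1:120))))
  L <- chol(A + diag(1e-8, 240))
  g1 <- sqrt(.4) * drop(crossprod(L, rnorm(240)))
  g2 <- sqrt(.4) * drop(crossprod(L, rnorm(240)))
  names(g1) <- names(g2) <- rownames(A)
  yPb <- setNames(g1[paste0("x", 1:120)] + rnorm(120, 0, sqrt(.6)),
                  paste0("x", 1:120))
  yCb <- setNames(g2[paste0("f", 1:120)] + rnorm(120, 0, sqrt(.6)),
                  paste0("f", 1:120))
  bi <- remlBivariate(yPb, yCb, A, constrainDiagonal = TRUE)
  u1 <- remlUnivariate(yPb, A)
  u2 <- remlUnivariate(yCb, A)
  expect_equal(bi$G0[1, 1], u1$sigma2a, tolerance = 0.02)
  expect_equal(bi$G0[2, 2], u2$sigma2a, tolerance = 0.02)
  expect_equal(bi$G0[1, 2], 0)
})

test_that("genetically identical animals relabeled as a second trait give rg ~ 1", {
  set.seed(13)
  nb <- 60
  base <- rbind(data.frame(id = paste0("p", 1:20), sire = NA, dam = NA,
                           line = "A"),
                data.frame(id = paste0("x", 1:nb),
                           sire = sample(paste0("p", 1:8), nb, TRUE),
                           dam = sample(paste0("p", 9:20), nb, TRUE),
                           line = "A"))
  A0 <- as.matrix(buildA(Pedigree(base), subset = paste0("x", 1:nb)))
  # clone block: "cb" animals are genetic copies of the "x" animals
  ids <- c(paste0("x", 1:nb), paste0("c", 1:nb))
  K <- rbind(cbind(A0, A0), cbind(A0, A0))
  dimnames(K) <- list(ids, ids)
  L <- chol(A0 + diag(1e-8, nb))
  g <- sqrt(.5) * drop(crossprod(L, rnorm(nb)))
  y1 <- setNames(g + rnorm(nb, 0, sqrt(.5)), paste0("x", 1:nb))
  y2 <- setNames(g + rnorm(nb, 0, sqrt(.5)), paste0("c", 1:nb))
  f <- remlBivariate(y1, y2, K)
  expect_gte(f$rg, 0.95)
})

test_that("bivariate REML rejects malformed inputs", {
  y <- setNames(rnorm(40), paste0("a", 1:40))
  K <- diag(40); dimnames(K) <- list(names(y), names(y))
  expect_error(remlBivariate(y[1:35], y[30:40], K), "cannot carry both")
  expect_error(remlBivariate(y[1:10], y[11:40], K), "at least 30")
})
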