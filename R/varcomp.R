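# BLUP solving and REML variance-component estimation.
#
# Model: y = X b + Z g + e with var(g) = K * sigma2a and heterogeneous
# residual variance var(e_i) = sigma2e / w_i. K is a relationship matrix
# (pedigree A or genomic G) over a superset of the recorded animals;
# animals without records are predicted purely through their relationships.

#' Solve Henderson's mixed-model equations
#'
#' Fits the animal model above for given variance components by dense
#' factorization of the mixed-model equations. The fixed design is an
#' intercept plus reference-coded line indicators when more than one line is
#' present among the records. Prediction-error variances come from the
#' inverse coefficient matrix; before inverting, K receives an eigenvalue
#' floor (epsilon = 1e-6 * mean diagonal) if its smallest eigenvalue falls
#' below 1e-8, and the perturbation is recorded.
#'
#' @param y named response vector (e.g. DEBVs); names must be animal ids
#'   present in `K`.
#' @param K a [RelationshipMatrix-class] or plain symmetric matrix over all
#'   animals to fit/predict.
#' @param weights named positive residual weights for the records (residual
#'   variance of record i is `sigma2e / weights[i]`); default 1.
#' @param lines named line label per animal in `K`; used for the fixed line
#'   effect (records) and the fixed part of predictions. NULL fits an
#'   intercept only.
#' @param sigma2a,sigma2e additive and residual variance components.
#' @return list of class `BlupFit`: `beta` (fixed effects), `gHat`, `pev`,
#'   `reliability` (`1 - pev / (sigma2a * K_ii)`, so an animal with no
#'   information scores 0 even when inbred) and `gebv` (fixed part + gHat)
#'   for every animal in `K`, plus solver metadata.
#' @export
solveBlup <- function(y, K, weights = NULL, lines = NULL,
                      sigma2a, sigma2e) {
  V <- if (is(K, "RelationshipMatrix")) as.matrix(K) else K
  ids <- rownames(V)
  rec <- names(y)
  if (is.null(rec) || !all(rec %in% ids))
    stop("all response names must be animal ids present in K")
  if (anyDuplicated(rec)) stop("duplicated record ids")
  if (is.null(weights)) weights <- setNames(rep(1, length(y)), rec)
  if (!all(rec %in% names(weights)) && length(weights) != length(y))
    stop("weight vector does not match the response vector")
  w <- if (is.null(names(weights))) setNames(weights, rec) else weights[rec]
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive finite")
  q <- length(ids)
  X <- fixedDesign(rec, if (is.null(lines)) NULL else lines[rec])
  p <- ncol(X)
  ri <- match(rec, ids)

  inv <- stabilizedInverse(V)
  lambda <- sigma2e / sigma2a
  C <- matrix(0, p + q, p + q)
  C[seq_len(p), seq_len(p)] <- crossprod(X, X * w)
  XtWZ <- matrix(0, p, q)
  XtWZ[, ri] <- t(X * w)
  C[seq_len(p), p + seq_len(q)] <- XtWZ
  C[p + seq_len(q), seq_len(p)] <- t(XtWZ)
  C22 <- inv$inverse * lambda
  diag(C22)[ri] <- diag(C22)[ri] + w
  C[p + seq_len(q), p + seq_len(q)] <- C22
  rhs <- c(crossprod(X, w * y),
           { zz <- numeric(q); zz[ri] <- w * y; zz })
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular mixed-model coefficient matrix: ", conditionMessage(e)))
  sol <- drop(Cinv %*% rhs)
  beta <- setNames(sol[seq_len(p)], colnames(X))
  gHat <- setNames(sol[p + seq_len(q)], ids)
  pev <- setNames(diag(Cinv)[p + seq_len(q)] * sigma2e, ids)
  fixedPart <- rep(beta[1], q)
  if (!is.null(lines) && p > 1) {
    for (nm in colnames(X)[-1]) {
      l <- sub("^line", "", nm)
      fixedPart[lines[ids] == l] <- fixedPart[lines[ids] == l] + beta[nm]
    }
  }
  structure(list(beta = beta, gHat = gHat, pev = pev,
                 reliability = 1 - pev / (sigma2a * diag(V)),
                 gebv = setNames(fixedPart + gHat, ids),
                 sigma2a = sigma2a, sigma2e = sigma2e, lambda = lambda,
                 weights = w, epsilon = inv$epsilon,
                 kind = if (is(K, "RelationshipMatrix")) kinshipKind(K)
                        else "matrix"),
            class = "BlupFit")
}

#' @export
print.BlupFit <- function(x, ...) {
  cat("BlupFit:", length(x$gHat), "animals,",
      sum(names(x$gHat) %in% names(x$weights)), "records; lambda =",
      signif(x$lambda, 4), "\n")
  invisible(x)
}

# Rotated-space REML machinery ------------------------------------------

# Projections in the eigenbasis where V = diag(lam*s2a + s2e).
.rotProject <- function(Vi, Xt, v) {
  a <- Vi * v
  a - (Vi * Xt) %*% solve(crossprod(Xt, Vi * Xt), crossprod(Xt, a))
}

.rotLoglik <- function(Vi, Xt, yt, Py) {
  XtViX <- crossprod(Xt, Vi * Xt)
  -0.5 * (sum(-log(Vi)) + determinant(XtViX, logarithm = TRUE)$modulus +
            sum(yt * Py))
}

#' Univariate REML for the animal model
#'
#' Estimates (sigma2a, sigma2e) by restricted maximum likelihood after an
#' eigen-rotation of the (weight-standardized) relationship matrix, which
#' makes every iteration O(n). `method = "em"` runs pure EM-REML, whose
#' restricted log-likelihood is non-decreasing at every step;
#' `method = "ai"` (default) warms up with EM and then switches to
#' average-information updates with step-halving back-off to EM, which
#' converges in far fewer iterations. Convergence when the relative
#' parameter change drops below `tol` or the log-likelihood change below
#' `llTol`.
#'
#' @param y named response vector.
#' @param K relationship matrix covering the records.
#' @param weights named positive residual weights (default 1).
#' @param lines optional named line labels for a fixed line effect.
#' @param method `"ai"` or `"em"`.
#' @param maxIter,tol,llTol iteration controls.
#' @return list of class `VarianceComponents`: `sigma2a`, `sigma2e`, `h2`,
#'   standard errors from the average-information matrix, `loglik`,
#'   `loglikTrace`, `nIter`, `converged`.
#' @export
remlUnivariate <- function(y, K, weights = NULL, lines = NULL,
                           method = c("ai", "em"), maxIter = 500L,
                           tol = 1e-8, llTol = 1e-10) {
  method <- match.arg(method)
  V <- if (is(K, "RelationshipMatrix")) as.matrix(K) else K
  ids <- names(y)
  if (is.null(ids) || !all(ids %in% rownames(V)))
    stop("all response names must appear in K")
  n <- length(y)
  if (n < 3) stop("need at least 3 records")
  Kr <- V[ids, ids]
  w <- if (is.null(weights)) rep(1, n) else
    as.numeric(if (is.null(names(weights))) weights else weights[ids])
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  sw <- sqrt(w)
  X <- fixedDesign(ids, if (is.null(lines)) NULL else lines[ids])
  Ks <- Kr * tcrossprod(sw)
  ee <- eigen(Ks, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  yt <- drop(crossprod(ee$vectors, sw * y))
  Xt <- crossprod(ee$vectors, X * sw)
  qa <- sum(lam > 1e-10 * max(lam, 1e-300))

  vy <- var(y)
  th <- c(a = 0.5 * vy, e = 0.5 * vy)
  floorv <- 1e-10 * vy
  llTrace <- numeric(0)
  llOld <- -Inf
  converged <- FALSE
  emPhase <- if (method == "em") maxIter else 20L

  emStep <- function(th, Py, trPA, trP, yPAPy, yPPy) {
    a <- th["a"] + (th["a"]^2 / qa) * (yPAPy - trPA)
    e <- th["e"] + (th["e"]^2 / n) * (yPPy - trP)
    c(a = max(unname(a), floorv), e = max(unname(e), floorv))
  }

  quantities <- function(th) {
    Vi <- 1 / (lam * th["a"] + th["e"])
    Py <- drop(.rotProject(Vi, Xt, yt))
    MS <- (Xt * Vi) %*% solve(crossprod(Xt, Vi * Xt))
    dP <- Vi - rowSums(MS * (Xt * Vi))
    list(Vi = Vi, Py = Py, trPA = sum(lam * dP), trP = sum(dP),
         yPAPy = sum(lam * Py^2), yPPy = sum(Py^2),
         ll = .rotLoglik(Vi, Xt, yt, Py))
  }

  it <- 0L
  qt <- quantities(th)
  while (it < maxIter) {
    it <- it + 1L
    llTrace <- c(llTrace, qt$ll)
    thNew <- NULL
    if (it > emPhase) {
      # average-information step with step-halving
      sc <- c(-0.5 * (qt$trPA - qt$yPAPy), -0.5 * (qt$trP - qt$yPPy))
      Vi <- qt$Vi
      a <- lam * qt$Py
      Pa <- drop(.rotProject(Vi, Xt, a))
      Pb <- drop(.rotProject(Vi, Xt, qt$Py))
      AI <- 0.5 * matrix(c(sum(a * Pa), sum(a * Pb),
                           sum(a * Pb), sum(qt$Py * Pb)), 2, 2)
      step <- tryCatch(solve(AI, sc), error = function(e) NULL)
      if (!is.null(step)) {
        alpha <- 1
        for (h in 1:10) {
          cand <- pmax(th + alpha * step, floorv)
          qc <- quantities(setNames(cand, c("a", "e")))
          if (is.finite(qc$ll) && qc$ll >= qt$ll - 1e-10) {
            thNew <- setNames(cand, c("a", "e")); qtNew <- qc
            break
          }
          alpha <- alpha / 2
        }
      }
    }
    if (is.null(thNew)) {
      thNew <- emStep(th, qt$Py, qt$trPA, qt$trP, qt$yPAPy, qt$yPPy)
      qtNew <- quantities(thNew)
    }
    rel <- max(abs(thNew - th) / (abs(th) + floorv))
    dll <- qtNew$ll - qt$ll
    th <- thNew; qt <- qtNew
    if (rel < tol || (it > 1L && abs(dll) < llTol)) {
      converged <- TRUE
      break
    }
  }
  llTrace <- c(llTrace, qt$ll)

  # SEs from the average information at the optimum
  Vi <- qt$Vi
  a <- lam * qt$Py
  Pa <- drop(.rotProject(Vi, Xt, a))
  Pb <- drop(.rotProject(Vi, Xt, qt$Py))
  AI <- 0.5 * matrix(c(sum(a * Pa), sum(a * Pb),
                       sum(a * Pb), sum(qt$Py * Pb)), 2, 2)
  covTh <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, 2, 2))
  s <- sum(th)
  gradH2 <- c(th["e"], -th["a"]) / s^2
  seH2 <- sqrt(max(0, drop(t(gradH2) %*% covTh %*% gradH2)))
  structure(list(sigma2a = unname(th["a"]), sigma2e = unname(th["e"]),
                 h2 = unname(th["a"] / s),
                 seSigma2a = sqrt(max(0, covTh[1, 1])),
                 seSigma2e = sqrt(max(0, covTh[2, 2])), seH2 = seH2,
                 loglik = unname(qt$ll), loglikTrace = llTrace,
                 nIter = it, converged = converged, method = method),
            class = "VarianceComponents")
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat(sprintf("REML: sigma2a = %.4g, sigma2e = %.4g, h2 = %.3f (SE %.3f); %s%d iterations\n",
              x$sigma2a, x$sigma2e, x$h2, x$seH2,
              if (x$converged) "converged in " else "NOT converged after ",
              x$nIter))
  invisible(x)
}

#' Bivariate REML for the purebred-crossbred genetic correlation
#'
#' Treats purebred and crossbred performance as two traits linked through a
#' pedigree relationship matrix: `var([g1; g2]) = G0 (x) A` with G0 the 2x2
#' genetic covariance matrix. Because every animal carries at most one of
#' the two traits, the residual covariance is not estimable and is fixed at
#' zero. Maximization is by average-information REML with step-halving and
#' an EM fallback for the variance parameters; if an update leaves G0
#' outside the positive-semidefinite cone the covariance is bent back to
#' 0.999 of its bound (flagged in the result).
#'
#' @param yPb,yCb named response vectors for purebred and crossbred animals
#'   (disjoint id sets, both present in `A`); each needs >= 30 records.
#' @param A a pedigree [RelationshipMatrix-class] (or plain matrix) linking
#'   the two sets.
#' @param linesPb optional named line labels for a fixed line effect among
#'   the purebred records.
#' @param constrainDiagonal fix the genetic covariance at zero (the model
#'   then decouples into the two univariate analyses).
#' @param maxIter,tol iteration controls.
#' @return list of class `BivariateComponents`: `G0`, `residuals` (the two
#'   residual variances), `rg` (genetic correlation), `seRg` (delta-method
#'   standard error from the information matrix), `loglik`, `nIter`,
#'   `converged`, `bent`.
#' @export
remlBivariate <- function(yPb, yCb, A, linesPb = NULL,
                          constrainDiagonal = FALSE, maxIter = 100L,
                          tol = 1e-6) {
  V <- if (is(A, "RelationshipMatrix")) as.matrix(A) else A
  i1 <- names(yPb); i2 <- names(yCb)
  if (length(intersect(i1, i2)))
    stop("an animal cannot carry both a purebred and a crossbred record")
  if (length(i1) < 30 || length(i2) < 30)
    stop("each trait needs at least 30 records")
  if (!all(c(i1, i2) %in% rownames(V)))
    stop("relationship matrix does not cover both record sets")
  A11 <- V[i1, i1]; A12 <- V[i1, i2]; A22 <- V[i2, i2]
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  y <- c(yPb, yCb)
  X1 <- fixedDesign(i1, if (is.null(linesPb)) NULL else linesPb[i1])
  X <- rbind(cbind(X1, 0), cbind(matrix(0, n2, ncol(X1)), 1))
  colnames(X) <- c(colnames(X1), "muCb")
  j1 <- seq_len(n1); j2 <- n1 + seq_len(n2)

  u1 <- remlUnivariate(yPb, V, lines = linesPb, method = "ai")
  u2 <- remlUnivariate(yCb, V, method = "ai")
  th <- c(g11 = u1$sigma2a, g12 = 0, g22 = u2$sigma2a,
          e1 = u1$sigma2e, e2 = u2$sigma2e)
  if (!constrainDiagonal)
    th["g12"] <- 0.1 * sqrt(th["g11"] * th["g22"])
  free <- if (constrainDiagonal) c(1L, 3L, 4L, 5L) else 1:5
  floorv <- 1e-10 * var(y)
  bent <- FALSE

  buildV <- function(th) {
    Vm <- matrix(0, n, n)
    Vm[j1, j1] <- th["g11"] * A11
    Vm[j2, j2] <- th["g22"] * A22
    Vm[j1, j2] <- th["g12"] * A12
    Vm[j2, j1] <- th["g12"] * t(A12)
    diag(Vm)[j1] <- diag(Vm)[j1] + th["e1"]
    diag(Vm)[j2] <- diag(Vm)[j2] + th["e2"]
    Vm
  }
  bend <- function(th) {
    bound <- sqrt(th["g11"] * th["g22"])
    if (abs(th["g12"]) > 0.999 * bound) {
      th["g12"] <- sign(th["g12"]) * 0.999 * bound
      bent <<- TRUE
    }
    th
  }
  quantities <- function(th) {
    Vm <- buildV(th)
    ch <- tryCatch(chol(Vm), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    S <- solve(crossprod(X, ViX))
    P <- Vi - ViX %*% tcrossprod(S, ViX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(crossprod(X, ViX),
                                logarithm = TRUE)$modulus + sum(y * Py))
    Wm <- cbind(g11 = c(A11 %*% Py[j1], rep(0, n2)),
                g12 = c(A12 %*% Py[j2], crossprod(A12, Py[j1])),
                g22 = c(rep(0, n1), A22 %*% Py[j2]),
                e1 = c(Py[j1], rep(0, n2)),
                e2 = c(rep(0, n1), Py[j2]))
    tr <- c(g11 = sum(P[j1, j1] * A11), g12 = 2 * sum(P[j1, j2] * A12),
            g22 = sum(P[j2, j2] * A22), e1 = sum(diag(P)[j1]),
            e2 = sum(diag(P)[j2]))
    yPBPy <- drop(crossprod(Wm, Py))
    PW <- P %*% Wm
    AI <- 0.5 * crossprod(Wm, PW)
    list(ll = drop(ll), score = -0.5 * (tr - yPBPy), AI = (AI + t(AI)) / 2,
         tr = tr, yPBPy = yPBPy)
  }

  th <- bend(th)
  qt <- quantities(th)
  if (is.null(qt)) stop("initial covariance matrix not positive definite")
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    step <- tryCatch(solve(qt$AI[free, free], qt$score[free]),
                     error = function(e) NULL)
    thNew <- NULL
    if (!is.null(step)) {
      alpha <- 1
      for (h in 1:12) {
        cand <- th
        cand[free] <- th[free] + alpha * step
        cand[c("g11", "g22", "e1", "e2")] <-
          pmax(cand[c("g11", "g22", "e1", "e2")], floorv)
        cand <- bend(cand)
        qc <- quantities(cand)
        if (!is.null(qc) && is.finite(qc$ll) && qc$ll >= qt$ll - 1e-8) {
          thNew <- cand; qtNew <- qc
          break
        }
        alpha <- alpha / 2
      }
    }
    if (is.null(thNew)) {
      # EM fallback on the variance parameters (covariance held)
      cand <- th
      for (k in c("g11", "g22", "e1", "e2")) {
        qk <- switch(k, g11 = n1, g22 = n2, e1 = n1, e2 = n2)
        cand[k] <- max(th[k] + (th[k]^2 / qk) * (qt$yPBPy[k] - qt$tr[k]),
                       floorv)
      }
      cand <- bend(cand)
      qc <- quantities(cand)
      if (is.null(qc)) break
      thNew <- cand; qtNew <- qc
    }
    rel <- max(abs(thNew - th) / (abs(th) + floorv))
    dll <- abs(qtNew$ll - qt$ll)
    th <- thNew; qt <- qtNew
    if (rel < tol || dll < 1e-8) {
      converged <- TRUE
      break
    }
  }

  G0 <- matrix(c(th["g11"], th["g12"], th["g12"], th["g22"]), 2, 2,
               dimnames = list(c("pb", "cb"), c("pb", "cb")))
  rg <- unname(th["g12"] / sqrt(th["g11"] * th["g22"]))
  covTh <- tryCatch(solve(qt$AI), error = function(e)
    matrix(NA_real_, 5, 5))
  grad <- c(-rg / (2 * th["g11"]), 1 / sqrt(th["g11"] * th["g22"]),
            -rg / (2 * th["g22"]), 0, 0)
  seRg <- sqrt(max(0, drop(t(grad) %*% covTh %*% grad)))
  structure(list(G0 = G0, residuals = c(e1 = unname(th["e1"]),
                                        e2 = unname(th["e2"])),
                 rg = rg, seRg = seRg, loglik = qt$ll, nIter = it,
                 converged = converged, bent = bent),
            class = "BivariateComponents")
}

#' @export
print.BivariateComponents <- function(x, ...) {
  cat(sprintf("Bivariate REML: rg = %.3f (SE %.3f); G0 diag = (%.4g, %.4g)%s\n",
              x$rg, x$seRg, x$G0[1, 1], x$G0[2, 2],
              if (x$bent) " [bent]" else ""))
  invisible(x)
}

#' Purebred-crossbred genetic correlation from a simulated population
#'
#' Convenience wrapper reproducing the bivariate analysis on a
#' [simulatePopulation()] result: crossbred records are the F1 phenotypes,
#' purebred records are the phenotypes of the F1's purebred parents topped
#' up (in pedigree order, deterministically) with other phenotyped purebred
#' animals to at most `maxPbRecords`, and the two are linked through the
#' pedigree relationship matrix. Parent records carry most of the
#' cross-trait information, since every F1 then has both parents recorded.
#'
#' @param sim a `SimulatedPopulation`.
#' @param maxPbRecords cap on purebred records (controls the dense-REML
#'   problem size).
#' @param ... passed to [remlBivariate()].
#' @return a `BivariateComponents` (see [remlBivariate()]).
#' @export
pbcbGeneticCorrelation <- function(sim, maxPbRecords = 1000, ...) {
  ph <- sim$phenotypes
  ptab <- pedigreeTable(sim$pedigree)
  lin <- lineOf(sim$pedigree)
  f1 <- ptab$id[ptab$line == "F1"]
  f1 <- f1[f1 %in% names(ph)]
  if (!length(f1)) stop("simulation has no phenotyped F1 animals")
  parents <- unique(c(ptab$sire[ptab$line == "F1"],
                      ptab$dam[ptab$line == "F1"]))
  parents <- parents[!is.na(parents) & parents %in% names(ph)]
  others <- setdiff(names(ph)[lin[names(ph)] != "F1"], parents)
  pb <- c(parents, head(others, max(0, maxPbRecords - length(parents))))
  A <- buildA(sim$pedigree, subset = c(pb, f1))
  remlBivariate(ph[pb], ph[f1], A, linesPb = lin, ...)
}
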