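# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs code as-is.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic child seed: distinct streams per (base, index), kept below
# 2^31 so it is always a valid integer seed.
deriveSeed <- function(base, index) {
  as.integer((as.numeric(base) * 69069 + 104729 * as.numeric(index)) %%
               2147483629)
}

# Symmetric inverse with an eigenvalue floor: when the smallest eigenvalue
# falls below `tol`, eps = 1e-6 * mean(diag) is added to every eigenvalue
# before inverting. Returns the inverse plus the perturbation applied.
stabilizedInverse <- function(K, tol = 1e-8) {
  ee <- eigen(K, symmetric = TRUE)
  eps <- 0
  d <- ee$values
  if (min(d) < tol) {
    eps <- 1e-6 * mean(diag(K))
    d <- d + eps
    if (min(d) <= 0) d <- pmax(d, eps)
  }
  inv <- ee$vectors %*% (t(ee$vectors) / d)
  list(inverse = (inv + t(inv)) / 2, epsilon = eps,
       minEigenvalue = min(ee$values))
}

# Reference-coded fixed-effect design: intercept plus indicators for every
# line after the first (alphabetical). `lines` may be NULL (intercept only).
fixedDesign <- function(ids, lines = NULL) {
  n <- length(ids)
  X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  if (!is.null(lines) && length(unique(lines)) > 1) {
    lv <- sort(unique(as.character(lines)))
    for (l in lv[-1]) {
      X <- cbind(X, as.numeric(lines == l))
      colnames(X)[ncol(X)] <- paste0("line", l)
    }
  }
  X
}
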