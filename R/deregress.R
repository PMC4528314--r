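# Deregression of EBVs into pseudo-phenotypes (DEBV) with reliability
# weights, following the two-effect (parent average + own information)
# mixed-model decomposition.

#' Residual weight for a deregressed proof
#'
#' `w = (1 - h2) / ((c + (1 - r2) / r2) * h2)`, where `c` is the fraction of
#' genetic variance not captured by the markers. The residual variance used
#' for record i in the prediction model is `sigma2e / w_i`, so records with
#' higher reliability carry more weight; w is monotone increasing in r2.
#'
#' @param r2 reliability (or vector) in (0, 1).
#' @param h2 heritability in (0, 1).
#' @param c fraction of genetic variance not captured by markers (>= 0).
#' @return positive weight(s).
#' @export
debvWeights <- function(r2, h2, c = 0) {
  stopifnot(h2 > 0, h2 < 1, c >= 0)
  if (any(r2 <= 0)) stop("reliability must be positive")
  if (any(r2 >= 1) && c == 0)
    stop("r2 = 1 with c = 0 gives an infinite weight; cap reliabilities ",
         "(e.g. at 0.99) before weighting")
  (1 - h2) / ((c + (1 - r2) / r2) * h2)
}

#' Deregress EBVs into pseudo-phenotypes
#'
#' `mode = "simple"` divides each EBV by its reliability (`debv = ebv/r2`),
#' undoing the shrinkage of the evaluation but not the parent-average
#' contribution. `mode = "parent_adjusted"` (default when a pedigree is
#' supplied) removes the parent-average information: for each animal with
#' both parents in the trait table, the two-unknown information system in
#' (parent average, own record) implied by `lambda = (1 - h2)/h2` is solved
#' so that feeding the solved pseudo-record back through the two-effect
#' mixed-model equations reproduces the input EBV and reliability exactly;
#' the DEBV is the own-information pseudo-record and the reported
#' reliability becomes the own-information reliability
#' `zzI / (zzI + lambda)`. Animals with missing parents, reliability not
#' exceeding their parent-average reliability, or non-positive solved
#' information fall back to simple mode (counted in the `"nFallback"`
#' attribute).
#'
#' Weights are computed by [debvWeights()] on the output reliability, with
#' reliabilities capped at 0.99 so weights stay finite.
#'
#' @param traits a [TraitRecords-class] with `ebv` and `r2`.
#' @param ped optional [Pedigree-class]; required for parent-adjusted mode.
#' @param h2 heritability used for deregression, in (0, 1).
#' @param c passed to [debvWeights()].
#' @param mode `"parent_adjusted"` or `"simple"`.
#' @return a new [TraitRecords-class] whose records gain `debv`, `weight`,
#'   `mode` and (parent-adjusted rows) the solved information `zzPa`, `zzI`
#'   and parent average `pa`; `r2` holds the output reliability and
#'   `r2Input` the original one.
#' @export
deregress <- function(traits, ped = NULL, h2, c = 0,
                      mode = c("parent_adjusted", "simple")) {
  mode <- match.arg(mode)
  stopifnot(is(traits, "TraitRecords"), h2 > 0, h2 < 1)
  r <- traitRecords(traits)
  lam <- (1 - h2) / h2
  n <- nrow(r)
  out <- r
  out$r2Input <- r$r2
  out$debv <- r$ebv / r$r2
  out$mode <- "simple"
  out$pa <- NA_real_; out$zzPa <- NA_real_; out$zzI <- NA_real_
  nFallback <- 0L
  if (mode == "parent_adjusted") {
    if (is.null(ped)) stop("parent-adjusted deregression needs a pedigree")
    tab <- pedigreeTable(ped)
    sire <- setNames(tab$sire, tab$id)[r$id]
    dam <- setNames(tab$dam, tab$id)[r$id]
    ebvOf <- setNames(r$ebv, r$id)
    r2Of <- setNames(r$r2, r$id)
    for (i in seq_len(n)) {
      s <- sire[i]; d <- dam[i]
      if (is.na(s) || is.na(d) || !s %in% r$id || !d %in% r$id) {
        nFallback <- nFallback + 1L
        next
      }
      pa <- (ebvOf[s] + ebvOf[d]) / 2
      r2pa <- (r2Of[s] + r2Of[d]) / 4
      r2i <- r$r2[i]
      if (r2i >= 1 - 1e-12 || r2i <= r2pa) {
        nFallback <- nFallback + 1L
        next
      }
      alpha <- 1 / (0.5 - r2pa)
      delta <- (0.5 - r2pa) / (1 - r2i)
      zzPa <- lam * (0.5 * alpha - 4) + 0.5 * lam * sqrt(alpha^2 + 16 / delta)
      zzI <- delta * zzPa + 2 * lam * (2 * delta - 1)
      if (!is.finite(zzI) || zzI <= 0) {
        nFallback <- nFallback + 1L
        next
      }
      yi <- -2 * lam * pa + (zzI + 2 * lam) * r$ebv[i]
      out$debv[i] <- yi / zzI
      out$r2[i] <- zzI / (zzI + lam)
      out$mode[i] <- "parent_adjusted"
      out$pa[i] <- pa; out$zzPa[i] <- zzPa; out$zzI[i] <- zzI
    }
  }
  r2w <- pmin(out$r2, 0.99)
  out$weight <- debvWeights(r2w, h2, c)
  res <- TraitRecords(out)
  attr(res, "h2") <- h2
  attr(res, "lambda") <- lam
  attr(res, "c") <- c
  attr(res, "nFallback") <- nFallback
  res
}

#' Re-solve the two-effect equations from deregressed records
#'
#' The inverse operation of parent-adjusted [deregress()]: rebuilds each
#' animal's two-effect mixed-model equations from the solved information
#' (`zzPa`, `zzI`), the parent average and the pseudo-record, solves them,
#' and returns the implied EBV and reliability. Used to verify that
#' deregression is self-inverse; rows deregressed in simple mode return
#' `debv * r2`.
#'
#' @param dr a [TraitRecords-class] produced by [deregress()].
#' @return data.frame with columns `id`, `ebv`, `r2` as implied by the
#'   equations.
#' @export
deregressRoundTrip <- function(dr) {
  r <- traitRecords(dr)
  lam <- attr(dr, "lambda")
  if (is.null(lam)) stop("not a deregressed TraitRecords")
  ebv <- numeric(nrow(r)); r2 <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    if (r$mode[i] == "parent_adjusted") {
      M <- matrix(c(r$zzPa[i] + 4 * lam, -2 * lam,
                    -2 * lam, r$zzI[i] + 2 * lam), 2, 2)
      # animal row of M %*% c(pa, ebv) = c(yPa*, zzI * debv):
      #   -2*lam*pa + (zzI + 2*lam)*ebv = zzI * debv
      ebv[i] <- (r$zzI[i] * r$debv[i] + 2 * lam * r$pa[i]) /
        (r$zzI[i] + 2 * lam)
      Cinv <- solve(M)
      r2[i] <- 1 - lam * Cinv[2, 2]
    } else {
      ebv[i] <- r$debv[i] * r$r2Input[i]
      r2[i] <- r$r2Input[i]
    }
  }
  data.frame(id = r$id, ebv = ebv, r2 = r2)
}

#' Add estimated line effects back onto (deregressed) breeding values
#'
#' In multi-population runs the fixed line effect removed during the
#' evaluation is added back so that mean differences between lines remain
#' in the response, and the prediction model then re-fits a line fixed
#' effect. Increments `ebv` and, when present, `debv` by the animal's line
#' effect; a `lineEffectAdded` column records the amount so the operation
#' can be undone by applying the negated effects.
#'
#' @param traits a [TraitRecords-class].
#' @param lineEffects named numeric vector, one entry per line present.
#' @return the adjusted [TraitRecords-class].
#' @export
addBackLineEffect <- function(traits, lineEffects) {
  r <- traitRecords(traits)
  unknown <- setdiff(unique(r$line), names(lineEffects))
  if (length(unknown))
    stop("no line effect supplied for line(s): ",
         paste(unknown, collapse = ", "))
  eff <- lineEffects[r$line]
  r$ebv <- r$ebv + eff
  if ("debv" %in% names(r)) r$debv <- r$debv + eff
  r$lineEffectAdded <- if ("lineEffectAdded" %in% names(r))
    r$lineEffectAdded + eff else eff
  res <- TraitRecords(r)
  for (a in c("h2", "lambda", "c", "nFallback"))
    attr(res, a) <- attr(traits, a)
  res
}
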