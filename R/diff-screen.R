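#' @importFrom stats t.test var
NULL

#' Differential-screen configuration
#'
#' @param q false discovery rate level in (0, 1); default 0.05, the level
#'   used throughout the screens.
#' @param logData test on log10-transformed values (default `TRUE`).
#' @param pseudo pseudo-count added before the log transform so zero
#'   proportions stay finite (default 1e-3 percentage points).
#' @return a list of class `"FdrConfig"`.
#' @export
fdrConfig <- function(q = 0.05, logData = TRUE, pseudo = 1e-3) {
  stopifnot(length(q) == 1L, q > 0, q < 1, pseudo >= 0)
  structure(list(q = q, logData = logData, pseudo = pseudo),
            class = "FdrConfig")
}

#' Two-sided pooled-variance Student t test
#'
#' Unpaired two-sample Student t test (pooled variance) on raw or
#' log10-transformed values; Welch's unequal-variance form is available
#' behind a flag. When the pooled variance is zero the statistic is
#' undefined and p is reported as 1 with a warning.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param logData if `TRUE`, test log10(value + pseudo).
#' @param pseudo pseudo-count used with `logData` (default 1e-3).
#' @param welch use Welch's t instead of the pooled form.
#' @return list with elements `t`, `df`, `p`.
#' @export
twoSampleT <- function(groupA, groupB, logData = FALSE, pseudo = 1e-3,
                       welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (logData) {
    groupA <- groupA + pseudo
    groupB <- groupB + pseudo
    if (any(groupA <= 0) || any(groupB <= 0))
      stop("log transform requires positive values after pseudo addition")
    groupA <- log10(groupA)
    groupB <- log10(groupB)
  }
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (mean(groupA) != mean(groupB))
      warning("zero pooled variance with unequal means: p reported as 1")
    return(list(t = 0, df = length(groupA) + length(groupB) - 2L, p = 1))
  }
  tt <- t.test(groupA, groupB, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Two-stage adaptive linear step-up FDR adjustment
#'
#' The two-stage linear step-up procedure of Benjamini, Krieger and
#' Yekutieli: stage one runs the linear step-up (Benjamini-Hochberg) test
#' at the deflated level q' = q/(1+q) and counts its rejections r1; unless
#' r1 is 0 (nothing discovered) or m (everything discovered), the number of
#' true nulls is estimated as m0 = m - r1 and stage two re-runs the step-up
#' at the inflated level q'·m/m0.
#'
#' Adjusted values are the step-up-min form
#' `min(1, min_{j >= i} p_(j)·(1+q)·m0/j)` (with m0 = m in the degenerate
#' stages), chosen so that thresholding `adjusted <= q` reproduces the
#' two-stage rejection set exactly.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q nominal FDR level (default 0.05).
#' @return list with `p_adj` (adjusted values, input order), `discovery`
#'   (logical flags), `m0_hat` (estimated null count, m - r1), and `r1`
#'   (stage-one rejections).
#' @examples
#' bkyAdjust(c(0.001, 0.008, 0.4, 0.9))
#' @export
bkyAdjust <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("need at least one p-value")
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(length(q) == 1L, q > 0, q < 1)
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  j <- seq_len(m)
  qp <- q / (1 + q)
  below <- which(ps <= j * qp / m)
  r1 <- if (length(below)) max(below) else 0L
  m0 <- if (r1 == 0L || r1 == m) m else m - r1
  adj <- pmin(1, rev(cummin(rev(ps * (1 + q) * m0 / j))))
  disc <- adj <= q
  # degenerate stages are forced by definition; the step-up-min form above
  # already agrees, this is belt-and-braces
  if (r1 == 0L) disc[] <- FALSE
  if (r1 == m) disc[] <- TRUE
  out_adj <- out_disc <- rep(NA, m)
  out_adj[o] <- adj
  out_disc[o] <- disc
  list(p_adj = as.numeric(out_adj), discovery = as.logical(out_disc),
       m0_hat = m - r1, r1 = r1)
}

#' Volcano screen table
#'
#' Per-feature differential screen between one treatment group and a
#' reference group. The effect size is the mean difference of percentage
#' changes: each replicate is expressed as a percentage change relative to
#' the reference-group mean (`100 (x - ref_mean)/ref_mean`) and the effect
#' is the mean change in the treatment group minus the mean change in the
#' reference group, in percentage points. Raw p-values come from
#' [twoSampleT()] on (by default) log10 data, and are adjusted across all
#' tested features with [bkyAdjust()].
#'
#' Features whose reference mean is zero have an undefined percentage
#' change and are excluded (with a warning) before the multiplicity count
#' m is fixed.
#'
#' @param x an [AbundanceExperiment-class].
#' @param contrast character vector `c(group, reference)` of treatment
#'   labels.
#' @param cfg an [fdrConfig()] list.
#' @return `data.frame` with columns `feature`, `effect_pct_points`,
#'   `p_raw`, `p_adj`, `discovery`, `neg_log10_p_adj`.
#' @export
volcanoTable <- function(x, contrast, cfg = fdrConfig()) {
  stopifnot(is(x, "AbundanceExperiment"), length(contrast) == 2L)
  cd <- colData(x)
  idxA <- which(cd$treatment == contrast[1L])
  idxR <- which(cd$treatment == contrast[2L])
  if (length(idxA) < 2L || length(idxR) < 2L)
    stop("both contrast groups need at least 2 replicates")
  v <- assay(x)
  refMean <- rowMeans(v[, idxR, drop = FALSE])
  drop <- !is.finite(refMean) | refMean == 0
  if (any(drop))
    warning(sum(drop), " feature(s) with zero reference mean excluded")
  v <- v[!drop, , drop = FALSE]
  refMean <- refMean[!drop]
  changesA <- 100 * sweep(v[, idxA, drop = FALSE], 1L, refMean, "-") / refMean
  changesR <- 100 * sweep(v[, idxR, drop = FALSE], 1L, refMean, "-") / refMean
  effect <- rowMeans(changesA) - rowMeans(changesR)
  pRaw <- vapply(seq_len(nrow(v)), function(i) {
    twoSampleT(v[i, idxA], v[i, idxR],
               logData = cfg$logData, pseudo = cfg$pseudo)$p
  }, numeric(1L))
  adj <- bkyAdjust(pRaw, q = cfg$q)
  data.frame(feature = rownames(v),
             effect_pct_points = unname(effect),
             p_raw = pRaw,
             p_adj = adj$p_adj,
             discovery = adj$discovery,
             neg_log10_p_adj = -log10(adj$p_adj),
             stringsAsFactors = FALSE, row.names = NULL)
}
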