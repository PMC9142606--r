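#' @importFrom stats sd
NULL

.lipidClasses <- function(x) {
  rd <- rowData(x)
  if (!"lipid_class" %in% colnames(rd)) {
    x <- annotateLipidRows(x)
    rd <- rowData(x)
  }
  rd$lipid_class
}

#' Absolute quantification against per-subclass internal standards
#'
#' Converts raw intensities to absolute amounts: each species intensity is
#' divided by the intensity of its subclass internal standard in the same
#' sample, multiplied by the spiked standard amount, and normalised to the
#' sample normaliser (cell number, protein content, or tissue mass) from
#' `colData(raw)$normalizer`.
#'
#' @param raw an [AbundanceExperiment-class] on the `raw_intensity` scale.
#' @param standardIntensity per-subclass standard intensities: either a
#'   named vector (constant across samples) or a subclass-by-sample matrix.
#' @param standardAmount named vector of spiked standard amounts per
#'   subclass (e.g. pmol).
#' @return an [AbundanceExperiment-class] on the `absolute` scale.
#' @export
absoluteQuantify <- function(raw, standardIntensity, standardAmount) {
  stopifnot(is(raw, "AbundanceExperiment"))
  if (abundanceScale(raw) != "raw_intensity")
    stop("absoluteQuantify() expects raw_intensity data")
  if (!"normalizer" %in% colnames(colData(raw)))
    stop("colData must carry a 'normalizer' column")
  norm <- colData(raw)$normalizer
  if (any(!is.finite(norm)) || any(norm <= 0))
    stop("sample normalizers must be positive")
  cls <- .lipidClasses(raw)
  v <- assay(raw)
  if (is.matrix(standardIntensity)) {
    si <- standardIntensity[, colnames(v), drop = FALSE]
  } else {
    si <- matrix(standardIntensity, nrow = length(standardIntensity),
                 ncol = ncol(v),
                 dimnames = list(names(standardIntensity), colnames(v)))
  }
  missing <- setdiff(unique(cls), rownames(si))
  if (length(missing))
    stop("no internal standard for subclass: ",
         paste(missing, collapse = ", "))
  missing <- setdiff(unique(cls), names(standardAmount))
  if (length(missing))
    stop("no standard amount for subclass: ",
         paste(missing, collapse = ", "))
  if (any(si[unique(cls), ] <= 0))
    stop("standard intensities must be positive")
  out <- v / si[cls, , drop = FALSE] * standardAmount[cls] /
    rep(norm, each = nrow(v))
  res <- raw
  assay(res) <- out
  abundanceScale(res) <- "absolute"
  res
}

#' Per-subclass relative proportions
#'
#' Within each (subclass, sample) block, values are rescaled so that the
#' species of a subclass sum to 100 percent in every sample. A subclass
#' whose total is zero in some sample yields missing proportions there,
#' with a warning.
#'
#' @param x an [AbundanceExperiment-class] on the `raw_intensity` or
#'   `absolute` scale.
#' @return an [AbundanceExperiment-class] on the `proportion_pct` scale.
#' @examples
#' vals <- matrix(c(1, 3), 2, 1,
#'                dimnames = list(c("PI(16:0/16:0)", "PI(18:1/18:1)"), "s1"))
#' des <- data.frame(sample_id = "s1", treatment = "vehicle",
#'                   timepoint_h = 0, replicate = 1)
#' ae <- AbundanceExperiment(vals, des, annotateLipids = TRUE)
#' assay(relativeProportions(ae))  # 25, 75
#' @export
relativeProportions <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  if (!abundanceScale(x) %in% c("raw_intensity", "absolute"))
    stop("relativeProportions() expects raw_intensity or absolute data")
  if (!"lipid_class" %in% colnames(rowData(x)))
    x <- annotateLipidRows(x)
  cls <- rowData(x)$lipid_class
  v <- assay(x)
  out <- v
  nZero <- 0L
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    tot <- colSums(v[idx, , drop = FALSE])
    zero <- !is.na(tot) & tot == 0
    nZero <- nZero + sum(zero)
    tot[zero] <- NA_real_
    out[idx, ] <- sweep(v[idx, , drop = FALSE], 2L, tot, "/") * 100
  }
  if (nZero)
    warning(nZero, " all-zero (subclass, sample) block(s): proportions ",
            "reported as missing")
  res <- x
  assay(res) <- out
  abundanceScale(res) <- "proportion_pct"
  res
}

#' MUFA-bound proportion of a subclass
#'
#' Sums, per sample, the relative proportions of the species of one
#' subclass that contain at least one monounsaturated acyl chain. Species
#' with unresolved chains (sum-composition shorthand) cannot be classified
#' and are excluded with a warning rather than silently dropped.
#'
#' @param x an [AbundanceExperiment-class] on the `proportion_pct` scale.
#' @param subclass single subclass label, e.g. `"PI"`.
#' @return named numeric vector, one MUFA-bound percentage per sample.
#' @export
mufaBoundProportion <- function(x, subclass) {
  stopifnot(is(x, "AbundanceExperiment"), length(subclass) == 1L)
  if (abundanceScale(x) != "proportion_pct")
    stop("mufaBoundProportion() expects proportion_pct data")
  if (!"lipid_class" %in% colnames(rowData(x)))
    x <- annotateLipidRows(x)
  rd <- rowData(x)
  idx <- which(rd$lipid_class == subclass)
  if (!length(idx))
    stop("no species of subclass '", subclass, "' present")
  unresolved <- idx[!rd$chain_resolved[idx]]
  if (length(unresolved))
    warning(length(unresolved), " chain-unresolved ", subclass,
            " species excluded from MUFA aggregation: ",
            paste(rownames(x)[unresolved], collapse = ", "))
  keep <- idx[rd$chain_resolved[idx] & rd$contains_mufa[idx] %in% TRUE]
  colSums(assay(x)[keep, , drop = FALSE])
}

#' Percent of vehicle control per timepoint
#'
#' Expresses every value relative to the mean of the vehicle-control
#' replicates at the same timepoint (vehicle mean maps to 100). Features
#' whose vehicle mean is zero at a timepoint become missing there, with a
#' warning.
#'
#' @param x an [AbundanceExperiment-class] (any scale).
#' @param vehicle treatment label of the control group (default
#'   `"vehicle"`).
#' @return an [AbundanceExperiment-class] on the `pct_of_control` scale.
#' @export
percentOfControl <- function(x, vehicle = "vehicle") {
  stopifnot(is(x, "AbundanceExperiment"))
  cd <- colData(x)
  if (!vehicle %in% cd$treatment)
    stop("no '", vehicle, "' samples in the design")
  v <- assay(x)
  out <- v
  nZero <- 0L
  for (tp in unique(cd$timepoint_h)) {
    atTp <- which(cd$timepoint_h == tp)
    veh <- atTp[cd$treatment[atTp] == vehicle]
    if (!length(veh))
      stop("no vehicle replicates at timepoint ", tp, " h")
    denom <- rowMeans(v[, veh, drop = FALSE])
    zero <- !is.na(denom) & denom == 0
    nZero <- nZero + sum(zero)
    denom[zero] <- NA_real_
    out[, atTp] <- v[, atTp, drop = FALSE] / denom * 100
  }
  if (nZero)
    warning(nZero, " feature/timepoint combination(s) with zero vehicle ",
            "mean reported as missing")
  res <- x
  assay(res) <- out
  abundanceScale(res) <- "pct_of_control"
  res
}

#' Lipid-uptake quality control
#'
#' Supplementation experiments pass uptake QC when the cellular proportion
#' of the supplemented species increases by at least `threshold` percent
#' relative to baseline (boundary inclusive).
#'
#' @param baselinePct baseline proportion(s), must be positive.
#' @param treatedPct post-supplementation proportion(s).
#' @param threshold required relative increase in percent (default 30).
#' @return logical vector of pass flags.
#' @examples
#' uptakeQC(2.0, 2.6)  # TRUE: +30 percent, boundary inclusive
#' uptakeQC(2.0, 2.5)  # FALSE
#' @export
uptakeQC <- function(baselinePct, treatedPct, threshold = 30) {
  if (any(!is.finite(baselinePct)) || any(baselinePct <= 0))
    stop("baseline proportion must be positive")
  100 * (treatedPct - baselinePct) / baselinePct >= threshold
}
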