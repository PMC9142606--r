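#' Construct effector nomination criteria
#'
#' Defaults follow the proteome filter used to nominate stress effectors:
#' concordant regulation of at least 20 percentage points under every
#' stressor, attenuation of the rescue-stressor effect by at least 10
#' points under co-treatment with the test lipid, and at least 10 points
#' more attenuation than the saturated control lipid achieves.
#'
#' @param concordanceMin minimum |change| per stressor, percentage points
#'   (default 20).
#' @param rescueMin minimum attenuation by the test lipid, points
#'   (default 10).
#' @param rescueMargin minimum test-minus-control attenuation difference,
#'   points (default 10).
#' @param stressors stressor condition labels (default VAL, MC, CAY).
#' @param rescueStressor stressor paired with the lipid co-treatments
#'   (default CAY).
#' @param rescueCondition test-lipid co-treatment label.
#' @param controlCondition control-lipid co-treatment label.
#' @param pathwaySets named list of character protein-id vectors; a protein
#'   passes criterion (i) when it belongs to any set.
#' @return an [EffectorCriteria-class].
#' @export
effectorCriteria <- function(concordanceMin = 20,
                             rescueMin = 10,
                             rescueMargin = 10,
                             stressors = c("VAL", "MC", "CAY"),
                             rescueStressor = "CAY",
                             rescueCondition = "CAY+PI(18:1/18:1)",
                             controlCondition = "CAY+PI(16:0/16:0)",
                             pathwaySets = defaultPathwaySets()) {
  new("EffectorCriteria",
      concordanceMin = concordanceMin, rescueMin = rescueMin,
      rescueMargin = rescueMargin, stressors = stressors,
      rescueStressor = rescueStressor, rescueCondition = rescueCondition,
      controlCondition = controlCondition, pathwaySets = pathwaySets)
}

#' Read pathway sets from text files
#'
#' Each file is one pathway: one protein identifier per line, blank lines
#' and `#` comments ignored; the set name is the file name without
#' extension.
#'
#' @param paths character vector of file paths.
#' @return named list of character vectors.
#' @export
readPathwaySets <- function(paths) {
  sets <- lapply(paths, function(p) {
    lines <- trimws(readLines(p))
    lines[nzchar(lines) & !startsWith(lines, "#")]
  })
  names(sets) <- sub("\\.[^.]*$", "", basename(paths))
  sets
}

#' Per-protein percentage changes versus vehicle
#'
#' For every non-vehicle condition, each protein's change is the mean over
#' replicates of `100 * value / vehicle_mean - 100`, in signed percentage
#' points. Proteins with a zero vehicle mean are excluded with a warning.
#'
#' @param x a protein [AbundanceExperiment-class].
#' @param vehicle vehicle treatment label.
#' @return numeric matrix, proteins x conditions.
#' @export
proteinPctChanges <- function(x, vehicle = "vehicle") {
  stopifnot(is(x, "AbundanceExperiment"))
  cd <- colData(x)
  veh <- which(cd$treatment == vehicle)
  if (!length(veh)) stop("no '", vehicle, "' replicates present")
  v <- assay(x)
  vehMean <- rowMeans(v[, veh, drop = FALSE])
  drop <- !is.finite(vehMean) | vehMean == 0
  if (any(drop))
    warning(sum(drop), " protein(s) with zero vehicle mean excluded")
  v <- v[!drop, , drop = FALSE]
  vehMean <- vehMean[!drop]
  conds <- setdiff(unique(cd$treatment), vehicle)
  chg <- vapply(conds, function(cc) {
    idx <- which(cd$treatment == cc)
    rowMeans(100 * v[, idx, drop = FALSE] / vehMean) - 100
  }, numeric(nrow(v)))
  chg <- matrix(chg, nrow = nrow(v),
                dimnames = list(rownames(v), conds))
  chg
}

#' Concordant-regulation criterion
#'
#' A protein passes when its changes under all stressors share one sign
#' and each magnitude is at least `minMagnitude` percentage points
#' (boundary inclusive).
#'
#' @param changes numeric vector, one signed change per stressor.
#' @param minMagnitude threshold in percentage points (default 20).
#' @return single logical.
#' @examples
#' concordancePass(c(25, 30, 22))    # TRUE
#' concordancePass(c(25, -30, 22))   # FALSE: direction conflict
#' @export
concordancePass <- function(changes, minMagnitude = 20) {
  if (any(!is.finite(changes))) return(FALSE)
  sameSign <- all(changes > 0) || all(changes < 0)
  sameSign && all(abs(changes) >= minMagnitude)
}

#' Preferential-rescue criterion
#'
#' Attenuation is how far a co-treatment moves the stressor effect back
#' toward vehicle: `|stress| - |rescue|`, with no extra credit for
#' overshooting past baseline (a co-treatment change of the opposite sign
#' counts as full attenuation to zero effect, not beyond). The criterion
#' passes when the test lipid attenuates by at least `rescueMin` points
#' and by at least `rescueMargin` points more than the control lipid.
#'
#' @param stressChange signed change under the stressor alone (nonzero).
#' @param rescueChange signed change under stressor + test lipid.
#' @param controlChange signed change under stressor + control lipid.
#' @param rescueMin minimum attenuation by the test lipid (default 10).
#' @param rescueMargin minimum test-minus-control margin (default 10).
#' @return single logical.
#' @examples
#' rescuePass(-40, -20, -35)  # TRUE: attenuations 20 vs 5
#' rescuePass(-40, -35, -30)  # FALSE: attenuation 5 < 10
#' @export
rescuePass <- function(stressChange, rescueChange, controlChange,
                       rescueMin = 10, rescueMargin = 10) {
  if (!is.finite(stressChange) || stressChange == 0)
    stop("stressor change must be nonzero")
  if (!is.finite(rescueChange) || !is.finite(controlChange)) return(FALSE)
  att <- function(co) {
    if (sign(co) == sign(stressChange)) abs(stressChange) - abs(co)
    else abs(stressChange)  # overshoot credited only down to zero effect
  }
  attTest <- att(rescueChange)
  attCtrl <- att(controlChange)
  attTest >= rescueMin && (attTest - attCtrl) >= rescueMargin
}

#' Nominate stress-effector proteins
#'
#' Applies the three-part filter to a proteome table: (i) pathway
#' membership, (ii) concordant regulation across all stressors, (iii)
#' preferential rescue by the test lipid over the control lipid. The full
#' audit trail (every change and every criterion flag) is returned for all
#' proteins, nominated first, then by |mean stressor change| descending.
#'
#' @param x a protein [AbundanceExperiment-class] (raw or absolute scale).
#' @param criteria an [EffectorCriteria-class] from [effectorCriteria()].
#' @param vehicle vehicle treatment label.
#' @return `data.frame`: `protein`, one `chg_<condition>` column per
#'   stressor plus the rescue and control co-treatments, `passes_pathway`,
#'   `passes_concordance`, `passes_rescue`, `nominated`.
#' @export
nominateEffectors <- function(x, criteria = effectorCriteria(),
                              vehicle = "vehicle") {
  stopifnot(is(x, "AbundanceExperiment"), is(criteria, "EffectorCriteria"))
  if (nrow(x) == 0L) {
    return(data.frame(protein = character(), passes_pathway = logical(),
                      passes_concordance = logical(),
                      passes_rescue = logical(), nominated = logical(),
                      stringsAsFactors = FALSE))
  }
  need <- c(criteria@stressors, criteria@rescueCondition,
            criteria@controlCondition)
  have <- unique(colData(x)$treatment)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("condition(s) absent from the design: ",
         paste(missing, collapse = ", "))
  if (!criteria@rescueStressor %in% criteria@stressors)
    stop("rescueStressor must be one of the stressors")
  chg <- proteinPctChanges(x, vehicle = vehicle)
  inPathway <- rownames(chg) %in% unique(unlist(criteria@pathwaySets))
  conc <- apply(chg[, criteria@stressors, drop = FALSE], 1L,
                concordancePass, minMagnitude = criteria@concordanceMin)
  resc <- vapply(seq_len(nrow(chg)), function(i) {
    s <- chg[i, criteria@rescueStressor]
    if (!is.finite(s) || s == 0) return(FALSE)
    rescuePass(s, chg[i, criteria@rescueCondition],
               chg[i, criteria@controlCondition],
               rescueMin = criteria@rescueMin,
               rescueMargin = criteria@rescueMargin)
  }, logical(1L))
  out <- data.frame(protein = rownames(chg), stringsAsFactors = FALSE)
  for (cc in need)
    out[[paste0("chg_", cc)]] <- unname(chg[, cc])
  out$passes_pathway <- inPathway
  out$passes_concordance <- unname(conc)
  out$passes_rescue <- resc
  out$nominated <- inPathway & conc & resc
  meanStress <- abs(rowMeans(chg[, criteria@stressors, drop = FALSE]))
  out <- out[order(-out$nominated, -meanStress, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
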