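#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList
NULL

#' Parsed lipid species
#'
#' Identity of one lipid species parsed from shorthand nomenclature: the
#' subclass, the acyl chains (carbons, double bonds) sorted canonically, and
#' whether the chains are resolved (sn-separated dialect) or only known as a
#' sum composition.
#'
#' @slot lipidClass single string, one of PC, PE, PS, PI, LPI, SM, TAG, CE,
#'   FA, CoA.
#' @slot carbons integer carbon counts per chain (sum over chains when
#'   unresolved).
#' @slot doubleBonds integer double-bond counts, parallel to `carbons`.
#' @slot resolved logical; `FALSE` for sum-composition species.
#' @slot raw the original input string.
#' @seealso [parseSpecies()], [formatSpecies()], [containsMUFA()]
#' @exportClass LipidSpecies
setClass("LipidSpecies",
  representation(
    lipidClass = "character",
    carbons = "integer",
    doubleBonds = "integer",
    resolved = "logical",
    raw = "character"
  )
)

setValidity("LipidSpecies", function(object) {
  msg <- character()
  if (length(object@lipidClass) != 1L)
    msg <- c(msg, "lipidClass must be a single string")
  if (length(object@carbons) != length(object@doubleBonds))
    msg <- c(msg, "carbons and doubleBonds must be parallel")
  if (any(object@doubleBonds < 0L) || any(object@carbons <= object@doubleBonds))
    msg <- c(msg, "each chain needs carbons > doubleBonds >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LipidSpecies", function(object) {
  cat("LipidSpecies ", formatSpecies(object),
      if (!object@resolved) "  [chain-unresolved]", "\n", sep = "")
})

.ABUNDANCE_SCALES <- c("raw_intensity", "absolute", "proportion_pct",
                       "pct_of_control")

#' Feature-by-sample abundance container
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one abundance
#' assay plus the experimental design (`treatment`, `timepoint_h`,
#' `replicate`, optional `normalizer`) in `colData`, and for lipid tables
#' the parsed species annotation in `rowData`. The `abundanceScale` slot
#' records which stage of normalisation the values are on.
#'
#' @slot abundanceScale one of `"raw_intensity"`, `"absolute"`,
#'   `"proportion_pct"`, `"pct_of_control"`.
#' @seealso [AbundanceExperiment()], [relativeProportions()],
#'   [percentOfControl()]
#' @exportClass AbundanceExperiment
setClass("AbundanceExperiment",
  contains = "SummarizedExperiment",
  representation(abundanceScale = "character")
)

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  if (length(object@abundanceScale) != 1L ||
      !object@abundanceScale %in% .ABUNDANCE_SCALES)
    msg <- c(msg, paste0("abundanceScale must be one of: ",
                         paste(.ABUNDANCE_SCALES, collapse = ", ")))
  cd <- colData(object)
  need <- c("treatment", "timepoint_h", "replicate")
  missing <- setdiff(need, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("colData lacks design columns: ",
                         paste(missing, collapse = ", ")))
  if (!length(missing)) {
    key <- paste(cd$treatment, cd$timepoint_h, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "(treatment, timepoint_h, replicate) must be unique")
    if (any(cd$timepoint_h < 0, na.rm = TRUE))
      msg <- c(msg, "timepoint_h must be non-negative")
  }
  if (length(assays(object)) >= 1L) {
    v <- assay(object)
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, "abundance values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param values numeric feature-by-sample matrix with row and column names;
#'   non-negative.
#' @param design `data.frame` with one row per sample; must contain
#'   `treatment`, `timepoint_h`, `replicate`, and either rownames or a
#'   `sample_id` column matching `colnames(values)`. An optional
#'   `normalizer` column (cell count, protein or tissue mass) is used by
#'   [absoluteQuantify()].
#' @param scale the abundance scale of `values` (default
#'   `"raw_intensity"`).
#' @param annotateLipids if `TRUE`, parse rownames as lipid shorthand and
#'   store the annotation in `rowData` (use `FALSE` for protein tables).
#' @return an [AbundanceExperiment-class].
#' @examples
#' vals <- matrix(c(1, 3, 2, 6), 2, 2,
#'                dimnames = list(c("PI(18:1/18:1)", "PI(16:0/16:0)"),
#'                                c("s1", "s2")))
#' des <- data.frame(sample_id = c("s1", "s2"),
#'                   treatment = c("vehicle", "TNF"),
#'                   timepoint_h = c(6, 6), replicate = c(1, 1))
#' AbundanceExperiment(vals, des, annotateLipids = TRUE)
#' @export
AbundanceExperiment <- function(values, design,
                                scale = "raw_intensity",
                                annotateLipids = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("'values' must have row (feature) names")
  if (is.null(colnames(values)))
    stop("'values' must have column (sample) names")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  design <- as.data.frame(design)
  if ("sample_id" %in% colnames(design)) {
    rownames(design) <- design$sample_id
  }
  if (!all(colnames(values) %in% rownames(design)))
    stop("every sample column must have a design row (by sample_id)")
  design <- design[colnames(values), , drop = FALSE]
  rd <- if (annotateLipids) DataFrame(parseLipidNames(rownames(values)))
        else DataFrame(row.names = rownames(values))
  se <- SummarizedExperiment(
    assays = SimpleList(abundance = values),
    colData = DataFrame(design),
    rowData = rd)
  new("AbundanceExperiment", se, abundanceScale = scale)
}

#' Abundance scale accessor
#'
#' @param x an [AbundanceExperiment-class].
#' @return the scale string.
#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))

#' @rdname abundanceScale
#' @export
setMethod("abundanceScale", "AbundanceExperiment",
          function(x) x@abundanceScale)

#' @rdname abundanceScale
#' @param value new scale string.
#' @export
setGeneric("abundanceScale<-",
           function(x, value) standardGeneric("abundanceScale<-"))

#' @rdname abundanceScale
#' @export
setReplaceMethod("abundanceScale", "AbundanceExperiment", function(x, value) {
  x@abundanceScale <- value
  validObject(x)
  x
})

setMethod("show", "AbundanceExperiment", function(object) {
  callNextMethod()
  cat("abundanceScale:", object@abundanceScale, "\n")
})

#' Annotate lipid rows in place
#'
#' Parses `rownames(x)` as lipid shorthand and replaces `rowData` with the
#' [parseLipidNames()] annotation.
#'
#' @param x an [AbundanceExperiment-class] whose rownames are lipid names.
#' @return the annotated object.
#' @export
annotateLipidRows <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  rowData(x) <- DataFrame(parseLipidNames(rownames(x)))
  x
}

#' Thresholded Pearson co-regulation network
#'
#' Undirected network over lipid species: nodes are species, and an edge is
#' present between two species iff the Pearson correlation of their mean
#' condition profiles exceeds `edgeThreshold` (strict). Readout
#' anti-correlation annotations may be attached per node.
#'
#' @slot nodes character vector of species (includes isolates).
#' @slot edges `data.frame` with columns `from`, `to`, `r`; `from < to`
#'   lexicographically, no self edges, every `r > edgeThreshold`.
#' @slot edgeThreshold the correlation cutoff used.
#' @slot annotations `data.frame` with columns `species`, `r_readout`,
#'   `flagged` (possibly empty).
#' @seealso [buildNetwork()], [networkClusters()], [readoutScreen()]
#' @exportClass CoregulationNetwork
setClass("CoregulationNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    edgeThreshold = "numeric",
    annotations = "data.frame"
  )
)

setValidity("CoregulationNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "r") %in% colnames(e)))
    msg <- c(msg, "edges need columns from, to, r")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self edges are not allowed")
    if (any(!(e$from %in% object@nodes) | !(e$to %in% object@nodes)))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(e$r <= object@edgeThreshold))
      msg <- c(msg, "every edge weight must exceed edgeThreshold (strict)")
    if (anyDuplicated(paste(pmin(e$from, e$to), pmax(e$from, e$to))))
      msg <- c(msg, "duplicate undirected edges")
  }
  if (length(object@edgeThreshold) != 1L)
    msg <- c(msg, "edgeThreshold must be a single number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoregulationNetwork", function(object) {
  cat("CoregulationNetwork:", length(object@nodes), "species,",
      nrow(object@edges), "edges (r >", object@edgeThreshold, ")\n")
  if (nrow(object@annotations))
    cat("  readout annotations:", sum(object@annotations$flagged),
        "species flagged anti-correlated\n")
})

#' Network accessors
#'
#' @param x a [CoregulationNetwork-class].
#' @return `networkNodes`: character vector; `networkEdges`: `data.frame`
#'   (`from`, `to`, `r`); `readoutAnnotations`: `data.frame` (`species`,
#'   `r_readout`, `flagged`).
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname network-accessors
#' @export
setMethod("networkNodes", "CoregulationNetwork", function(x) x@nodes)

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname network-accessors
#' @export
setMethod("networkEdges", "CoregulationNetwork", function(x) x@edges)

#' @rdname network-accessors
#' @export
setGeneric("readoutAnnotations",
           function(x) standardGeneric("readoutAnnotations"))

#' @rdname network-accessors
#' @export
setMethod("readoutAnnotations", "CoregulationNetwork",
          function(x) x@annotations)

#' @rdname network-accessors
#' @param value annotation `data.frame` as returned by [readoutScreen()].
#' @export
setGeneric("readoutAnnotations<-",
           function(x, value) standardGeneric("readoutAnnotations<-"))

#' @rdname network-accessors
#' @export
setReplaceMethod("readoutAnnotations", "CoregulationNetwork",
  function(x, value) {
    stopifnot(all(c("species", "r_readout", "flagged") %in% colnames(value)))
    x@annotations <- as.data.frame(value)
    x
  })

#' Effector nomination criteria
#'
#' Thresholds and condition labels for the proteome effector filter: a
#' protein is nominated iff it (i) belongs to a supplied pathway set, (ii)
#' changes concordantly (same direction, magnitude at or above
#' `concordanceMin` percentage points) under every stressor, and (iii) its
#' change under the rescue stressor is attenuated by at least `rescueMin`
#' points by the test lipid, and by at least `rescueMargin` points more than
#' by the control lipid.
#'
#' @slot concordanceMin minimum per-stressor |change| (percentage points).
#' @slot rescueMin minimum attenuation by the test lipid (points).
#' @slot rescueMargin minimum superiority of test over control lipid
#'   (points).
#' @slot stressors stressor condition labels.
#' @slot rescueStressor the stressor whose effect the lipids must rescue.
#' @slot rescueCondition stressor + test-lipid co-treatment label.
#' @slot controlCondition stressor + control-lipid co-treatment label.
#' @slot pathwaySets named list of character protein-id sets.
#' @seealso [effectorCriteria()], [nominateEffectors()]
#' @exportClass EffectorCriteria
setClass("EffectorCriteria",
  representation(
    concordanceMin = "numeric",
    rescueMin = "numeric",
    rescueMargin = "numeric",
    stressors = "character",
    rescueStressor = "character",
    rescueCondition = "character",
    controlCondition = "character",
    pathwaySets = "list"
  )
)

setValidity("EffectorCriteria", function(object) {
  msg <- character()
  for (s in c("concordanceMin", "rescueMin", "rescueMargin"))
    if (length(slot(object, s)) != 1L || slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  if (!length(object@stressors)) msg <- c(msg, "stressors must be non-empty")
  if (!length(object@pathwaySets) ||
      !all(vapply(object@pathwaySets, is.character, logical(1L))))
    msg <- c(msg, "pathwaySets must be a non-empty list of character vectors")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EffectorCriteria", function(object) {
  cat("EffectorCriteria: concordance >=", object@concordanceMin,
      "pts under", paste(object@stressors, collapse = "/"),
      "; rescue >=", object@rescueMin, "pts, margin >=",
      object@rescueMargin, "pts\n  rescue:", object@rescueCondition,
      "vs control:", object@controlCondition, "\n  pathway sets:",
      paste(names(object@pathwaySets), collapse = ", "), "\n")
})
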