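#' @importFrom stats cor complete.cases
#' @importFrom igraph graph_from_data_frame components write_graph
NULL

#' Mean condition profiles
#'
#' Collapses replicates to one mean value per (treatment, timepoint) cell,
#' giving the feature-by-cell matrix that correlation networks are built
#' from. Cells are ordered deterministically: treatments in order of first
#' appearance in the design (factor levels if `treatment` is a factor),
#' then timepoints ascending. Cell labels are `"<treatment>_<t>h"`.
#'
#' @param x an [AbundanceExperiment-class], typically on the
#'   `proportion_pct` scale.
#' @return numeric matrix features x cells with a `"cells"` attribute
#'   (`data.frame` of treatment and timepoint per column).
#' @export
meanProfiles <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  cd <- colData(x)
  treatments <- if (is.factor(cd$treatment)) levels(cd$treatment)
                else unique(cd$treatment)
  cells <- do.call(rbind, lapply(treatments, function(tr) {
    tps <- sort(unique(cd$timepoint_h[cd$treatment == tr]))
    data.frame(treatment = tr, timepoint_h = tps)
  }))
  v <- assay(x)
  prof <- vapply(seq_len(nrow(cells)), function(i) {
    idx <- which(cd$treatment == cells$treatment[i] &
                 cd$timepoint_h == cells$timepoint_h[i])
    rowMeans(v[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(v)))
  prof <- matrix(prof, nrow = nrow(v))
  prof[is.nan(prof)] <- NA_real_
  dimnames(prof) <- list(rownames(v),
                         paste0(cells$treatment, "_", cells$timepoint_h, "h"))
  incomplete <- rowSums(is.na(prof)) > 0
  if (any(incomplete))
    warning(sum(incomplete), " feature(s) missing in at least one cell; ",
            "their correlations use pairwise-complete cells")
  attr(prof, "cells") <- cells
  prof
}

#' Pearson product-moment correlation
#'
#' Thin checked wrapper used for co-regulation and readout screening:
#' requires at least 3 paired observations and returns `NA` with a warning
#' when either vector is constant (the correlation is then undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pearsonR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired finite observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(x, y)
}

#' Build the thresholded co-regulation network
#'
#' Computes all pairwise Pearson correlations between feature profiles and
#' keeps an (undirected) edge wherever r strictly exceeds `edgeThreshold`.
#' Profiles with missing cells are compared on their shared cells
#' (pairwise-complete), requiring at least `minShared` cells; pairs below
#' that support get no edge and are counted in a warning. All features stay
#' in the node set, including isolates.
#'
#' @param profiles feature-by-cell matrix from [meanProfiles()].
#' @param edgeThreshold correlation cutoff, strict (default 0.7).
#' @param minShared minimum shared non-missing cells per pair (default 3).
#' @return a [CoregulationNetwork-class].
#' @export
buildNetwork <- function(profiles, edgeThreshold = 0.7, minShared = 3L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L)
    stop("need at least 2 features")
  if (ncol(profiles) < 3L)
    stop("need at least 3 condition cells")
  if (edgeThreshold <= 0 || edgeThreshold >= 1)
    stop("edgeThreshold must lie in (0, 1)")
  r <- suppressWarnings(cor(t(profiles), use = "pairwise.complete.obs"))
  obs <- !is.na(profiles)
  shared <- tcrossprod(obs * 1)
  low <- shared < minShared
  diag(low) <- FALSE
  if (any(low[upper.tri(low)]))
    warning(sum(low[upper.tri(low)]),
            " feature pair(s) with fewer than ", minShared,
            " shared cells: correlation undefined, no edge")
  r[low] <- NA_real_
  keep <- which(upper.tri(r) & !is.na(r) & r > edgeThreshold, arr.ind = TRUE)
  nodes <- rownames(profiles)
  edges <- data.frame(
    from = pmin(nodes[keep[, 1L]], nodes[keep[, 2L]]),
    to = pmax(nodes[keep[, 1L]], nodes[keep[, 2L]]),
    r = r[keep],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("CoregulationNetwork",
      nodes = nodes, edges = edges, edgeThreshold = edgeThreshold,
      annotations = data.frame(species = character(), r_readout = numeric(),
                               flagged = logical()))
}

#' Connected components of the network
#'
#' Co-regulated clusters are the connected components of the thresholded
#' network; isolated species form singleton clusters. Components are
#' returned largest first (ties broken by the lexicographically first
#' member), with members sorted within each cluster.
#'
#' @param net a [CoregulationNetwork-class].
#' @return list of character vectors, one per cluster.
#' @export
networkClusters <- function(net) {
  stopifnot(is(net, "CoregulationNetwork"))
  g <- graph_from_data_frame(net@edges[, c("from", "to")],
                             directed = FALSE,
                             vertices = data.frame(name = net@nodes))
  comp <- components(g)
  cl <- split(names(comp$membership), comp$membership)
  cl <- lapply(cl, function(v) sort(unname(v)))
  ord <- order(-lengths(cl), vapply(cl, `[`, character(1L), 1L))
  unname(cl[ord])
}

#' Screen species for anti-correlation with a stress readout
#'
#' Correlates each feature's mean condition profile with an external
#' per-cell readout (e.g. mean phospho-p38 densitometry over the same
#' condition cells) and flags species whose correlation falls strictly
#' below `antiThreshold`.
#'
#' @param profiles feature-by-cell matrix from [meanProfiles()].
#' @param readout numeric readout, one value per profile column; if named,
#'   names must match the profile cell labels (any order).
#' @param antiThreshold flagging cutoff, strict (default -0.6).
#' @return `data.frame` with columns `species`, `r_readout`, `flagged`.
#' @export
readoutScreen <- function(profiles, readout, antiThreshold = -0.6) {
  profiles <- as.matrix(profiles)
  if (!is.null(names(readout))) {
    if (!setequal(names(readout), colnames(profiles)))
      stop("readout cell labels do not match the profile cells")
    readout <- readout[colnames(profiles)]
  } else if (length(readout) != ncol(profiles)) {
    stop("readout length must equal the number of profile cells")
  }
  r <- apply(profiles, 1L, function(p) {
    ok <- is.finite(p) & is.finite(readout)
    if (sum(ok) < 3L || sd(p[ok]) == 0 || sd(readout[ok]) == 0)
      return(NA_real_)
    cor(p[ok], readout[ok])
  })
  data.frame(species = rownames(profiles),
             r_readout = unname(r),
             flagged = !is.na(r) & r < antiThreshold,
             stringsAsFactors = FALSE)
}

#' Export a network to SIF and/or GraphML
#'
#' SIF lines are `"<from> coreg <to>"` in sorted order; isolated species
#' are written as bare node lines so the node set round-trips. GraphML
#' (written through igraph) carries the correlation as edge attribute `r`
#' and, when readout annotations are attached, `r_readout` and `flagged`
#' as node attributes. Output ordering is deterministic, so re-exports are
#' byte-identical.
#'
#' @param net a [CoregulationNetwork-class].
#' @param sif optional path for the SIF file.
#' @param graphml optional path for the GraphML file.
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(net, sif = NULL, graphml = NULL) {
  stopifnot(is(net, "CoregulationNetwork"))
  written <- character()
  e <- net@edges[order(net@edges$from, net@edges$to), , drop = FALSE]
  if (!is.null(sif)) {
    lines <- sprintf("%s coreg %s", e$from, e$to)
    isolates <- sort(setdiff(net@nodes, unique(c(e$from, e$to))))
    writeLines(c(lines, isolates), sif)
    written <- c(written, sif)
  }
  if (!is.null(graphml)) {
    vert <- data.frame(name = sort(net@nodes), stringsAsFactors = FALSE)
    ann <- net@annotations
    if (nrow(ann)) {
      m <- match(vert$name, ann$species)
      vert$r_readout <- ann$r_readout[m]
      vert$flagged <- ann$flagged[m]
    }
    g <- graph_from_data_frame(e, directed = FALSE, vertices = vert)
    write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}
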