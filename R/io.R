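#' @importFrom utils read.csv write.csv
NULL

.readTable <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an abundance table plus design from delimited files
#'
#' Accepts the two common dialects: wide (first column = feature id, one
#' column per sample) and long (columns `feature`, `sample_id`, `value`).
#' The design file needs `sample_id`, `treatment`, `timepoint_h`,
#' `replicate` and optionally `normalizer`. Extension `.tsv`/`.txt` selects
#' tab separation, anything else comma.
#'
#' @param valuesPath path to the abundance file.
#' @param designPath path to the design file.
#' @param scale abundance scale of the stored values.
#' @param annotateLipids parse feature ids as lipid shorthand.
#' @return an [AbundanceExperiment-class].
#' @export
readAbundanceTable <- function(valuesPath, designPath,
                               scale = "raw_intensity",
                               annotateLipids = FALSE) {
  tbl <- .readTable(valuesPath)
  design <- .readTable(designPath)
  if (all(c("feature", "sample_id", "value") %in% colnames(tbl))) {
    wide <- tapply(tbl$value, list(tbl$feature, tbl$sample_id), mean)
    vals <- matrix(as.numeric(wide), nrow = nrow(wide),
                   dimnames = dimnames(wide))
  } else {
    vals <- as.matrix(tbl[, -1L, drop = FALSE])
    rownames(vals) <- tbl[[1L]]
  }
  AbundanceExperiment(vals, design, scale = scale,
                      annotateLipids = annotateLipids)
}

#' Write an abundance table (wide CSV, full precision)
#'
#' @param x an [AbundanceExperiment-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeAbundanceTable <- function(x, path) {
  stopifnot(is(x, "AbundanceExperiment"))
  df <- data.frame(feature = rownames(x), assay(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
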