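#' @include AllClasses.R
NULL

# chain arity expected per lipid class; 1 = lyso/free, 2 = diacyl, 3 = triacyl
.LIPID_ARITY <- c(
  PC = 2L, PE = 2L, PS = 2L, PI = 2L, SM = 2L,
  TAG = 3L, LPI = 1L, CE = 1L, FA = 1L, CoA = 1L
)

#' Parse a lipid shorthand name
#'
#' Parses species shorthand such as `"PI(18:1/18:1)"` into a
#' [LipidSpecies-class] object. Both the sn-separated dialect
#' (`"PI(18:1/18:1)"`) and the sum-composition dialect (`"PI(36:2)"`) are
#' accepted; the latter yields a chain-unresolved species whose stored
#' carbon/double-bond counts are the totals over the (unknown) chains.
#'
#' Chain order within a species is treated as unordered: MRM-style targeted
#' acquisition detects fatty-acyl fragments without sn-positional assignment,
#' so the canonical form sorts chains by carbon count, then by double bonds.
#' Ether/plasmalogen species (`"O-"`, `"P-"` chain prefixes) are rejected.
#'
#' @param name a single non-empty lipid shorthand string.
#' @return a [LipidSpecies-class] object.
#' @examples
#' parseSpecies("PI(18:1/18:1)")
#' parseSpecies("PI(36:2)")   # chain-unresolved
#' @seealso [formatSpecies()], [parseLipidNames()]
#' @export
parseSpecies <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name)))
    stop("'name' must be a single non-empty string")
  raw <- trimws(name)
  m <- regmatches(raw, regexec("^([A-Za-z]+)\\((.*)\\)$", raw))[[1L]]
  if (length(m) != 3L)
    stop("malformed lipid name: '", raw, "'")
  cls <- m[2L]
  body <- m[3L]
  if (!cls %in% names(.LIPID_ARITY))
    stop("unknown lipid class prefix '", cls, "' in '", raw, "'")
  tokens <- strsplit(body, "/", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || !nzchar(body))
    stop("malformed lipid name: '", raw, "' (empty chain list)")
  if (any(grepl("^[OPdt]-|^d\\d|^t\\d", tokens)))
    stop("ether/plasmalogen or sphingoid-base chain notation is not ",
         "supported: '", raw, "'")
  bad <- tokens[!grepl("^[0-9]+:[0-9]+$", tokens)]
  if (length(bad))
    stop("malformed acyl-chain token '", bad[1L], "' in '", raw, "'")
  parts <- do.call(rbind, strsplit(tokens, ":", fixed = TRUE))
  carbons <- as.integer(parts[, 1L])
  dbonds <- as.integer(parts[, 2L])
  arity <- .LIPID_ARITY[[cls]]
  resolved <- length(tokens) == arity
  if (!resolved && length(tokens) != 1L)
    stop("'", raw, "': expected ", arity, " chains for class ", cls,
         " (or one sum-composition token), got ", length(tokens))
  # chain-level sanity; for sum compositions the bound is over all chains
  bad <- which(dbonds >= carbons | carbons < 2L)
  if (length(bad))
    stop("invalid acyl chain '", tokens[bad[1L]], "' in '", raw,
         "': double bonds must be fewer than carbons (carbons >= 2)")
  ord <- order(carbons, dbonds)
  new("LipidSpecies",
      lipidClass = cls,
      carbons = carbons[ord],
      doubleBonds = dbonds[ord],
      resolved = resolved,
      raw = raw)
}

#' Canonical shorthand for a parsed species
#'
#' Chains are emitted sorted by carbons then double bonds, so
#' `formatSpecies(parseSpecies(x))` is idempotent and independent of the
#' chain order in the input.
#'
#' @param species a [LipidSpecies-class] object.
#' @return a single canonical shorthand string.
#' @export
formatSpecies <- function(species) {
  stopifnot(is(species, "LipidSpecies"))
  paste0(species@lipidClass, "(",
         paste0(species@carbons, ":", species@doubleBonds, collapse = "/"),
         ")")
}

#' Saturation class of an acyl chain
#'
#' Classifies chains by double-bond count: 0 is saturated (SFA), exactly 1
#' is monounsaturated (MUFA), 2 or more is polyunsaturated (PUFA).
#'
#' @param carbons integer vector of chain carbon counts (> double bonds).
#' @param doubleBonds integer vector of double-bond counts (>= 0).
#' @return character vector in `c("SFA", "MUFA", "PUFA")`.
#' @examples
#' chainClass(18, 0)  # "SFA"
#' chainClass(c(16, 20), c(1, 4))
#' @export
chainClass <- function(carbons, doubleBonds) {
  carbons <- as.integer(carbons)
  doubleBonds <- as.integer(doubleBonds)
  if (length(carbons) != length(doubleBonds))
    stop("'carbons' and 'doubleBonds' must have equal length")
  if (any(is.na(carbons) | is.na(doubleBonds)) ||
      any(doubleBonds < 0L) || any(carbons <= doubleBonds))
    stop("invalid chain: need carbons > doubleBonds >= 0")
  ifelse(doubleBonds == 0L, "SFA", ifelse(doubleBonds == 1L, "MUFA", "PUFA"))
}

#' Does a species carry at least one monounsaturated chain?
#'
#' The MUFA-bound aggregation counts phospholipid species containing at
#' least one fatty acid with a single double bond; this predicate implements
#' that membership test. Sum-composition (chain-unresolved) species cannot
#' be classified and raise an error.
#'
#' @param species a [LipidSpecies-class] object or a shorthand string.
#' @return `TRUE` iff any chain has exactly one double bond.
#' @examples
#' containsMUFA("PI(18:1/18:1)")  # TRUE
#' containsMUFA("PI(18:0/20:4)")  # FALSE
#' @export
setGeneric("containsMUFA", function(species) standardGeneric("containsMUFA"))

#' @rdname containsMUFA
#' @export
setMethod("containsMUFA", "LipidSpecies", function(species) {
  if (!species@resolved)
    stop("'", species@raw, "' is chain-unresolved (sum composition); ",
         "resolve acyl chains before MUFA classification")
  any(species@doubleBonds == 1L)
})

#' @rdname containsMUFA
#' @export
setMethod("containsMUFA", "character", function(species) {
  vapply(species, function(s) containsMUFA(parseSpecies(s)), logical(1L),
         USE.NAMES = FALSE)
})

#' Sum composition of a species
#'
#' Total carbons and total double bonds over all chains, the quantity that
#' isobaric sum-composition shorthand like `"PI(36:2)"` reports.
#'
#' @param species a [LipidSpecies-class] object or a shorthand string.
#' @return named integer vector `c(carbons = , double_bonds = )`.
#' @examples
#' sumComposition("PI(18:1/18:1)")  # 36, 2
#' @export
setGeneric("sumComposition", function(species) standardGeneric("sumComposition"))

#' @rdname sumComposition
#' @export
setMethod("sumComposition", "LipidSpecies", function(species) {
  c(carbons = sum(species@carbons), double_bonds = sum(species@doubleBonds))
})

#' @rdname sumComposition
#' @export
setMethod("sumComposition", "character", function(species) {
  if (length(species) == 1L) return(sumComposition(parseSpecies(species)))
  t(vapply(species, function(s) sumComposition(parseSpecies(s)),
           integer(2L)))
})

#' Parse a vector of lipid names into an annotation table
#'
#' Vectorised front end to [parseSpecies()] used to annotate the rows of an
#' abundance table. Mixed dialects are allowed; chain-unresolved species get
#' `contains_mufa = NA` and are excluded (with a warning) from MUFA
#' aggregation downstream.
#'
#' @param names character vector of lipid shorthand names.
#' @return a `data.frame` with one row per name: `raw_name`, `canonical`,
#'   `lipid_class`, `chain_resolved`, `n_chains`, `chains`, `total_carbons`,
#'   `total_double_bonds`, `contains_mufa`.
#' @export
parseLipidNames <- function(names) {
  stopifnot(is.character(names), length(names) >= 1L)
  rows <- lapply(names, function(nm) {
    sp <- parseSpecies(nm)
    data.frame(
      raw_name = nm,
      canonical = formatSpecies(sp),
      lipid_class = sp@lipidClass,
      chain_resolved = sp@resolved,
      n_chains = if (sp@resolved) length(sp@carbons) else NA_integer_,
      chains = paste0(sp@carbons, ":", sp@doubleBonds, collapse = "/"),
      total_carbons = sum(sp@carbons),
      total_double_bonds = sum(sp@doubleBonds),
      contains_mufa = if (sp@resolved) any(sp@doubleBonds == 1L) else NA,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names
  out
}
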