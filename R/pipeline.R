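#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom utils packageVersion write.csv
NULL

#' Default pipeline configuration
#'
#' All stage thresholds in one place, defaulting to the values used
#' throughout the screens: co-regulation edge threshold 0.7, readout
#' anti-correlation threshold -0.6, FDR level 0.05, effector concordance
#' 20 points, rescue attenuation 10 points, rescue margin 10 points,
#' uptake QC 30 percent. When input paths are omitted the corresponding
#' stage runs on seeded synthetic data, so a default run exercises the
#' whole chain.
#'
#' @param seed RNG seed for the synthetic stages.
#' @param output_dir run directory to create.
#' @return a nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L, output_dir = "lipokine_run") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    lipidome = list(values = NULL, design = NULL),
    readout = list(values = NULL),
    proteome = list(values = NULL, design = NULL),
    pathways = NULL,
    thresholds = list(edge = 0.7, anti = -0.6, q = 0.05,
                      concordance = 20, rescue_min = 10,
                      rescue_margin = 10, uptake = 30),
    screen = list(contrast = c("VAL", "vehicle"))
  )
}

.validatePipelineConfig <- function(cfg) {
  th <- cfg$thresholds
  if (th$edge <= 0 || th$edge >= 1)
    stop("config: edge threshold must lie in (0, 1)")
  if (th$anti >= 0 || th$anti <= -1)
    stop("config: anti-correlation threshold must lie in (-1, 0)")
  if (th$q <= 0 || th$q >= 1)
    stop("config: FDR level must lie in (0, 1)")
  for (nm in c("concordance", "rescue_min", "rescue_margin", "uptake"))
    if (th[[nm]] <= 0)
      stop("config: threshold '", nm, "' must be positive")
  paths <- c(cfg$lipidome$values, cfg$lipidome$design,
             cfg$readout$values, cfg$proteome$values, cfg$proteome$design,
             cfg$pathways)
  missing <- paths[!vapply(paths, file.exists, logical(1L))]
  if (length(missing))
    stop("config: input file(s) not found: ",
         paste(missing, collapse = ", "))
  invisible(cfg)
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full screening pipeline
#'
#' Chains quantification (per-subclass proportions), co-regulation network
#' inference plus readout screening, the differential volcano screen, and
#' the proteome effector filter, writing every stage output and a run
#' manifest (configuration echo, seed, package version, md5 of every
#' output, and a planted-signal/summary block) into the run directory.
#' With a fixed seed the run is deterministic, so two runs produce
#' identical manifests.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]), or
#'   a path to a YAML/JSON file holding one; omitted entries fall back to
#'   the defaults.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else read_yaml(config)
  }
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  .validatePipelineConfig(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  th <- cfg$thresholds
  summary <- list()

  # --- lipidome: load or simulate, then proportions --------------------
  if (!is.null(cfg$lipidome$values)) {
    lip <- readAbundanceTable(cfg$lipidome$values, cfg$lipidome$design,
                              annotateLipids = TRUE)
    latent <- NULL
  } else {
    sim <- simulateLipidome(lipidomeSimConfig(seed = cfg$seed))
    lip <- sim$experiment
    latent <- sim$latent
  }
  prop <- relativeProportions(lip)
  writeAbundanceTable(prop, out("proportions.csv"))

  # --- network + readout screen ---------------------------------------
  prof <- meanProfiles(prop)
  write.csv(data.frame(feature = rownames(prof), prof, check.names = FALSE),
            out("mean_profiles.csv"), row.names = FALSE)
  net <- buildNetwork(prof, edgeThreshold = th$edge)
  if (!is.null(cfg$readout$values)) {
    ro <- .readTable(cfg$readout$values)
    readout <- stats::setNames(ro[[2L]], ro[[1L]])
  } else {
    readout <- simulateReadout(latent, seed = cfg$seed)
  }
  ann <- readoutScreen(prof, readout, antiThreshold = th$anti)
  readoutAnnotations(net) <- ann
  exportNetwork(net, sif = out("network.sif"),
                graphml = out("network.graphml"))
  write.csv(ann, out("readout_screen.csv"), row.names = FALSE)
  cl <- networkClusters(net)
  writeLines(vapply(cl, paste, character(1L), collapse = "\t"),
             out("clusters.tsv"))
  summary$n_species <- nrow(prof)
  summary$n_edges <- nrow(networkEdges(net))
  summary$n_clusters <- length(cl)
  summary$n_flagged_anticorrelated <- sum(ann$flagged)

  # --- differential screen --------------------------------------------
  screen <- volcanoTable(prop, contrast = unlist(cfg$screen$contrast),
                         cfg = fdrConfig(q = th$q))
  write.csv(screen, out("screen.csv"), row.names = FALSE)
  summary$n_screen_discoveries <- sum(screen$discovery)

  # --- effector filter -------------------------------------------------
  if (!is.null(cfg$proteome$values)) {
    prot <- readAbundanceTable(cfg$proteome$values, cfg$proteome$design)
  } else {
    prot <- simulateProteome(proteomeSimConfig(seed = cfg$seed))$experiment
  }
  sets <- if (!is.null(cfg$pathways)) readPathwaySets(cfg$pathways)
          else defaultPathwaySets()
  crit <- effectorCriteria(concordanceMin = th$concordance,
                           rescueMin = th$rescue_min,
                           rescueMargin = th$rescue_margin,
                           pathwaySets = sets)
  eff <- nominateEffectors(prot, crit)
  write.csv(eff, out("effectors.csv"), row.names = FALSE)
  summary$nominated_effectors <- eff$protein[eff$nominated]

  # --- manifest --------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$output_dir), "manifest.json"))
  hashes <- as.list(md5sum(file.path(cfg$output_dir, files)))
  names(hashes) <- files
  manifest <- list(
    package = "lipokineScreen",
    version = as.character(packageVersion("lipokineScreen")),
    seed = cfg$seed,
    config = cfg,
    summary = summary,
    file_md5 = hashes)
  write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
             pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
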