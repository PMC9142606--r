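#' @importFrom stats rlnorm rnorm pt
NULL

# run expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# fixed species catalogues per subclass; MUFA-containing PI species first so
# the default planted cluster is well defined
.SPECIES_CATALOG <- list(
  PI = c("PI(16:1/16:1)", "PI(16:1/18:1)", "PI(18:1/18:1)",
         "PI(16:0/16:1)", "PI(16:0/18:1)", "PI(18:0/18:1)",
         "PI(16:0/16:0)", "PI(18:0/20:4)", "PI(16:0/20:4)",
         "PI(18:0/22:6)", "PI(16:0/22:6)", "PI(18:0/18:2)"),
  PC = c("PC(16:0/16:0)", "PC(16:0/18:2)", "PC(16:0/20:4)",
         "PC(18:0/18:2)", "PC(18:0/20:4)", "PC(16:0/18:1)",
         "PC(18:1/18:1)", "PC(16:0/22:6)", "PC(18:2/18:2)",
         "PC(18:0/22:6)"),
  PE = c("PE(16:0/18:2)", "PE(18:0/20:4)", "PE(16:0/20:4)",
         "PE(18:0/22:6)", "PE(18:1/18:1)", "PE(16:0/18:1)",
         "PE(18:0/18:2)", "PE(16:0/22:6)")
)

#' Lipidome simulation configuration
#'
#' Describes a multi-stressor time-course lipidomics experiment with a
#' planted co-depleting cluster: a set of MUFA-containing PI species share
#' one latent depletion factor that falls monotonically to
#' `1 - depletionDepth` at the final timepoint under every non-vehicle
#' treatment, while all other species are flat. Replicate noise is
#' multiplicative log-normal.
#'
#' @param nSpecies named integer vector, species per subclass (defaults to
#'   12 PI, 10 PC, 8 PE drawn from a fixed catalogue).
#' @param plantedCluster species ids sharing the latent factor (default:
#'   the 6 MUFA-containing PI species).
#' @param timepointsH timepoints in hours (default 0.17, 6, 24, 48).
#' @param treatments condition labels, vehicle first (default: vehicle plus
#'   9 cytotoxic stressors).
#' @param nReplicates independent replicates per cell (default 3).
#' @param depletionDepth fractional loss of planted species at the final
#'   timepoint, in \[0, 1) (default 0.6).
#' @param noiseSdLog SD of the log-normal replicate noise on the natural-log
#'   scale (default 0.1).
#' @param coupling strength linking the latent depletion to the stress
#'   readout (default 1.5; see [simulateReadout()]).
#' @param readoutNoiseSd additive readout noise SD (default 0.05).
#' @param seed RNG seed; the same seed reproduces identical output.
#' @return a validated list of class `"LipidomeSimConfig"`.
#' @export
lipidomeSimConfig <- function(nSpecies = c(PI = 12L, PC = 10L, PE = 8L),
                              plantedCluster = .SPECIES_CATALOG$PI[1:6],
                              timepointsH = c(0.17, 6, 24, 48),
                              treatments = c("vehicle", "TNF", "STS", "CHX",
                                             "ETO", "TPG", "VAL", "MC",
                                             "I3M", "SER"),
                              nReplicates = 3L,
                              depletionDepth = 0.6,
                              noiseSdLog = 0.1,
                              coupling = 1.5,
                              readoutNoiseSd = 0.05,
                              seed = 1L) {
  stopifnot(depletionDepth >= 0, depletionDepth < 1, noiseSdLog >= 0,
            nReplicates >= 1L, length(timepointsH) >= 2L,
            "vehicle" %in% treatments)
  bad <- setdiff(names(nSpecies), names(.SPECIES_CATALOG))
  if (length(bad))
    stop("no species catalogue for subclass: ", paste(bad, collapse = ", "))
  over <- nSpecies > lengths(.SPECIES_CATALOG)[names(nSpecies)]
  if (any(over))
    stop("nSpecies exceeds the catalogue for: ",
         paste(names(nSpecies)[over], collapse = ", "))
  species <- unlist(lapply(names(nSpecies), function(cl)
    .SPECIES_CATALOG[[cl]][seq_len(nSpecies[[cl]])]), use.names = FALSE)
  if (!all(plantedCluster %in% species))
    stop("plantedCluster species must be among the simulated species")
  structure(list(nSpecies = nSpecies, species = species,
                 plantedCluster = plantedCluster,
                 timepointsH = sort(timepointsH), treatments = treatments,
                 nReplicates = as.integer(nReplicates),
                 depletionDepth = depletionDepth, noiseSdLog = noiseSdLog,
                 coupling = coupling, readoutNoiseSd = readoutNoiseSd,
                 seed = as.integer(seed)),
            class = "LipidomeSimConfig")
}

#' Simulate a stressor time-course lipidome
#'
#' Baseline species abundances are drawn log-normally once per species;
#' planted species are multiplied by the latent depletion trajectory
#' `1 - depletionDepth * t / max(t)` under every non-vehicle treatment
#' (vehicle stays flat); every measurement gets independent multiplicative
#' log-normal noise.
#'
#' @param cfg a [lipidomeSimConfig()] object.
#' @return list with `experiment` (raw-intensity
#'   [AbundanceExperiment-class], lipid-annotated), `design` (the sample
#'   sheet), `latent` (named per-cell latent factor, cells labelled as in
#'   [meanProfiles()]), and `config`.
#' @export
simulateLipidome <- function(cfg = lipidomeSimConfig()) {
  stopifnot(inherits(cfg, "LipidomeSimConfig"))
  design <- expand.grid(replicate = seq_len(cfg$nReplicates),
                        timepoint_h = cfg$timepointsH,
                        treatment = cfg$treatments,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("treatment", "timepoint_h", "replicate")]
  design$sample_id <- paste0(design$treatment, "_", design$timepoint_h,
                             "h_r", design$replicate)
  tmax <- max(cfg$timepointsH)
  latentOf <- function(treatment, tp)
    ifelse(treatment == "vehicle", 1, 1 - cfg$depletionDepth * tp / tmax)
  planted <- cfg$species %in% cfg$plantedCluster
  .withSeed(cfg$seed, {
    baseline <- rlnorm(length(cfg$species), meanlog = log(100), sdlog = 1)
    mu <- outer(ifelse(planted, 1, 0),
                latentOf(design$treatment, design$timepoint_h)) +
          outer(ifelse(planted, 0, 1), rep(1, nrow(design)))
    vals <- baseline * mu *
      matrix(rlnorm(length(mu), 0, cfg$noiseSdLog), nrow = nrow(mu))
  })
  dimnames(vals) <- list(cfg$species, design$sample_id)
  ae <- AbundanceExperiment(vals, design, scale = "raw_intensity",
                            annotateLipids = TRUE)
  cells <- unique(design[, c("treatment", "timepoint_h")])
  latent <- latentOf(cells$treatment, cells$timepoint_h)
  names(latent) <- paste0(cells$treatment, "_", cells$timepoint_h, "h")
  list(experiment = ae, design = design, latent = latent, config = cfg)
}

#' Simulate a per-cell stress readout
#'
#' The readout (e.g. mean phospho-p38 densitometry per condition cell)
#' rises as the latent lipid factor depletes:
#' `baseline + coupling * (1 - latent) + noise`. With positive coupling the
#' planted species are anti-correlated with the readout by construction
#' (exactly -1 in the noiseless limit).
#'
#' @param latent named per-cell latent vector from [simulateLipidome()].
#' @param coupling coupling strength (default 1.5).
#' @param noiseSd additive Gaussian noise SD (default 0.05).
#' @param baseline readout baseline level (default 1).
#' @param seed RNG seed.
#' @return named numeric readout vector aligned to the latent cells.
#' @export
simulateReadout <- function(latent, coupling = 1.5, noiseSd = 0.05,
                            baseline = 1, seed = 1L) {
  stopifnot(is.numeric(latent), length(latent) >= 3L)
  .withSeed(seed, {
    out <- baseline + coupling * (1 - latent) +
      rnorm(length(latent), 0, noiseSd)
  })
  names(out) <- names(latent)
  out
}

#' Proteome simulation configuration
#'
#' Describes a vehicle-anchored label-free proteome with planted effectors:
#' each planted protein has fixed per-condition mean percentage changes
#' (versus vehicle = 100), null proteins have mean change zero everywhere,
#' and replicate noise is additive on the percent scale.
#'
#' The default plants one phosphatase-like effector, `"Ppp2ca"`, depleted
#' under all three stressors (-35, -30, -40 points under VAL, MC, CAY) and
#' preferentially rescued by the test lipid (to -15) over the control lipid
#' (still -35).
#'
#' @param nNull number of null proteins (default 200).
#' @param plantedEffectors named list; each element is a named numeric
#'   vector of per-condition mean changes in percentage points.
#' @param conditions condition labels, vehicle first.
#' @param nReplicates replicates per condition (default 3).
#' @param noiseSd additive noise SD on the percent scale (default 5).
#' @param seed RNG seed.
#' @return a validated list of class `"ProteomeSimConfig"`.
#' @export
proteomeSimConfig <- function(nNull = 200L,
                              plantedEffectors = list(
                                Ppp2ca = c("VAL" = -35, "MC" = -30,
                                           "CAY" = -40,
                                           "CAY+PI(18:1/18:1)" = -15,
                                           "CAY+PI(16:0/16:0)" = -35)),
                              conditions = c("vehicle", "VAL", "MC", "CAY",
                                             "CAY+PI(18:1/18:1)",
                                             "CAY+PI(16:0/16:0)"),
                              nReplicates = 3L,
                              noiseSd = 5,
                              seed = 1L) {
  stopifnot(nNull >= 0L, noiseSd >= 0, nReplicates >= 2L,
            conditions[1L] == "vehicle")
  for (eff in plantedEffectors)
    if (!all(names(eff) %in% conditions))
      stop("planted effector refers to unknown condition(s)")
  structure(list(nNull = as.integer(nNull),
                 plantedEffectors = plantedEffectors,
                 conditions = conditions,
                 nReplicates = as.integer(nReplicates),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "ProteomeSimConfig")
}

#' Simulate a label-free proteome with planted effectors
#'
#' Per-protein baseline intensities are log-normal; each measurement is
#' `baseline * (100 + mean_change + noise) / 100` with additive Gaussian
#' noise on the percent scale (truncated at zero), so
#' [proteinPctChanges()] recovers the planted means exactly in the
#' noiseless limit.
#'
#' @param cfg a [proteomeSimConfig()] object.
#' @return list with `experiment` (protein [AbundanceExperiment-class]),
#'   `design`, and `config`.
#' @export
simulateProteome <- function(cfg = proteomeSimConfig()) {
  stopifnot(inherits(cfg, "ProteomeSimConfig"))
  proteins <- c(names(cfg$plantedEffectors),
                sprintf("P%04d", seq_len(cfg$nNull)))
  design <- expand.grid(replicate = seq_len(cfg$nReplicates),
                        treatment = cfg$conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("treatment", "replicate")]
  design$timepoint_h <- 48
  design$sample_id <- paste0(design$treatment, "_r", design$replicate)
  shift <- matrix(0, nrow = length(proteins), ncol = nrow(design),
                  dimnames = list(proteins, design$sample_id))
  for (nm in names(cfg$plantedEffectors)) {
    eff <- cfg$plantedEffectors[[nm]]
    for (cc in names(eff))
      shift[nm, design$treatment == cc] <- eff[[cc]]
  }
  .withSeed(cfg$seed, {
    baseline <- rlnorm(length(proteins), meanlog = log(1e6), sdlog = 1)
    pct <- 100 + shift +
      matrix(rnorm(length(shift), 0, cfg$noiseSd), nrow = nrow(shift))
    vals <- baseline * pmax(pct, 0) / 100
  })
  dimnames(vals) <- dimnames(shift)
  ae <- AbundanceExperiment(vals, design, scale = "raw_intensity",
                            annotateLipids = FALSE)
  list(experiment = ae, design = design, config = cfg)
}

#' Default pathway membership sets
#'
#' Small built-in stand-ins for user-supplied pathway lists (stress
#' signalling, unfolded protein response, autophagy, programmed cell
#' death), sufficient for the planted-effector simulations; real analyses
#' should load curated sets with [readPathwaySets()].
#'
#' @return named list of character protein-id vectors.
#' @export
defaultPathwaySets <- function() {
  list(
    p38_stress_signalling = c("Ppp2ca", "Mapk14", "Mapkapk2", "Map2k3",
                              "Map2k6", "Dusp1"),
    unfolded_protein_response = c("Hspa5", "Ddit3", "Atf4", "Ern1",
                                  "Eif2ak3", "Xbp1"),
    autophagy = c("Sqstm1", "Map1lc3b", "Atg5", "Atg7", "Becn1"),
    programmed_cell_death = c("Casp3", "Casp8", "Bax", "Bcl2", "Parp1")
  )
}

# vectorised two-sided pooled-variance t over feature rows; agrees with
# twoSampleT() cell-by-cell (asserted in the test suite)
.pooledTMatrix <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  df <- nA + nB - 2L
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  p <- 2 * pt(-abs(t), df)
  p[se == 0] <- 1
  p
}

#' Simulate replicate p-value vectors for FDR calibration
#'
#' Monte-Carlo harness for the multiple-testing procedure: per replicate,
#' `m` independent two-sample comparisons (n per group, unit-variance
#' normals) are drawn, a fixed fraction of which carry a true mean shift,
#' and two-sided pooled-t p-values are computed. Defaults give roughly 80
#' percent marginal power per true effect.
#'
#' @param m features per replicate (default 200).
#' @param nReps number of Monte-Carlo replicates (default 2000).
#' @param effectFraction fraction of features with a true shift
#'   (default 0.25; the first `round(m * effectFraction)` features).
#' @param shift true mean difference for non-null features (default 2).
#' @param nPerGroup samples per group (default 5).
#' @param seed RNG seed.
#' @return list with `pvalues` (nReps x m matrix), `truth` (logical m
#'   vector, `TRUE` = real effect), and the generating parameters.
#' @seealso [empiricalFdr()]
#' @export
simulateNullPvalues <- function(m = 200L, nReps = 2000L,
                                effectFraction = 0.25, shift = 2,
                                nPerGroup = 5L, seed = 1L) {
  stopifnot(m >= 1L, nReps >= 1L, effectFraction >= 0, effectFraction <= 1,
            nPerGroup >= 2L)
  nTrue <- round(m * effectFraction)
  truth <- seq_len(m) <= nTrue
  mu <- ifelse(truth, shift, 0)
  p <- matrix(NA_real_, nrow = nReps, ncol = m)
  .withSeed(seed, {
    for (rep in seq_len(nReps)) {
      A <- matrix(rnorm(m * nPerGroup, mean = mu), nrow = m)
      B <- matrix(rnorm(m * nPerGroup), nrow = m)
      p[rep, ] <- .pooledTMatrix(A, B)
    }
  })
  list(pvalues = p, truth = truth, m = m, nReps = nReps,
       effectFraction = effectFraction, shift = shift,
       nPerGroup = nPerGroup, seed = seed)
}

#' Empirical FDR and power of the adaptive procedure
#'
#' Applies [bkyAdjust()] to every simulated replicate and summarises the
#' false discovery proportion FDP = FP / max(1, discoveries) and the power
#' (fraction of true effects discovered) over replicates.
#'
#' @param sim output of [simulateNullPvalues()].
#' @param q nominal FDR level (default 0.05).
#' @return list with `fdr` (mean FDP), `fdrSe` (Monte-Carlo standard
#'   error), `power`, and `nReps`.
#' @export
empiricalFdr <- function(sim, q = 0.05) {
  fdp <- numeric(sim$nReps)
  tpr <- numeric(sim$nReps)
  nTrue <- sum(sim$truth)
  for (rep in seq_len(sim$nReps)) {
    disc <- bkyAdjust(sim$pvalues[rep, ], q = q)$discovery
    fdp[rep] <- sum(disc & !sim$truth) / max(1, sum(disc))
    tpr[rep] <- if (nTrue) sum(disc & sim$truth) / nTrue else NA_real_
  }
  list(fdr = mean(fdp), fdrSe = sd(fdp) / sqrt(sim$nReps),
       power = mean(tpr), nReps = sim$nReps)
}
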