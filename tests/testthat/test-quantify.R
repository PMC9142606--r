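test_that("absolute quantification follows the internal-standard ratio", {
  vals <- matrix(2.0, 1, 1, dimnames = list("PI(18:1/18:1)", "s1"))
  des <- data.frame(sample_id = "s1", treatment = "vehicle",
                    timepoint_h = 0, replicate = 1, normalizer = 1)
  ae <- AbundanceExperiment(vals, des, annotateLipids = TRUE)
  abs1 <- absoluteQuantify(ae, standardIntensity = c(PI = 1.0),
                           standardAmount = c(PI = 10))
  expect_equal(unname(assay(abs1)[1, 1]), 20)  # 2/1 * 10 pmol / 1e6 cells
  expect_equal(abundanceScale(abs1), "absolute")

  # zero raw intensity stays zero
  vals[1, 1] <- 0
  ae0 <- AbundanceExperiment(vals, des, annotateLipids = TRUE)
  expect_equal(unname(assay(absoluteQuantify(ae0, c(PI = 1), c(PI = 10)))[1, 1]), 0)
})

test_that("absolute quantification matches element-wise hand computation", {
  set.seed(11)
  feats <- c(randomLipidNames(3, "PI"), randomLipidNames(2, "PC"))
  vals <- matrix(runif(15, 0.5, 5), 5, 3,
                 dimnames = list(feats, paste0("s", 1:3)))
  des <- data.frame(sample_id = paste0("s", 1:3), treatment = "vehicle",
                    timepoint_h = 0, replicate = 1:3,
                    normalizer = c(1.0, 2.0, 0.5))
  ae <- AbundanceExperiment(vals, des, annotateLipids = TRUE)
  si <- matrix(runif(6, 0.5, 2), 2, 3,
               dimnames = list(c("PI", "PC"), paste0("s", 1:3)))
  sa <- c(PI = 10, PC = 25)
  got <- assay(absoluteQuantify(ae, si, sa))
  cls <- parseLipidNames(feats)$lipid_class
  for (f in 1:5) {
    for (s in 1:3) {
      expected <- unname(vals[f, s] / si[cls[f], s] * sa[cls[f]] /
                           des$normalizer[s])
      expect_equal(unname(got[f, s]), expected)
    }
  }
  expect_error(absoluteQuantify(ae, si["PI", , drop = FALSE], sa),
               "no internal standard")
})

test_that("subclass proportions sum to 100 and match the summation oracle", {
  set.seed(21)
  feats <- c(randomLipidNames(12, "PI"), randomLipidNames(8, "PC"))
  vals <- matrix(rlnorm(20 * 4), 20, 4,
                 dimnames = list(feats, paste0("s", 1:4)))
  ae <- makeLipidExperiment(vals, rep("vehicle", 4), rep(0, 4), 1:4)
  prop <- relativeProportions(ae)
  got <- assay(prop)
  cls <- rowData(prop)$lipid_class
  for (cl in unique(cls)) {
    sums <- colSums(got[cls == cl, , drop = FALSE])
    expect_true(all(abs(sums - 100) < 1e-9))
  }
  expect_equal(got, oracleProportions(vals, cls))
  expect_equal(abundanceScale(prop), "proportion_pct")
})

test_that("proportions are invariant to per-(subclass, sample) rescaling", {
  set.seed(22)
  feats <- c(randomLipidNames(6, "PI"), randomLipidNames(5, "PC"))
  vals <- matrix(rlnorm(11 * 3), 11, 3,
                 dimnames = list(feats, paste0("s", 1:3)))
  ae <- makeLipidExperiment(vals, rep("vehicle", 3), rep(0, 3), 1:3)
  p1 <- assay(relativeProportions(ae))
  scaled <- vals
  cls <- parseLipidNames(feats)$lipid_class
  scaled[cls == "PI", 2] <- scaled[cls == "PI", 2] * 7.3
  scaled[cls == "PC", 1] <- scaled[cls == "PC", 1] * 0.01
  ae2 <- makeLipidExperiment(scaled, rep("vehicle", 3), rep(0, 3), 1:3)
  expect_equal(assay(relativeProportions(ae2)), p1)
})

test_that("degenerate proportion inputs behave as documented", {
  # single species in a subclass takes the full 100 percent
  vals <- matrix(c(1, 3, 5), 3, 1,
                 dimnames = list(c("PI(18:1/18:1)", "PC(16:0/16:0)",
                                   "PC(16:0/18:1)"), "s1"))
  ae <- makeLipidExperiment(vals, "vehicle", 0, 1)
  got <- assay(relativeProportions(ae))
  expect_equal(unname(got[1, 1]), 100)
  expect_equal(unname(got[2:3, 1]), c(37.5, 62.5))

  # an all-zero subclass yields missing proportions with a warning
  vals[c(2, 3), 1] <- 0
  ae0 <- makeLipidExperiment(vals, "vehicle", 0, 1)
  expect_warning(p0 <- relativeProportions(ae0), "all-zero")
  expect_true(all(is.na(assay(p0)[2:3, 1])))
  expect_equal(unname(assay(p0)[1, 1]), 100)
})

test_that("MUFA-bound proportion equals the filter-and-sum oracle", {
  expect_equal(
    unname(mufaBoundProportion(
      relativeProportions(makeLipidExperiment(
        matrix(5, 1, 1, dimnames = list("PI(18:1/18:1)", "s1")),
        "vehicle", 0, 1)), "PI")),
    100)
  vals <- matrix(c(3, 3), 2, 1,
                 dimnames = list(c("PI(16:0/16:0)", "PI(18:1/18:1)"), "s1"))
  expect_equal(
    unname(mufaBoundProportion(
      relativeProportions(makeLipidExperiment(vals, "vehicle", 0, 1)), "PI")),
    50)

  set.seed(31)
  feats <- randomLipidNames(12, "PI")
  vals <- matrix(rlnorm(12 * 5), 12, 5,
                 dimnames = list(feats, paste0("s", 1:5)))
  prop <- relativeProportions(
    makeLipidExperiment(vals, rep("vehicle", 5), rep(0, 5), 1:5))
  got <- mufaBoundProportion(prop, "PI")
  isMufa <- parseLipidNames(feats)$contains_mufa
  manual <- colSums(assay(prop)[isMufa, , drop = FALSE])
  expect_equal(got, manual)
  expect_true(all(got <= 100 + 1e-9))
})

test_that("chain-unresolved species are excluded from MUFA sums, loudly", {
  vals <- matrix(c(2, 2, 6), 3, 1,
                 dimnames = list(c("PI(18:1/18:1)", "PI(36:2)",
                                   "PI(16:0/16:0)"), "s1"))
  prop <- relativeProportions(makeLipidExperiment(vals, "vehicle", 0, 1))
  expect_warning(got <- mufaBoundProportion(prop, "PI"), "PI\\(36:2\\)")
  expect_equal(unname(got), 20)  # 2 of 10 total; PI(36:2) not counted
})

test_that("percent of control matches the loop oracle, vehicle mean = 100", {
  set.seed(41)
  feats <- randomLipidNames(8, "PI")
  design <- expand.grid(replicate = 1:3, timepoint_h = c(0.17, 6, 24, 48),
                        treatment = c("vehicle", "TNF", "STS"),
                        stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$treatment, "_", design$timepoint_h,
                             "_r", design$replicate)
  vals <- matrix(rlnorm(length(feats) * nrow(design)), length(feats),
                 dimnames = list(feats, design$sample_id))
  ae <- AbundanceExperiment(vals, design)
  pc <- percentOfControl(ae)
  expect_equal(assay(pc), oraclePctControl(vals, design))
  expect_equal(abundanceScale(pc), "pct_of_control")
  # the vehicle-group mean is exactly 100 at every timepoint
  cd <- as.data.frame(colData(pc))
  for (tp in unique(cd$timepoint_h)) {
    veh <- which(cd$treatment == "vehicle" & cd$timepoint_h == tp)
    expect_equal(unname(rowMeans(assay(pc)[, veh, drop = FALSE])),
                 rep(100, length(feats)))
  }
  # a treated value at half the vehicle mean maps to 50
  vm <- mean(vals[1, design$treatment == "vehicle" & design$timepoint_h == 6])
  vals2 <- vals
  vals2[1, design$sample_id == "TNF_6_r1"] <- vm / 2
  got <- percentOfControl(AbundanceExperiment(vals2, design))
  expect_equal(unname(assay(got)[1, "TNF_6_r1"]), 50)
})

test_that("percent of control requires matched vehicle cells", {
  vals <- matrix(1:4, 1, 4,
                 dimnames = list("PI(18:1/18:1)", paste0("s", 1:4)))
  design <- data.frame(sample_id = paste0("s", 1:4),
                       treatment = c("vehicle", "vehicle", "TNF", "TNF"),
                       timepoint_h = c(6, 6, 6, 24), replicate = c(1:2, 1, 1))
  ae <- AbundanceExperiment(vals, design)
  expect_error(percentOfControl(ae), "timepoint 24")
  # zero vehicle mean: missing with warning
  vals2 <- matrix(c(0, 0, 2, 3), 1, 4,
                  dimnames = list("PI(18:1/18:1)", paste0("s", 1:4)))
  design$timepoint_h <- 6
  design$replicate <- c(1, 2, 1, 2)
  expect_warning(pc <- percentOfControl(AbundanceExperiment(vals2, design)),
                 "zero vehicle mean")
  expect_true(all(is.na(assay(pc))))
})

test_that("uptake QC is boundary-inclusive at the configured increase", {
  expect_true(uptakeQC(2.0, 2.6))   # exactly +30 percent
  expect_false(uptakeQC(2.0, 2.5))  # +25 percent
  expect_true(uptakeQC(2.0, 4.0))   # +100 percent
  expect_false(uptakeQC(2.0, 1.0))  # depletion never passes
  expect_true(uptakeQC(2.0, 2.2, threshold = 10))
  expect_error(uptakeQC(0, 1), "positive")
})
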