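profilesFixture <- function(nFeat = 10, nCells = 8, seed = 51) {
  set.seed(seed)
  m <- matrix(rnorm(nFeat * nCells), nFeat, nCells,
              dimnames = list(randomLipidNames(nFeat, "PI"),
                              paste0("cell", seq_len(nCells))))
  m
}

test_that("mean profiles equal the group-by mean, deterministically ordered", {
  feats <- randomLipidNames(5, "PI")
  design <- expand.grid(replicate = 1:2, timepoint_h = c(6, 24),
                        treatment = c("vehicle", "TNF", "STS"),
                        stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$treatment, "_", design$timepoint_h,
                             "_r", design$replicate)
  set.seed(52)
  vals <- matrix(rlnorm(5 * nrow(design)), 5,
                 dimnames = list(feats, design$sample_id))
  ae <- AbundanceExperiment(vals, design)
  prof <- meanProfiles(ae)
  # brute-force group-by mean
  for (i in seq_len(nrow(design) / 2)) {
    cells <- attr(prof, "cells")
    idx <- which(design$treatment == cells$treatment[i] &
                 design$timepoint_h == cells$timepoint_h[i])
    expect_equal(unname(prof[, i]), unname(rowMeans(vals[, idx])))
  }
  # vehicle cells come first, timepoints ascending
  expect_equal(colnames(prof), c("vehicle_6h", "vehicle_24h", "TNF_6h",
                                 "TNF_24h", "STS_6h", "STS_24h"))
  # replicates {4, 6} average to 5; a single replicate is its own mean
  v2 <- matrix(c(4, 6, 3), 1, 3, dimnames = list("PI(18:1/18:1)",
                                                 c("a", "b", "c")))
  d2 <- data.frame(sample_id = c("a", "b", "c"),
                   treatment = c("TNF", "TNF", "vehicle"),
                   timepoint_h = 6, replicate = c(1, 2, 1))
  p2 <- meanProfiles(AbundanceExperiment(v2, d2))
  expect_equal(colnames(p2), c("TNF_6h", "vehicle_6h"))
  expect_equal(unname(p2[1, ]), c(5, 3))
})

test_that("pearsonR matches the direct formula and guards its domain", {
  expect_equal(pearsonR(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearsonR(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(53)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(pearsonR(x, y), oraclePearson(x, y), tolerance = 1e-12)
  }
  expect_warning(r <- pearsonR(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(pearsonR(c(1, 2), c(1, 2)), "at least 3")
})

test_that("network edges equal the all-pairs brute-force oracle", {
  for (seed in c(61, 62, 63)) {
    prof <- profilesFixture(nFeat = 12, nCells = 6, seed = seed)
    net <- buildNetwork(prof, edgeThreshold = 0.3)
    e <- networkEdges(net)
    got <- sort(paste(e$from, e$to, sep = "|"))
    expect_equal(got, oracleNetworkEdges(prof, 0.3))
    expect_true(all(e$r > 0.3))
    expect_setequal(networkNodes(net), rownames(prof))
  }
})

test_that("edge threshold is strict and monotone", {
  # two identical profiles give one edge at r = 1
  prof <- matrix(rep(c(1, 2, 3, 5), 2), 2, 4, byrow = TRUE,
                 dimnames = list(c("PI(18:1/18:1)", "PI(16:0/18:1)"), NULL))
  net <- buildNetwork(prof)
  expect_equal(nrow(networkEdges(net)), 1L)
  expect_equal(networkEdges(net)$r, 1.0)

  # an r computed exactly at the threshold yields no edge (strict >)
  set.seed(64)
  prof2 <- matrix(rnorm(20), 2, 10,
                  dimnames = list(c("PI(18:1/18:1)", "PI(16:0/18:1)"), NULL))
  prof2[2, ] <- prof2[1, ] + rnorm(10, 0, 0.4)  # strongly positive r
  rExact <- networkEdges(buildNetwork(prof2, edgeThreshold = 0.1))$r
  expect_true(rExact > 0.1 && rExact < 1)
  expect_equal(nrow(networkEdges(buildNetwork(prof2, edgeThreshold = rExact))), 0L)

  # raising the threshold never adds edges
  prof3 <- profilesFixture(nFeat = 10, nCells = 6, seed = 65)
  eLow <- networkEdges(buildNetwork(prof3, edgeThreshold = 0.2))
  eHigh <- networkEdges(buildNetwork(prof3, edgeThreshold = 0.6))
  expect_true(all(paste(eHigh$from, eHigh$to) %in% paste(eLow$from, eLow$to)))
})

test_that("edge set is invariant to feature ordering", {
  prof <- profilesFixture(nFeat = 8, nCells = 6, seed = 66)
  net1 <- buildNetwork(prof, edgeThreshold = 0.3)
  perm <- sample(nrow(prof))
  net2 <- buildNetwork(prof[perm, ], edgeThreshold = 0.3)
  key <- function(n) sort(paste(networkEdges(n)$from, networkEdges(n)$to))
  expect_equal(key(net1), key(net2))
})

test_that("clusters are connected components, matching union-find", {
  # edgeless network: three singletons
  prof <- matrix(c(1, 2, 3, 3, -1, 9, 5, 5, -7), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  netE <- new("CoregulationNetwork", nodes = c("a", "b", "c"),
              edges = data.frame(from = character(), to = character(),
                                 r = numeric()),
              edgeThreshold = 0.7,
              annotations = data.frame(species = character(),
                                       r_readout = numeric(),
                                       flagged = logical()))
  expect_equal(networkClusters(netE), list("a", "b", "c"))

  # path a-b, b-c is one transitive cluster
  netP <- new("CoregulationNetwork", nodes = c("a", "b", "c"),
              edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                 r = c(0.9, 0.8)),
              edgeThreshold = 0.7,
              annotations = netE@annotations)
  expect_equal(networkClusters(netP), list(c("a", "b", "c")))

  # random planted two-block structure matches the union-find oracle
  set.seed(71)
  for (rep in 1:5) {
    prof <- profilesFixture(nFeat = 12, nCells = 6, seed = 70 + rep)
    net <- buildNetwork(prof, edgeThreshold = 0.3)
    expect_equal(networkClusters(net),
                 oracleComponents(networkNodes(net), networkEdges(net)))
  }
})

test_that("readout screen flags strict anti-correlation only", {
  prof <- profilesFixture(nFeat = 6, nCells = 8, seed = 72)
  readout <- rnorm(8)
  # a species tracking -readout (affine) is flagged at r = -1
  prof[1, ] <- 5 - 2 * readout
  # a species tracking +readout is not flagged
  prof[2, ] <- 1 + readout
  ann <- readoutScreen(prof, readout)
  expect_equal(ann$r_readout[1], -1)
  expect_true(ann$flagged[1])
  expect_equal(ann$r_readout[2], 1)
  expect_false(ann$flagged[2])
  # flags equal the correlate-then-threshold oracle
  for (i in seq_len(nrow(prof))) {
    r <- oraclePearson(prof[i, ], readout)
    expect_equal(ann$r_readout[i], r, tolerance = 1e-12)
    expect_equal(ann$flagged[i], r < -0.6)
  }
})

test_that("readout cells must align with profile cells", {
  prof <- profilesFixture(nFeat = 3, nCells = 4, seed = 73)
  readout <- setNames(rnorm(4), paste0("cell", 1:4))
  # named readout may arrive in any order
  a1 <- readoutScreen(prof, readout)
  a2 <- readoutScreen(prof, readout[c(3, 1, 4, 2)])
  expect_equal(a1, a2)
  expect_error(readoutScreen(prof, setNames(rnorm(4), paste0("x", 1:4))),
               "do not match")
  expect_error(readoutScreen(prof, rnorm(3)), "length")
})

test_that("network export is deterministic and round-trips", {
  prof <- profilesFixture(nFeat = 8, nCells = 6, seed = 74)
  net <- buildNetwork(prof, edgeThreshold = 0.3)
  readoutAnnotations(net) <- readoutScreen(prof, rnorm(6))
  sif1 <- tempfile(fileext = ".sif"); gml1 <- tempfile(fileext = ".graphml")
  sif2 <- tempfile(fileext = ".sif"); gml2 <- tempfile(fileext = ".graphml")
  exportNetwork(net, sif = sif1, graphml = gml1)
  exportNetwork(net, sif = sif2, graphml = gml2)
  expect_identical(readLines(sif1), readLines(sif2))
  expect_identical(readLines(gml1), readLines(gml2))

  # SIF: one line per edge plus bare lines for isolates
  lines <- readLines(sif1)
  edgeLines <- grep(" coreg ", lines, value = TRUE)
  expect_equal(length(edgeLines), nrow(networkEdges(net)))
  expect_equal(length(lines) - length(edgeLines),
               sum(!networkNodes(net) %in%
                     unlist(networkEdges(net)[, c("from", "to")])))

  # GraphML read-back reproduces the edge set
  g <- igraph::read_graph(gml1, format = "graphml")
  el <- igraph::as_edgelist(g)
  gotKeys <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                        sep = "|"))
  e <- networkEdges(net)
  expect_equal(gotKeys, sort(paste(e$from, e$to, sep = "|")))
  expect_equal(sort(igraph::V(g)$name), sort(networkNodes(net)))
})

test_that("one-edge network exports a single SIF edge line", {
  net <- new("CoregulationNetwork", nodes = c("a", "b"),
             edges = data.frame(from = "a", to = "b", r = 0.95),
             edgeThreshold = 0.7,
             annotations = data.frame(species = character(),
                                      r_readout = numeric(),
                                      flagged = logical()))
  f <- tempfile(fileext = ".sif")
  exportNetwork(net, sif = f)
  expect_equal(readLines(f), "a coreg b")
})
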