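# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, textbook formulas) and
# share no code with the package implementation.

# textbook pooled-variance two-sided Student t
oraclePooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# explicit covariance / variance Pearson formula
oraclePearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# the two-stage linear step-up definition, coded step by step:
# stage 1 = linear step-up at q' = q/(1+q); stage 2 = linear step-up at
# q'' = q' * m / m0 with m0 = m - r1. Returns rejection flags in input order.
oracleBkyFlags <- function(p, q) {
  m <- length(p)
  stepUp <- function(pvec, alpha) {
    ord <- order(pvec)
    ps <- pvec[ord]
    r <- 0L
    for (j in seq_len(m)) if (ps[j] <= j * alpha / m) r <- j
    rej <- rep(FALSE, m)
    if (r > 0L) rej[ord[seq_len(r)]] <- TRUE
    rej
  }
  qp <- q / (1 + q)
  stage1 <- stepUp(p, qp)
  r1 <- sum(stage1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  stepUp(p, qp * m / (m - r1))
}

# per-cell proportion normalisation by explicit loops
oracleProportions <- function(values, classes) {
  out <- values
  for (s in seq_len(ncol(values))) {
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      tot <- sum(values[idx, s])
      for (i in idx) out[i, s] <- values[i, s] * 100 / tot
    }
  }
  out
}

# percent-of-control by explicit loops over features and timepoints
oraclePctControl <- function(values, design, vehicle = "vehicle") {
  out <- values
  for (tp in unique(design$timepoint_h)) {
    veh <- which(design$treatment == vehicle & design$timepoint_h == tp)
    cols <- which(design$timepoint_h == tp)
    for (f in seq_len(nrow(values))) {
      vm <- mean(values[f, veh])
      for (s in cols) out[f, s] <- values[f, s] * 100 / vm
    }
  }
  out
}

# all-pairs thresholded network as a sorted "from|to" edge-key vector
oracleNetworkEdges <- function(profiles, threshold) {
  keys <- character()
  n <- nrow(profiles)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- oraclePearson(profiles[i, ], profiles[j, ])
      if (r > threshold) {
        a <- sort(c(rownames(profiles)[i], rownames(profiles)[j]))
        keys <- c(keys, paste(a[1], a[2], sep = "|"))
      }
    }
  }
  sort(keys)
}

# connected components by union-find
oracleComponents <- function(nodes, edges) {
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(match(edges$from[k], nodes))
      rj <- find(match(edges$to[k], nodes))
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp <- split(nodes, roots)
  comp <- lapply(comp, sort)
  unname(comp[order(-lengths(comp), vapply(comp, `[`, character(1), 1))])
}

# small valid lipid design + experiment builder for unit tests
makeLipidExperiment <- function(values, treatments, timepoints, replicates,
                                annotate = TRUE) {
  design <- data.frame(
    sample_id = colnames(values),
    treatment = treatments,
    timepoint_h = timepoints,
    replicate = replicates,
    stringsAsFactors = FALSE)
  AbundanceExperiment(values, design, annotateLipids = annotate)
}

randomLipidNames <- function(n, class = "PI") {
  chains <- c("16:0", "16:1", "18:0", "18:1", "18:2", "20:4", "22:6")
  combos <- expand.grid(a = chains, b = chains, stringsAsFactors = FALSE)
  combos <- combos[as.integer(factor(combos$a, chains)) <=
                   as.integer(factor(combos$b, chains)), ]
  stopifnot(n <= nrow(combos))
  paste0(class, "(", combos$a[seq_len(n)], "/", combos$b[seq_len(n)], ")")
}
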