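# Independent brute-force oracles and small fixture builders.

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf = no
# edge); independent of the package's Dijkstra route.
fwOracle <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

lengthsFromWeights <- function(w) {
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

nodalEffOracle <- function(w) {
  d <- fwOracle(lengthsFromWeights(w))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(w) - 1)
}

localEffOracle <- function(w) {
  vapply(seq_len(nrow(w)), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    d <- fwOracle(lengthsFromWeights(w[nb, nb, drop = FALSE]))
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

clusteringOracle <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    acc <- 0
    for (j in seq_len(n))
      for (h in seq_len(n))
        if (j != i && h != i && j != h)
          acc <- acc + wh[i, j] * wh[i, h] * wh[j, h]
    acc / (k * (k - 1))
  }, numeric(1))
}

# random connected-ish symmetric weight matrix, weights in (0, 1]
randomWeightGraph <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < density]
  w[on] <- runif(length(on), 0.05, 1)
  w + t(w)
}

unitComplete <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}

starGraph <- function(nLeaves = 3) {
  w <- matrix(0, nLeaves + 1, nLeaves + 1)
  w[1, -1] <- w[-1, 1] <- 1
  w
}

# build a ConnectomeSet from a named list of sc matrices; distances are a
# constant-pattern matrix matching the union support
makeTinySet <- function(scList, fi = NULL, ages = NULL) {
  n <- nrow(scList[[1]])
  nSub <- length(scList)
  if (is.null(names(scList))) names(scList) <- sprintf("T%02d", seq_len(nSub))
  if (is.null(ages)) ages <- seq(25, 75, length.out = nSub)
  if (is.null(fi)) fi <- rep(30, nSub)
  behavior <- data.frame(id = names(scList), age = ages,
                         sex = rep(c("F", "M"), length.out = nSub),
                         fluid_intelligence = fi,
                         group = ifelse(ages < 50, "YA", "OA"),
                         missing_behavior = is.na(fi),
                         stringsAsFactors = FALSE)
  regions <- data.frame(id = seq_len(n),
                        label = sprintf("r%02d", seq_len(n)),
                        hemisphere = rep(c("L", "R"),
                                         each = ceiling(n / 2))[seq_len(n)],
                        subcortical = 0L, stringsAsFactors = FALSE)
  distList <- lapply(scList, function(m) (m > 0) * 10)
  ConnectomeSet(scList, distList, regions, behavior)
}

# The 12-subject QC fixture: 8 regions; base edges (ring + four spokes)
# present everywhere; edge e1 in exactly 6/12 subjects (boundary
# inclusive), e2 in 7/12, e3 in 5/12 (below threshold); subject S10 lacks
# behavior, S11 has region 8 isolated, S12 is a complete-graph density
# outlier. Expected: mask = base + e1 + e2; exclusions = exactly those
# three subjects with their reasons.
qcFixture <- function() {
  n <- 8
  pair <- function(i, j) { m <- matrix(0, n, n); m[i, j] <- m[j, i] <- 1; m }
  ring <- Reduce(`+`, Map(pair, 1:8, c(2:8, 1)))
  spokes <- pair(1, 3) + pair(2, 4) + pair(3, 5) + pair(4, 6)
  base <- ring + spokes
  e1 <- pair(5, 7)   # in S1-S3, S10, S11, S12: exactly 6/12 (boundary)
  e2 <- pair(6, 1)   # in S4-S9 and S12: 7/12
  e3 <- pair(2, 5)   # in S1-S4 and S12: 5/12, below threshold
  ids <- sprintf("S%02d", 1:12)
  scList <- list()
  for (k in 1:9) {
    m <- base
    if (k <= 3) m <- m + e1 else m <- m + e2
    if (k <= 4) m <- m + e3
    scList[[ids[k]]] <- m * 0.5
  }
  scList[["S10"]] <- (base + e1) * 0.5                # missing behavior
  iso <- base; iso[8, ] <- 0; iso[, 8] <- 0           # region 8 isolated
  scList[["S11"]] <- (iso + e1) * 0.5
  full <- matrix(1, n, n); diag(full) <- 0            # density outlier
  scList[["S12"]] <- full * 0.5
  fi <- c(rnorm(9, 30, 3), NA, 30, 30)
  set <- makeTinySet(scList, fi = fi)
  maskExpected <- (base + e1 + e2) > 0
  list(set = set, maskExpected = maskExpected,
       baseEdges = base, e1 = e1, e2 = e2, e3 = e3)
}

# map full-triangle edge indices (truth support) to columns of a
# plsFromEdges design, given the set it was built from
supportColumns <- function(set, supportIdx) {
  present <- rowSums(SummarizedExperiment::assay(set, "sc") > 0) > 0
  match(supportIdx, which(present))
}
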