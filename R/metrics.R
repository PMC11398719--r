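# Weighted graph measures on streamline-probability matrices. Edge
# "length" is the inverse weight, so with probabilities in (0, 1] every
# finite path length is >= 1 and all efficiencies land in [0, 1].

asWeightMatrix <- function(w) {
  if (is(w, "ConnectomeSet")) stop("pass a single subject matrix, not a set")
  if (min(w) < 0) stop("negative weights are not allowed")
  checkSymmetricNonneg(w, "weight matrix")
  w
}

#' All-pairs weighted shortest path lengths
#'
#' Edge lengths are inverse weights (1/w for w > 0, infinite otherwise);
#' path lengths are computed by Dijkstra's algorithm from every source.
#' Disconnected pairs get \code{Inf}; the diagonal is 0.
#'
#' @param w Symmetric nonnegative weight matrix with zero diagonal.
#' @return Matrix of shortest path lengths.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
#' w[2, 3] <- w[3, 2] <- 1; w[1, 3] <- w[3, 1] <- 0.25
#' shortestPathLengths(w)[1, 3]  # 2: the two-hop route beats 1/0.25
#' @export
shortestPathLengths <- function(w) {
  w <- asWeightMatrix(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Nodal efficiency
#'
#' Mean inverse weighted shortest path length from each region to all
#' others: \code{E_nodal[j] = mean_i(1 / l_ij)} over the other N - 1
#' regions, with 1/Inf taken as 0 for disconnected pairs. High for hub
#' regions closely connected to the rest of the network.
#'
#' @param w Symmetric nonnegative weight matrix (N >= 2).
#' @return Numeric vector of length N.
#' @export
nodalEfficiency <- function(w) {
  stopifnot(nrow(w) >= 2)
  d <- shortestPathLengths(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(w) - 1)
}

#' Local efficiency
#'
#' For each region i, take the subgraph induced by i's neighbors with i
#' itself removed, and average the inverse shortest path lengths computed
#' within that subgraph (original weights, no re-weighting by the stem
#' edges). Regions with fewer than two neighbors score 0. A measure of
#' fault tolerance: how well a region's neighborhood communicates without
#' it.
#'
#' @param w Symmetric nonnegative weight matrix (N >= 3).
#' @return Numeric vector of length N.
#' @export
localEfficiency <- function(w) {
  w <- asWeightMatrix(w)
  stopifnot(nrow(w) >= 3)
  vapply(seq_len(nrow(w)), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    dsub <- shortestPathLengths(w[nb, nb, drop = FALSE])
    inv <- 1 / dsub
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity on weights rescaled by the maximum
#' weight: \code{C_i = sum_jh (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))}
#' with binary degree k. Regions with fewer than two neighbors score 0.
#'
#' @param w Symmetric nonnegative weight matrix.
#' @return Numeric vector of per-region clustering coefficients.
#' @export
weightedClustering <- function(w) {
  w <- asWeightMatrix(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, nrow(w)))
  w3 <- (w / mx)^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(w > 0)
  ifelse(k < 2, 0, tri / (k * (k - 1)))
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal weighted shortest path lengths;
#' disconnected pairs are omitted.
#'
#' @param w Symmetric nonnegative weight matrix (N >= 3).
#' @return Scalar.
#' @export
characteristicPathLength <- function(w) {
  d <- shortestPathLengths(w)
  off <- d[upper.tri(d) | lower.tri(d)]
  mean(off[is.finite(off)])
}

# one degree-preserving Maslov-Sneppen null: rewire the binary topology,
# then shuffle the observed weight multiset onto the rewired edges;
# nSwaps == 0 returns the graph (and weights) untouched
rewiredNull <- function(w, nSwaps) {
  if (nSwaps == 0) return(w)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  weights <- w[upper.tri(w)][w[upper.tri(w)] > 0]
  for (try in seq_len(10)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = nSwaps))
    if (igraph::is_connected(gr)) break
    if (try == 10) {
      warning("rewired null disconnected; using its largest component")
      comp <- igraph::components(gr)
      gr <- igraph::induced_subgraph(
        gr, which(comp$membership == which.max(comp$csize)))
    }
  }
  a <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
  out <- matrix(0, nrow(a), ncol(a))
  idx <- which(upper.tri(a) & a > 0)
  out[idx] <- sample(weights, length(idx),
                     replace = length(idx) > length(weights))
  out + t(out)
}

#' Small-worldness
#'
#' The ratio of ratios \code{sigma = (C / C_null) / (L / L_null)}, where C
#' is the mean Onnela clustering coefficient, L the characteristic path
#' length, and the null values are means over \code{nNull} degree-
#' preserving Maslov-Sneppen rewirings with the weight multiset shuffled
#' onto the rewired topology. A small-world network has sigma > 1: more
#' clustered than random at comparable path length.
#'
#' @param w Symmetric nonnegative weight matrix of a connected graph.
#' @param nNull Number of rewired null networks, default 10.
#' @param nSwapsPerEdge Rewiring attempts per edge (default 10); 0 keeps
#'   the network untouched, making sigma exactly 1.
#' @param seed Optional integer seed.
#' @return Scalar sigma.
#' @export
smallWorldness <- function(w, nNull = 10, nSwapsPerEdge = 10, seed = NULL) {
  w <- asWeightMatrix(w)
  stopifnot(nNull >= 1)
  withSeed(seed)
  C <- mean(weightedClustering(w))
  L <- characteristicPathLength(w)
  nE <- sum(w[upper.tri(w)] > 0)
  nulls <- lapply(seq_len(nNull), function(k)
    rewiredNull(w, nSwapsPerEdge * nE))
  Cn <- mean(vapply(nulls, function(x) mean(weightedClustering(x)),
                    numeric(1)))
  Ln <- mean(vapply(nulls, characteristicPathLength, numeric(1)))
  (C / Cn) / (L / Ln)
}

#' Per-subject graph metrics table
#'
#' Computes every graph measure used downstream for each subject of a
#' (QC'd) [ConnectomeSet-class]: region-wise nodal efficiency
#' (\code{ne_*}), local efficiency (\code{le_*}), clustering
#' (\code{cc_*}) and degree (\code{deg_*}) in wide form, plus whole-brain
#' characteristic path length, small-worldness, SC total (sum of
#' streamline probabilities over undirected pairs) and mean SC distance
#' (mean streamline distance over connected pairs).
#'
#' @param set A [ConnectomeSet-class].
#' @param nNull Null networks per subject for small-worldness.
#' @param seed Optional seed (per-subject seeds are derived from it).
#' @return data.frame, one row per subject; behavior columns included.
#' @export
computeGraphMetrics <- function(set, nNull = 10, seed = NULL) {
  stopifnot(is(set, "ConnectomeSet"))
  ids <- subjectIds(set)
  n <- nRegions(set)
  rl <- sprintf("%03d", regionInfo(set)$id)
  rows <- lapply(seq_along(ids), function(s) {
    w <- scMatrix(set, ids[s])
    dm <- distMatrix(set, ids[s])
    ne <- nodalEfficiency(w)
    le <- localEfficiency(w)
    cc <- weightedClustering(w)
    deg <- rowSums(w > 0)
    up <- upper.tri(w)
    sw <- smallWorldness(w, nNull = nNull,
                         seed = if (is.null(seed)) NULL else seed + s)
    out <- c(char_path_length = characteristicPathLength(w),
             small_worldness = sw,
             sc_total = sum(w[up]),
             mean_sc_distance = mean(dm[up][w[up] > 0]),
             setNames(ne, paste0("ne_", rl)),
             setNames(le, paste0("le_", rl)),
             setNames(cc, paste0("cc_", rl)),
             setNames(deg, paste0("deg_", rl)))
    out
  })
  mat <- do.call(rbind, rows)
  cbind(cohort(set), as.data.frame(mat))
}

#' Whole-brain summaries
#'
#' SC total (sum of streamline probabilities over retained undirected
#' pairs) and mean SC distance (mean streamline distance over pairs with a
#' connection) per subject.
#'
#' @param set A [ConnectomeSet-class].
#' @return data.frame with columns \code{id}, \code{sc_total},
#'   \code{mean_sc_distance}.
#' @export
wholeBrainSummaries <- function(set) {
  sc <- assay(set, "sc")
  di <- assay(set, "dist")
  msd <- vapply(seq_len(ncol(sc)), function(s) {
    nz <- sc[, s] > 0
    if (!any(nz)) return(NA_real_)
    mean(di[nz, s])
  }, numeric(1))
  data.frame(id = subjectIds(set), sc_total = colSums(sc),
             mean_sc_distance = msd, stringsAsFactors = FALSE)
}
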