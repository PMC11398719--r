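triangle <- function(wAB = 1, wBC = 1, wAC = 0.25) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- wAB
  w[2, 3] <- w[3, 2] <- wBC
  w[1, 3] <- w[3, 1] <- wAC
  w
}

test_that("shortest paths take the cheaper multi-hop route", {
  d <- shortestPathLengths(triangle())
  expect_equal(d[1, 3], 2)          # via node 2: 1 + 1 beats 1/0.25 = 4
  expect_equal(d[1, 2], 1)
  expect_equal(unname(diag(d)), rep(0, 3))
  dK <- shortestPathLengths(unitComplete(5))
  expect_equal(dK[upper.tri(dK)], rep(1, 10))
  expect_error(shortestPathLengths(matrix(c(0, -1, -1, 0), 2)),
               "negative|nonnegative")
})

test_that("nodal efficiency matches hand-computed and analytic values", {
  expect_equal(nodalEfficiency(unitComplete(6)), rep(1, 6))
  ne <- nodalEfficiency(triangle())
  expect_equal(ne, c(0.75, 1, 0.75))
  w <- unitComplete(4)
  w[4, ] <- w[, 4] <- 0            # isolate node 4
  expect_equal(nodalEfficiency(w)[4], 0)
})

test_that("local efficiency handles cliques, stars and hubs", {
  expect_equal(localEfficiency(unitComplete(4)), rep(1, 4))
  le <- localEfficiency(starGraph(3))
  expect_equal(le, rep(0, 4))      # hub: disconnected leaves; leaves: k=1
})

test_that("efficiencies match the Floyd-Warshall brute force", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(5:10, 1)
    w <- randomWeightGraph(n, runif(1, 0.3, 0.9))
    expect_equal(nodalEfficiency(w), nodalEffOracle(w), tolerance = 1e-12)
    expect_equal(localEfficiency(w), localEffOracle(w), tolerance = 1e-12)
  }
})

test_that("metrics are permutation-equivariant and monotone in edges", {
  set.seed(72)
  w <- randomWeightGraph(8, 0.5)
  p <- sample(8)
  wp <- w[p, p]
  expect_equal(nodalEfficiency(wp), nodalEfficiency(w)[p],
               tolerance = 1e-12)
  expect_equal(localEfficiency(wp), localEfficiency(w)[p],
               tolerance = 1e-12)
  expect_equal(weightedClustering(wp), weightedClustering(w)[p],
               tolerance = 1e-12)
  # adding an edge never decreases nodal efficiency
  off <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
  ij <- off[1, ]
  w2 <- w
  w2[ij[1], ij[2]] <- w2[ij[2], ij[1]] <- 0.5
  expect_true(all(nodalEfficiency(w2) >= nodalEfficiency(w) - 1e-12))
  # bounded in [0, 1] for weights in (0, 1]
  expect_true(all(nodalEfficiency(w) >= 0 & nodalEfficiency(w) <= 1))
  expect_true(all(localEfficiency(w) >= 0 & localEfficiency(w) <= 1))
})

test_that("clustering is 1 on cliques, 0 on triangle-free graphs", {
  expect_equal(weightedClustering(unitComplete(5)), rep(1, 5))
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_equal(weightedClustering(ring), rep(0, 6))
  set.seed(73)
  w <- randomWeightGraph(8, 0.6)
  expect_equal(weightedClustering(w), clusteringOracle(w),
               tolerance = 1e-12)
})

test_that("small-worldness is 1 against an untouched null and seeded", {
  set.seed(74)
  w <- randomWeightGraph(10, 0.5)
  expect_equal(smallWorldness(w, nNull = 3, nSwapsPerEdge = 0, seed = 1), 1)
  s1 <- smallWorldness(w, nNull = 5, seed = 9)
  s2 <- smallWorldness(w, nNull = 5, seed = 9)
  expect_identical(s1, s2)
  # a ring-with-neighbors lattice is more clustered than its rewired nulls
  n <- 20
  lat <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in 1:2) {
    j <- (i + k - 1) %% n + 1
    lat[i, j] <- lat[j, i] <- 1
  }
  expect_gt(smallWorldness(lat, nNull = 5, seed = 2), 1)
})

test_that("whole-brain summaries sum and average retained pairs", {
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 0.2
  sc[1, 3] <- sc[3, 1] <- 0.3
  di <- matrix(0, 3, 3)
  di[1, 2] <- di[2, 1] <- 10
  di[1, 3] <- di[3, 1] <- 30
  di[2, 3] <- di[3, 2] <- 99       # no sc edge there: must be ignored
  beh <- data.frame(id = "a", age = 30, sex = "F", fluid_intelligence = 30,
                    group = "YA", missing_behavior = FALSE)
  regions <- data.frame(id = 1:3, label = c("r1", "r2", "r3"),
                        hemisphere = c("L", "L", "R"), subcortical = 0L)
  set <- ConnectomeSet(list(a = sc), list(a = di), regions, beh)
  ws <- wholeBrainSummaries(set)
  expect_equal(ws$sc_total, 0.5)
  expect_equal(ws$mean_sc_distance, 20)
  # doubling weights doubles the total, leaves the distance mean alone
  set2 <- ConnectomeSet(list(a = sc * 2), list(a = di), regions, beh)
  ws2 <- wholeBrainSummaries(set2)
  expect_equal(ws2$sc_total, 1)
  expect_equal(ws2$mean_sc_distance, 20)
})

test_that("the per-subject metrics table carries every measure", {
  sim <- simulateCohort(syntheticSpec(nSubjects = 10, nRegions = 10,
                                      seed = 21))
  met <- computeGraphMetrics(sim$set, nNull = 2, seed = 7)
  expect_identical(nrow(met), 10L)
  expect_true(all(c("char_path_length", "small_worldness", "sc_total",
                    "mean_sc_distance") %in% names(met)))
  expect_length(grep("^ne_", names(met)), 10L)
  expect_length(grep("^le_", names(met)), 10L)
  w <- scMatrix(sim$set, subjectIds(sim$set)[2])
  expect_equal(unname(unlist(met[2, grep("^ne_", names(met))])),
               nodalEfficiency(w))
  met2 <- computeGraphMetrics(sim$set, nNull = 2, seed = 7)
  expect_identical(met, met2)
})
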