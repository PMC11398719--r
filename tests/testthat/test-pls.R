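test_that("identical brain and behavior blocks give one perfect LV", {
  set.seed(31)
  y <- rnorm(10)
  m <- plsFit(cbind(y, y), cbind(y, y))
  expect_equal(singularValues(m), c(2, 0), tolerance = 1e-10)
})

test_that("singular values match an eigen-decomposition oracle", {
  set.seed(32)
  X <- matrix(rnorm(18), 6, 3)
  Y <- matrix(rnorm(12), 6, 2)
  m <- plsFit(X, Y)
  R <- cor(Y, X)
  sOracle <- sqrt(sort(eigen(R %*% t(R), symmetric = TRUE)$values,
                       decreasing = TRUE))
  expect_equal(singularValues(m), sOracle, tolerance = 1e-10)
  # reconstruction
  recon <- saliences(m, "behavior") %*% diag(singularValues(m)) %*%
    t(saliences(m, "brain"))
  expect_equal(recon, R, tolerance = 1e-10, ignore_attr = TRUE)
  # orthonormal saliences
  expect_equal(crossprod(saliences(m, "brain")), diag(2),
               tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention: dominant behavior salience positive
  U <- saliences(m, "behavior")
  for (k in 1:2) expect_gt(U[which.max(abs(U[, k])), k], 0)
})

test_that("correlation-based PLS is scale invariant", {
  set.seed(33)
  X <- matrix(rnorm(60), 15, 4)
  Y <- matrix(rnorm(30), 15, 2)
  m1 <- plsFit(X, Y)
  X2 <- X
  X2[, 2] <- X2[, 2] * 1000
  m2 <- plsFit(X2, Y)
  expect_equal(m1@R, m2@R, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(singularValues(m1), singularValues(m2), tolerance = 1e-12)
})

test_that("degenerate inputs are refused", {
  set.seed(34)
  X <- matrix(rnorm(30), 10, 3)
  expect_error(plsFit(X, cbind(rep(1, 10), rnorm(10))), "constant")
  expect_error(plsFit(matrix(1, 10, 3), matrix(rnorm(20), 10, 2)))
  Xz <- cbind(X, 0)
  expect_warning(m <- plsFit(Xz, matrix(rnorm(20), 10, 2)),
                 "zero-variance")
  expect_identical(m@droppedColumns, "x4")
  expect_identical(ncol(m@X), 3L)
})

test_that("permutation p uses the add-one estimator and finds signal", {
  set.seed(35)
  y <- rnorm(12)
  X <- cbind(y + rnorm(12, 0, 0.01), rnorm(12))
  Y <- cbind(y, rnorm(12))
  m <- plsPermutation(plsFit(X, Y), nPerm = 19, seed = 2)
  expect_equal(permPValues(m)[1], 1 / 20)   # nothing beats a near-perfect LV
  expect_gte(min(permPValues(m)), 1 / 20)
  m2 <- plsPermutation(plsFit(X, Y), nPerm = 19, seed = 2)
  expect_identical(permPValues(m), permPValues(m2))
})

test_that("bootstrap ratios separate planted from null variables", {
  sim <- simulateCohort(syntheticSpec(
    nSubjects = 150, nRegions = 16, seed = 36,
    plantedComponents = list(plantedEffect("edge_set", nSupport = 10,
                                           loadingAge = -0.8,
                                           loadingFi = 0.5))))
  set <- applyQC(sim$set)$set
  m <- plsBootstrap(plsFromEdges(set), nBoot = 200, seed = 4)
  cols <- supportColumns(set, sim$truth$supports[[1]])
  bsr <- bootstrapRatios(m)[, 1]
  expect_gt(mean(abs(bsr[cols]) >= 2), 0.85)
  expect_lt(mean(abs(bsr[-cols]) >= 2), 0.15)
  # CIs present for each LV and behavior
  expect_length(m@scoreCorCI, 2L)
  expect_identical(dim(m@scoreCorCI[[1]]), c(2L, 2L))
  # paired-seed stability under a larger bootstrap
  m2 <- plsBootstrap(plsFromEdges(set), nBoot = 400, seed = 4)
  expect_gt(cor(bootstrapRatios(m)[, 1], bootstrapRatios(m2)[, 1]), 0.98)
})

test_that("near-constant columns trigger redraws", {
  set.seed(37)
  X <- cbind(c(1, rep(0, 11)), rnorm(12))
  Y <- cbind(rnorm(12), rnorm(12))
  m <- plsBootstrap(plsFit(X, Y), nBoot = 60, seed = 5)
  expect_gt(m@bootRedraws, 0)
})

test_that("split-half flags a strong LV and not permuted labels", {
  sim <- simulateCohort(syntheticSpec(
    nSubjects = 160, nRegions = 16, seed = 38,
    plantedComponents = list(plantedEffect("edge_set", nSupport = 10,
                                           loadingAge = -0.8,
                                           loadingFi = 0.5))))
  set <- applyQC(sim$set)$set
  m <- plsSplitHalf(plsFromEdges(set), nSplits = 60, seed = 6)
  z <- splitHalfZ(m)
  expect_true(z$reproducible[1])
  expect_gt(z$Zsvec[1], 2 + z$ZsvecNull[1])
  # on noiseless rank-1 data every split agrees almost perfectly
  set.seed(39)
  v <- rnorm(20)
  score <- rnorm(40)
  Xr <- outer(score, v)
  Yr <- cbind(score, score * 0.5 + rnorm(40, 0, 1e-6))
  mr <- plsSplitHalf(plsFit(Xr, Yr), nSplits = 30, seed = 7)
  expect_gt(min(mr@splitDetail$svec[, 1]), 0.999)
  # permuted labels: not reproducible
  perm <- sample(nrow(m@Y))
  mp <- plsSplitHalf(plsFit(m@X, m@Y[perm, ]), nSplits = 60, seed = 8)
  zp <- splitHalfZ(mp)
  expect_false(any(zp$reproducible))
})

test_that("reliable patterns report hubs and hemispheric splits", {
  set.seed(40)
  # 6 regions, edges labelled; build a model and inject known BSRs
  ei <- edgeIndex(6)
  X <- matrix(rnorm(15 * nrow(ei)), 15, nrow(ei))
  Y <- cbind(rnorm(15), rnorm(15))
  m <- plsFit(X, Y, edgeMap = ei)
  regions <- data.frame(id = 1:6, label = sprintf("r%d", 1:6),
                        hemisphere = rep(c("L", "R"), each = 3),
                        subcortical = 0L)
  bsr <- matrix(0, nrow(ei), 2)
  # region 1 participates in 4 selected edges; all within hemisphere L or
  # touching it -- pick the 3 intra-L pairs plus 1-4 and 1-5
  selEdges <- list(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(1, 5))
  for (e in selEdges)
    bsr[which(ei$i == e[1] & ei$j == e[2]), 1] <- 5
  m@BSR <- bsr
  pat <- reliablePattern(m, 1, 2, regions, sign = "positive")
  expect_identical(nrow(pat$variables), 5L)
  expect_identical(pat$hubs, 1L)            # degree 4 > 3
  expect_equal(pat$pctIntraL, 60)
  expect_equal(pat$pctIntraR, 0)
  expect_equal(pat$pctInter, 40)
  expect_equal(pat$pctIntraL + pat$pctIntraR + pat$pctInter, 100)
  # all-intra-L selection
  bsr2 <- matrix(0, nrow(ei), 2)
  for (e in list(c(1, 2), c(1, 3), c(2, 3)))
    bsr2[which(ei$i == e[1] & ei$j == e[2]), 1] <- -4
  m@BSR <- bsr2
  neg <- reliablePattern(m, 1, 2, regions, sign = "negative")
  expect_equal(neg$pctIntraL, 100)
  expect_equal(neg$pctInter, 0)
  # empty selection at a huge threshold is fine; bad threshold is not
  empty <- reliablePattern(m, 1, 1e6, regions)
  expect_identical(nrow(empty$variables), 0L)
  expect_error(reliablePattern(m, 1, 0, regions), "positive")
})
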