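test_that("behavior generation hits the target age-cognition correlation", {
  for (sd in c(11, 12, 13, 14, 15)) {
    b <- generateBehavior(syntheticSpec(nSubjects = 300, seed = sd))
    expect_lte(abs(cor(b$age, b$fluid_intelligence) - (-0.65)), 0.05)
    expect_true(all(b$age >= 18.5 & b$age <= 89))
    expect_identical(b$group, ifelse(b$age < 50, "YA", "OA"))
  }
  b <- generateBehavior(syntheticSpec(nSubjects = 300,
                                      targetAgeFiCorr = -0.99, seed = 1))
  expect_lt(cor(b$age, b$fluid_intelligence), -0.95)
  expect_error(generateBehavior(syntheticSpec(nSubjects = 5)),
               "at least 10")
})

test_that("the generator is deterministic under its seed", {
  spec <- syntheticSpec(nSubjects = 15, nRegions = 12, seed = 42)
  a <- simulateCohort(spec)
  b <- simulateCohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(SummarizedExperiment::assay(a$set, "sc"),
                   SummarizedExperiment::assay(b$set, "sc"))
  expect_identical(SummarizedExperiment::assay(a$set, "dist"),
                   SummarizedExperiment::assay(b$set, "dist"))
})

test_that("generated matrices are symmetric, nonnegative, hollow, bounded", {
  sim <- simulateCohort(syntheticSpec(nSubjects = 12, nRegions = 14,
                                      seed = 8))
  for (id in subjectIds(sim$set)) {
    m <- scMatrix(sim$set, id)
    expect_identical(m, t(m))
    expect_identical(unname(diag(m)), rep(0, 14))
    expect_gte(min(m), 0)
    expect_lte(max(m), 1)
    d <- distMatrix(sim$set, id)
    expect_identical(d, t(d))
    expect_gte(min(d), 0)
  }
})

test_that("zero noise and no planted effects collapse to one template", {
  spec <- syntheticSpec(nSubjects = 10, nRegions = 12, edgeNoiseSd = 0,
                        distNoiseSd = 0, seed = 3)
  sim <- simulateCohort(spec)
  sc <- SummarizedExperiment::assay(sim$set, "sc")
  expect_true(all(sc == sc[, 1]))
})

test_that("planted negative age loading lowers weights with age", {
  spec <- syntheticSpec(nSubjects = 300, nRegions = 16, seed = 5,
                        plantedComponents = list(
                          plantedEffect("edge_set", nSupport = 12,
                                        loadingAge = -0.2,
                                        hemisphericBias = "intra")))
  sim <- simulateCohort(spec)
  sup <- sim$truth$supports[[1]]
  ages <- sim$cohort$age
  mw <- colMeans(SummarizedExperiment::assay(sim$set, "sc")[sup, ])
  expect_lt(cor(ages, mw), 0)
  # doubling the loading strengthens the dependence
  spec2 <- spec
  spec2$plantedComponents[[1]]$loadingAge <- -0.4
  sim2 <- simulateCohort(spec2)
  mw2 <- colMeans(SummarizedExperiment::assay(sim2$set, "sc")[
    sim2$truth$supports[[1]], ])
  expect_gt(abs(cor(sim2$cohort$age, mw2)), abs(cor(ages, mw)))
  # intra bias respected
  ei <- edgeIndex(16)
  hemi <- regionInfo(sim$set)$hemisphere
  expect_true(all(hemi[ei$i[sup]] == hemi[ei$j[sup]]))
})

test_that("region-level planted effects touch the right connections", {
  spec <- syntheticSpec(nSubjects = 12, nRegions = 12, seed = 6,
                        plantedComponents = list(
                          plantedEffect("region_nodal", support = 3,
                                        loadingAge = 0.4)))
  sim <- simulateCohort(spec)
  ei <- edgeIndex(12)
  sup <- sim$truth$supports[[1]]
  expect_true(all(ei$i[sup] == 3 | ei$j[sup] == 3))
  expect_gt(length(sup), 0)
})

test_that("fixtures round-trip losslessly and reproducibly", {
  spec <- syntheticSpec(nSubjects = 10, nRegions = 8, seed = 11)
  sim <- simulateCohort(spec)
  three <- sim$set[, 1:3]           # 3 subjects, 8 regions
  d1 <- file.path(tempdir(), "fx1")
  unlink(d1, recursive = TRUE)
  man <- writeFixture(three, d1, spec = spec)
  expect_length(grep("\\.csv$", man$files), 2 + 6)
  expect_identical(man$seed, 11L)
  expect_error(writeFixture(three, d1), "overwrite")

  back <- loadConnectomes(d1)
  for (id in subjectIds(three)) {
    expect_lt(max(abs(scMatrix(back, id) - scMatrix(three, id))), 1e-12)
    expect_lt(max(abs(distMatrix(back, id) - distMatrix(three, id))),
              1e-12)
  }
  # regeneration from the manifest seed gives byte-identical files
  d2 <- file.path(tempdir(), "fx2")
  unlink(d2, recursive = TRUE)
  writeFixture(simulateCohort(spec)$set[, 1:3], d2, spec = spec)
  for (f in man$files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})
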