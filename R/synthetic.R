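#' Specify a synthetic connectome cohort
#'
#' Describes the study conditions for the synthetic-cohort generator:
#' cohort size, parcellation size, age range, the target age/fluid
#' intelligence correlation, connectome density, edge noise, and any
#' planted latent effects linking brain weights to age and cognition.
#'
#' Defaults emulate a large lifespan aging cohort: roughly 600 adults aged
#' 18.5-89 whose fluid intelligence declines with age at r close to -0.65,
#' with sparse nonnegative connectomes whose weights decay with
#' inter-region distance. The default parcellation is 64 regions (two
#' 32-region synthetic hemispheres) to keep graph computations fast; any
#' even count from 6 up (e.g. 218) is accepted.
#'
#' @param nSubjects Number of subjects (at least 10).
#' @param nRegions Even region count, at least 6; regions are split into
#'   two lateralized blocks acting as hemispheres.
#' @param ageRange Length-2 numeric, years; ages are drawn uniformly.
#' @param targetAgeFiCorr Target Pearson correlation between age and fluid
#'   intelligence, in (-1, 0).
#' @param baseDensity Fraction of undirected region pairs retained in the
#'   group template, in (0, 1].
#' @param edgeNoiseSd SD of per-subject log-normal edge noise (log scale).
#' @param distNoiseSd SD of per-subject log-normal jitter on streamline
#'   distances, emulating subject-specific streamline curvature; 0 gives
#'   every subject the shared Euclidean distances.
#' @param plantedComponents List of [plantedEffect()] objects.
#' @param seed Integer seed controlling the whole cohort.
#' @return A \code{syntheticSpec} list.
#' @examples
#' spec <- syntheticSpec(nSubjects = 50, nRegions = 16, seed = 7)
#' @export
syntheticSpec <- function(nSubjects = 600, nRegions = 64,
                          ageRange = c(18.5, 89),
                          targetAgeFiCorr = -0.65,
                          baseDensity = 0.35, edgeNoiseSd = 0.3,
                          distNoiseSd = 0.05,
                          plantedComponents = list(), seed = 1) {
  stopifnot(length(ageRange) == 2, ageRange[1] < ageRange[2],
            ageRange[1] > 0)
  if (nRegions < 6 || nRegions %% 2 != 0)
    stop("nRegions must be even and at least 6")
  if (targetAgeFiCorr <= -1 || targetAgeFiCorr >= 0)
    stop("targetAgeFiCorr must lie in (-1, 0)")
  if (baseDensity <= 0 || baseDensity > 1)
    stop("baseDensity must lie in (0, 1]")
  if (edgeNoiseSd < 0) stop("edgeNoiseSd must be nonnegative")
  if (distNoiseSd < 0) stop("distNoiseSd must be nonnegative")
  for (pc in plantedComponents)
    if (!inherits(pc, "plantedEffect")) stop("plantedComponents must be plantedEffect objects")
  structure(list(nSubjects = as.integer(nSubjects),
                 nRegions = as.integer(nRegions),
                 ageRange = as.numeric(ageRange),
                 targetAgeFiCorr = targetAgeFiCorr,
                 baseDensity = baseDensity, edgeNoiseSd = edgeNoiseSd,
                 distNoiseSd = distNoiseSd,
                 plantedComponents = plantedComponents,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Planted latent brain-behavior effect
#'
#' A multiplicative effect applied on the log-weight scale to a set of
#' connections (or the connections of a set of regions), with loadings on
#' standardized age and on the age-residualized component of fluid
#' intelligence. Log-scale application keeps streamline probabilities
#' nonnegative.
#'
#' @param kind \code{"edge_set"} (support indexes undirected edges in
#'   [edgeIndex()] order), \code{"region_nodal"} (all connections incident
#'   to the support regions) or \code{"region_local"} (connections among
#'   each support region's template neighbors).
#' @param support Integer indices; \code{NULL} lets the generator pick
#'   \code{nSupport} template edges (edge_set mode) honoring
#'   \code{hemisphericBias}.
#' @param loadingAge Log-weight change per SD of age.
#' @param loadingFi Log-weight change per SD of age-residualized cognition.
#' @param hemisphericBias \code{"intra"}, \code{"inter"} or \code{"none"};
#'   constrains auto-picked supports.
#' @param nSupport Number of edges to auto-pick when \code{support} is NULL.
#' @return A \code{plantedEffect} list.
#' @export
plantedEffect <- function(kind = c("edge_set", "region_nodal", "region_local"),
                          support = NULL, loadingAge = 0, loadingFi = 0,
                          hemisphericBias = c("none", "intra", "inter"),
                          nSupport = 120) {
  kind <- match.arg(kind)
  hemisphericBias <- match.arg(hemisphericBias)
  if (!is.null(support)) {
    support <- as.integer(support)
    if (!length(support) || any(support < 1))
      stop("support must be non-empty positive indices")
  }
  structure(list(kind = kind, support = support, loadingAge = loadingAge,
                 loadingFi = loadingFi, hemisphericBias = hemisphericBias,
                 nSupport = as.integer(nSupport)),
            class = "plantedEffect")
}

#' Default planted component for recovery experiments
#'
#' One intrahemispheric edge-set component whose connections weaken with
#' age and strengthen with age-residualized fluid intelligence. Strong
#' enough (relative to the default edge noise) that behavioral PLS should
#' recover its support.
#' @return A [plantedEffect()].
#' @export
defaultPlantedEffect <- function() {
  plantedEffect("edge_set", support = NULL, loadingAge = -0.6,
                loadingFi = 0.45, hemisphericBias = "intra", nSupport = 120)
}

#' Generate the behavior table of a synthetic cohort
#'
#' Ages are uniform on the spec's range; sex is balanced Bernoulli(1/2);
#' fluid intelligence is built as
#' \code{fi = rho * z(age) + sqrt(1 - rho^2) * z(noise)} on a Cattell-like
#' scale (mean 33, SD 6.5), with the noise orthogonalized against age in
#' sample so the realized Pearson correlation equals the target.
#'
#' @param spec A [syntheticSpec()].
#' @return A behavior data.frame with columns \code{id}, \code{age},
#'   \code{sex}, \code{fluid_intelligence}, \code{group} (YA below age 50,
#'   OA otherwise), \code{missing_behavior}.
#' @examples
#' b <- generateBehavior(syntheticSpec(nSubjects = 300, seed = 2))
#' cor(b$age, b$fluid_intelligence)
#' @export
generateBehavior <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  n <- spec$nSubjects
  if (n < 10) stop("nSubjects must be at least 10 for correlation calibration")
  withSeed(spec$seed)
  age <- sort(runif(n, spec$ageRange[1], spec$ageRange[2]))
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "M", "F")
  rho <- spec$targetAgeFiCorr
  za <- zscore(age)
  eps <- rnorm(n)
  eps <- eps - za * sum(eps * za) / sum(za * za)  # orthogonalize in sample
  fiz <- rho * za + sqrt(1 - rho^2) * zscore(eps)
  data.frame(id = sprintf("S%04d", seq_len(n)), age = age, sex = sex,
             fluid_intelligence = 33 + 6.5 * fiz,
             group = ifelse(age < 50, "YA", "OA"),
             missing_behavior = FALSE, stringsAsFactors = FALSE)
}

# resolve a planted effect to the edge indices (into the full upper
# triangle) it touches, given the template mask and region layout
resolveSupport <- function(effect, maskVec, ei, hemi, template) {
  maskedIdx <- which(maskVec)
  intra <- hemi[ei$i] == hemi[ei$j]
  if (effect$kind == "edge_set") {
    if (!is.null(effect$support)) {
      if (max(effect$support) > length(maskVec))
        stop("planted support outside matrix bounds")
      return(intersect(effect$support, maskedIdx))
    }
    pool <- switch(effect$hemisphericBias,
                   intra = maskedIdx[intra[maskedIdx]],
                   inter = maskedIdx[!intra[maskedIdx]],
                   none = maskedIdx)
    if (length(pool) < effect$nSupport)
      stop("not enough template edges to place the planted component")
    return(sort(sample(pool, effect$nSupport)))
  }
  if (is.null(effect$support))
    stop("region-level planted effects need an explicit region support")
  nReg <- length(hemi)
  if (max(effect$support) > nReg)
    stop("planted support outside matrix bounds")
  if (effect$kind == "region_nodal") {
    touch <- (ei$i %in% effect$support) | (ei$j %in% effect$support)
    return(maskedIdx[touch[maskedIdx]])
  }
  # region_local: edges among each support region's template neighbors
  adj <- edgeMatrix(as.numeric(maskVec), nReg)
  idx <- integer(0)
  for (r in effect$support) {
    nb <- setdiff(which(adj[r, ] > 0), r)
    touch <- (ei$i %in% nb) & (ei$j %in% nb)
    idx <- c(idx, maskedIdx[touch[maskedIdx]])
  }
  sort(unique(idx))
}

#' Generate synthetic connectomes with planted structure
#'
#' Places regions at random 3D coordinates in two lateralized blocks,
#' builds a distance-decay group template \code{exp(-d/lambda)} (lambda =
#' 30 mm) sparsified to the spec's density, then derives each subject's
#' weights as template x lognormal noise x planted multiplicative effects,
#' globally rescaled so the maximum weight is 1. Distances are Euclidean
#' distances on the shared coordinates, zeroed where no connection exists.
#' A disconnected template triggers a warning and a redraw of coordinates
#' (at most 10 attempts).
#'
#' @param spec A [syntheticSpec()].
#' @param behavior Behavior table from [generateBehavior()].
#' @return List with elements \code{set} (a [ConnectomeSet-class]) and
#'   \code{truth} (ground truth: support masks, loadings, latent cognition
#'   residual, template and coordinates).
#' @export
generateConnectomes <- function(spec, behavior) {
  stopifnot(inherits(spec, "syntheticSpec"))
  n <- spec$nRegions
  nSub <- nrow(behavior)
  withSeed(spec$seed + 1000L)
  ei <- edgeIndex(n)
  nPair <- nrow(ei)
  half <- n %/% 2
  hemi <- rep(c("L", "R"), each = half)
  for (attempt in seq_len(10)) {
    coords <- cbind(
      x = c(runif(half, -70, -15), runif(half, 15, 70)),
      y = runif(n, -60, 60), z = runif(n, -40, 50))
    D <- as.matrix(stats::dist(coords))
    template <- exp(-D / 30)
    diag(template) <- 0
    tv <- edgeVector(template)
    keep <- round(spec$baseDensity * nPair)
    maskVec <- rep(FALSE, nPair)
    maskVec[order(tv, decreasing = TRUE)[seq_len(keep)]] <- TRUE
    g <- igraph::graph_from_adjacency_matrix(
      edgeMatrix(as.numeric(maskVec), n) > 0, mode = "undirected")
    if (igraph::is_connected(g)) break
    if (attempt == 10)
      stop("template graph disconnected after 10 attempts; raise baseDensity")
    warning("disconnected template graph; redrawing coordinates")
  }
  supports <- lapply(spec$plantedComponents, resolveSupport,
                     maskVec = maskVec, ei = ei, hemi = hemi,
                     template = template)
  za <- zscore(behavior$age)
  fires <- zscore(residuals(lm(behavior$fluid_intelligence ~ behavior$age)))
  logt <- ifelse(maskVec, log(tv), -Inf)
  scv <- matrix(0, nPair, nSub)
  for (s in seq_len(nSub)) {
    lw <- logt
    if (spec$edgeNoiseSd > 0)
      lw[maskVec] <- lw[maskVec] + rnorm(sum(maskVec), 0, spec$edgeNoiseSd)
    for (k in seq_along(supports)) {
      eff <- spec$plantedComponents[[k]]
      lw[supports[[k]]] <- lw[supports[[k]]] +
        eff$loadingAge * za[s] + eff$loadingFi * fires[s]
    }
    scv[, s] <- ifelse(is.finite(lw), exp(lw), 0)
  }
  scv <- scv / max(scv)
  dv0 <- edgeVector(D) * as.numeric(maskVec)
  dvm <- matrix(dv0, nPair, nSub)
  if (spec$distNoiseSd > 0)
    dvm[maskVec, ] <- dvm[maskVec, ] *
      exp(matrix(rnorm(sum(maskVec) * nSub, 0, spec$distNoiseSd),
                 sum(maskVec), nSub))
  nSubc <- max(1L, round(0.08 * half))
  regions <- data.frame(
    id = seq_len(n),
    label = sprintf("%s_region%03d", hemi, seq_len(n)),
    hemisphere = hemi,
    subcortical = as.integer(seq_len(n) %% half <= nSubc & seq_len(n) %% half > 0),
    stringsAsFactors = FALSE)
  ids <- as.character(behavior$id)
  scl <- lapply(seq_len(nSub), function(s) edgeMatrix(scv[, s], n))
  dil <- lapply(seq_len(nSub), function(s) edgeMatrix(dvm[, s], n))
  names(scl) <- names(dil) <- ids
  set <- ConnectomeSet(scl, dil, regions, behavior)
  truth <- list(maskVec = maskVec, supports = supports,
                components = spec$plantedComponents,
                cognitionResidual = fires, ageZ = za,
                coords = coords, templateVec = tv)
  list(set = set, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: [generateBehavior()] then [generateConnectomes()].
#'
#' @param spec A [syntheticSpec()].
#' @return List with \code{set}, \code{cohort} (behavior table) and
#'   \code{truth}.
#' @examples
#' sim <- simulateCohort(syntheticSpec(nSubjects = 20, nRegions = 16,
#'                                     seed = 3))
#' sim$set
#' @export
simulateCohort <- function(spec) {
  behavior <- generateBehavior(spec)
  out <- generateConnectomes(spec, behavior)
  list(set = out$set, cohort = behavior, truth = out$truth)
}

#' Write a cohort to a plain-text fixture directory
#'
#' Lays out \code{subjects.csv}, \code{regions.csv}, one header-less
#' comma-delimited square matrix per subject under \code{sc/} and
#' \code{dist/}, and a \code{manifest.json} recording the generating spec
#' (when supplied) so the fixture can be reproduced from its seed. The
#' layout round-trips losslessly through [loadConnectomes()].
#'
#' @param set A [ConnectomeSet-class].
#' @param dir Output directory.
#' @param overwrite Overwrite an existing fixture? Default FALSE.
#' @param spec Optional [syntheticSpec()] recorded in the manifest.
#' @return Invisibly, the manifest as a list (also written as JSON).
#' @export
writeFixture <- function(set, dir, overwrite = FALSE, spec = NULL) {
  manifestPath <- file.path(dir, "manifest.json")
  if (file.exists(manifestPath) && !overwrite)
    stop("fixture already exists at ", dir, " (use overwrite = TRUE)")
  dir.create(file.path(dir, "sc"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "dist"), recursive = TRUE, showWarnings = FALSE)
  beh <- cohort(set)
  utils::write.csv(beh[, c("id", "age", "sex", "fluid_intelligence")],
                   file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(regionInfo(set), file.path(dir, "regions.csv"),
                   row.names = FALSE)
  ids <- subjectIds(set)
  for (id in ids) {
    write.table(format(scMatrix(set, id), digits = 17, scientific = TRUE,
                       trim = TRUE),
                file.path(dir, "sc", paste0(id, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    write.table(format(distMatrix(set, id), digits = 17, scientific = TRUE,
                       trim = TRUE),
                file.path(dir, "dist", paste0(id, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    format = "connlife-fixture-v1",
    n_subjects = length(ids), n_regions = nRegions(set),
    files = c("subjects.csv", "regions.csv",
              file.path("sc", paste0(ids, ".csv")),
              file.path("dist", paste0(ids, ".csv"))))
  if (!is.null(spec)) {
    manifest$seed <- spec$seed
    manifest$spec <- unclass(spec[setdiff(names(spec), "plantedComponents")])
    manifest$spec$plantedComponents <- lapply(spec$plantedComponents, unclass)
  }
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
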