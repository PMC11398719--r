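# End-to-end orchestration: simulate/load -> QC -> graph metrics -> PLS
# (edges all-subjects; nodal and local efficiency per age group) ->
# rolling correlations -> whole-brain regression models -> report.json.

# small deterministic FNV-1a hash for provenance stamps
configHash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Pipeline run configuration
#'
#' Collects input source, stage toggles, resampling counts, thresholds and
#' the master seed for [runPipeline()]. The configuration (plus its hash)
#' is serialized into every output for provenance. Defaults mirror the
#' study conventions: 50\% consistency threshold, 3 SD density exclusion,
#' BSR threshold 2, age-group split at 50 years (subjects exactly at the
#' boundary count as OA).
#'
#' @param inputDir Fixture directory to load; NULL simulates from
#'   \code{spec}.
#' @param spec A [syntheticSpec()] used when \code{inputDir} is NULL.
#' @param stages Character vector of stages to run, in dependency order
#'   among \code{c("qc", "metrics", "pls", "rolling", "regress")}.
#' @param nPerm,nBoot,nSplits Resampling counts (study profile 1000; a
#'   reduced profile of 100 keeps reruns quick).
#' @param nNull Null networks per subject for small-worldness.
#' @param consistency Consistency threshold fraction.
#' @param densitySd Density outlier cut (SD units).
#' @param bsrThreshold BSR magnitude threshold for reliable patterns.
#' @param rollingWidth,rollingStep Rolling-window width and step (years).
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param outputDir Where artifacts are written.
#' @return A \code{runConfig} list.
#' @export
runConfig <- function(inputDir = NULL,
                      spec = syntheticSpec(plantedComponents =
                                             list(defaultPlantedEffect())),
                      stages = c("qc", "metrics", "pls", "rolling",
                                 "regress"),
                      nPerm = 100, nBoot = 100, nSplits = 100, nNull = 10,
                      consistency = 0.5, densitySd = 3, bsrThreshold = 2,
                      rollingWidth = 10, rollingStep = 1,
                      seed = 1, outputDir = tempfile("connlife_run_")) {
  stopifnot(nPerm >= 19, nBoot >= 50, nSplits >= 2, nNull >= 1,
            consistency > 0, densitySd > 0, bsrThreshold > 0,
            rollingWidth > 0)
  structure(list(inputDir = inputDir, spec = spec, stages = stages,
                 nPerm = nPerm, nBoot = nBoot, nSplits = nSplits,
                 nNull = nNull, consistency = consistency,
                 densitySd = densitySd, bsrThreshold = bsrThreshold,
                 rollingWidth = rollingWidth, rollingStep = rollingStep,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "runConfig")
}

plsSummary <- function(model) {
  K <- length(singularValues(model))
  lapply(seq_len(K), function(k) {
    out <- list(lv = k, singular_value = singularValues(model)[k],
                perm_p = permPValues(model)[k])
    sc <- model@scoreCor[, k]
    ci <- model@scoreCorCI[[k]]
    out$behavior_correlations <- lapply(
      seq_along(sc), function(j) list(
        behavior = model@behaviorLabels[j], r = unname(sc[j]),
        ci_low = ci[1, j], ci_high = ci[2, j]))
    out$Z_sval <- model@Zsval[k]
    out$Z_sval_null <- model@ZsvalNull[k]
    out$Z_svec <- model@Zsvec[k]
    out$Z_svec_null <- model@ZsvecNull[k]
    out$reproducible <- unname(model@Zsvec[k] > 2 + model@ZsvecNull[k])
    out
  })
}

runPLSBlock <- function(model, label, config, seedOffset) {
  m <- plsPermutation(model, nPerm = config$nPerm,
                      seed = config$seed + seedOffset)
  m <- plsBootstrap(m, nBoot = config$nBoot,
                    seed = config$seed + seedOffset + 1)
  m <- plsSplitHalf(m, nSplits = config$nSplits,
                    seed = config$seed + seedOffset + 2)
  m
}

# regions selected by sign of LV1 BSR in a metric-mode model; integer ids
selectedRegions <- function(model, threshold, sign) {
  bsr <- bootstrapRatios(model)[, 1]
  idx <- if (sign == "positive") which(bsr >= threshold)
         else which(bsr <= -threshold)
  as.integer(sub("^(ne|le)_", "", names(bsr)[idx]))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on either a loaded
#' fixture or a freshly simulated cohort, writes per-stage artifacts
#' (CSV/JSON) into the output directory, and returns (and writes) a
#' consolidated \code{report.json}: QC counts, PLS blocks (edge weights on
#' all subjects; nodal and local efficiency per age group) with singular
#' values, permutation p, split-half Z statistics and behavior
#' correlations with CIs, hub tables, rolling-correlation curves, and the
#' three whole-brain regression models per age group. Every stochastic
#' step is seeded from the master seed, so a rerun with the same
#' configuration reproduces the report bit for bit.
#'
#' @param config A [runConfig()].
#' @return The report, invisibly (also written to
#'   \code{config$outputDir/report.json}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  needs <- list(metrics = "qc", pls = c("qc", "metrics"),
                rolling = c("metrics", "pls"),
                regress = c("metrics", "pls"))
  for (st in config$stages) {
    missing <- setdiff(needs[[st]], config$stages)
    if (length(missing))
      stop("stage '", st, "' requires stage(s): ",
           paste(missing, collapse = ", "))
  }
  provenance <- list(seed = config$seed,
                     config = unclass(config[setdiff(names(config),
                                                     c("spec"))]),
                     config_hash = configHash(unclass(config)))
  report <- list(provenance = provenance)

  set <- if (is.null(config$inputDir)) {
    sim <- simulateCohort(config$spec)
    report$input <- list(source = "synthetic",
                         n_subjects = config$spec$nSubjects,
                         n_regions = config$spec$nRegions,
                         spec_seed = config$spec$seed)
    sim$set
  } else {
    report$input <- list(source = config$inputDir)
    loadConnectomes(config$inputDir)
  }

  metrics <- NULL
  plsBlocks <- list()
  if ("qc" %in% config$stages) {
    qc <- applyQC(set, sdThreshold = config$densitySd,
                  minFraction = config$consistency)
    set <- qc$set
    writeQCReport(qc$report, file.path(config$outputDir, "qc_report.json"))
    report$qc <- list(n_input = qc$report@nInput,
                      n_retained = length(qc$report@density),
                      retained_edges = qc$report@retainedEdges,
                      exclusions = qc$report@exclusions)
  }
  if ("metrics" %in% config$stages) {
    metrics <- computeGraphMetrics(set, nNull = config$nNull,
                                   seed = config$seed + 100)
    utils::write.csv(metrics, file.path(config$outputDir, "metrics.csv"),
                     row.names = FALSE)
    report$metrics <- list(
      n_subjects = nrow(metrics),
      mean_small_worldness = mean(metrics$small_worldness),
      mean_sc_total = mean(metrics$sc_total))
  }
  if ("pls" %in% config$stages) {
    plsBlocks$edges_all <- runPLSBlock(plsFromEdges(set, "all"),
                                       "edges_all", config, 200)
    if (!is.null(metrics)) {
      for (grp in c("YA", "OA")) {
        plsBlocks[[paste0("nodal_", grp)]] <- runPLSBlock(
          plsFromMetrics(metrics, "nodal", grp), paste0("nodal_", grp),
          config, 300 + 10 * (grp == "OA"))
        plsBlocks[[paste0("local_", grp)]] <- runPLSBlock(
          plsFromMetrics(metrics, "local", grp), paste0("local_", grp),
          config, 400 + 10 * (grp == "OA"))
      }
    }
    report$pls <- lapply(plsBlocks, plsSummary)
    edgePat <- reliablePattern(plsBlocks$edges_all, 1,
                               config$bsrThreshold, regionInfo(set),
                               sign = "positive")
    report$pls_edge_lv1_positive <- list(
      n_selected = nrow(edgePat$variables), hubs = edgePat$hubs,
      pct_intra_L = edgePat$pctIntraL, pct_intra_R = edgePat$pctIntraR,
      pct_inter = edgePat$pctInter)
    for (nmb in names(plsBlocks)) {
      bsr <- bootstrapRatios(plsBlocks[[nmb]])
      utils::write.csv(data.frame(variable = rownames(bsr), bsr,
                                  row.names = NULL),
                       file.path(config$outputDir,
                                 paste0("bsr_", nmb, ".csv")),
                       row.names = FALSE)
    }
  }
  if ("rolling" %in% config$stages) {
    rollSpec <- list(
      nodal = list(model = plsBlocks$nodal_OA, prefix = "ne_",
                   sign = "positive"),
      local = list(model = plsBlocks$local_YA, prefix = "le_",
                   sign = "positive"))
    report$rolling <- list()
    for (nm in names(rollSpec)) {
      rs <- rollSpec[[nm]]
      regs <- selectedRegions(rs$model, config$bsrThreshold, rs$sign)
      usedAll <- length(regs) == 0
      cols <- if (usedAll) grep(paste0("^", rs$prefix), names(metrics),
                                value = TRUE)
              else paste0(rs$prefix, sprintf("%03d", regs))
      mvec <- rowMeans(metrics[, cols, drop = FALSE])
      curve <- rollingCorrelation(metrics$age, mvec,
                                  metrics$fluid_intelligence,
                                  width = config$rollingWidth,
                                  step = config$rollingStep,
                                  nBoot = config$nBoot,
                                  seed = config$seed + 500 +
                                    1000 * (nm == "local"))
      utils::write.csv(curve,
                       file.path(config$outputDir,
                                 paste0("rolling_", nm, ".csv")),
                       row.names = FALSE)
      best <- which.max(curve$r)
      report$rolling[[nm]] <- list(
        n_windows = nrow(curve), regions = regs,
        region_fallback_all = usedAll,
        peak_window_start = curve$age_start[best],
        peak_r = curve$r[best])
    }
  }
  if ("regress" %in% config$stages) {
    regs <- selectedRegions(plsBlocks$local_OA, config$bsrThreshold,
                            "negative")
    if (!length(regs)) regs <- regionInfo(set)$id
    report$regress <- list(dependent_regions = regs, models = list())
    for (mId in 1:3) {
      fits <- lapply(c(YA = "YA", OA = "OA"), function(g)
        fitLocalEfficiencyModels(metrics, modelId = mId, group = g,
                                 regionSet = regs))
      for (g in names(fits))
        utils::write.csv(fits[[g]],
                         file.path(config$outputDir,
                                   sprintf("model%d_%s.csv", mId, g)),
                         row.names = FALSE)
      comp <- lapply(setdiff(fits$YA$term, "Intercept"), function(tm)
        compareGroupEstimates(fits$YA, fits$OA, tm))
      report$regress$models[[paste0("model", mId)]] <- list(
        r2 = lapply(fits, attr, "r.squared"),
        n = lapply(fits, attr, "n"),
        group_comparisons = lapply(comp, function(x)
          list(term = x$term, verdict = x$verdict)))
    }
  }
  jsonlite::write_json(report, file.path(config$outputDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

#' Validate a fixture directory
#'
#' Checks the on-disk inputs without correcting anything: required files,
#' matrix squareness, symmetry, value ranges, behavior/matrix id
#' alignment, and region-metadata completeness.
#'
#' @param dir Fixture directory.
#' @return data.frame of diagnostics with columns \code{item} and
#'   \code{problem}; zero rows means a clean fixture.
#' @export
validateInputs <- function(dir) {
  dg <- data.frame(item = character(0), problem = character(0),
                     stringsAsFactors = FALSE)
  note <- function(item, problem)
    rbind(dg, data.frame(item = item, problem = problem,
                           stringsAsFactors = FALSE))
  subj <- file.path(dir, "subjects.csv")
  regs <- file.path(dir, "regions.csv")
  if (!file.exists(subj)) return(note("subjects.csv", "missing file"))
  if (!file.exists(regs)) return(note("regions.csv", "missing file"))
  beh <- try(loadCohort(subj), silent = TRUE)
  if (inherits(beh, "try-error"))
    return(note("subjects.csv", conditionMessage(attr(beh, "condition"))))
  regions <- read.csv(regs, stringsAsFactors = FALSE)
  need <- c("id", "label", "hemisphere", "subcortical")
  for (cn in setdiff(need, names(regions)))
    dg <- note("regions.csv", paste("missing column", cn))
  if ("hemisphere" %in% names(regions) &&
      !all(regions$hemisphere %in% c("L", "R")))
    dg <- note("regions.csv", "hemisphere values must be L or R")
  n <- nrow(regions)
  for (id in beh$id) {
    for (kind in c("sc", "dist")) {
      f <- file.path(dir, kind, paste0(id, ".csv"))
      if (!file.exists(f)) {
        dg <- note(paste0(kind, "/", id), "matrix file missing")
        next
      }
      m <- try(as.matrix(read.csv(f, header = FALSE)), silent = TRUE)
      if (inherits(m, "try-error")) {
        dg <- note(paste0(kind, "/", id), "unreadable matrix")
        next
      }
      storage.mode(m) <- "double"
      if (nrow(m) != n || ncol(m) != n)
        dg <- note(paste0(kind, "/", id),
                     sprintf("not %dx%d", n, n))
      else {
        if (max(abs(m - t(m))) > 1e-8)
          dg <- note(paste0(kind, "/", id), "asymmetric matrix")
        if (min(m) < 0)
          dg <- note(paste0(kind, "/", id), "negative entries")
        if (kind == "sc" && max(m) > 1)
          dg <- note(paste0(kind, "/", id),
                       "streamline probabilities above 1")
        if (any(diag(m) != 0))
          dg <- note(paste0(kind, "/", id), "nonzero diagonal")
      }
    }
  }
  extra <- setdiff(sub("\\.csv$", "", list.files(file.path(dir, "sc"))),
                   beh$id)
  for (id in extra)
    dg <- note(paste0("sc/", id), "matrix without behavior row")
  dg
}
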