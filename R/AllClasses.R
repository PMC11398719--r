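#' ConnectomeSet: per-subject structural connectomes with behavior
#'
#' An S4 container extending
#' \link[SummarizedExperiment]{SummarizedExperiment} for a cohort of
#' subject-level structural connectomes. Rows are undirected region pairs
#' (edges, in the order of [edgeIndex()]), columns are subjects. Two assays
#' are carried: \code{"sc"}, the streamline probability of each connection
#' (dimensionless, in [0, 1]), and \code{"dist"}, the streamline distance in
#' millimetres (0 where no connection exists). \code{colData} holds the
#' behavior table (age, sex, fluid intelligence, derived age group);
#' \code{metadata(x)$regions} holds the region metadata (label, hemisphere,
#' subcortical flag).
#'
#' @slot .data inherited \code{SummarizedExperiment} internals.
#' @seealso [ConnectomeSet()] (constructor), [scMatrix()], [applyQC()]
#' @export
setClass("ConnectomeSet", contains = "SummarizedExperiment")

setValidity("ConnectomeSet", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("sc", "dist") %in% an))
    msgs <- c(msgs, "assays must include 'sc' and 'dist'")
  regs <- metadata(object)$regions
  if (is.null(regs) || !is.data.frame(regs))
    msgs <- c(msgs, "metadata(object)$regions must be a data.frame")
  else {
    need <- c("id", "label", "hemisphere", "subcortical")
    if (!all(need %in% names(regs)))
      msgs <- c(msgs, paste("regions metadata needs columns:",
                            paste(need, collapse = ", ")))
    n <- nrow(regs)
    if (nrow(object) != n * (n - 1) / 2)
      msgs <- c(msgs, "row count must equal n_regions*(n_regions-1)/2")
  }
  if ("sc" %in% an) {
    sc <- assay(object, "sc")
    if (length(sc) && (min(sc) < 0 || max(sc) > 1))
      msgs <- c(msgs, "'sc' entries must lie in [0, 1]")
  }
  if ("dist" %in% an) {
    d <- assay(object, "dist")
    if (length(d) && min(d) < 0)
      msgs <- c(msgs, "'dist' entries must be nonnegative")
  }
  cd <- colData(object)
  if (!all(c("id", "age", "sex", "fluid_intelligence", "group") %in%
           colnames(cd)))
    msgs <- c(msgs, paste("colData needs columns id, age, sex,",
                          "fluid_intelligence, group"))
  else if (anyDuplicated(cd$id))
    msgs <- c(msgs, "subject ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' QCReport: quality-control summary for a connectome cohort
#'
#' Records the consistency mask, per-subject connectome density, and every
#' subject exclusion (with reason) produced by [applyQC()].
#'
#' @slot density Named numeric, post-mask density per retained subject
#'   (fraction of possible undirected pairs with a nonzero connection).
#' @slot densityMean,densitySd Mean and SD of density over the subjects
#'   entering the outlier pass.
#' @slot exclusions data.frame with columns \code{id} and \code{reason}
#'   (one of \code{missing_behavior}, \code{zero_connection_region},
#'   \code{density_outlier}).
#' @slot mask Logical symmetric matrix: edges retained by the consistency
#'   threshold.
#' @slot retainedEdges Integer, number of retained undirected edges.
#' @slot nInput Integer, subjects before QC.
#' @slot settings List of thresholds used.
#' @export
setClass("QCReport",
  representation(density = "numeric", densityMean = "numeric",
                 densitySd = "numeric", exclusions = "data.frame",
                 mask = "matrix", retainedEdges = "integer",
                 nInput = "integer", settings = "list"))

#' PLSModel: behavioral partial least squares decomposition
#'
#' Holds the SVD of the behaviors-by-brain-variables correlation matrix and
#' (once the corresponding inference steps are run) permutation p values,
#' bootstrap ratios, latent-variable/behavior correlations with bootstrap
#' CIs, and split-half reproducibility statistics.
#'
#' @slot R Behaviors x brain-variables Pearson correlation matrix.
#' @slot U Behavior saliences (orthonormal columns).
#' @slot V Brain saliences (orthonormal columns).
#' @slot S Singular values, descending.
#' @slot brainScores,behaviorScores Subject scores on each latent variable,
#'   computed on column-standardized data.
#' @slot permP Permutation p value per latent variable (empty until
#'   [plsPermutation()] is run).
#' @slot scoreCor Behaviors x LV matrix of correlations between brain scores
#'   and each behavior column.
#' @slot scoreCorCI List per LV of 2 x behaviors percentile CI bounds.
#' @slot BSR Brain-variable x LV bootstrap ratio matrix.
#' @slot bootRedraws Integer, degenerate bootstrap samples redrawn.
#' @slot Zsval,Zsvec,ZsvalNull,ZsvecNull Split-half reproducibility Z
#'   statistics and their permutation-null counterparts, per LV.
#' @slot splitDetail List with the per-split similarity draws.
#' @slot X,Y The subjects x brain-variables and subjects x behaviors data
#'   matrices the model was fit to (kept so resampling inference can be run
#'   on the fitted object).
#' @slot brainLabels,behaviorLabels Variable names.
#' @slot edgeMap Optional data.frame mapping brain variables (edge mode) to
#'   region pairs, columns \code{i}, \code{j}.
#' @slot droppedColumns Names of zero-variance brain columns removed.
#' @slot settings List recording resampling counts and seeds used.
#' @export
setClass("PLSModel",
  representation(R = "matrix", U = "matrix", V = "matrix", S = "numeric",
                 brainScores = "matrix", behaviorScores = "matrix",
                 permP = "numeric", scoreCor = "matrix", scoreCorCI = "list",
                 BSR = "matrix", bootRedraws = "integer",
                 Zsval = "numeric", Zsvec = "numeric",
                 ZsvalNull = "numeric", ZsvecNull = "numeric",
                 splitDetail = "list", X = "matrix", Y = "matrix",
                 brainLabels = "character", behaviorLabels = "character",
                 edgeMap = "data.frame", droppedColumns = "character",
                 settings = "list"),
  prototype(permP = numeric(0), scoreCorCI = list(),
            BSR = matrix(numeric(0), 0, 0), bootRedraws = 0L,
            Zsval = numeric(0), Zsvec = numeric(0),
            ZsvalNull = numeric(0), ZsvecNull = numeric(0),
            splitDetail = list(), edgeMap = data.frame(),
            droppedColumns = character(0), settings = list()))
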