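#' Consistency threshold mask
#'
#' An edge is retained when the fraction of subjects with a nonzero
#' streamline probability at that connection is at least
#' \code{minFraction} (boundary inclusive: an edge present in exactly half
#' the subjects survives the default 50\% threshold).
#'
#' @param set A [ConnectomeSet-class] with at least one subject.
#' @param minFraction Minimum fraction of subjects, default 0.5.
#' @return A logical symmetric matrix with zero (FALSE) diagonal; TRUE
#'   marks retained edges.
#' @export
consistencyMask <- function(set, minFraction = 0.5) {
  stopifnot(is(set, "ConnectomeSet"), ncol(set) >= 1)
  frac <- rowMeans(assay(set, "sc") > 0)
  edgeMatrix(as.numeric(frac >= minFraction), nRegions(set)) > 0
}

# zero both assays outside the mask (vector over edges)
maskSet <- function(set, maskVec) {
  a <- assays(set)
  a$sc <- a$sc * maskVec
  a$dist <- a$dist * maskVec
  SummarizedExperiment::assays(set) <- a
  set
}

# per-subject density: fraction of possible undirected pairs with a
# nonzero connection
densityOf <- function(set) colMeans(assay(set, "sc") > 0)

#' Apply cohort-level quality control
#'
#' Reproduces the study's exclusion cascade in a fixed order: (1) apply the
#' consistency mask; (2) exclude subjects with missing behavior; (3)
#' exclude subjects left with any region of zero post-mask degree; (4)
#' compute connectome density over the remaining subjects and, in a single
#' pass, exclude those whose density is \code{sdThreshold} SDs or more from
#' the mean (inclusive boundary, with a 1e-12 numeric tolerance; a zero SD
#' excludes no one). The SD is the descriptive (population) SD of the
#' cohort densities. Densities are computed after masking.
#'
#' @param set A [ConnectomeSet-class].
#' @param sdThreshold Density outlier cut in SD units, default 3.
#' @param minFraction Consistency threshold passed to [consistencyMask()].
#' @return List with \code{set} (masked, subjects filtered) and
#'   \code{report} (a [QCReport-class]).
#' @export
applyQC <- function(set, sdThreshold = 3, minFraction = 0.5) {
  stopifnot(is(set, "ConnectomeSet"))
  mask <- consistencyMask(set, minFraction)
  maskVec <- edgeVector(mask)
  masked <- maskSet(set, maskVec)
  cd <- cohort(masked)
  excl <- data.frame(id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)

  behBad <- cd$missing_behavior
  if (any(behBad))
    excl <- rbind(excl, data.frame(id = cd$id[behBad],
                                   reason = "missing_behavior"))
  keep <- !behBad

  ei <- edgeIndex(nRegions(set))
  scm <- assay(masked, "sc")
  isolated <- vapply(seq_len(ncol(scm)), function(s) {
    nz <- scm[, s] > 0
    deg <- tabulate(c(ei$i[nz], ei$j[nz]), nbins = nRegions(set))
    any(deg == 0)
  }, logical(1))
  newIso <- keep & isolated
  if (any(newIso))
    excl <- rbind(excl, data.frame(id = cd$id[newIso],
                                   reason = "zero_connection_region"))
  keep <- keep & !isolated

  if (!any(keep)) stop("all subjects excluded during QC")
  dens <- densityOf(masked)[keep]
  dm <- mean(dens)
  ds <- sqrt(mean((dens - dm)^2))  # descriptive SD of the cohort
  if (length(dens) > 1 && ds > 0) {
    out <- abs(dens - dm) >= sdThreshold * ds - 1e-12
    if (any(out)) {
      excl <- rbind(excl, data.frame(id = cd$id[keep][out],
                                     reason = "density_outlier"))
      keepIds <- cd$id[keep][!out]
      keep <- cd$id %in% keepIds
    }
  }
  if (!any(keep)) stop("all subjects excluded during QC")

  report <- new("QCReport",
                density = setNames(densityOf(masked)[keep], cd$id[keep]),
                densityMean = dm, densitySd = if (is.na(ds)) 0 else ds,
                exclusions = excl, mask = mask,
                retainedEdges = as.integer(sum(maskVec)),
                nInput = ncol(set),
                settings = list(minFraction = minFraction,
                                sdThreshold = sdThreshold,
                                densityComputedAfterMasking = TRUE))
  list(set = masked[, keep], report = report)
}

#' Accessors for QCReport objects
#'
#' @param object A [QCReport-class].
#' @return \code{exclusions}: data.frame of excluded ids and reasons.
#'   \code{consistencyRetained}: the logical edge mask.
#'   \code{subjectDensity}: named per-subject densities of retained
#'   subjects.
#' @name QCReport-accessors
NULL

#' @rdname QCReport-accessors
#' @export
setMethod("exclusions", "QCReport", function(object) object@exclusions)

#' @rdname QCReport-accessors
#' @export
setMethod("consistencyRetained", "QCReport", function(object) object@mask)

#' @rdname QCReport-accessors
#' @export
setMethod("subjectDensity", "QCReport", function(object) object@density)

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@nInput, "subjects in,",
      length(object@density), "retained\n")
  cat(sprintf("  density (post-mask) mean %.4f sd %.4f; %d edges retained\n",
              object@densityMean, object@densitySd, object@retainedEdges))
  if (nrow(object@exclusions)) {
    tab <- table(object@exclusions$reason)
    for (r in names(tab)) cat("  excluded", tab[[r]], "for", r, "\n")
  } else cat("  no exclusions\n")
  invisible(NULL)
})

#' Write a QC report as JSON
#'
#' @param report A [QCReport-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeQCReport <- function(report, path) {
  jsonlite::write_json(list(
    note = "densities computed after consistency masking",
    n_input = report@nInput,
    n_retained = length(report@density),
    density = as.list(report@density),
    density_mean = report@densityMean,
    density_sd = report@densitySd,
    retained_edges = report@retainedEdges,
    exclusions = report@exclusions,
    settings = report@settings), path, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}
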