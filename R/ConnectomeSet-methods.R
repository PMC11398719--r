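#' Construct a ConnectomeSet
#'
#' Assembles per-subject streamline-probability and distance matrices, a
#' region metadata table, and a behavior table into a [ConnectomeSet-class].
#' Matrices are validated (square, symmetric, nonnegative, zero diagonal,
#' probabilities at most 1) and stored as vectorized upper triangles.
#'
#' @param sc Named list of symmetric streamline-probability matrices, one
#'   per subject; names are subject ids.
#' @param dist Named list of symmetric distance matrices (mm), aligned to
#'   \code{sc}.
#' @param regions data.frame with columns \code{id}, \code{label},
#'   \code{hemisphere} (\code{"L"}/\code{"R"}), \code{subcortical} (0/1).
#' @param behavior Behavior table as returned by [loadCohort()]: columns
#'   \code{id}, \code{age}, \code{sex}, \code{fluid_intelligence},
#'   \code{group}, \code{missing_behavior}.
#' @return A [ConnectomeSet-class].
#' @examples
#' spec <- syntheticSpec(nSubjects = 12, nRegions = 16, seed = 1)
#' sim <- simulateCohort(spec)
#' sim$set
#' @export
ConnectomeSet <- function(sc, dist, regions, behavior) {
  stopifnot(is.list(sc), is.list(dist), length(sc) == length(dist))
  if (is.null(names(sc))) names(sc) <- behavior$id
  if (is.null(names(dist))) names(dist) <- names(sc)
  if (!identical(names(sc), names(dist)))
    stop("sc and dist subject ids differ")
  ids <- as.character(behavior$id)
  if (!setequal(names(sc), ids))
    stop("matrix subject ids do not match behavior table ids")
  sc <- sc[ids]; dist <- dist[ids]
  n <- nrow(regions)
  scv <- vapply(seq_along(sc), function(k) {
    checkSymmetricNonneg(sc[[k]], paste0("sc[", ids[k], "]"), upper = 1)
    if (nrow(sc[[k]]) != n) stop("sc matrix dimension != region count")
    edgeVector(sc[[k]])
  }, numeric(n * (n - 1) / 2))
  dv <- vapply(seq_along(dist), function(k) {
    checkSymmetricNonneg(dist[[k]], paste0("dist[", ids[k], "]"))
    if (nrow(dist[[k]]) != n) stop("dist matrix dimension != region count")
    edgeVector(dist[[k]])
  }, numeric(n * (n - 1) / 2))
  scv <- matrix(scv, ncol = length(ids), dimnames = list(NULL, ids))
  dv <- matrix(dv, ncol = length(ids), dimnames = list(NULL, ids))
  ei <- edgeIndex(n)
  se <- SummarizedExperiment(
    assays = list(sc = scv, dist = dv),
    rowData = DataFrame(i = ei$i, j = ei$j),
    colData = DataFrame(behavior, row.names = ids),
    metadata = list(regions = regions))
  obj <- new("ConnectomeSet", se)
  validObject(obj)
  obj
}

#' Accessors for ConnectomeSet objects
#'
#' @param x A [ConnectomeSet-class].
#' @param subject Subject id (character) or column index.
#' @return \code{nRegions}: region count. \code{regionInfo}: the region
#'   metadata data.frame. \code{subjectIds}: character vector of ids.
#'   \code{cohort}: the behavior table as a data.frame. \code{scMatrix} /
#'   \code{distMatrix}: the subject's reconstructed symmetric matrix.
#' @name ConnectomeSet-accessors
NULL

#' @rdname ConnectomeSet-accessors
#' @export
setMethod("nRegions", "ConnectomeSet", function(x)
  nrow(metadata(x)$regions))

#' @rdname ConnectomeSet-accessors
#' @export
setMethod("regionInfo", "ConnectomeSet", function(x) metadata(x)$regions)

#' @rdname ConnectomeSet-accessors
#' @export
setMethod("subjectIds", "ConnectomeSet", function(x)
  as.character(colData(x)$id))

#' @rdname ConnectomeSet-accessors
#' @export
setMethod("cohort", "ConnectomeSet", function(x)
  as.data.frame(colData(x), row.names = NULL))

#' @rdname ConnectomeSet-accessors
#' @export
setMethod("scMatrix", "ConnectomeSet", function(x, subject)
  edgeMatrix(assay(x, "sc")[, subject], nRegions(x)))

#' @rdname ConnectomeSet-accessors
#' @export
setMethod("distMatrix", "ConnectomeSet", function(x, subject)
  edgeMatrix(assay(x, "dist")[, subject], nRegions(x)))

setMethod("show", "ConnectomeSet", function(object) {
  n <- nRegions(object)
  cat("ConnectomeSet with", ncol(object), "subjects,", n, "regions (",
      nrow(object), "undirected pairs )\n")
  cd <- colData(object)
  if (nrow(cd)) {
    cat(sprintf("  age %.1f-%.1f years; %d YA / %d OA\n",
                min(cd$age), max(cd$age),
                sum(cd$group == "YA"), sum(cd$group == "OA")))
  }
  dens <- mean(assay(object, "sc") > 0)
  cat(sprintf("  mean density %.3f\n", dens))
  invisible(NULL)
})
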