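#' Load a behavior table
#'
#' Reads a CSV behavior table with columns \code{id}, \code{age},
#' \code{sex} and \code{fluid_intelligence}, types the records, assigns the
#' YA/OA age group (younger adults below 50 years), and flags -- without
#' dropping -- subjects with missing fluid intelligence; exclusion happens
#' later in [applyQC()].
#'
#' @param path Path to the CSV file.
#' @return A behavior data.frame with columns \code{id}, \code{age},
#'   \code{sex}, \code{fluid_intelligence}, \code{group},
#'   \code{missing_behavior}.
#' @export
loadCohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "fluid_intelligence")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("behavior table lacks columns: ", paste(miss, collapse = ", "))
  tab$id <- as.character(tab$id)
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop("duplicated subject ids: ", paste(dup, collapse = ", "))
  ageNum <- suppressWarnings(as.numeric(tab$age))
  bad <- which(is.na(ageNum) & !is.na(tab$age) & tab$age != "")
  if (length(bad))
    stop("non-numeric age in row(s) ", paste(bad, collapse = ", "),
         " (id ", paste(tab$id[bad], collapse = ", "), ")")
  if (any(is.na(ageNum)) || any(ageNum <= 0))
    stop("ages must be present and positive")
  sex <- toupper(substr(as.character(tab$sex), 1, 1))
  if (!all(sex %in% c("F", "M")))
    stop("sex must be coded F or M")
  fi <- suppressWarnings(as.numeric(tab$fluid_intelligence))
  data.frame(id = tab$id, age = ageNum, sex = sex,
             fluid_intelligence = fi,
             group = ifelse(ageNum < 50, "YA", "OA"),
             missing_behavior = is.na(fi), stringsAsFactors = FALSE)
}

readSquareMatrix <- function(path, n, what) {
  if (!file.exists(path)) stop("missing matrix file for ", what, ": ", path)
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != n || ncol(m) != n)
    stop(what, ": expected a ", n, "x", n, " matrix in ", path)
  storage.mode(m) <- "double"
  m
}

#' Load a connectome fixture directory
#'
#' Reads the fixture layout written by [writeFixture()]:
#' \code{subjects.csv}, \code{regions.csv}, and header-less square CSV
#' matrices \code{sc/<id>.csv} and \code{dist/<id>.csv}.
#'
#' @param dir Fixture directory.
#' @return A [ConnectomeSet-class].
#' @export
loadConnectomes <- function(dir) {
  behavior <- loadCohort(file.path(dir, "subjects.csv"))
  regions <- read.csv(file.path(dir, "regions.csv"),
                      stringsAsFactors = FALSE)
  n <- nrow(regions)
  sc <- lapply(behavior$id, function(id)
    readSquareMatrix(file.path(dir, "sc", paste0(id, ".csv")), n, id))
  dist <- lapply(behavior$id, function(id)
    readSquareMatrix(file.path(dir, "dist", paste0(id, ".csv")), n, id))
  names(sc) <- names(dist) <- behavior$id
  ConnectomeSet(sc, dist, regions, behavior)
}
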