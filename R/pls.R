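# Behavioral PLS: SVD of the behaviors x brain-variables correlation
# matrix, with permutation significance, Procrustes-aligned bootstrap
# ratios, and split-half reproducibility statistics.

corSVD <- function(X, Y) {
  R <- suppressWarnings(cor(Y, X))
  R[is.na(R)] <- 0  # columns constant within this (sub)sample correlate as 0
  sv <- svd(R)
  K <- min(dim(R))
  list(R = R, U = sv$u[, seq_len(K), drop = FALSE],
       V = sv$v[, seq_len(K), drop = FALSE], S = sv$d[seq_len(K)])
}

# orient each LV so the largest-magnitude behavior salience is positive
orientLVs <- function(dec) {
  for (k in seq_along(dec$S)) {
    i <- which.max(abs(dec$U[, k]))
    if (dec$U[i, k] < 0) {
      dec$U[, k] <- -dec$U[, k]
      dec$V[, k] <- -dec$V[, k]
    }
  }
  dec
}

colVariances <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

#' Fit a behavioral PLS model
#'
#' Computes the behaviors x brain-variables Pearson correlation matrix R,
#' decomposes it as R = U diag(S) V' by SVD, and derives subject scores on
#' column-standardized data. Each latent variable (LV) is oriented so its
#' largest-magnitude behavior salience is positive. Zero-variance brain
#' columns are dropped with a warning and recorded; a constant behavior
#' column is an error.
#'
#' @param X Subjects x brain-variables matrix (edge weights or region-wise
#'   graph metrics); at least 3 subjects, no missing values.
#' @param Y Subjects x behaviors matrix (e.g. age and fluid intelligence).
#' @param edgeMap Optional data.frame with columns \code{i}, \code{j}
#'   mapping each X column to a region pair (edge mode); enables
#'   [reliablePattern()] degree/hemisphere reporting.
#' @return A [PLSModel-class] with point estimates; run
#'   [plsPermutation()], [plsBootstrap()] and [plsSplitHalf()] for
#'   inference.
#' @export
plsFit <- function(X, Y, edgeMap = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  if (anyNA(X) || anyNA(Y)) stop("PLS input must not contain missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (any(colVariances(Y) == 0)) stop("constant behavior column")
  vx <- colVariances(X)
  dropped <- colnames(X)[vx == 0]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " zero-variance brain column(s)")
    keep <- vx > 0
    X <- X[, keep, drop = FALSE]
    if (!is.null(edgeMap)) edgeMap <- edgeMap[keep, , drop = FALSE]
  }
  dec <- orientLVs(corSVD(X, Y))
  Xz <- scale(X); Yz <- scale(Y)
  brainScores <- Xz %*% dec$V
  behaviorScores <- Yz %*% dec$U
  new("PLSModel", R = dec$R, U = dec$U, V = dec$V, S = dec$S,
      brainScores = brainScores, behaviorScores = behaviorScores,
      scoreCor = cor(Y, brainScores), X = X, Y = Y,
      brainLabels = colnames(X), behaviorLabels = colnames(Y),
      edgeMap = if (is.null(edgeMap)) data.frame() else edgeMap,
      droppedColumns = dropped, settings = list())
}

#' Accessors for PLSModel objects
#'
#' @param object A [PLSModel-class].
#' @param side \code{"brain"} (V) or \code{"behavior"} (U).
#' @return \code{singularValues}: numeric vector S. \code{saliences}: the
#'   requested singular-vector matrix. \code{permPValues}: permutation p
#'   per LV. \code{bootstrapRatios}: brain-variable x LV BSR matrix.
#'   \code{splitHalfZ}: data.frame of Z_sval/Z_svec and their null
#'   thresholds per LV.
#' @name PLSModel-accessors
NULL

#' @rdname PLSModel-accessors
#' @export
setMethod("singularValues", "PLSModel", function(object) object@S)

#' @rdname PLSModel-accessors
#' @export
setMethod("saliences", "PLSModel", function(object,
                                            side = c("brain", "behavior")) {
  side <- match.arg(side)
  if (side == "brain") object@V else object@U
})

#' @rdname PLSModel-accessors
#' @export
setMethod("permPValues", "PLSModel", function(object) object@permP)

#' @rdname PLSModel-accessors
#' @export
setMethod("bootstrapRatios", "PLSModel", function(object) object@BSR)

#' @rdname PLSModel-accessors
#' @export
setMethod("splitHalfZ", "PLSModel", function(object)
  data.frame(lv = seq_along(object@Zsval),
             Zsval = object@Zsval, ZsvalNull = object@ZsvalNull,
             Zsvec = object@Zsvec, ZsvecNull = object@ZsvecNull,
             reproducible = object@Zsvec > 2 + object@ZsvecNull))

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", length(object@S), "latent variable(s),",
      ncol(object@X), "brain variables,", nrow(object@X), "subjects\n")
  for (k in seq_along(object@S)) {
    cat(sprintf("  LV%d: S = %.4f", k, object@S[k]))
    if (length(object@permP) >= k)
      cat(sprintf(", perm p = %.4g", object@permP[k]))
    if (length(object@Zsvec) >= k)
      cat(sprintf(", Z_svec = %.2f (null %.2f)", object@Zsvec[k],
                  object@ZsvecNull[k]))
    cat("\n")
  }
  invisible(NULL)
})

#' Permutation test for latent variable significance
#'
#' Rows of Y are permuted relative to X (joint row permutation, preserving
#' the behavior covariance) and the cross-block SVD refit each iteration.
#' Per LV k the p value is \code{(1 + #{S_perm[k] >= S[k]}) / (nPerm + 1)}.
#'
#' @param model A fitted [PLSModel-class].
#' @param nPerm Number of permutations, at least 19 (default 1000).
#' @param seed Optional integer seed.
#' @return The model with \code{permPValues()} filled in.
#' @export
plsPermutation <- function(model, nPerm = 1000, seed = NULL) {
  stopifnot(is(model, "PLSModel"), nPerm >= 19)
  withSeed(seed)
  n <- nrow(model@X)
  K <- length(model@S)
  exceed <- integer(K)
  for (b in seq_len(nPerm)) {
    Sp <- svd(cor(model@Y[sample.int(n), , drop = FALSE], model@X),
              nu = 0, nv = 0)$d[seq_len(K)]
    exceed <- exceed + (Sp >= model@S)
  }
  model@permP <- (1 + exceed) / (nPerm + 1)
  model@settings$nPerm <- nPerm
  model@settings$permSeed <- seed
  model
}

procrustesRotation <- function(Uboot, U) {
  s <- svd(crossprod(Uboot, U))
  s$u %*% t(s$v)
}

#' Bootstrap ratios and score-correlation intervals
#'
#' Subjects are resampled with replacement; each bootstrap SVD is aligned
#' to the original solution by an orthogonal Procrustes rotation of the
#' behavior saliences (propagated to the brain saliences) to remove
#' sign/axis indeterminacy. The bootstrap ratio of each brain variable is
#' its original salience, scaled by the singular value (the "singular
#' image", the toolbox-standard quantity), divided by the bootstrap
#' standard error of that quantity; values exceeding |2| are
#' conventionally deemed reliable. Percentile 95\% CIs
#' are produced for the correlation between brain scores and each behavior
#' column. Bootstrap samples in which any column becomes constant are
#' redrawn (at most 100 times each).
#'
#' @param model A fitted [PLSModel-class].
#' @param nBoot Number of bootstrap samples, at least 50 (default 1000).
#' @param seed Optional integer seed.
#' @return The model with \code{bootstrapRatios()}, \code{scoreCorCI} and
#'   the redraw count filled in.
#' @export
plsBootstrap <- function(model, nBoot = 1000, seed = NULL) {
  stopifnot(is(model, "PLSModel"), nBoot >= 50)
  withSeed(seed)
  X <- model@X; Y <- model@Y
  n <- nrow(X); K <- length(model@S); nb <- ncol(Y)
  Vsum <- matrix(0, ncol(X), K)
  Vsq <- matrix(0, ncol(X), K)
  corArr <- array(NA_real_, c(nb, K, nBoot))
  redraws <- 0L
  for (b in seq_len(nBoot)) {
    for (try in seq_len(101)) {
      if (try == 101)
        stop("degenerate input: bootstrap samples keep producing ",
             "constant columns")
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      if (all(colVariances(Xb) > 0) && all(colVariances(Yb) > 0)) break
      redraws <- redraws + 1L
    }
    dec <- corSVD(Xb, Yb)
    Q <- procrustesRotation(dec$U, model@U)
    Vb <- dec$V %*% Q
    VSb <- dec$V %*% diag(dec$S, nrow = K) %*% Q
    Vsum <- Vsum + VSb
    Vsq <- Vsq + VSb^2
    corArr[, , b] <- cor(Yb, scale(Xb) %*% Vb)
  }
  se <- sqrt(pmax(0, (Vsq - Vsum^2 / nBoot) / (nBoot - 1)))
  model@BSR <- (model@V %*% diag(model@S, nrow = K)) / se
  dimnames(model@BSR) <- list(model@brainLabels,
                              paste0("LV", seq_len(K)))
  model@scoreCorCI <- lapply(seq_len(K), function(k) {
    ci <- apply(corArr[, k, , drop = FALSE], 1, quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    colnames(ci) <- model@behaviorLabels
    ci
  })
  model@bootRedraws <- redraws
  model@settings$nBoot <- nBoot
  model@settings$bootSeed <- seed
  model
}

# greedy LV matching between two half-sample solutions by absolute
# salience correlation; returns per-LV similarity of singular vectors and
# the matched singular-value products
splitSimilarity <- function(fitA, fitB, Sfull) {
  K <- length(Sfull)
  cm <- abs(cor(fitA$V, fitB$V))
  svec <- numeric(K); sval <- numeric(K)
  used <- rep(FALSE, K)
  for (k in seq_len(K)) {
    j <- which.max(ifelse(used, -Inf, cm[k, ]))
    used[j] <- TRUE
    svec[k] <- cm[k, j]
    sval[k] <- (fitA$S[k] * fitB$S[j]) / Sfull[k]^2
  }
  list(svec = svec, sval = sval)
}

splitOnce <- function(X, Y, Sfull) {
  n <- nrow(X)
  idx <- sample.int(n)
  h1 <- idx[seq_len(ceiling(n / 2))]
  h2 <- idx[-seq_len(ceiling(n / 2))]
  fa <- corSVD(X[h1, , drop = FALSE], Y[h1, , drop = FALSE])
  fb <- corSVD(X[h2, , drop = FALSE], Y[h2, , drop = FALSE])
  splitSimilarity(fa, fb, Sfull)
}

#' Split-half reproducibility of latent variables
#'
#' Subjects are repeatedly split into random halves (the larger half takes
#' the extra subject when n is odd) and the PLS refit in each half. Per
#' LV, the singular-vector similarity is the absolute correlation between
#' the two halves' brain saliences after greedy LV matching, and the
#' singular-value similarity is the matched product of half singular
#' values normalized by the squared full-data singular value. Z_svec and
#' Z_sval are the mean/SD of these draws over splits. Null Z values are
#' computed identically on data whose Y rows are freshly permuted each
#' split; an LV is flagged reproducible when its Z exceeds 2 plus the null
#' Z.
#'
#' @param model A fitted [PLSModel-class] with at least 8 subjects.
#' @param nSplits Number of random splits (default 1000).
#' @param seed Optional integer seed.
#' @return The model with \code{splitHalfZ()} filled in; per-split draws
#'   are kept in \code{model@splitDetail}.
#' @export
plsSplitHalf <- function(model, nSplits = 1000, seed = NULL) {
  stopifnot(is(model, "PLSModel"), nSplits >= 2)
  X <- model@X; Y <- model@Y
  if (nrow(X) < 8) stop("split-half needs at least 8 subjects")
  withSeed(seed)
  K <- length(model@S)
  svec <- matrix(NA_real_, nSplits, K)
  sval <- matrix(NA_real_, nSplits, K)
  for (b in seq_len(nSplits)) {
    sim <- splitOnce(X, Y, model@S)
    svec[b, ] <- sim$svec; sval[b, ] <- sim$sval
  }
  nsvec <- matrix(NA_real_, nSplits, K)
  nsval <- matrix(NA_real_, nSplits, K)
  for (b in seq_len(nSplits)) {
    Yp <- Y[sample.int(nrow(Y)), , drop = FALSE]
    Sp <- corSVD(X, Yp)$S
    sim <- splitOnce(X, Yp, Sp)
    nsvec[b, ] <- sim$svec; nsval[b, ] <- sim$sval
  }
  zOf <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    ifelse(s > 0, mu / s, ifelse(mu > 0, Inf, 0))
  }
  model@Zsvec <- zOf(svec); model@Zsval <- zOf(sval)
  model@ZsvecNull <- zOf(nsvec); model@ZsvalNull <- zOf(nsval)
  model@splitDetail <- list(svec = svec, sval = sval,
                            svecNull = nsvec, svalNull = nsval)
  model@settings$nSplits <- nSplits
  model@settings$splitSeed <- seed
  model
}

#' Reliable pattern of a latent variable
#'
#' Thresholds the bootstrap ratios of one LV at \code{|BSR| >=
#' bsrThreshold}, keeping one sign at a time, and summarizes the selected
#' variables. In edge mode (the model carries an edge-to-region map) the
#' summary includes per-region degree over selected edges, hub regions
#' (degree greater than 3), and the percentage split of selected edges
#' into left-intrahemispheric, right-intrahemispheric and interhemispheric
#' (summing to 100).
#'
#' @param model A [PLSModel-class] after [plsBootstrap()].
#' @param lv Latent variable index.
#' @param bsrThreshold Positive BSR magnitude threshold (default 2).
#' @param regions Region metadata data.frame (needs \code{id},
#'   \code{hemisphere}) for edge mode.
#' @param sign \code{"positive"} or \code{"negative"}: which salience sign
#'   to report.
#' @return A list of class \code{reliablePattern}: \code{lv}, \code{sign},
#'   \code{variables} (label + BSR), and in edge mode \code{degree},
#'   \code{hubs}, \code{pctIntraL}, \code{pctIntraR}, \code{pctInter}.
#' @export
reliablePattern <- function(model, lv, bsrThreshold = 2, regions = NULL,
                            sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (bsrThreshold <= 0) stop("bsrThreshold must be positive")
  if (!length(model@BSR)) stop("run plsBootstrap() first")
  bsr <- model@BSR[, lv]
  sel <- if (sign == "positive") which(bsr >= bsrThreshold)
         else which(bsr <= -bsrThreshold)
  out <- list(lv = lv, sign = sign, bsrThreshold = bsrThreshold,
              variables = data.frame(label = model@brainLabels[sel],
                                     bsr = unname(bsr[sel]),
                                     stringsAsFactors = FALSE))
  if (nrow(model@edgeMap)) {
    em <- model@edgeMap[sel, , drop = FALSE]
    nReg <- if (!is.null(regions)) nrow(regions) else max(model@edgeMap$j)
    deg <- tabulate(c(em$i, em$j), nbins = nReg)
    out$degree <- deg
    out$hubs <- which(deg > 3)
    if (!is.null(regions) && nrow(em)) {
      hi <- regions$hemisphere[em$i]
      hj <- regions$hemisphere[em$j]
      out$pctIntraL <- 100 * mean(hi == "L" & hj == "L")
      out$pctIntraR <- 100 * mean(hi == "R" & hj == "R")
      out$pctInter <- 100 * mean(hi != hj)
    } else if (!is.null(regions)) {
      out$pctIntraL <- out$pctIntraR <- out$pctInter <- NA_real_
    }
  }
  class(out) <- "reliablePattern"
  out
}

#' @export
print.reliablePattern <- function(x, ...) {
  cat(sprintf("LV%d %s pattern: %d variable(s) at |BSR| >= %g\n", x$lv,
              x$sign, nrow(x$variables), x$bsrThreshold))
  if (!is.null(x$hubs) && length(x$hubs))
    cat("  hub regions (degree > 3):", paste(x$hubs, collapse = ", "), "\n")
  if (!is.null(x$pctIntraL) && !is.na(x$pctIntraL))
    cat(sprintf("  intra-L %.1f%% / intra-R %.1f%% / inter %.1f%%\n",
                x$pctIntraL, x$pctIntraR, x$pctInter))
  invisible(x)
}

#' Assemble PLS inputs from a connectome cohort
#'
#' \code{plsFromEdges} vectorizes each subject's retained connections
#' (edges with any nonzero weight across subjects) into X;
#' \code{plsFromMetrics} uses the region-wise nodal (\code{ne_*}) or local
#' (\code{le_*}) efficiency columns of a [computeGraphMetrics()] table.
#' Both take Y = (age, fluid intelligence) and return a fitted point-
#' estimate model.
#'
#' @param set A QC'd [ConnectomeSet-class].
#' @param metrics A [computeGraphMetrics()] table.
#' @param mode \code{"nodal"} or \code{"local"}.
#' @param group Optional subject filter: \code{"YA"}, \code{"OA"} or
#'   \code{"all"} (default).
#' @return A fitted [PLSModel-class].
#' @export
plsFromEdges <- function(set, group = "all") {
  cd <- cohort(set)
  keep <- if (group == "all") rep(TRUE, nrow(cd)) else cd$group == group
  sc <- assay(set, "sc")[, keep, drop = FALSE]
  present <- rowSums(sc > 0) > 0
  ei <- edgeIndex(nRegions(set))[present, ]
  X <- t(sc[present, , drop = FALSE])
  colnames(X) <- paste0("e", ei$i, "_", ei$j)
  Y <- cbind(age = cd$age[keep],
             fluid_intelligence = cd$fluid_intelligence[keep])
  plsFit(X, Y, edgeMap = ei)
}

#' @rdname plsFromEdges
#' @export
plsFromMetrics <- function(metrics, mode = c("nodal", "local"),
                           group = "all") {
  mode <- match.arg(mode)
  prefix <- if (mode == "nodal") "ne_" else "le_"
  keep <- if (group == "all") rep(TRUE, nrow(metrics))
          else metrics$group == group
  cols <- grep(paste0("^", prefix), names(metrics), value = TRUE)
  X <- as.matrix(metrics[keep, cols])
  Y <- cbind(age = metrics$age[keep],
             fluid_intelligence = metrics$fluid_intelligence[keep])
  plsFit(X, Y)
}
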