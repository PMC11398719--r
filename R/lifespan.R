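# Rolling-window lifespan correlations with BCa bootstrap intervals,
# t tests, and the whole-brain multilinear models of local efficiency.

resampleRows <- function(x, idx) {
  if (is.matrix(x) || is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa interval for an arbitrary scalar statistic: the bias
#' correction z0 comes from the fraction of bootstrap replicates below the
#' point estimate, the acceleration a from the jackknife skewness, and the
#' percentile endpoints are adjusted accordingly. With z0 = 0 and a = 0
#' the interval reduces to the plain percentile interval. A degenerate
#' bootstrap distribution (all replicates equal) collapses the interval to
#' the point estimate.
#'
#' @param sample Data: a vector, or a matrix/data.frame resampled by rows.
#' @param statistic Function of the (re)sampled data returning a scalar.
#' @param nBoot Bootstrap replicates (default 1000).
#' @param alpha Two-sided miss probability (default 0.05 for a 95\% CI).
#' @param seed Optional integer seed.
#' @return Numeric \code{c(low, high)}.
#' @export
bcaInterval <- function(sample, statistic, nBoot = 1000, alpha = 0.05,
                        seed = NULL) {
  n <- NROW(sample)
  stopifnot(n >= 3, nBoot >= 50)
  withSeed(seed)
  t0 <- statistic(sample)
  tb <- vapply(seq_len(nBoot), function(b)
    statistic(resampleRows(sample, sample.int(n, n, replace = TRUE))),
    numeric(1))
  tb <- tb[is.finite(tb)]
  if (!length(tb) || sd(tb) == 0) return(c(t0, t0))
  p0 <- (sum(tb < t0) + 0.5 * sum(tb == t0)) / length(tb)
  p0 <- min(max(p0, 1 / (length(tb) + 1)), length(tb) / (length(tb) + 1))
  z0 <- qnorm(p0)
  tj <- vapply(seq_len(n), function(i)
    statistic(resampleRows(sample, -i)), numeric(1))
  tj <- tj[is.finite(tj)]
  dev <- mean(tj) - tj
  denom <- 6 * sum(dev^2)^1.5
  a <- if (denom > 0) sum(dev^3) / denom else 0
  adj <- function(z) {
    zt <- z0 + z
    pnorm(z0 + zt / (1 - a * zt))
  }
  unname(quantile(tb, c(adj(qnorm(alpha / 2)), adj(qnorm(1 - alpha / 2)))))
}

#' Rolling-window correlation across the lifespan
#'
#' Slides a fixed-width age window (default 10 years, stepping 1 year)
#' over the cohort and correlates a per-subject brain measure with fluid
#' intelligence inside each window. Windows start at integer years from
#' \code{floor(min(age))} to \code{floor(max(age)) - width + 1}
#' (inclusive), with half-open membership \code{[start, start + width)}.
#' Each window's Pearson r gets a BCa bootstrap CI; windows with fewer
#' than 3 subjects report NA.
#'
#' @param ages,metric,fi Equal-length numeric vectors per subject.
#' @param width Window width in years (positive; default 10).
#' @param step Window step in years (default 1).
#' @param nBoot Bootstrap replicates per window.
#' @param seed Optional integer seed (per-window seeds are derived).
#' @return data.frame with columns \code{age_start}, \code{age_end},
#'   \code{n}, \code{r}, \code{ci_low}, \code{ci_high}.
#' @export
rollingCorrelation <- function(ages, metric, fi, width = 10, step = 1,
                               nBoot = 1000, seed = NULL) {
  if (width <= 0) stop("width must be positive")
  stopifnot(length(ages) == length(metric), length(ages) == length(fi))
  starts <- seq(floor(min(ages)), floor(max(ages)) - width + 1, by = step)
  rows <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    sel <- ages >= s & ages < s + width
    nw <- sum(sel)
    if (nw < 3)
      return(data.frame(age_start = s, age_end = s + width, n = nw,
                        r = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_))
    d <- cbind(metric[sel], fi[sel])
    r <- cor(d[, 1], d[, 2])
    ci <- bcaInterval(d, function(x) suppressWarnings(cor(x[, 1], x[, 2])),
                      nBoot = nBoot,
                      seed = if (is.null(seed)) NULL else seed + k)
    data.frame(age_start = s, age_end = s + width, n = nw, r = r,
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, rows)
}

#' Two-sided t tests
#'
#' Paired t test (df = n - 1) or independent-samples t test, the latter
#' with the Welch correction by default or pooled variance (df = n1 + n2 -
#' 2) when \code{pooled = TRUE}. A paired test of identical vectors
#' returns t = 0, p = 1.
#'
#' @param a,b Numeric samples (equal length when paired).
#' @param paired Paired test? Default FALSE.
#' @param pooled Pooled-variance independent test? Default FALSE (Welch).
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
tTests <- function(a, b, paired = FALSE, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 observations")
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must be equal length")
    d <- a - b
    n <- length(d)
    s <- sd(d)
    t <- if (s == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else mean(d) / (s / sqrt(n))
    df <- n - 1
    return(list(t = t, df = df, p = 2 * pt(-abs(t), df)))
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

modelTermMap <- c("(Intercept)" = "Intercept", age = "Age",
                  sexM = "Sex (male)", small_worldness = "Small-worldness",
                  sc_total = "SC total", mean_sc_distance = "SC distance")

#' Whole-brain multilinear models of local efficiency
#'
#' Ordinary least squares relating the mean local efficiency over a region
#' set (typically the regions a PLS analysis flagged) to whole-brain
#' network measures within an age group. Model 1 uses age, sex,
#' small-worldness and SC total; Model 2 substitutes mean SC distance for
#' SC total; Model 3 includes both. Sex is coded with female as the
#' reference level, so the reported term is "Sex (male)".
#'
#' @param metrics A [computeGraphMetrics()] table.
#' @param modelId 1, 2 or 3.
#' @param group \code{"YA"}, \code{"OA"} or \code{"all"}.
#' @param regionSet Integer region ids over which the dependent mean local
#'   efficiency is taken; default all regions.
#' @return data.frame of class \code{"regressionFit"} with columns
#'   \code{term}, \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{se}, \code{t}, \code{p}; attributes \code{r.squared}, \code{n},
#'   \code{dependent}.
#' @export
fitLocalEfficiencyModels <- function(metrics, modelId = 1, group = "all",
                                     regionSet = NULL) {
  stopifnot(modelId %in% 1:3)
  keep <- if (group == "all") rep(TRUE, nrow(metrics))
          else metrics$group == group
  dat <- metrics[keep, , drop = FALSE]
  leCols <- grep("^le_", names(dat), value = TRUE)
  if (!is.null(regionSet)) {
    leCols <- paste0("le_", sprintf("%03d", regionSet))
    miss <- setdiff(leCols, names(dat))
    if (length(miss)) stop("unknown regions: ", paste(miss, collapse = ", "))
  }
  dv <- rowMeans(dat[, leCols, drop = FALSE])
  terms <- switch(modelId,
                  c("age", "sex", "small_worldness", "sc_total"),
                  c("age", "sex", "small_worldness", "mean_sc_distance"),
                  c("age", "sex", "small_worldness", "sc_total",
                    "mean_sc_distance"))
  df <- dat[, terms, drop = FALSE]
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df$.y <- dv
  fit <- lm(.y ~ ., data = df)
  mm <- model.matrix(fit)
  if (qr(mm)$rank < ncol(mm)) {
    bad <- names(which(is.na(coef(fit))))
    stop("collinear design; offending term(s): ",
         paste(bad, collapse = ", "))
  }
  cn <- kappa(scale(mm[, -1, drop = FALSE]), exact = TRUE)
  if (is.finite(cn) && cn > 1e10)
    stop("near-collinear design (condition number ", format(cn), "): ",
         paste(colnames(mm)[-1], collapse = ", "))
  sm <- summary(fit)
  co <- sm$coefficients
  crit <- qt(0.975, fit$df.residual)
  nm <- modelTermMap[rownames(co)]
  nm[is.na(nm)] <- rownames(co)[is.na(nm)]
  out <- data.frame(term = unname(nm), estimate = co[, 1],
                    ci_low = co[, 1] - crit * co[, 2],
                    ci_high = co[, 1] + crit * co[, 2],
                    se = co[, 2], t = co[, 3], p = co[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "r.squared") <- sm$r.squared
  attr(out, "n") <- nrow(df)
  attr(out, "dependent") <- sprintf(
    "mean local efficiency over %d region(s), group %s",
    length(leCols), group)
  attr(out, "modelId") <- modelId
  class(out) <- c("regressionFit", "data.frame")
  out
}

#' Compare a coefficient between two group fits by CI overlap
#'
#' Declares the two estimates "different" only when their 95\% confidence
#' intervals do not overlap -- a deliberately conservative criterion.
#'
#' @param fitA,fitB Fits from [fitLocalEfficiencyModels()].
#' @param term Term name present in both fits (e.g. "Small-worldness").
#' @return List with \code{term}, \code{verdict} ("different" or
#'   "not different"), and both intervals.
#' @export
compareGroupEstimates <- function(fitA, fitB, term) {
  ra <- fitA[fitA$term == term, ]
  rb <- fitB[fitB$term == term, ]
  if (nrow(ra) != 1 || nrow(rb) != 1)
    stop("term not found in both fits: ", term)
  disjoint <- ra$ci_low > rb$ci_high || rb$ci_low > ra$ci_high
  list(term = term,
       verdict = if (disjoint) "different" else "not different",
       ciA = c(ra$ci_low, ra$ci_high), ciB = c(rb$ci_low, rb$ci_high))
}
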