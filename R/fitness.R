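#' @include AllClasses.R AllGenerics.R simulate.R
NULL

#' Growth recovery rate from colony sizes
#'
#' \deqn{recovery = (S_i - S_r) / S_r \times 100}
#' where \eqn{S_i} is the mean colony size (diameter, mm) of the SCRaMbLEd
#' strain and \eqn{S_r} that of its unSCRaMbLEd disome parent.  Negative
#' values (slower than the parent) are allowed.  The screen protocol averages
#' at least 200 single colonies per strain; a warning is emitted below that.
#'
#' @param colonySizes colony diameters of strain i (mm).
#' @param refColonySizes colony diameters of the reference strain.
#' @param useMedian use medians instead of means (robust variant; the screen
#'   itself uses means).
#' @return list with \code{Si}, \code{Sr}, \code{valuePct}.
#' @export
growthRecoveryRate <- function(colonySizes, refColonySizes,
                               useMedian = FALSE) {
  if (length(colonySizes) == 0L || length(refColonySizes) == 0L)
    stop("colony size samples must be nonempty")
  if (length(colonySizes) < 200L || length(refColonySizes) < 200L)
    warning("fewer than 200 colonies; the screen protocol averages >= 200")
  mid <- if (useMedian) stats::median else mean
  si <- mid(colonySizes); sr <- mid(refColonySizes)
  if (sr <= 0) stop("reference colony size must be positive")
  list(Si = si, Sr = sr, valuePct = (si - sr) / sr * 100)
}

#' Doubling time from an OD600 growth curve
#'
#' The OD readings are log10-transformed; an ordinary least-squares slope is
#' fitted in every window of 7 consecutive measurements; the largest slope
#' \eqn{k} (per minute) defines the doubling time \eqn{DT = \log_{10}(2)/k}.
#' Exact on pure exponentials regardless of window position, and insensitive
#' to lag and saturation phases by construction of the max-slope rule.
#'
#' @param curve data.frame with columns \code{time_min} and \code{od600}
#'   (all OD > 0), at least 7 readings.
#' @param window window length in readings (default 7).
#' @return list with \code{k} (max slope of log10 OD per minute) and
#'   \code{dtMin} (doubling time, minutes).
#' @export
doublingTime <- function(curve, window = 7L) {
  stopifnot(all(c("time_min", "od600") %in% names(curve)))
  if (nrow(curve) < window)
    stop("need at least ", window, " readings")
  if (any(curve$od600 <= 0)) stop("all OD readings must be positive")
  y <- log10(curve$od600)
  t <- curve$time_min
  nw <- nrow(curve) - window + 1L
  slopes <- vapply(seq_len(nw), function(i) {
    idx <- i:(i + window - 1L)
    tt <- t[idx]; yy <- y[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  k <- max(slopes)
  if (k <= 0) stop("no growth detected (max slope <= 0)")
  list(k = k, dtMin = log10(2) / k)
}

#' Retention vs growth-recovery regression across a population
#'
#' Pearson correlation and ordinary least-squares fit of growth recovery
#' (percent) on retained fraction, with a pointwise 95 percent confidence
#' band for the fitted line.  In the calibrated simulation, as in the screen,
#' the association is negative: strains that lost more chromosome content
#' recover more fitness.
#'
#' @param population a \linkS4class{ScramblePopulation} or list of
#'   \linkS4class{StrainRecord} with fitness assigned.
#' @param level confidence level for the band.
#' @return list with \code{r}, \code{slope}, \code{intercept}, \code{fit}
#'   (the \code{lm} object) and \code{band} (data.frame: retained, fit, lwr,
#'   upr).
#' @export
retentionRecoveryRegression <- function(population, level = 0.95) {
  recs <- if (is(population, "ScramblePopulation")) population@strains
  else population
  if (length(recs) < 3L) stop("need at least 3 strains")
  x <- vapply(recs, function(r) r@retainedFraction, numeric(1))
  y <- vapply(recs, function(r) r@recoveryRatePct, numeric(1))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in retention or recovery")
  fit <- stats::lm(y ~ x)
  grid <- data.frame(x = seq(min(x), max(x), length.out = 50L))
  ci <- stats::predict(fit, newdata = grid, interval = "confidence",
                       level = level)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       fit = fit,
       band = data.frame(retained = grid$x, fit = ci[, "fit"],
                         lwr = ci[, "lwr"], upr = ci[, "upr"]))
}

#' Deletion matrix of a population
#'
#' @param population a \linkS4class{ScramblePopulation} or list of
#'   \linkS4class{StrainRecord}.
#' @param map reference \linkS4class{SegmentMap}.
#' @return strains x segments binary matrix; 1 = segment deleted (absent
#'   from the strain's word).
#' @export
deletionMatrix <- function(population, map) {
  recs <- if (is(population, "ScramblePopulation")) population@strains
  else population
  ids <- segIds(map)
  m <- t(vapply(recs, function(r)
    as.integer(!(ids %in% r@structure@segIds)), integer(length(ids))))
  dimnames(m) <- list(vapply(recs, function(r) r@strainId, character(1)), ids)
  m
}

#' Chromosome-wide deletion vs fitness association scan
#'
#' For every segment, compares growth recovery between strains that deleted
#' it and strains that retained it (Welch two-sample t-test by default, or a
#' seeded permutation test), with family-wise control by Bonferroni.
#' Segments deleted in all strains or in none are returned untested with a
#' reason.
#'
#' @param deletions strains x segments binary matrix (see
#'   \code{\link{deletionMatrix}}).
#' @param recovery per-strain growth recovery percent, aligned with rows.
#' @param method \code{"welch"} or \code{"permutation"}.
#' @param nPerm permutations when \code{method = "permutation"}.
#' @param alpha family-wise level for the Bonferroni flag.
#' @param minGroup minimum strains per group for a segment to be testable.
#' @param seed optional seed for the permutation method.
#' @return data.frame with one row per segment: group means, statistic,
#'   \code{p}, \code{pBonferroni}, \code{pass}, group sizes, \code{reason}
#'   (\code{NA} for tested segments, e.g. "no contrast" otherwise).
#' @export
associationScan <- function(deletions, recovery, method = c("welch",
                                                            "permutation"),
                            nPerm = 1000L, alpha = 0.05, minGroup = 2L,
                            seed = NULL) {
  method <- match.arg(method)
  stopifnot(nrow(deletions) == length(recovery))
  segs <- colnames(deletions)
  res <- data.frame(segment = segs, meanDeleted = NA_real_,
                    meanRetained = NA_real_, statistic = NA_real_,
                    p = NA_real_, pBonferroni = NA_real_, pass = FALSE,
                    nDeleted = colSums(deletions),
                    nRetained = nrow(deletions) - colSums(deletions),
                    reason = NA_character_, stringsAsFactors = FALSE)
  testable <- res$nDeleted >= minGroup & res$nRetained >= minGroup
  res$reason[!testable] <- ifelse(
    res$nDeleted[!testable] == 0L | res$nRetained[!testable] == 0L,
    "no contrast", "group too small")
  nTest <- sum(testable)
  if (nTest == 0L) stop("no testable segment")
  .withSeed(seed, {
    for (j in which(testable)) {
      del <- deletions[, j] == 1L
      a <- recovery[del]; b <- recovery[!del]
      tt <- stats::t.test(a, b)
      res$meanDeleted[j] <- mean(a)
      res$meanRetained[j] <- mean(b)
      res$statistic[j] <- unname(tt$statistic)
      if (method == "welch") {
        res$p[j] <- tt$p.value
      } else {
        obs <- abs(unname(tt$statistic))
        hits <- 0L
        for (b_ in seq_len(nPerm)) {
          perm <- sample(recovery)
          tp <- stats::t.test(perm[del], perm[!del])$statistic
          if (abs(unname(tp)) >= obs) hits <- hits + 1L
        }
        res$p[j] <- (hits + 1L) / (nPerm + 1L)
      }
    }
  })
  res$pBonferroni <- pmin(res$p * nTest, 1)
  res$pass <- !is.na(res$p) & res$pBonferroni < alpha
  res
}

#' Generations to lose a circular chromosome from a population
#'
#' With a per-division loss probability \eqn{p}, the fraction of the
#' population still carrying the chromosome after \eqn{g} generations is
#' \eqn{(1-p)^g}; the closed form for the generation at which it crosses a
#' target fraction is \eqn{g = \ln(target)/\ln(1-p)}.  A Monte Carlo
#' companion simulates independent lineages and reports the empirical
#' crossing generation.
#'
#' @param pLoss per-division loss probability in [0, 1).
#' @param targetFraction population fraction still retaining the chromosome,
#'   in (0, 1).
#' @param nLineages Monte Carlo lineages (0 to skip simulation).
#' @param maxGenerations simulation horizon.
#' @param seed optional seed.
#' @return list with \code{generations} (closed form; \code{Inf} when
#'   \code{pLoss = 0}) and \code{mcGenerations} (\code{NA} if skipped).
#' @export
stabilityGenerations <- function(pLoss, targetFraction, nLineages = 0L,
                                 maxGenerations = 2000L, seed = NULL) {
  stopifnot(pLoss >= 0, pLoss < 1, targetFraction > 0, targetFraction < 1)
  g <- if (pLoss == 0) Inf else log(targetFraction) / log(1 - pLoss)
  mc <- NA_real_
  if (nLineages > 0L && pLoss > 0) {
    mc <- .withSeed(seed, {
      # lineage loses at a geometric generation; crossing generation is the
      # empirical quantile of loss times
      lossGen <- stats::rgeom(nLineages, pLoss) + 1L
      retain <- vapply(seq_len(maxGenerations), function(gen)
        mean(lossGen > gen), numeric(1))
      idx <- which(retain < targetFraction)[1L]
      if (is.na(idx)) NA_real_ else as.numeric(idx)
    })
  }
  list(generations = g, mcGenerations = mc)
}
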