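#' @include AllClasses.R AllGenerics.R simulate.R segment-map.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Synthetic environmental stress response gene sets
#'
#' The ESR program comprises roughly 300 induced (iESR) and 600 repressed
#' (rESR) genes; this builds disjoint synthetic id sets of those sizes,
#' living on the background genome (not on the SCRaMbLEd chromosome).
#'
#' @param nIesr,nResr set sizes.
#' @return list with character vectors \code{iESR} and \code{rESR}.
#' @export
makeEsrGeneSets <- function(nIesr = 300L, nResr = 600L)
  list(iESR = sprintf("ESRi%03d", seq_len(nIesr)),
       rESR = sprintf("ESRr%03d", seq_len(nResr)))

#' Expression generator parameters
#'
#' @param baselineMeanLog,baselineSdLog log-normal law for per-gene baseline
#'   means (defaults centre near 200 counts).
#' @param dispersion negative-binomial dispersion (\code{size = 1/dispersion}).
#' @param bufferedFraction fraction of chromosome genes whose expression is
#'   dosage-buffered (held at 1x despite two copies); default 0.10.
#' @param esrLog2fcMax log2 shift of ESR genes at full fitness burden; the
#'   realized shift is \code{esrLog2fcMax * burden} with burden
#'   \code{= 1 - recovery/100} clamped to [0, 1].  The default (2.5) puts a
#'   fully burdened disome's ESR genes far past the 0.001 call threshold
#'   under the default dispersion, while a largely recovered strain's
#'   residual shift is called only at the background rate.
#' @param nBackground additional unregulated background-genome genes.
#' @param noise draw negative-binomial counts (\code{TRUE}) or emit exact
#'   means (\code{FALSE}).
#' @return list of class parameters used by \code{\link{simulateExpression}}.
#' @export
expressionParams <- function(baselineMeanLog = log(200), baselineSdLog = 0.5,
                             dispersion = 0.05, bufferedFraction = 0.10,
                             esrLog2fcMax = 2.5, nBackground = 300L,
                             noise = TRUE) {
  if (bufferedFraction < 0 || bufferedFraction > 1)
    stop("bufferedFraction must be in [0, 1]")
  list(baselineMeanLog = baselineMeanLog, baselineSdLog = baselineSdLog,
       dispersion = dispersion, bufferedFraction = bufferedFraction,
       esrLog2fcMax = esrLog2fcMax, nBackground = as.integer(nBackground),
       noise = noise)
}

#' Simulate a dosage + ESR expression matrix
#'
#' Builds a genes x strains count matrix: chromosome genes double their mean
#' when their segment is retained on the synthetic copy (one wild-type plus
#' one synthetic copy), except a fixed buffered subset held at 1x; iESR and
#' rESR genes shift up/down by \code{2^(esrLog2fcMax * burden)} where burden
#' is the strain's fitness burden (zero at full recovery); an euploid
#' \code{"reference"} column (all copies 1, burden 0) is always included.
#'
#' @param population a \linkS4class{ScramblePopulation} or list of
#'   \linkS4class{StrainRecord} with recovery rates assigned.
#' @param map reference \linkS4class{SegmentMap}.
#' @param geneSets from \code{\link{makeEsrGeneSets}}.
#' @param params from \code{\link{expressionParams}}.
#' @param seed optional seed.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assays
#'   \code{counts} and \code{copies}, gene metadata (segment, buffered, ESR
#'   set) and strain metadata (recovery, burden).
#' @export
simulateExpression <- function(population, map,
                               geneSets = makeEsrGeneSets(),
                               params = expressionParams(), seed = NULL) {
  recs <- if (is(population, "ScramblePopulation")) population@strains
  else population
  .withSeed(seed, {
    segGeneList <- segGenes(map)
    chrGenes <- unlist(segGeneList, use.names = FALSE)
    geneSeg <- rep(names(segGeneList), lengths(segGeneList))
    bg <- sprintf("BG%04d", seq_len(params$nBackground))
    genes <- c(chrGenes, geneSets$iESR, geneSets$rESR, bg)
    seg <- c(geneSeg, rep("background", length(genes) - length(chrGenes)))
    nG <- length(genes)
    base <- stats::rlnorm(nG, params$baselineMeanLog, params$baselineSdLog)
    buffered <- rep(FALSE, nG)
    nBuf <- round(params$bufferedFraction * length(chrGenes))
    buffered[sample(length(chrGenes), nBuf)] <- TRUE
    set <- rep("none", nG)
    set[genes %in% geneSets$iESR] <- "iESR"
    set[genes %in% geneSets$rESR] <- "rESR"

    strainNames <- c("reference",
                     vapply(recs, function(r) r@strainId, character(1)))
    burden <- c(0, vapply(recs, function(r)
      min(max(1 - r@recoveryRatePct / 100, 0), 1), numeric(1)))
    copies <- matrix(1L, nG, length(strainNames),
                     dimnames = list(genes, strainNames))
    for (j in seq_along(recs)) {
      present <- seg %in% recs[[j]]@structure@segIds
      copies[present, j + 1L] <- 2L
    }
    mu <- matrix(base, nG, length(strainNames),
                 dimnames = list(genes, strainNames))
    dosageFactor <- ifelse(copies == 2L & !buffered, 2, 1)
    mu <- mu * dosageFactor
    esrShift <- outer(ifelse(set == "iESR", 1, ifelse(set == "rESR", -1, 0)),
                      burden * params$esrLog2fcMax)
    mu <- mu * 2^esrShift
    counts <- if (params$noise)
      matrix(stats::rnbinom(length(mu), size = 1 / params$dispersion,
                            mu = mu), nG, length(strainNames),
             dimnames = dimnames(mu))
    else mu
    se <- SummarizedExperiment(
      assays = list(counts = counts, copies = copies),
      rowData = DataFrame(gene = genes, segment = seg,
                          buffered = buffered, esrSet = set),
      colData = DataFrame(strain = strainNames, burden = burden,
                          row.names = strainNames))
    S4Vectors::metadata(se)$dispersion <- params$dispersion
    se
  })
}

# per-gene fold change of one strain column vs the reference column; exact
# ratio when the reference count is positive, pseudocount-guarded otherwise
.foldChange <- function(counts, strain, reference, pseudocount = 1) {
  x <- counts[, strain]; r <- counts[, reference]
  ifelse(r > 0, x / r, (x + pseudocount) / pseudocount)
}

#' Dosage summary: fold changes and the buffered-gene fraction
#'
#' Computes per-gene log2 fold change of each strain against the reference
#' column and, among that strain's duplicated genes (copy number 2), the
#' fraction whose fold change stays below the buffering threshold.
#'
#' @param se SummarizedExperiment from \code{\link{simulateExpression}} (or
#'   compatible, with assays \code{counts} and \code{copies}).
#' @param reference reference column name (default \code{"reference"}).
#' @param bufferedLog2fc genes with log2 FC below this count as buffered
#'   (default 0.32, i.e. below 1.25x).
#' @param pseudocount used only when the reference count is zero.
#' @return list with \code{log2fc} (genes x strains matrix, reference column
#'   dropped) and \code{bufferedFraction} (named per strain; \code{NaN} for
#'   strains with no duplicated gene).
#' @export
dosageSummary <- function(se, reference = "reference",
                          bufferedLog2fc = 0.32, pseudocount = 1) {
  counts <- assay(se, "counts")
  copies <- assay(se, "copies")
  if (!reference %in% colnames(counts))
    stop("reference strain not in matrix: ", reference)
  strains <- setdiff(colnames(counts), reference)
  l2 <- vapply(strains, function(s)
    log2(.foldChange(counts, s, reference, pseudocount)),
    numeric(nrow(counts)))
  rownames(l2) <- rownames(counts)
  buf <- vapply(strains, function(s) {
    dup <- copies[, s] == 2L
    if (!any(dup)) return(NaN)
    mean(l2[dup, s] < bufferedLog2fc)
  }, numeric(1))
  # pooled estimate: averaging log2 FC over replicate strains before
  # thresholding shrinks the per-gene measurement noise, so with a few
  # replicates the estimate converges on the true buffered fraction
  dupAll <- rowSums(copies[, strains, drop = FALSE] == 2L) ==
    length(strains)
  pooled <- if (any(dupAll))
    mean(rowMeans(l2[dupAll, , drop = FALSE]) < bufferedLog2fc)
  else NaN
  list(log2fc = l2, bufferedFraction = buf, bufferedFractionPooled = pooled)
}

# two-sided test of count x vs reference count r under a shared negative-
# binomial model with known dispersion: the log ratio of two NB counts with
# equal means has variance approximately 2 * (dispersion + 1/mu), so a
# z-test on log((x+0.5)/(r+0.5)) controls the call rate under the
# generator's own noise (a Poisson-conditional binomial test would be badly
# anticonservative at biological dispersions)
.countTestP <- function(x, r, dispersion) {
  mu <- (x + r) / 2
  if (mu <= 0) return(1)
  se <- sqrt(2 * (dispersion + 1 / max(mu, 0.5)))
  z <- log((x + 0.5) / (r + 0.5)) / se
  2 * stats::pnorm(-abs(z))
}

#' ESR signature score of one strain
#'
#' Calls each gene up- or down-regulated versus the reference column (exact
#' conditional two-sample count test at \code{deThreshold}), reports the
#' fraction of iESR genes called up and of rESR genes called down, and tests
#' enrichment of each set among the calls in its direction with the exact
#' hypergeometric tail, Benjamini-Hochberg-adjusted across the reported
#' tests.
#'
#' @param se SummarizedExperiment with assay \code{counts}.
#' @param strain strain column to score.
#' @param geneSets list with \code{iESR} and \code{rESR} id vectors, all
#'   present in the matrix.
#' @param reference reference column (default \code{"reference"}).
#' @param deThreshold p-value threshold for the up/down call (default 0.001).
#' @param dispersion negative-binomial dispersion assumed by the call test;
#'   taken from the matrix metadata when present.
#' @return list with \code{iesrUpFraction}, \code{resrDownFraction},
#'   \code{pIesr}, \code{pResr} (hypergeometric), \code{qIesr}, \code{qResr}
#'   (BH), \code{nUp}, \code{nDown}.
#' @export
esrScore <- function(se, strain, geneSets, reference = "reference",
                     deThreshold = 0.001, dispersion = NULL) {
  if (is.null(dispersion))
    dispersion <- S4Vectors::metadata(se)$dispersion
  if (is.null(dispersion)) dispersion <- 0.05
  counts <- assay(se, "counts")
  missing <- setdiff(c(geneSets$iESR, geneSets$rESR), rownames(counts))
  if (length(missing))
    stop("gene set ids absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  x <- counts[, strain]; r <- counts[, reference]
  p <- vapply(seq_along(x), function(i)
    .countTestP(x[i], r[i], dispersion), numeric(1))
  up <- p < deThreshold & x > r
  down <- p < deThreshold & x < r
  genes <- rownames(counts)
  iesr <- genes %in% geneSets$iESR
  resr <- genes %in% geneSets$rESR
  nG <- length(genes)
  hyper <- function(hits, setSize, drawn)
    stats::phyper(hits - 1L, setSize, nG - setSize, drawn,
                  lower.tail = FALSE)
  pI <- hyper(sum(up & iesr), sum(iesr), sum(up))
  pR <- hyper(sum(down & resr), sum(resr), sum(down))
  q <- stats::p.adjust(c(pI, pR), method = "BH")
  list(iesrUpFraction = mean(up[iesr]),
       resrDownFraction = mean(down[resr]),
       pIesr = pI, pResr = pR, qIesr = q[1L], qResr = q[2L],
       nUp = sum(up), nDown = sum(down))
}

#' ESR reversal report across strains
#'
#' Scores every strain and flags an ESR reversal when, compared with the
#' disome parent's strong signature, both the iESR-up and rESR-down fractions
#' fall below the configured cutoffs (both directions are required).
#'
#' @param se SummarizedExperiment from \code{\link{simulateExpression}}.
#' @param geneSets ESR sets.
#' @param disome column name of the unSCRaMbLEd disome parent.
#' @param strains columns to report (default: all but the reference).
#' @param reference euploid reference column.
#' @param iesrCutoff,resrCutoff fraction cutoffs for the reversal call
#'   (defaults 0.5 each).
#' @param deThreshold passed to \code{\link{esrScore}}.
#' @return data.frame, one row per strain: both fractions, hypergeometric
#'   p/q values, and \code{reversed}.
#' @export
esrReversalReport <- function(se, geneSets, disome,
                              strains = NULL, reference = "reference",
                              iesrCutoff = 0.5, resrCutoff = 0.5,
                              deThreshold = 0.001) {
  counts <- assay(se, "counts")
  if (is.null(strains))
    strains <- setdiff(colnames(counts), reference)
  if (!disome %in% colnames(counts))
    stop("disome column not in matrix: ", disome)
  rows <- lapply(strains, function(s) {
    sc <- esrScore(se, s, geneSets, reference, deThreshold)
    data.frame(strain = s, iesrUpFraction = sc$iesrUpFraction,
               resrDownFraction = sc$resrDownFraction,
               pIesr = sc$pIesr, pResr = sc$pResr,
               qIesr = sc$qIesr, qResr = sc$qResr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dsc <- if (disome %in% out$strain) {
    out[match(disome, out$strain), ]
  } else {
    sc <- esrScore(se, disome, geneSets, reference, deThreshold)
    data.frame(iesrUpFraction = sc$iesrUpFraction,
               resrDownFraction = sc$resrDownFraction)
  }
  # a reversal is only meaningful when the disome itself shows the signature
  disomeSignature <- dsc$iesrUpFraction >= iesrCutoff &&
    dsc$resrDownFraction >= resrCutoff
  out$reversed <- disomeSignature &
    out$iesrUpFraction < iesrCutoff & out$resrDownFraction < resrCutoff
  out
}
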