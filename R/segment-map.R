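#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SegmentMap from vectors
#'
#' @param lengths positive integer segment lengths (bp), left to right.
#' @param ids segment ids; default \code{"S01"..}.
#' @param centromere index (or id) of the centromere segment.
#' @param marker index (or id) of the segment carrying the selection marker,
#'   with \code{markerLabel} naming it; \code{NULL} for none.
#' @param genes optional list of character vectors of gene labels per segment.
#' @param chrom chromosome name used in file output.
#' @param markerLabel marker name recorded on the marker segment.
#' @return a \linkS4class{SegmentMap}.
#' @export
SegmentMap <- function(lengths, ids = NULL, centromere, marker = NULL,
                       genes = NULL, chrom = "synVII", markerLabel = "LEU2") {
  n <- length(lengths)
  stopifnot(n >= 1L, all(lengths >= 1))
  if (is.null(ids))
    ids <- sprintf("S%0*d", max(2L, nchar(n)), seq_len(n))
  idx <- function(x) if (is.character(x)) match(x, ids) else as.integer(x)
  cen <- idx(centromere)
  if (is.na(cen) || cen < 1L || cen > n) stop("invalid centromere segment")
  isCen <- seq_len(n) == cen
  mk <- rep(NA_character_, n)
  if (!is.null(marker)) mk[idx(marker)] <- markerLabel
  arm <- ifelse(isCen, "centromeric",
                ifelse(seq_len(n) < cen, "left", "right"))
  if (is.null(genes)) genes <- rep(list(character(0)), n)
  geneStr <- vapply(genes, function(g)
    if (length(g)) paste(g, collapse = ";") else NA_character_, character(1))
  ends <- cumsum(as.numeric(lengths))
  starts <- c(1, head(ends, -1) + 1)
  gr <- GRanges(chrom, IRanges(start = starts, end = ends))
  mcols(gr) <- DataFrame(segId = ids, genes = geneStr,
                         isCentromere = isCen, marker = mk, arm = arm)
  new("SegmentMap", ranges = gr)
}

#' Read a segment map from a BED-like TSV
#'
#' Columns (tab-separated, with header): \code{chrom}, \code{start},
#' \code{end} (0-based half-open), \code{id}, \code{centromere} (0/1),
#' \code{marker} (label or \code{.}), \code{arm}, \code{genes}
#' (semicolon-separated or \code{.}).  Records must tile the chromosome
#' without gaps or overlaps; exactly one record must be flagged centromere.
#'
#' @param path file path.
#' @return a \linkS4class{SegmentMap}.
#' @export
loadSegmentMap <- function(path) {
  if (!file.exists(path)) stop("segment map file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(start = "numeric", end = "numeric"))
  need <- c("chrom", "start", "end", "id", "centromere")
  if (!all(need %in% names(df)))
    stop("segment map must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$start), , drop = FALSE]
  if (anyDuplicated(df$id)) stop("duplicate segment ids in map file")
  if (sum(df$centromere != 0) != 1L)
    stop("segment map must flag exactly one centromere segment")
  if (any(df$end <= df$start)) stop("segment with nonpositive length")
  if (nrow(df) > 1L) {
    gaps <- df$start[-1L] - df$end[-nrow(df)]
    if (any(gaps > 0)) stop("gap between segment intervals")
    if (any(gaps < 0)) stop("overlapping segment intervals")
  }
  if (df$start[1L] != 0) stop("map must start at coordinate 0")
  marker <- if ("marker" %in% names(df)) df$marker else rep(".", nrow(df))
  marker[is.na(marker)] <- "."
  genes <- if ("genes" %in% names(df)) df$genes else rep(".", nrow(df))
  genes[is.na(genes)] <- "."
  geneList <- lapply(genes, function(g)
    if (g == ".") character(0) else strsplit(g, ";", fixed = TRUE)[[1L]])
  mkIdx <- which(marker != ".")
  if (length(mkIdx) > 1L) stop("at most one marker segment supported")
  SegmentMap(lengths = as.integer(df$end - df$start), ids = df$id,
             centromere = which(df$centromere != 0),
             marker = if (length(mkIdx)) mkIdx else NULL,
             genes = geneList, chrom = df$chrom[1L],
             markerLabel = if (length(mkIdx)) marker[mkIdx] else "LEU2")
}

#' Write a segment map to the BED-like TSV format read by loadSegmentMap
#'
#' @param map a \linkS4class{SegmentMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSegmentMap <- function(map, path) {
  gr <- map@ranges
  m <- mcols(gr)
  genes <- ifelse(is.na(m$genes) | m$genes == "", ".", m$genes)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   id = m$segId, centromere = as.integer(m$isCentromere),
                   marker = ifelse(is.na(m$marker), ".", m$marker),
                   arm = m$arm, genes = genes,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic reference map
#'
#' Builds the reference chromosome used throughout: a 1,028,952-bp synthetic
#' chromosome partitioned into \code{n} loxPsym-delimited segments with one
#' small centromeric segment at about 48\% of the length, the selection
#' marker on the segment immediately to its right, and a designated ~20-kb
#' two-segment causal region (the del20K analogue) in the middle of the right
#' arm.  Segment lengths are drawn once from a fixed internal seed so the
#' default map is a deterministic design, then rescaled to the exact total.
#' Gene labels are laid down at roughly one gene per 1.8 kb (about 563 genes
#' at the default size).
#'
#' @param n number of segments (default 40; the real segment count is not a
#'   published value, so this is a free design parameter).
#' @param totalLength total chromosome length in bp.
#' @return a \linkS4class{SegmentMap}.
#' @export
syntheticSegmentMap <- function(n = 40L, totalLength = 1028952L) {
  stopifnot(n >= 8L)
  # fixed design, independent of the caller's RNG
  state <- .saveRngState()
  on.exit(.restoreRngState(state))
  set.seed(20230707L)
  cen <- max(2L, round(0.48 * n))
  causal <- cen + round(0.55 * (n - cen))
  lens <- stats::rgamma(n, shape = 3, rate = 1)
  lens[cen] <- 0.1                       # small centromeric segment
  fixed <- rep(NA_real_, n)
  fixed[causal] <- 20000                 # the 20-kb causal segment
  free <- is.na(fixed)
  budget <- totalLength - sum(fixed, na.rm = TRUE)
  out <- fixed
  out[free] <- floor(lens[free] / sum(lens[free]) * budget)
  out[which(free)[1L]] <- out[which(free)[1L]] + (budget - sum(out[free]))
  lens <- as.integer(out)
  ids <- sprintf("S%02d", seq_len(n))
  nGenes <- pmax(0L, round(lens / 1828))
  counter <- cumsum(c(0L, head(nGenes, -1L)))
  genes <- lapply(seq_len(n), function(i)
    if (nGenes[i] == 0L) character(0)
    else sprintf("G%04d", counter[i] + seq_len(nGenes[i])))
  map <- SegmentMap(lengths = lens, ids = ids, centromere = cen,
                    marker = cen + 1L, genes = genes)
  map
}

#' Segment ids of the default planted causal region
#'
#' @param map a map built by \code{\link{syntheticSegmentMap}} (any map
#'   works; the heuristic picks the right-arm segment of exactly 20 kb when
#'   present, else the right-arm segment closest to 20 kb).
#' @return character vector of segment ids (length 1 for the default map).
#' @export
causalRegionIds <- function(map) {
  lens <- segLengths(map)
  arm <- segArm(map)
  right <- which(arm == "right")
  if (length(right) == 0L) stop("map has no right-arm segment")
  hit <- right[lens[right] == 20000L]
  if (length(hit) >= 1L) return(segIds(map)[hit[1L]])
  segIds(map)[right[which.min(abs(lens[right] - 20000))]]
}

# ---- accessors -------------------------------------------------------------

#' @describeIn SegmentMap segment ids in map order
#' @param x a SegmentMap
#' @export
setMethod("segIds", "SegmentMap", function(x) mcols(x@ranges)$segId)

#' @describeIn SegmentMap segment lengths (bp), named by id
#' @export
setMethod("segLengths", "SegmentMap", function(x)
  stats::setNames(width(x@ranges), segIds(x)))

#' @describeIn SegmentMap number of segments
#' @export
setMethod("nSegments", "SegmentMap", function(x) length(x@ranges))

#' @describeIn SegmentMap total chromosome length (bp)
#' @export
setMethod("totalLength", "SegmentMap", function(x) sum(width(x@ranges)))

#' @describeIn SegmentMap id of the centromere segment
#' @export
setMethod("centromereId", "SegmentMap", function(x)
  segIds(x)[mcols(x@ranges)$isCentromere])

#' @describeIn SegmentMap id of the marker-bearing segment (NA if none)
#' @export
setMethod("markerId", "SegmentMap", function(x) {
  i <- which(!is.na(mcols(x@ranges)$marker))
  if (length(i)) segIds(x)[i] else NA_character_
})

#' @describeIn SegmentMap named list of gene labels per segment
#' @export
setMethod("segGenes", "SegmentMap", function(x) {
  g <- mcols(x@ranges)$genes
  out <- lapply(g, function(s)
    if (is.na(s) || s == "") character(0)
    else strsplit(s, ";", fixed = TRUE)[[1L]])
  stats::setNames(out, segIds(x))
})

#' @describeIn SegmentMap arm assignment per segment, named by id
#' @export
setMethod("segArm", "SegmentMap", function(x)
  stats::setNames(mcols(x@ranges)$arm, segIds(x)))

setMethod("show", "SegmentMap", function(object) {
  cat(sprintf("SegmentMap: %d segments, %s bp, centromere %s, marker %s\n",
              nSegments(object),
              format(totalLength(object), big.mark = ","),
              centromereId(object),
              markerId(object)))
})
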