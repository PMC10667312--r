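#' @include AllClasses.R AllGenerics.R structure.R simulate.R
NULL

# oriented adjacency list of a word: data.frame(endA, endB) with one row per
# adjacent occurrence pair (wrapping pair included for circular words).
# Traversing forward, a +X occurrence is entered at X.l and left at X.r; a -X
# occurrence is entered at X.r and left at X.l.  Each junction is stored with
# its two oriented ends sorted, since a junction has no reading direction.
.wordJunctions <- function(structure) {
  segs <- structure@segIds; signs <- structure@signs
  n <- length(segs)
  outEnd <- paste0(segs, ifelse(signs > 0L, ".r", ".l"))
  inEnd <- paste0(segs, ifelse(signs > 0L, ".l", ".r"))
  if (n < 2L && structure@topology == "linear")
    return(data.frame(endA = character(0), endB = character(0)))
  i <- if (structure@topology == "circular") seq_len(n) else seq_len(n - 1L)
  nxt <- if (structure@topology == "circular") c(2:n, 1L)[i] else i + 1L
  a <- outEnd[i]; b <- inEnd[nxt]
  swap <- a > b
  data.frame(endA = ifelse(swap, b, a), endB = ifelse(swap, a, b))
}

.countJunctions <- function(structure) {
  j <- .wordJunctions(structure)
  if (nrow(j) == 0L)
    return(data.frame(endA = character(0), endB = character(0),
                      mult = integer(0)))
  key <- paste(j$endA, j$endB, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  data.frame(endA = vapply(parts, `[`, character(1), 1L),
             endB = vapply(parts, `[`, character(1), 2L),
             mult = as.integer(tab))
}

#' Generate sequencing-style evidence for a strain
#'
#' Expected synthetic-specific depth per reference segment is
#' \code{baseline * copies * recoveryFactor}, where the recovery factor is
#' \code{circularRecovery} (default 1/3) for circular molecules — the
#' library-prep bias against circular chromosomes — and 1 otherwise.  With
#' \code{noise = TRUE}, depths are Poisson and junction support counts are
#' Poisson with mean \code{junctionRate} per adjacency copy; noise-free
#' evidence is information-complete.  PCRTag-style wild-type vs synthetic
#' read counts are drawn at 1:1 for disomic strains and 2:1 for
#' trisomy-flagged (whole-genome-duplication) strains.
#'
#' @param strain a \linkS4class{StrainRecord}.
#' @param map reference \linkS4class{SegmentMap}.
#' @param baseline expected single-copy linear depth (> 0).
#' @param noise logical; Poisson noise on depths, junction support and
#'   PCRTag reads.
#' @param circularRecovery depth recovery factor for circular molecules.
#' @param junctionRate expected junction-spanning reads per adjacency copy.
#' @param pcrtagReads total PCRTag reads.
#' @param seed optional seed.
#' @return an \linkS4class{EvidenceSet}.
#' @export
generateEvidence <- function(strain, map, baseline = 100, noise = TRUE,
                             circularRecovery = 1 / 3, junctionRate = 20,
                             pcrtagReads = 300L, seed = NULL) {
  if (baseline <= 0) stop("baseline depth must be positive")
  .withSeed(seed, {
    st <- strain@structure
    circ <- st@topology == "circular"
    rf <- if (circ) circularRecovery else 1
    ids <- segIds(map)
    copies <- vapply(ids, function(i) sum(st@segIds == i), integer(1))
    expDepth <- baseline * copies * rf
    depth <- if (noise) as.numeric(stats::rpois(length(ids), expDepth))
    else expDepth
    jn <- .countJunctions(st)
    support <- if (noise) stats::rpois(nrow(jn), junctionRate * jn$mult)
    else as.integer(round(junctionRate * jn$mult))
    jn$support <- as.integer(support)
    jn$mult <- NULL
    jn <- jn[jn$support >= 1L, , drop = FALSE]
    rownames(jn) <- NULL
    synFrac <- if (strain@trisomyFlag) 1 / 3 else 1 / 2
    synReads <- if (noise) stats::rbinom(1L, pcrtagReads, synFrac)
    else as.integer(round(pcrtagReads * synFrac))
    new("EvidenceSet",
        segDepth = stats::setNames(depth, ids),
        baselineDepth = baseline,
        junctions = jn,
        wtReads = as.integer(pcrtagReads - synReads),
        synReads = as.integer(synReads),
        topologyHint = st@topology)
  })
}

#' Estimate per-segment copy numbers from depth evidence
#'
#' The recovery factor is re-estimated from the centromere and marker
#' segments — always retained at (almost always) single copy under the dual
#' selection — so the circular-molecule depth deficit self-normalizes:
#' \code{copies = round(depth / (baseline * rfEstimate))}.
#'
#' @param evidence an \linkS4class{EvidenceSet}.
#' @param map reference \linkS4class{SegmentMap}.
#' @return named integer vector of copy numbers in map order.
#' @export
estimateCopyNumbers <- function(evidence, map) {
  d <- evidence@segDepth
  if (all(d == 0)) stop("all segment depths are zero: no chromosome")
  b <- evidence@baselineDepth
  anchor <- c(centromereId(map), markerId(map))
  anchor <- anchor[!is.na(anchor)]
  u0 <- c(mean(d[anchor]), min(d[anchor])) / b
  u0 <- unique(u0[is.finite(u0) & u0 > 0])
  if (length(u0) == 0L)
    stop("cannot estimate recovery factor: anchor segments have no depth")
  # The anchors are presumed single copy, but a duplication spanning the
  # centromere inflates the initial unit by an integer factor; fit each
  # divisor hypothesis by a short fixed-point refinement and keep the one
  # with the best Poisson likelihood, lightly penalized by total copy
  # number so that globally rescaled solutions resolve to the fewest
  # copies.
  best <- NULL
  for (start in as.vector(outer(u0, 1:4, "/"))) {
    u <- start
    copies <- NULL
    for (it in 1:4) {
      copies <- pmax(round(d / (b * u)), 0)
      copies[anchor] <- pmax(copies[anchor], 1)
      tot <- sum(copies)
      if (tot == 0) break
      u <- sum(d) / (b * tot)
    }
    if (is.null(copies) || sum(copies) == 0 || u <= 0) next
    ll <- sum(stats::dpois(round(d), pmax(b * u * copies, 1e-9),
                           log = TRUE)) - 1.0 * sum(copies)
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, copies = copies)
  }
  if (is.null(best)) stop("copy-number estimation failed")
  stats::setNames(as.integer(best$copies), names(d))
}

#' Flag a whole-genome-duplication ploidy anomaly
#'
#' Exact two-sided binomial test of the synthetic-read fraction against 1/2
#' on PCRTag read counts; the flag is raised when the test rejects at
#' \code{alpha} and the observed wild-type:synthetic ratio (or its inverse)
#' reaches \code{foldMin}.
#'
#' @param evidence an \linkS4class{EvidenceSet}.
#' @param alpha significance level (default 0.05).
#' @param foldMin minimum observed fold ratio (default 1.5).
#' @return list with \code{flag}, \code{p}, \code{ratio} (wt/syn),
#'   \code{wtReads}, \code{synReads}.
#' @export
flagPloidyAnomaly <- function(evidence, alpha = 0.05, foldMin = 1.5) {
  wt <- evidence@wtReads; syn <- evidence@synReads
  total <- wt + syn
  if (total == 0L) stop("no PCRTag reads")
  p <- stats::binom.test(syn, total, p = 0.5)$p.value
  ratio <- if (syn == 0L) Inf else wt / syn
  fold <- max(ratio, 1 / ratio)
  list(flag = (p < alpha) && (fold >= foldMin), p = p, ratio = ratio,
       wtReads = wt, synReads = syn)
}

#' Write / read an EvidenceSet as two TSVs plus a JSON header
#'
#' Files written: \code{<base>.segments.tsv} (id, depth),
#' \code{<base>.junctions.tsv} (end_a, end_b, support) and
#' \code{<base>.header.json} (baseline, read counts, ratio, topology hint).
#'
#' @param evidence an \linkS4class{EvidenceSet}.
#' @param base path prefix.
#' @return \code{base}, invisibly.
#' @export
writeEvidence <- function(evidence, base) {
  utils::write.table(data.frame(id = names(evidence@segDepth),
                                depth = evidence@segDepth),
                     paste0(base, ".segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jn <- evidence@junctions
  names(jn) <- c("end_a", "end_b", "support")
  utils::write.table(jn, paste0(base, ".junctions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(baseline = evidence@baselineDepth,
                            wt_reads = evidence@wtReads,
                            syn_reads = evidence@synReads,
                            wt_syn_ratio = if (evidence@synReads > 0)
                              evidence@wtReads / evidence@synReads else NA,
                            topology_hint = evidence@topologyHint),
                       paste0(base, ".header.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname writeEvidence
#' @export
readEvidence <- function(base) {
  seg <- utils::read.delim(paste0(base, ".segments.tsv"))
  jn <- utils::read.delim(paste0(base, ".junctions.tsv"),
                          colClasses = c("character", "character", "integer"))
  names(jn) <- c("endA", "endB", "support")
  hd <- jsonlite::fromJSON(paste0(base, ".header.json"))
  new("EvidenceSet",
      segDepth = stats::setNames(seg$depth, seg$id),
      baselineDepth = hd$baseline,
      junctions = jn,
      wtReads = as.integer(hd$wt_reads), synReads = as.integer(hd$syn_reads),
      topologyHint = hd$topology_hint)
}

setMethod("show", "EvidenceSet", function(object) {
  cat(sprintf(paste0("EvidenceSet: %d segments (baseline %.1f), ",
                     "%d junctions, wt:syn %d:%d, topology hint %s\n"),
              length(object@segDepth), object@baselineDepth,
              nrow(object@junctions), object@wtReads, object@synReads,
              object@topologyHint))
})
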