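#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges start end width
#' @importFrom IRanges IRanges
NULL

#' SegmentMap: a loxPsym-partitioned reference chromosome
#'
#' An ordered, gap-free tiling of a (synthetic) chromosome into the segments
#' delimited by consecutive loxPsym sites.  Exactly one segment carries the
#' centromere; a selection marker may be annotated on any segment (by design it
#' sits next to the centromere, which is what forces SCRaMbLE survivors to keep
#' centromere-adjacent content).  The underlying intervals are stored as a
#' \link[GenomicRanges]{GRanges} in BED convention (0-based half-open on disk,
#' 1-based closed in the GRanges).
#'
#' @slot ranges GRanges of the segment intervals, ordered left telomere to
#'   right telomere, with metadata columns \code{segId}, \code{genes}
#'   (semicolon-separated labels), \code{isCentromere}, \code{marker}
#'   (\code{NA} or a marker label) and \code{arm}
#'   (\code{"left"|"right"|"centromeric"}).
#'
#' @export
setClass("SegmentMap", representation(ranges = "GRanges"))

setValidity("SegmentMap", function(object) {
  gr <- object@ranges
  need <- c("segId", "genes", "isCentromere", "marker", "arm")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(mcols(gr))), collapse = ", ")))
  if (length(gr) == 0L) return("empty segment map")
  ids <- mcols(gr)$segId
  if (anyDuplicated(ids)) return("duplicate segment ids")
  if (any(width(gr) < 1L)) return("segment lengths must be >= 1 bp")
  if (sum(mcols(gr)$isCentromere) != 1L)
    return("a segment map must contain exactly one centromere segment")
  # gap/overlap-free tiling in file order
  if (length(gr) > 1L) {
    s <- start(gr)[-1L]
    e <- end(gr)[-length(gr)]
    if (any(s != e + 1L)) return("segments must tile without gaps or overlaps")
  }
  if (start(gr)[1L] != 1L) return("map must start at position 0 (BED)")
  TRUE
})

#' ChromosomeStructure: a topology plus a signed segment word
#'
#' The state SCRaMbLE acts on: an ordered word of signed segment occurrences
#' (sign \code{-1} means the segment occurs inverted) together with a topology
#' flag.  Circular structures are rotation/reflection-equivalent; use
#' \code{\link{canonicalForm}} before comparing them.
#'
#' @slot topology \code{"linear"} or \code{"circular"}.
#' @slot segIds character vector of segment ids, in word order.
#' @slot signs integer vector of +1/-1, parallel to \code{segIds}.
#'
#' @export
setClass("ChromosomeStructure",
         representation(topology = "character",
                        segIds = "character",
                        signs = "integer"))

setValidity("ChromosomeStructure", function(object) {
  if (!object@topology %in% c("linear", "circular"))
    return("topology must be 'linear' or 'circular'")
  if (length(object@segIds) != length(object@signs))
    return("segIds and signs must have equal length")
  if (length(object@segIds) == 0L) return("structure word must be nonempty")
  if (!all(object@signs %in% c(-1L, 1L))) return("signs must be +1 or -1")
  TRUE
})

#' ScrambleEvent: one recombination outcome
#'
#' @slot kind \code{"deletion"}, \code{"inversion"}, \code{"duplication"} or
#'   \code{"circularization"}.
#' @slot junctions integer pair of 1-based inter-segment positions in the word
#'   the event was applied to; position \code{j} is the boundary immediately
#'   before the \code{j}-th segment, so the pair \code{(j1, j2)} with
#'   \code{j1 < j2} spans segments \code{j1 .. j2-1}.  On circular words a
#'   pair with \code{j1 > j2} denotes the cyclic span wrapping past the end
#'   of the stored word.
#' @slot payload signed-id character vector of the affected sub-word (as it
#'   read immediately before the event).
#'
#' @export
setClass("ScrambleEvent",
         representation(kind = "character",
                        junctions = "integer",
                        payload = "character"))

setValidity("ScrambleEvent", function(object) {
  if (!object@kind %in% c("deletion", "inversion", "duplication",
                          "circularization"))
    return("unknown event kind")
  if (length(object@junctions) != 2L) return("junctions must be a pair")
  if (any(object@junctions < 1L)) return("junction positions are 1-based")
  if (object@junctions[1L] == object@junctions[2L])
    return("junction positions must be distinct")
  if (object@kind == "circularization" &&
      object@junctions[2L] <= object@junctions[1L])
    return("circularization requires j1 < j2")
  TRUE
})

#' SimParams: calibrated simulator parameters
#'
#' Defaults reproduce the headline statistics of the SCRaMbLEd disome screen:
#' event types drawn from a (deletion, inversion, duplication) multinomial of
#' (0.622, 0.292, 0.086); a zero-truncated negative-binomial event count with
#' (truncated) mean 4.42 and dispersion \code{size = 2} (chosen so that about
#' 7.8\% of strains carry >= 10 events, the observed long-tail frequency); a
#' per-strain circularization probability of 0.89; and a fitness model
#' \deqn{R = \beta_0 + \beta_{mass}(1 - retained) + \beta_{region} 1[region
#' deleted] + \epsilon .}
#'
#' @slot eventTypeProbs named numeric (deletion, inversion, duplication),
#'   summing to 1.
#' @slot meanEvents positive real; mean of the zero-truncated event-count law.
#' @slot eventCountDispersion positive real; negative-binomial \code{size}.
#' @slot circularizationProb probability that a strain circularizes (applied
#'   once, before other events).
#' @slot mechanistic logical; if \code{TRUE}, event types are drawn
#'   mechanistically (deletion/inversion equiprobable per intramolecular
#'   event, duplication with its own probability) instead of from
#'   \code{eventTypeProbs}.
#' @slot siteWeights optional named per-segment weights biasing junction
#'   choice (a boundary inherits the weight of the segment to its right);
#'   \code{numeric(0)} for uniform.
#' @slot spanMeanSegments mean event span in segments for the proximal
#'   component.  Intramolecular Cre recombination favours proximal loxPsym
#'   pairs, so most span lengths follow a geometric law with this mean;
#'   \code{Inf} selects junction pairs uniformly instead.
#' @slot spanLongFraction probability that an event is long-range instead
#'   (span uniform over all valid lengths), the tail that removes large
#'   chromosome chunks.
#' @slot circTelomereOffsetMean mean offset (segments, geometric) of the
#'   circularization junctions from the two chromosome ends; circles form
#'   between telomere-proximal sites.
#' @slot causalRegion segment ids of the planted fitness-relevant region
#'   (del20K analogue); empty for none.
#' @slot beta0,betaMass,betaRegion,noiseSd fitness coefficients (percent
#'   recovery scale) and residual standard deviation.
#' @slot recoveryFloor lower clamp for the latent recovery percent.
#' @slot colonyN number of colonies measured per strain.
#' @slot colonyRefMm reference (parent) mean colony diameter, mm.
#' @slot colonyCv coefficient of variation of colony diameters.
#' @slot trisomyFraction fraction of strains flagged as whole-genome
#'   duplication escapees (2:1 wild-type:synthetic read ratio).
#' @slot rejectionCap attempts allowed when rejection-sampling a viable strain.
#'
#' @export
setClass("SimParams",
         representation(eventTypeProbs = "numeric",
                        meanEvents = "numeric",
                        eventCountDispersion = "numeric",
                        circularizationProb = "numeric",
                        mechanistic = "logical",
                        siteWeights = "numeric",
                        spanMeanSegments = "numeric",
                        spanLongFraction = "numeric",
                        circTelomereOffsetMean = "numeric",
                        causalRegion = "character",
                        beta0 = "numeric",
                        betaMass = "numeric",
                        betaRegion = "numeric",
                        noiseSd = "numeric",
                        recoveryFloor = "numeric",
                        colonyN = "integer",
                        colonyRefMm = "numeric",
                        colonyCv = "numeric",
                        trisomyFraction = "numeric",
                        rejectionCap = "integer"))

setValidity("SimParams", function(object) {
  p <- object@eventTypeProbs
  if (length(p) != 3L ||
      !identical(names(p), c("deletion", "inversion", "duplication")))
    return("eventTypeProbs must be named (deletion, inversion, duplication)")
  if (abs(sum(p) - 1) > 1e-8) return("eventTypeProbs must sum to 1")
  if (any(p < 0)) return("eventTypeProbs must be nonnegative")
  if (object@meanEvents != 0 && object@meanEvents <= 1)
    return("meanEvents must be 0 (no rearrangement) or > 1 (truncated mean)")
  if (object@eventCountDispersion <= 0)
    return("eventCountDispersion must be positive")
  if (object@circularizationProb < 0 || object@circularizationProb > 1)
    return("circularizationProb must be in [0,1]")
  if (object@trisomyFraction < 0 || object@trisomyFraction > 1)
    return("trisomyFraction must be in [0,1]")
  if (object@rejectionCap < 1L) return("rejectionCap must be >= 1")
  TRUE
})

#' StrainRecord: one SCRaMbLEd strain
#'
#' @slot strainId character label.
#' @slot structure the strain's \linkS4class{ChromosomeStructure}.
#' @slot events list of \linkS4class{ScrambleEvent} applied, in order.
#' @slot retainedFraction bp-weighted fraction of reference segments retained.
#' @slot recoveryRatePct growth recovery percent relative to the unSCRaMbLEd
#'   disome parent.
#' @slot colonySizesMm colony diameters (mm).
#' @slot trisomyFlag whole-genome-duplication escapee flag.
#' @slot conditionLabel growth condition the fitness values refer to.
#'
#' @export
setClass("StrainRecord",
         representation(strainId = "character",
                        structure = "ChromosomeStructure",
                        events = "list",
                        retainedFraction = "numeric",
                        recoveryRatePct = "numeric",
                        colonySizesMm = "numeric",
                        trisomyFlag = "logical",
                        conditionLabel = "character"))

#' ScramblePopulation: a screened collection of SCRaMbLEd strains
#'
#' @slot strains list of \linkS4class{StrainRecord}.
#' @slot map the \linkS4class{SegmentMap} the strains derive from.
#' @slot params the \linkS4class{SimParams} used (for provenance).
#'
#' @export
setClass("ScramblePopulation",
         representation(strains = "list",
                        map = "SegmentMap",
                        params = "SimParams"))

setValidity("ScramblePopulation", function(object) {
  if (length(object@strains) == 0L) return("population is empty")
  if (!all(vapply(object@strains, is, logical(1), "StrainRecord")))
    return("strains must all be StrainRecord objects")
  TRUE
})

#' EvidenceSet: sequencing-style observables for one strain
#'
#' Segment-level read-out of a strain's synthetic chromosome: per-segment
#' synthetic-specific depth, the observed junction list, and PCRTag-style
#' wild-type vs synthetic read counts.  Circular molecules are recovered less
#' efficiently during library preparation, so their depth is scaled by a
#' recovery factor (about 1/3) that downstream copy-number estimation must
#' self-normalize away.
#'
#' @slot segDepth named numeric, synthetic-copy depth per reference segment.
#' @slot baselineDepth depth expected for a single-copy segment on a linear
#'   molecule.
#' @slot junctions data.frame with columns \code{endA}, \code{endB} (oriented
#'   segment ends, e.g. \code{"S03.r"}) and \code{support} (read count).
#' @slot wtReads,synReads PCRTag read counts for the wild-type and synthetic
#'   alleles.
#' @slot topologyHint \code{"linear"}, \code{"circular"} or \code{"unknown"}.
#'
#' @export
setClass("EvidenceSet",
         representation(segDepth = "numeric",
                        baselineDepth = "numeric",
                        junctions = "data.frame",
                        wtReads = "integer",
                        synReads = "integer",
                        topologyHint = "character"))

setValidity("EvidenceSet", function(object) {
  if (object@baselineDepth <= 0) return("baselineDepth must be positive")
  if (any(!is.finite(object@segDepth)) || any(object@segDepth < 0))
    return("segment depths must be finite and nonnegative")
  if (nrow(object@junctions) > 0 && any(object@junctions$support < 1))
    return("junction support counts must be >= 1")
  if (!object@topologyHint %in% c("linear", "circular", "unknown"))
    return("topologyHint must be linear|circular|unknown")
  TRUE
})

#' EventDecomposition: a classified event list explaining a structure
#'
#' @slot events list of \linkS4class{ScrambleEvent} which, replayed on the
#'   reference, reproduce the observed structure (up to canonical form).
#' @slot k number of events.
#' @slot isMinimal \code{TRUE} when \code{k} is a certified minimum (exact
#'   breadth-first search or a provably tight construction), \code{FALSE} when
#'   it is the greedy upper bound.
#'
#' @export
setClass("EventDecomposition",
         representation(events = "list",
                        k = "integer",
                        isMinimal = "logical"))
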