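#' @include AllClasses.R AllGenerics.R structure.R events.R utils.R
NULL

#' Construct simulator parameters
#'
#' All arguments have calibrated defaults; see \linkS4class{SimParams} for
#' their meaning.  \code{meanEvents} is the mean of the zero-truncated
#' event-count law and must exceed 1 (every SCRaMbLEd strain has at least one
#' event); the special value \code{0} disables rearrangement entirely
#' (unSCRaMbLEd controls).
#'
#' @param eventTypeProbs deletion/inversion/duplication multinomial.
#' @param meanEvents mean number of events per strain.
#' @param eventCountDispersion negative-binomial \code{size}.
#' @param circularizationProb per-strain circularization probability.
#' @param mechanistic draw event types mechanistically instead of from the
#'   multinomial.
#' @param siteWeights optional named per-segment weights biasing where
#'   junctions fall (a boundary inherits the weight of the segment to its
#'   right); unnamed empty numeric for uniform.
#' @param spanMeanSegments mean geometric event span (segments) of the
#'   proximal component; \code{Inf} for uniform junction pairs.
#' @param spanLongFraction probability of a long-range event (uniform span).
#' @param circTelomereOffsetMean mean geometric offset of circularization
#'   junctions from the chromosome ends.
#' @param causalRegion ids of the planted fitness-relevant region.
#' @param hotspotWeight site-weight multiplier applied to the causal-region
#'   boundaries when no explicit \code{siteWeights} are given (the del20K
#'   analogue sits in the observed deletion hotspot).
#' @param beta0,betaMass,betaRegion,noiseSd fitness model coefficients
#'   (percent scale).
#' @param recoveryFloor clamp for latent recovery.
#' @param colonyN colonies per strain.
#' @param colonyRefMm parent mean colony diameter (mm).
#' @param colonyCv colony-size coefficient of variation.
#' @param trisomyFraction fraction of whole-genome-duplication escapees.
#' @param rejectionCap viable-strain rejection-sampling cap.
#' @return a \linkS4class{SimParams}.
#' @export
SimParams <- function(eventTypeProbs = c(deletion = 0.622, inversion = 0.292,
                                         duplication = 0.086),
                      meanEvents = 4.42,
                      eventCountDispersion = 2,
                      circularizationProb = 0.89,
                      mechanistic = FALSE,
                      siteWeights = numeric(0),
                      spanMeanSegments = 1,
                      spanLongFraction = 0.06,
                      circTelomereOffsetMean = 1,
                      causalRegion = character(0),
                      hotspotWeight = 4,
                      beta0 = 5, betaMass = 50, betaRegion = 25,
                      noiseSd = 8, recoveryFloor = 0,
                      colonyN = 200L, colonyRefMm = 1.2, colonyCv = 0.15,
                      trisomyFraction = 0, rejectionCap = 1000L) {
  if (meanEvents != 0 && meanEvents <= 1)
    stop("meanEvents must be 0 (no rearrangement) or > 1 (zero-truncated law)")
  if (length(causalRegion) && length(siteWeights) == 0L) {
    # the causal region models the del20K analogue, which sits inside the
    # screen's right-arm deletion hotspot: give its sites elevated
    # recombination propensity by default
    siteWeights <- stats::setNames(rep(hotspotWeight, length(causalRegion)),
                                   causalRegion)
  }
  new("SimParams",
      eventTypeProbs = eventTypeProbs[c("deletion", "inversion",
                                        "duplication")],
      meanEvents = meanEvents,
      eventCountDispersion = eventCountDispersion,
      circularizationProb = circularizationProb,
      mechanistic = mechanistic,
      siteWeights = siteWeights,
      spanMeanSegments = spanMeanSegments,
      spanLongFraction = spanLongFraction,
      circTelomereOffsetMean = circTelomereOffsetMean,
      causalRegion = causalRegion,
      beta0 = beta0, betaMass = betaMass, betaRegion = betaRegion,
      noiseSd = noiseSd, recoveryFloor = recoveryFloor,
      colonyN = as.integer(colonyN), colonyRefMm = colonyRefMm,
      colonyCv = colonyCv, trisomyFraction = trisomyFraction,
      rejectionCap = as.integer(rejectionCap))
}

#' Viability under centromere + marker selection
#'
#' A SCRaMbLEd structure survives the dual selection when it still carries
#' the centromere segment and the (centromere-adjacent) marker segment, each
#' at one or more copies.
#'
#' @param structure a \linkS4class{ChromosomeStructure}.
#' @param map the reference \linkS4class{SegmentMap}.
#' @return logical.
#' @export
selectionFilter <- function(structure, map) {
  need <- c(centromereId(map), markerId(map))
  need <- need[!is.na(need)]
  all(need %in% structure@segIds)
}

# weight of each valid boundary of `structure`: the weight of the segment
# occurrence immediately to its right (events spanning from boundary j act
# on that segment first); uniform when no weights configured
.boundaryWeights <- function(structure, siteWeights) {
  valid <- .validBoundaries(structure)
  if (length(siteWeights) == 0L || length(valid) == 0L)
    return(rep(1, length(valid)))
  w <- siteWeights[structure@segIds]
  w[is.na(w)] <- 1
  unname(w[valid])
}

# sample one viable event for the current word.  A rearrangement that
# destroys the centromere or marker is lethal and never observed among
# selected strains, so junction pairs are redrawn (up to `tries`) until the
# product passes selection; a kind with no viable junctions is redrawn among
# the remaining kinds.  Returns list(event, structure) or NULL when the word
# admits no further event at all.
.sampleEvent <- function(structure, params, map, tries = 20L) {
  valid <- .validBoundaries(structure)
  if (length(valid) < 2L) return(NULL)
  circ <- structure@topology == "circular"
  kinds <- names(params@eventTypeProbs)
  probs <- if (params@mechanistic) {
    pd <- params@eventTypeProbs[["duplication"]]
    c(deletion = (1 - pd) / 2, inversion = (1 - pd) / 2, duplication = pd)
  } else params@eventTypeProbs
  bw <- .boundaryWeights(structure, params@siteWeights)
  n <- length(structure@segIds)
  drawPair <- function() {
    if (!is.finite(params@spanMeanSegments)) {
      pair <- sample(valid, 2L, prob = bw)
      if (circ) {
        if (stats::runif(1) < 0.5) pair <- rev(pair)
      } else pair <- sort(pair)
      return(pair)
    }
    # proximity bias: geometric span from a (site-weighted) start boundary,
    # with a long-range uniform tail
    j1 <- if (length(valid) == 1L) valid else sample(valid, 1L, prob = bw)
    L <- if (stats::runif(1) < params@spanLongFraction)
      sample.int(max(n - 1L, 1L), 1L)
    else 1L + stats::rgeom(1L, min(1, 1 / params@spanMeanSegments))
    if (circ) {
      L <- min(L, n - 1L)
      c(j1, ((j1 + L - 1L) %% n) + 1L)
    } else {
      if (j1 + L <= n) c(j1, j1 + L)
      else c(max(2L, j1 - L), j1)     # reflect a span that would overrun
    }
  }
  kinds <- kinds[probs[kinds] > 0]
  while (length(kinds)) {
    kind <- if (length(kinds) == 1L) kinds
    else sample(kinds, 1L, prob = probs[kinds])
    for (i in seq_len(tries)) {
      pair <- drawPair()
      if (pair[1L] == pair[2L]) next
      ev <- tryCatch(.eventWithPayload(structure, kind, pair[1L], pair[2L]),
                     error = function(e) NULL)
      if (is.null(ev)) next
      s2 <- tryCatch(applyEvent(structure, ev), error = function(e) NULL)
      if (!is.null(s2) && selectionFilter(s2, map))
        return(list(event = ev, structure = s2))
    }
    kinds <- setdiff(kinds, kind)
  }
  NULL
}

# circularization junctions: circles form between telomere-proximal sites
# (geometric offsets from the two ends), and the kept interior arc must
# contain the centromere and marker or the circle is lost at the first
# division
.sampleCircularization <- function(structure, params, map, tries = 200L) {
  n <- length(structure@segIds)
  off <- function() stats::rgeom(1L, min(1, 1 / params@circTelomereOffsetMean))
  for (i in seq_len(tries)) {
    if (is.finite(params@circTelomereOffsetMean)) {
      j1 <- min(2L + off(), n)
      j2 <- max(n - off(), 2L)
    } else {
      pair <- sort(sample(.validBoundaries(structure), 2L))
      j1 <- pair[1L]; j2 <- pair[2L]
    }
    if (j1 >= j2) next
    ev <- .eventWithPayload(structure, "circularization", j1, j2)
    s2 <- applyEvent(structure, ev)
    if (selectionFilter(s2, map))
      return(list(event = ev, structure = s2))
  }
  NULL
}

#' Simulate one SCRaMbLEd strain
#'
#' Optionally circularizes first (keeping a uniformly chosen interior arc),
#' draws the event count from the zero-truncated negative binomial, applies
#' that many events with types from the configured multinomial and junction
#' pairs uniform over the current word's loxPsym boundaries, and
#' rejection-samples the whole trajectory until the final structure passes
#' \code{\link{selectionFilter}}.
#'
#' @param map reference \linkS4class{SegmentMap}.
#' @param params a \linkS4class{SimParams}.
#' @param strainId label for the record.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return a \linkS4class{StrainRecord} (fitness fields unset; see
#'   \code{\link{assignFitness}}).
#' @export
simulateStrain <- function(map, params, strainId = "strain001", seed = NULL) {
  .withSeed(seed, {
    ref <- referenceStructure(map)
    for (attempt in seq_len(params@rejectionCap)) {
      st <- ref
      events <- list()
      if (stats::runif(1) < params@circularizationProb) {
        res <- .sampleCircularization(st, params, map)
        if (is.null(res)) next
        st <- res$structure
        events[[length(events) + 1L]] <- res$event
      }
      k <- if (params@meanEvents == 0) 0L
      else .rztnb(1L, params@meanEvents, params@eventCountDispersion)
      for (i in seq_len(k)) {
        res <- .sampleEvent(st, params, map)
        if (is.null(res)) break           # word too short for further events
        st <- res$structure
        events[[length(events) + 1L]] <- res$event
      }
      if (selectionFilter(st, map)) {
        return(new("StrainRecord", strainId = strainId, structure = st,
                   events = events,
                   retainedFraction = retainedFraction(st, map),
                   recoveryRatePct = NA_real_, colonySizesMm = numeric(0),
                   trisomyFlag = FALSE, conditionLabel = "YPD"))
      }
    }
    stop("no viable strain after rejection cap of ", params@rejectionCap,
         " attempts")
  })
}

#' Assign fitness to a simulated strain
#'
#' Latent growth recovery (percent) follows
#' \code{beta0 + betaMass * (1 - retained) + betaRegion * [causal region fully
#' deleted] + Normal(0, noiseSd)}, clamped at \code{recoveryFloor}; colony
#' diameters are drawn around the implied mean with the configured CV.
#'
#' @param strain a \linkS4class{StrainRecord}.
#' @param params a \linkS4class{SimParams}.
#' @param seed optional seed.
#' @return the strain with \code{recoveryRatePct} and \code{colonySizesMm}
#'   filled in.
#' @export
assignFitness <- function(strain, params, seed = NULL) {
  .withSeed(seed, {
    regionDeleted <- length(params@causalRegion) > 0L &&
      !any(params@causalRegion %in% strain@structure@segIds)
    r <- params@beta0 +
      params@betaMass * (1 - strain@retainedFraction) +
      params@betaRegion * regionDeleted +
      stats::rnorm(1L, 0, params@noiseSd)
    r <- max(r, params@recoveryFloor)
    meanMm <- params@colonyRefMm * (1 + r / 100)
    sizes <- stats::rnorm(params@colonyN, meanMm, params@colonyCv * meanMm)
    sizes <- pmax(sizes, 0.05)
    strain@recoveryRatePct <- r
    strain@colonySizesMm <- sizes
    strain
  })
}

#' Colony sizes for the unSCRaMbLEd reference strain
#'
#' @param params a \linkS4class{SimParams}.
#' @param seed optional seed.
#' @return numeric vector of \code{colonyN} diameters (mm) around
#'   \code{colonyRefMm}.
#' @export
referenceColonySizes <- function(params, seed = NULL)
  .withSeed(seed, pmax(stats::rnorm(params@colonyN, params@colonyRefMm,
                                    params@colonyCv * params@colonyRefMm),
                       0.05))

#' Simulate an OD600 growth curve
#'
#' Logistic trajectory sampled on a uniform 20-minute grid over 48 hours,
#' starting at the inoculum density, with the requested exponential-phase
#' doubling time and optional multiplicative (log-normal) noise.
#'
#' @param doublingTimeMin exponential-phase doubling time, minutes (> 0).
#' @param od0 inoculum OD600 (default 0.01).
#' @param capacity carrying-capacity OD600.
#' @param hours duration.
#' @param stepMin grid spacing, minutes.
#' @param noiseSd multiplicative noise standard deviation (on the log scale,
#'   e.g. 0.02 for 2 percent); 0 for noise-free.
#' @param seed optional seed.
#' @return data.frame with columns \code{time_min} and \code{od600}.
#' @export
simulateGrowthCurve <- function(doublingTimeMin, od0 = 0.01, capacity = 2,
                                hours = 48, stepMin = 20, noiseSd = 0,
                                seed = NULL) {
  if (doublingTimeMin <= 0) stop("doubling time must be positive")
  .withSeed(seed, {
    t <- seq(0, hours * 60, by = stepMin)
    r <- log(2) / doublingTimeMin
    od <- capacity * od0 * exp(r * t) / (capacity + od0 * (exp(r * t) - 1))
    if (noiseSd > 0) od <- od * exp(stats::rnorm(length(t), 0, noiseSd))
    data.frame(time_min = t, od600 = od)
  })
}

#' Simulate a screened population of SCRaMbLEd strains
#'
#' @param map reference \linkS4class{SegmentMap}.
#' @param params a \linkS4class{SimParams}.
#' @param nStrains population size (default 219, the size of the screen this
#'   simulator is calibrated to).
#' @param seed optional integer seed governing all randomness of the run.
#' @return a \linkS4class{ScramblePopulation}; a
#'   \code{round(trisomyFraction * nStrains)}-sized random subset carries
#'   \code{trisomyFlag}.
#' @export
simulatePopulation <- function(map, params, nStrains = 219L, seed = NULL) {
  stopifnot(nStrains >= 1L)
  .withSeed(seed, {
    recs <- lapply(seq_len(nStrains), function(i)
      assignFitness(simulateStrain(map, params,
                                   strainId = sprintf("strain%03d", i)),
                    params))
    nTri <- round(params@trisomyFraction * nStrains)
    if (nTri > 0L) {
      flag <- sample(nStrains, nTri)
      for (i in flag) recs[[i]]@trisomyFlag <- TRUE
    }
    new("ScramblePopulation", strains = recs, map = map, params = params)
  })
}

#' @describeIn ScramblePopulation list of StrainRecord
#' @param x a ScramblePopulation
#' @export
setMethod("strains", "ScramblePopulation", function(x) x@strains)

#' @describeIn ScramblePopulation strain ids
#' @export
setMethod("strainIds", "ScramblePopulation", function(x)
  vapply(x@strains, function(r) r@strainId, character(1)))

#' @describeIn ScramblePopulation number of strains
#' @export
setMethod("length", "ScramblePopulation", function(x) length(x@strains))

setMethod("show", "ScramblePopulation", function(object) {
  topo <- vapply(object@strains, function(r) r@structure@topology,
                 character(1))
  nev <- vapply(object@strains, function(r) length(r@events), numeric(1))
  cat(sprintf(paste0("ScramblePopulation: %d strains ",
                     "(%.0f%% circular, %.2f events/strain applied)\n"),
              length(object@strains), 100 * mean(topo == "circular"),
              mean(nev)))
})

setMethod("show", "StrainRecord", function(object) {
  cat(sprintf("StrainRecord %s: %s, %d segments, retained %.3f%s%s\n",
              object@strainId, object@structure@topology,
              length(object@structure), object@retainedFraction,
              if (is.na(object@recoveryRatePct)) ""
              else sprintf(", recovery %.1f%%", object@recoveryRatePct),
              if (object@trisomyFlag) " [trisomy]" else ""))
})
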