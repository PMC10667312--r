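#' @include AllClasses.R AllGenerics.R structure.R
NULL

#' Construct a ScrambleEvent
#'
#' @param kind one of \code{"deletion"}, \code{"inversion"},
#'   \code{"duplication"}, \code{"circularization"}.
#' @param j1,j2 1-based inter-segment positions in the word the event is to be
#'   applied to (see \linkS4class{ScrambleEvent} for the span convention).
#' @param payload optional signed sub-word affected (recorded by
#'   \code{\link{applyEvent}} when it applies the event).
#' @return a \linkS4class{ScrambleEvent}.
#' @export
ScrambleEvent <- function(kind, j1, j2, payload = character(0))
  new("ScrambleEvent", kind = kind,
      junctions = c(as.integer(j1), as.integer(j2)),
      payload = as.character(payload))

setMethod("show", "ScrambleEvent", function(object) {
  cat(sprintf("ScrambleEvent: %s at (%d, %d)%s\n", object@kind,
              object@junctions[1L], object@junctions[2L],
              if (length(object@payload))
                paste0(" [", paste(object@payload, collapse = ","), "]")
              else ""))
})

#' @describeIn ScrambleEvent event kind of an event or list of events
#' @param x a ScrambleEvent or list of them
#' @export
setMethod("eventKinds", "ScrambleEvent", function(x) x@kind)

#' @export
setMethod("eventKinds", "list", function(x)
  vapply(x, function(e) e@kind, character(1)))

# valid recombination boundaries of a word: on a linear molecule only the
# interior boundaries are loxPsym sites (the two ends are telomeres); on a
# circular molecule every boundary is a site.
.validBoundaries <- function(structure) {
  n <- length(structure@segIds)
  if (structure@topology == "linear") {
    if (n < 2L) integer(0) else 2:n
  } else seq_len(n)
}

# cyclic span positions of pair (j1, j2) on a word of length n
.spanIdx <- function(j1, j2, n, circular) {
  if (j1 < j2) return(j1:(j2 - 1L))
  if (!circular) stop("junctions out of range for a linear word")
  c(j1:n, if (j2 > 1L) 1:(j2 - 1L))
}

#' Apply one SCRaMbLE event to a structure
#'
#' Deletion removes the spanned sub-word; inversion reverses it and flips all
#' signs; duplication inserts a tandem copy immediately after it;
#' circularization (linear molecules only) keeps the interior sub-word as a
#' circular structure and discards both telomeric end fragments.  Circular
#' structures can never revert to a linear state.
#'
#' @param structure a \linkS4class{ChromosomeStructure}.
#' @param event a \linkS4class{ScrambleEvent} whose junctions are valid
#'   positions of \code{structure}'s word.
#' @return the rearranged \linkS4class{ChromosomeStructure}.
#' @export
applyEvent <- function(structure, event) {
  n <- length(structure@segIds)
  circ <- structure@topology == "circular"
  j1 <- event@junctions[1L]; j2 <- event@junctions[2L]
  valid <- .validBoundaries(structure)
  if (event@kind == "circularization") {
    if (circ) stop("cannot circularize an already circular structure")
    if (!(j1 %in% valid) || !(j2 %in% valid) || j1 >= j2)
      stop("circularization junctions out of range")
    keep <- j1:(j2 - 1L)
    return(new("ChromosomeStructure", topology = "circular",
               segIds = structure@segIds[keep],
               signs = structure@signs[keep]))
  }
  if (!(j1 %in% valid) || !(j2 %in% valid))
    stop("event junctions out of range")
  if (!circ && j1 >= j2) stop("junctions out of range for a linear word")
  span <- .spanIdx(j1, j2, n, circ)
  if (length(span) >= n) stop("event span covers the whole word")
  segs <- structure@segIds; signs <- structure@signs
  out <- switch(event@kind,
    deletion = list(segIds = segs[-span], signs = signs[-span]),
    inversion = {
      segs[span] <- segs[rev(span)]
      signs[span] <- -signs[rev(span)]
      list(segIds = segs, signs = signs)
    },
    duplication = {
      last <- span[length(span)]
      ins <- function(v, piece) append(v, piece, after = last)
      list(segIds = ins(segs, segs[span]), signs = ins(signs, signs[span]))
    },
    stop("unknown event kind: ", event@kind))
  new("ChromosomeStructure", topology = structure@topology,
      segIds = out$segIds, signs = out$signs)
}

#' Replay a recorded event list on a starting structure
#'
#' @param structure starting \linkS4class{ChromosomeStructure} (usually the
#'   reference).
#' @param events list of \linkS4class{ScrambleEvent}.
#' @return the resulting structure; replaying a strain's recorded events on
#'   the reference reproduces its recorded structure exactly.
#' @export
replayEvents <- function(structure, events) {
  for (e in events) structure <- applyEvent(structure, e)
  structure
}

# payload of an event as it would read on `structure` (helper used by the
# simulator when recording events)
.eventWithPayload <- function(structure, kind, j1, j2) {
  n <- length(structure@segIds)
  span <- if (kind == "circularization") j1:(j2 - 1L)
  else .spanIdx(j1, j2, n, structure@topology == "circular")
  ScrambleEvent(kind, j1, j2,
                payload = paste0(ifelse(structure@signs[span] < 0L, "-", ""),
                                 structure@segIds[span]))
}
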