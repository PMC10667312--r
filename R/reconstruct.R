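#' @include AllClasses.R AllGenerics.R structure.R events.R evidence.R
NULL

#' AdjacencyGraph: oriented segment-end graph built from evidence
#'
#' Nodes are oriented segment ends (\code{id.l}, \code{id.r}); segment edges
#' connect the two ends of a segment with multiplicity equal to its estimated
#' copy number; junction edges come from the evidence.  Junctions that
#' reference a zero-copy segment are recorded as conflicts, never silently
#' dropped.
#'
#' @slot copies named integer, estimated copy number per reference segment.
#' @slot junctions data.frame(endA, endB, support) of usable junction edges.
#' @slot conflicts data.frame of junction edges in conflict with the copy
#'   numbers, with a \code{reason} column.
#' @slot topologyHint from the evidence.
#'
#' @export
setClass("AdjacencyGraph",
         representation(copies = "integer",
                        junctions = "data.frame",
                        conflicts = "data.frame",
                        topologyHint = "character"))

setMethod("show", "AdjacencyGraph", function(object) {
  cat(sprintf(paste0("AdjacencyGraph: %d segments present, %d junction ",
                     "edges, %d conflicts, topology hint %s\n"),
              sum(object@copies > 0L), nrow(object@junctions),
              nrow(object@conflicts), object@topologyHint))
})

.endSeg <- function(end) sub("\\.[lr]$", "", end)

#' Build the adjacency graph for a strain's evidence
#'
#' @param evidence an \linkS4class{EvidenceSet}.
#' @param map reference \linkS4class{SegmentMap}.
#' @param supportMin minimum junction support to treat a junction as
#'   observed (use 2 with noisy evidence; 1 is appropriate noise-free).
#' @return an \linkS4class{AdjacencyGraph}.
#' @export
buildGraph <- function(evidence, map, supportMin = 1L) {
  copies <- estimateCopyNumbers(evidence, map)
  jn <- evidence@junctions
  jn <- jn[jn$support >= supportMin, , drop = FALSE]
  bad <- copies[.endSeg(jn$endA)] == 0L | copies[.endSeg(jn$endB)] == 0L
  conflicts <- jn[bad, , drop = FALSE]
  if (nrow(conflicts))
    conflicts$reason <- "junction references a zero-copy segment"
  else conflicts$reason <- character(0)
  jn <- jn[!bad, , drop = FALSE]
  rownames(jn) <- NULL; rownames(conflicts) <- NULL
  new("AdjacencyGraph", copies = copies, junctions = jn,
      conflicts = conflicts, topologyHint = evidence@topologyHint)
}

# enumerate traversals of the graph consistent with copy numbers (each
# segment used exactly `copies` times) and junctions (steps only along
# junction edges; every junction edge used at least once).  Returns a list of
# ChromosomeStructure.
.enumerateTraversals <- function(graph, topology, cap, budget = 200000L) {
  copies <- graph@copies
  present <- names(copies)[copies > 0L]
  if (length(present) == 0L) return(list())
  jn <- graph@junctions
  total <- sum(copies)
  # adjacency lookup: for an oriented end, the junction indices touching it
  ends <- unique(c(jn$endA, jn$endB))
  touch <- lapply(stats::setNames(ends, ends), function(e)
    which(jn$endA == e | jn$endB == e))
  outEnd <- function(seg, sign) paste0(seg, if (sign > 0L) ".r" else ".l")
  inEnd <- function(seg, sign) paste0(seg, if (sign > 0L) ".l" else ".r")
  results <- list()
  expansions <- 0L
  overBudget <- FALSE

  recurse <- function(seg, sign, left, usedJn, path) {
    if (length(results) >= cap || overBudget) return()
    expansions <<- expansions + 1L
    if (expansions > budget) { overBudget <<- TRUE; return() }
    if (length(path$seg) == total) {
      ok <- if (topology == "circular") {
        e <- outEnd(seg, sign); f <- inEnd(path$seg[1L], path$sign[1L])
        key <- paste(sort(c(e, f)), collapse = "|")
        closing <- which(paste(pmin(jn$endA, jn$endB),
                               pmax(jn$endA, jn$endB), sep = "|") == key)
        length(closing) > 0L && all(usedJn | seq_len(nrow(jn)) %in% closing)
      } else all(usedJn)
      if (ok)
        results[[length(results) + 1L]] <<-
          new("ChromosomeStructure", topology = topology,
              segIds = path$seg, signs = path$sign)
      return()
    }
    e <- outEnd(seg, sign)
    for (ji in touch[[e]]) {
      f <- if (jn$endA[ji] == e) jn$endB[ji] else jn$endA[ji]
      nseg <- .endSeg(f)
      if (left[nseg] == 0L) next
      nsign <- if (endsWith(f, ".l")) 1L else -1L
      left2 <- left; left2[nseg] <- left2[nseg] - 1L
      used2 <- usedJn; used2[ji] <- TRUE
      recurse(nseg, nsign, left2,
              used2, list(seg = c(path$seg, nseg),
                          sign = c(path$sign, nsign)))
    }
  }

  if (topology == "circular") {
    # fix the start to break rotation symmetry
    seg0 <- present[1L]
    left <- copies; left[seg0] <- left[seg0] - 1L
    recurse(seg0, 1L, left, rep(FALSE, nrow(jn)),
            list(seg = seg0, sign = 1L))
    if (length(results) == 0L) {
      # the fixed start may only occur inverted relative to this rotation
      left <- copies; left[seg0] <- left[seg0] - 1L
      recurse(seg0, -1L, left, rep(FALSE, nrow(jn)),
              list(seg = seg0, sign = -1L))
    }
  } else {
    # start at occurrences whose in-end carries no junction
    starts <- list()
    for (seg in present) for (sign in c(1L, -1L)) {
      ie <- inEnd(seg, sign)
      if (is.null(touch[[ie]]) || length(touch[[ie]]) == 0L)
        starts[[length(starts) + 1L]] <- c(seg, sign)
    }
    if (length(starts) == 0L)
      for (seg in present) for (sign in c(1L, -1L))
        starts[[length(starts) + 1L]] <- c(seg, sign)
    for (s in starts) {
      left <- copies; left[s[1L]] <- left[s[1L]] - 1L
      recurse(s[1L], as.integer(s[2L]), left, rep(FALSE, nrow(jn)),
              list(seg = s[1L], sign = as.integer(s[2L])))
    }
  }
  attr(results, "overBudget") <- overBudget
  results
}

#' Infer chromosome structures consistent with an adjacency graph
#'
#' Enumerates Eulerian-style traversals — every present segment used exactly
#' its copy number of times, steps only along observed junctions, every
#' junction explained — deduplicates by canonical form, and ranks by minimal
#' event distance to the reference (ties broken by canonical word order).
#' On noise-free simulated evidence the true structure is always in the
#' list, and is the unique entry whenever the traversal is unique.
#'
#' @param graph an \linkS4class{AdjacencyGraph}.
#' @param map reference \linkS4class{SegmentMap}.
#' @param topologyHint \code{"linear"}, \code{"circular"} or
#'   \code{"unknown"} (tries both).
#' @param cap maximum number of candidate structures returned.
#' @return list of \linkS4class{ChromosomeStructure}, best first, with the
#'   per-candidate event distances in attribute \code{"eventDistance"}.
#' @export
inferStructures <- function(graph, map,
                            topologyHint = graph@topologyHint, cap = 1000L) {
  topos <- if (topologyHint == "unknown") c("linear", "circular")
  else topologyHint
  cands <- list()
  for (tp in topos)
    cands <- c(cands, .enumerateTraversals(graph, tp, cap))
  if (length(cands) == 0L) {
    msg <- "unresolvable evidence: no traversal consistent with copy numbers and junctions"
    if (nrow(graph@conflicts))
      msg <- paste0(msg, "; conflicts: ",
                    paste(sprintf("%s-%s (%s)", graph@conflicts$endA,
                                  graph@conflicts$endB,
                                  graph@conflicts$reason), collapse = ", "))
    stop(msg)
  }
  # deduplicate by canonical form
  rank <- .mapRank(map)
  keys <- vapply(cands, .structKey, character(1), rank)
  cands <- cands[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  ref <- referenceStructure(map)
  dist <- vapply(cands, function(s)
    tryCatch(minEventDistance(ref, s, map, kMax = 0L)@k,
             error = function(e) .Machine$integer.max), integer(1))
  ord <- order(dist, keys)
  out <- cands[ord]
  attr(out, "eventDistance") <- dist[ord]
  out
}

# ---------------------------------------------------------------------------
# minimal event distance

.structKey <- function(s, rank) .canonKey(s@topology, s@segIds, s@signs, rank)

.mapRank <- function(map) stats::setNames(seq_len(nSegments(map)), segIds(map))

# --- integer-coded word machinery for the exact search -------------------
# a state is a signed integer vector of segment ranks plus a topology flag;
# this avoids S4 allocation in the search hot path

.iSpan <- function(j1, j2, n) {
  if (j1 < j2) j1:(j2 - 1L)
  else c(j1:n, if (j2 > 1L) 1:(j2 - 1L))
}

.iApply <- function(w, circ, kind, j1, j2) {
  n <- length(w)
  if (kind == "circularization")
    return(list(w = w[j1:(j2 - 1L)], circ = TRUE))
  span <- .iSpan(j1, j2, n)
  if (length(span) >= n) return(NULL)
  if (kind == "deletion") list(w = w[-span], circ = circ)
  else if (kind == "inversion") {
    w[span] <- -w[rev(span)]
    list(w = w, circ = circ)
  } else {
    list(w = append(w, w[span], after = span[length(span)]), circ = circ)
  }
}

.iKey <- function(w, circ) {
  v <- 2L * abs(w) + (w < 0L)
  vm <- rev(2L * abs(w) + (w > 0L))
  best <- if (!circ) {
    if (.lexLess(vm, v)) vm else v
  } else {
    a <- .minRotation(v)$v; b <- .minRotation(vm)$v
    if (.lexLess(b, a)) b else a
  }
  paste0(if (circ) "c" else "l", paste(best, collapse = ","))
}

# all single-event moves available from an integer state: rows (kindCode,
# j1, j2) with kind 1 = deletion, 2 = inversion, 3 = duplication,
# 4 = circularization
.iMoves <- function(w, circ) {
  n <- length(w)
  if (circ) {
    if (n < 2L) return(NULL)
    grid <- expand.grid(a = seq_len(n), b = seq_len(n))
    grid <- grid[grid$a != grid$b, ]
    cbind(kind = rep(1:3, each = nrow(grid)),
          j1 = rep(grid$a, 3L), j2 = rep(grid$b, 3L))
  } else {
    if (n < 3L) return(NULL)
    pr <- utils::combn(2:n, 2L)
    cbind(kind = rep(1:4, each = ncol(pr)),
          j1 = rep(pr[1L, ], 4L), j2 = rep(pr[2L, ], 4L))
  }
}

.kindName <- c("deletion", "inversion", "duplication", "circularization")

# breadth-first search up to depth kMax over event space (integer-coded).
# Returns list(status = "found", events = ...), list(status = "exhausted")
# when every state within kMax events was visited without reaching the
# target (so the true distance exceeds kMax), or list(status = "overBudget").
.bfsDistance <- function(reference, target, map, kMax,
                         nodeBudget = 150000L) {
  rank <- .mapRank(map)
  enc <- function(s) unname(rank[s@segIds] * s@signs)
  w0 <- enc(reference); circ0 <- reference@topology == "circular"
  targetKey <- .iKey(enc(target), target@topology == "circular")
  if (.iKey(w0, circ0) == targetKey)
    return(list(status = "found", events = list()))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(.iKey(w0, circ0), TRUE, envir = seen)
  frontier <- list(list(w = w0, circ = circ0, mv = NULL))
  nodes <- 0L
  finish <- function(mvMat) {
    # replay the move list through the S4 path to record proper events
    events <- list(); cur <- reference
    for (r in seq_len(nrow(mvMat))) {
      ev <- .eventWithPayload(cur, .kindName[mvMat[r, 1L]],
                              mvMat[r, 2L], mvMat[r, 3L])
      cur <- applyEvent(cur, ev)
      events[[length(events) + 1L]] <- ev
    }
    list(status = "found", events = events)
  }
  for (depth in seq_len(kMax)) {
    nxt <- list()
    for (node in frontier) {
      mvs <- .iMoves(node$w, node$circ)
      if (is.null(mvs)) next
      for (r in seq_len(nrow(mvs))) {
        nodes <- nodes + 1L
        if (nodes > nodeBudget) return(list(status = "overBudget"))
        if (mvs[r, 1L] == 4L && node$circ) next
        s2 <- .iApply(node$w, node$circ, .kindName[mvs[r, 1L]],
                      mvs[r, 2L], mvs[r, 3L])
        if (is.null(s2)) next
        key <- .iKey(s2$w, s2$circ)
        mvMat <- rbind(node$mv, mvs[r, ])
        if (key == targetKey) return(finish(mvMat))
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(w = s2$w, circ = s2$circ,
                                          mv = mvMat)
        }
      }
    }
    if (length(nxt) == 0L) return(list(status = "exhausted"))
    frontier <- nxt
  }
  list(status = "exhausted")
}

# ---- greedy constructive decomposition (upper bound) ----------------------

# rotate/mirror a circular structure so that the smallest present reference
# segment occurs first with sign +; free operations (rotation/reflection
# equivalence), applied once before the greedy pass.
.anchorRotate <- function(x, map) {
  rank <- stats::setNames(seq_len(nSegments(map)), segIds(map))
  anchorSeg <- x@segIds[which.min(rank[x@segIds])]
  i <- which(x@segIds == anchorSeg)[1L]
  if (x@signs[i] < 0L) {
    x <- .mirror(x)
    i <- which(x@segIds == anchorSeg)[1L]
  }
  .rotate(x, i - 1L)
}

# find a maximal-progress tandem repeat (u u) in the word; returns c(start,
# len) of the first copy, or NULL.  With circular = TRUE the search is
# cyclic (the repeat may wrap the stored-word boundary; the caller rotates
# before collapsing).
.findTandem <- function(segs, signs, circular = FALSE) {
  n <- length(segs)
  # a duplication span never covers the whole molecule, so on circular
  # words the repeat unit is capped below n/2
  Lmax <- if (circular) (n - 1L) %/% 2L else n %/% 2L
  for (L in rev(seq_len(Lmax))) {
    imax <- if (circular) n else n - 2L * L + 1L
    for (i in seq_len(imax)) {
      a <- ((i - 1L + 0:(L - 1L)) %% n) + 1L
      b <- ((i - 1L + L:(2L * L - 1L)) %% n) + 1L
      if (!circular && (i + 2L * L - 1L) > n) next
      if (identical(segs[a], segs[b]) && identical(signs[a], signs[b]))
        return(c(i, L))
    }
  }
  NULL
}

#' Minimal-event decomposition of a structure
#'
#' Searches for a shortest list of SCRaMbLE events transforming the
#' reference into the observed structure.  Small cases are solved exactly by
#' breadth-first search over event space (up to \code{kMax} events);
#' deletion-only patterns are recognized in closed form (one circularization
#' if circular plus one deletion per maximal missing interior run, which is
#' provably minimal); everything else falls back to a constructive greedy
#' upper bound (collapse tandem duplications, merge stray copies, sort by
#' reversals, delete missing runs) with \code{isMinimal = FALSE}.
#'
#' @param reference the reference \linkS4class{ChromosomeStructure}.
#' @param structure the observed structure, over the same map.
#' @param map the \linkS4class{SegmentMap}.
#' @param kMax exact-search depth (default 4); \code{kMax = 0} skips BFS and
#'   uses only the closed form / greedy path (fast, used for ranking).
#' @return an \linkS4class{EventDecomposition}; replaying its events on the
#'   reference reproduces the observed structure up to canonical form.
#' @export
minEventDistance <- function(reference, structure, map, kMax = 4L) {
  refIds <- segIds(map)
  if (!all(structure@segIds %in% refIds))
    stop("structure references segments absent from the map")
  if (sameStructure(reference, structure, map))
    return(new("EventDecomposition", events = list(), k = 0L,
               isMinimal = TRUE))

  # closed form: in-order, all-forward, duplicate-free target
  cf <- .deletionOnlyDecomposition(reference, structure, map)
  if (!is.null(cf))
    return(new("EventDecomposition", events = cf, k = length(cf),
               isMinimal = TRUE))

  greedy <- tryCatch(.greedyDecomposition(reference, structure, map),
                     error = function(e) NULL)
  if (is.null(greedy)) {
    # tangled word the constructive pass cannot express: pure exact search
    if (kMax > 0L && .bfsFeasible(reference, kMax)) {
      res <- .bfsDistance(reference, structure, map, kMax)
      if (res$status == "found")
        return(new("EventDecomposition", events = res$events,
                   k = length(res$events), isMinimal = TRUE))
    }
    stop("unreachable within fallback budget")
  }
  kg <- length(greedy)
  if (kg <= 1L)   # a nonidentical structure needs at least one event
    return(new("EventDecomposition", events = greedy, k = kg,
               isMinimal = TRUE))
  # certify (or improve) the greedy bound by searching all shorter lists
  depth <- min(kMax, kg - 1L)
  if (depth >= 1L && .bfsFeasible(reference, depth)) {
    res <- .bfsDistance(reference, structure, map, depth)
    if (res$status == "found")
      return(new("EventDecomposition", events = res$events,
                 k = length(res$events), isMinimal = TRUE))
    if (res$status == "exhausted")
      return(new("EventDecomposition", events = greedy, k = kg,
                 isMinimal = TRUE))
  }
  new("EventDecomposition", events = greedy, k = kg, isMinimal = FALSE)
}

# rough branching estimate: skip exact search when the event space is too
# large for the node budget.  BFS stops at the first (shortest) hit, so only
# the levels below the answer must be affordable; level counts beyond 3 are
# not charged because a shallower hit returns early.
.bfsFeasible <- function(reference, depth, nodeBudget = 150000L) {
  n <- length(reference@segIds)
  b <- if (reference@topology == "circular") 3 * n * (n - 1)
  else 4 * choose(max(n - 1, 0), 2)
  b > 0 && b <= 1500 &&
    sum(b^seq_len(min(depth, 3L))) <= nodeBudget
}

# closed-form decomposition when the target is an in-order all-forward
# duplicate-free subword: circularization (if circular) + one deletion per
# maximal missing interior run.  Returns the event list or NULL if the
# pattern does not apply.
.deletionOnlyDecomposition <- function(reference, target, map) {
  refIds <- segIds(map)
  t <- if (target@topology == "circular") .anchorRotate(target, map)
  else {
    cf <- canonicalForm(target, map)
    cf
  }
  if (any(t@signs < 0L) || anyDuplicated(t@segIds)) return(NULL)
  pos <- match(t@segIds, refIds)
  if (is.unsorted(pos, strictly = TRUE)) return(NULL)
  n <- length(refIds)
  events <- list()
  cur <- reference
  if (t@topology == "circular") {
    a <- pos[1L]; b <- pos[length(pos)]
    if (a < 2L || b > n - 1L) return(NULL)   # arc must exclude telomeric ends
    ev <- .eventWithPayload(cur, "circularization", a, b + 1L)
    cur <- applyEvent(cur, ev)
    events[[length(events) + 1L]] <- ev
  } else {
    # terminal segments cannot be deleted from a linear molecule
    if (pos[1L] != 1L || pos[length(pos)] != n) return(NULL)
  }
  # delete maximal missing runs, right to left so positions stay valid
  curPos <- match(cur@segIds, refIds)
  missing <- setdiff(curPos, pos)
  if (length(missing)) {
    runs <- split(sort(missing), cumsum(c(1L, diff(sort(missing)) != 1L)))
    for (run in rev(runs)) {
      i1 <- match(run[1L], match(cur@segIds, refIds))
      i2 <- match(run[length(run)], match(cur@segIds, refIds))
      ev <- .eventWithPayload(cur, "deletion", i1, i2 + 1L)
      cur <- applyEvent(cur, ev)
      events[[length(events) + 1L]] <- ev
    }
  }
  if (!sameStructure(cur, target, map)) return(NULL)
  events
}

# greedy sorting of a signed permutation by reversals via breakpoint
# reduction, falling back to a placement step when no reversal reduces
# breakpoints.  Returns a list of c(i, j) reversal index pairs.  Position 1
# is held fixed; for linear molecules the last position is fixed too.
.greedySortReversals <- function(perm, circular) {
  m <- length(perm)
  p <- c(0L, perm, m + 1L)     # sentinels at both ends
  lastFree <- if (circular) m else m - 1L
  bpAfter <- function(x) sum(x[-1L] - x[-length(x)] != 1L)
  revs <- list()
  guard <- 0L
  while (bpAfter(p) > 0L) {
    guard <- guard + 1L
    if (guard > 3L * m + 30L) stop("unreachable within fallback budget")
    best <- NULL; bestDelta <- 0L
    for (i in 3:(lastFree + 1L)) {       # indices into p (word pos i-1)
      for (j in i:(lastFree + 1L)) {
        oldBad <- (p[i] - p[i - 1L] != 1L) + (p[j + 1L] - p[j] != 1L)
        newBad <- (-p[j] - p[i - 1L] != 1L) + (p[j + 1L] + p[i] != 1L)
        delta <- oldBad - newBad
        if (delta > bestDelta) { bestDelta <- delta; best <- c(i, j) }
      }
    }
    if (is.null(best)) {
      # no breakpoint-reducing reversal: place the first out-of-order
      # element (guaranteed progress, pancake style)
      w <- which(p[-1L] - p[-length(p)] != 1L)[1L]  # adjacency (w, w+1) bad
      tgt <- p[w] + 1L
      q <- which(p == tgt | p == -tgt)
      if (length(q) == 0L || q > lastFree + 1L)
        stop("unreachable within fallback budget")
      best <- c(w + 1L, q)
      if (best[1L] > best[2L]) stop("unreachable within fallback budget")
    }
    i <- best[1L]; j <- best[2L]
    p[i:j] <- -p[j:i]
    revs[[length(revs) + 1L]] <- c(i - 1L, j - 1L)   # word coordinates
  }
  revs
}

# longest exactly repeated non-overlapping block, forward (same segments
# and signs) or reverse-complement; returns list(i, j, L, reversed) with
# j >= i + L, or NULL when no segment repeats
.longestRepeatBlock <- function(segs, signs) {
  n <- length(segs)
  key <- paste0(ifelse(signs < 0L, "-", ""), segs)
  rkey <- paste0(ifelse(signs > 0L, "-", ""), segs)   # reverse-complement
  for (L in rev(seq_len(n %/% 2L))) {
    fw <- vapply(seq_len(n - L + 1L), function(i)
      paste(key[i:(i + L - 1L)], collapse = "|"), character(1))
    rv <- vapply(seq_len(n - L + 1L), function(i)
      paste(rev(rkey[i:(i + L - 1L)]), collapse = "|"), character(1))
    for (i in seq_along(fw)) {
      jf <- which(fw == fw[i])
      jf <- jf[jf >= i + L]
      if (length(jf))
        return(list(i = i, j = jf[1L], L = L, reversed = FALSE))
      jr <- which(rv == fw[i])
      jr <- jr[jr >= i + L]
      if (length(jr))
        return(list(i = i, j = jr[1L], L = L, reversed = TRUE))
    }
  }
  NULL
}

# Near-tandem completion.  Finds the first duplicated segment, aligns the
# two copy regions with a two-pointer walk, and repairs small divergences:
# a run present in only one copy is re-inserted into the other (one undo
# insert = one forward deletion), an orientation mismatch is fixed with a
# single-element reversal.  On success the copies become an exact tandem
# that the main loop collapses next.  Returns list(segs, signs, undo) or
# NULL when the pattern is too tangled (caller falls back).
.copyCompletion <- function(segs, signs, circ, rank, maxOps = 12L) {
  n <- length(segs)
  dupSeg <- segs[duplicated(segs)][1L]
  occ <- which(segs == dupSeg)
  # The duplication pair may sit anywhere around the stored origin of a
  # circular word, and single-copy runs outside the duplicated span must
  # end up beyond the copies: try the two occurrence anchors plus a
  # rotation placing each maximal single-copy run at the stored end.
  rots <- 0L
  if (circ) {
    cnt <- table(segs)
    single <- cnt[segs] == 1L
    runEnds <- which(single & c(!single[-1L], TRUE))
    rots <- unique(c(occ[1L] - 1L, occ[2L] - 1L,
                     utils::head(runEnds, 8L) %% n))
  }
  uuRes <- NULL
  for (k in unique(rots)) {
    res <- .copyCompletionAt(segs, signs, circ, dupSeg, k, maxOps)
    if (is.null(res)) next
    if (is.null(res$fail)) return(res)
    if (identical(res$fail, "uu") && circ && is.null(uuRes)) uuRes <- res
  }
  if (!is.null(uuRes)) {
    # completing both copies duplicated every element, which no single
    # duplication can produce: the true history deleted a run that sat
    # outside the duplicated span.  Re-introduce one such segment at the
    # inter-copy joint (one forward deletion) so the collapse is legal.
    refIds <- names(rank)
    present <- unique(uuRes$segs)
    pr <- range(rank[present])
    cand <- c(if (pr[2L] + 1L <= length(refIds) - 1L) pr[2L] + 1L,
              if (pr[1L] - 1L >= 2L) pr[1L] - 1L)
    cand <- cand[!(refIds[cand] %in% present)]
    if (length(cand)) {
      segs2 <- c(uuRes$segs, refIds[cand[1L]])
      signs2 <- c(uuRes$signs, 1L)
      undo2 <- c(uuRes$undo,
                 list(list(op = "insert", p = length(segs2), len = 1L)))
      return(list(segs = segs2, signs = signs2, undo = undo2))
    }
  }
  NULL
}

.copyCompletionAt <- function(segs, signs, circ, dupSeg, k, maxOps,
                              probe = FALSE) {
  n <- length(segs)
  undo <- list()
  if (circ && k > 0L) {
    undo[[length(undo) + 1L]] <- list(op = "rotate", k = k)
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    segs <- segs[idx]; signs <- signs[idx]
  }
  dupSeg <- segs[duplicated(segs)][1L]   # first duplicated segment in the
  occ <- which(segs == dupSeg)           # rotated frame anchors the pairing
  if (length(occ) < 2L) return(NULL)
  q1 <- occ[1L]; q2 <- occ[2L]
  counts <- table(segs)
  i <- q1; j <- q2
  ops <- 0L
  while (i < q2 && j <= length(segs)) {
    if (ops > maxOps) return(NULL)
    if (segs[i] == segs[j] && signs[i] == signs[j]) {
      i <- i + 1L; j <- j + 1L
      next
    }
    # an inverted block in one copy: patch the second copy with one
    # reversal (h = 0 is a single-element orientation flip)
    maxH <- min(q2 - 1L - i, length(segs) - j)
    patched <- FALSE
    for (h in rev(0:maxH)) {
      a <- i:(i + h); b <- j:(j + h)
      if (identical(segs[a], rev(segs[b])) &&
          identical(signs[a], -rev(signs[b]))) {
        undo[[length(undo) + 1L]] <- list(op = "reversal", i = j, j = j + h)
        segs[b] <- segs[rev(b)]; signs[b] <- -signs[rev(b)]
        ops <- ops + 1L
        patched <- TRUE
        break
      }
    }
    if (patched) next
    if (counts[[segs[j]]] == 1L) {
      # run private to copy 2: re-insert it into copy 1 (undo a deletion)
      e <- j
      while (e + 1L <= length(segs) && counts[[segs[e + 1L]]] == 1L)
        e <- e + 1L
      if (probe) return(list(probeEnd = e))
      len <- e - j + 1L
      undo[[length(undo) + 1L]] <- list(op = "insert", p = i, len = len)
      segs <- append(segs, segs[j:e], after = i - 1L)
      signs <- append(signs, signs[j:e], after = i - 1L)
      q2 <- q2 + len
      i <- i + len
      j <- j + 2L * len
      ops <- ops + 1L
    } else if (counts[[segs[i]]] == 1L) {
      # run private to copy 1: re-insert it into copy 2
      e <- i
      while (e + 1L < q2 && counts[[segs[e + 1L]]] == 1L) e <- e + 1L
      if (probe) return(list(probeEnd = e))
      len <- e - i + 1L
      undo[[length(undo) + 1L]] <- list(op = "insert", p = j, len = len)
      segs <- append(segs, segs[i:e], after = j - 1L)
      signs <- append(signs, signs[i:e], after = j - 1L)
      i <- i + len
      j <- j + len
      ops <- ops + 1L
    } else return(NULL)
  }
  if (i != q2) return(NULL)
  L <- q2 - q1
  if (q2 + L - 1L > length(segs)) return(NULL)
  # a duplication span never covers the whole molecule
  if (circ && 2L * L >= length(segs))
    return(list(fail = "uu", segs = segs, signs = signs, undo = undo))
  a <- q1:(q2 - 1L); b <- q2:(q2 + L - 1L)
  if (!identical(segs[a], segs[b]) || !identical(signs[a], signs[b]))
    return(NULL)
  list(segs = segs, signs = signs, undo = undo)
}

# constructive greedy decomposition: backward rewriting of the target into
# the reference, then inversion of the undo list into forward events.
.greedyDecomposition <- function(reference, target, map) {
  refIds <- segIds(map)
  rank <- stats::setNames(seq_along(refIds), refIds)
  n <- length(refIds)
  circ <- target@topology == "circular"
  t <- if (circ) .anchorRotate(target, map) else target
  segs <- t@segIds; signs <- t@signs
  undo <- list()   # each: list(op=, ...positions in the pre-undo word)
  guard <- 0L

  # 1. collapse tandem repeats (cyclic search on circular words; a wrapping
  #    repeat is realigned first with a free rotation, recorded in the undo
  #    log); make stray duplicates tandem via reversals
  repeat {
    guard <- guard + 1L
    if (guard > 500L) stop("unreachable within fallback budget")
    n_ <- length(segs)
    td <- .findTandem(segs, signs, circular = circ)
    if (!is.null(td)) {
      i <- td[1L]; L <- td[2L]
      if (circ && (i + 2L * L - 1L) > n_) {
        # repeat wraps the stored boundary: rotate it to the front
        k <- i - 1L
        undo[[length(undo) + 1L]] <- list(op = "rotate", k = k)
        idx <- ((seq_len(n_) - 1L + k) %% n_) + 1L
        segs <- segs[idx]; signs <- signs[idx]
        i <- 1L
      }
      undo[[length(undo) + 1L]] <- list(op = "collapse", i = i, L = L)
      drop <- (i + L):(i + 2L * L - 1L)
      segs <- segs[-drop]; signs <- signs[-drop]
      next
    }
    dupSeg <- segs[duplicated(segs)]
    if (length(dupSeg) == 0L) break
    # near-tandem completion: a duplication whose copies later diverged by
    # small deletions/flips is repaired by re-inserting the missing runs
    # (each one forward deletion) until the copies match exactly
    comp <- .copyCompletion(segs, signs, circ, rank)
    if (!is.null(comp)) {
      segs <- comp$segs; signs <- comp$signs
      undo <- c(undo, comp$undo)
      next
    }
    # fallback: locate the longest exactly repeated block (forward or
    # reverse-complement) and bring the copies tandem-adjacent with at most
    # two reversals, so the main loop can collapse a whole block at a time
    blk <- .longestRepeatBlock(segs, signs)
    if (is.null(blk)) stop("unreachable within fallback budget")
    i <- blk$i; j <- blk$j; L <- blk$L
    if (blk$reversed) {
      # make the second copy read forward first
      b <- j:(j + L - 1L)
      undo[[length(undo) + 1L]] <- list(op = "reversal", i = j,
                                        j = j + L - 1L)
      segs[b] <- segs[rev(b)]; signs[b] <- -signs[rev(b)]
      next
    }
    if (j == i + L) next    # already tandem; the collapse handles it
    # reverse the stretch between copy 1's end and copy 2's end, then
    # re-orient the displaced copy: X M X -> X -X' -M' -> X X M'
    s1 <- (i + L):(j + L - 1L)
    undo[[length(undo) + 1L]] <- list(op = "reversal", i = i + L,
                                      j = j + L - 1L)
    segs[s1] <- segs[rev(s1)]; signs[s1] <- -signs[rev(s1)]
    s2 <- (i + L):(i + 2L * L - 1L)
    undo[[length(undo) + 1L]] <- list(op = "reversal", i = i + L,
                                      j = i + 2L * L - 1L)
    segs[s2] <- segs[rev(s2)]; signs[s2] <- -signs[rev(s2)]
  }

  # re-anchor after the duplication phase (rotations/collapses may have
  # moved the anchor); rotation and mirror are free symmetries of a circular
  # molecule, recorded so that replay coordinates stay aligned
  if (circ) {
    anchorSeg <- segs[which.min(rank[segs])]
    i <- which(segs == anchorSeg)[1L]
    if (signs[i] < 0L) {
      undo[[length(undo) + 1L]] <- list(op = "mirror")
      segs <- rev(segs); signs <- rev(-signs)
      i <- which(segs == anchorSeg)[1L]
    }
    if (i > 1L) {
      k <- i - 1L
      undo[[length(undo) + 1L]] <- list(op = "rotate", k = k)
      n_ <- length(segs)
      idx <- ((seq_len(n_) - 1L + k) %% n_) + 1L
      segs <- segs[idx]; signs <- signs[idx]
    }
  }

  # 2. sort by reversals into reference order, all signs +, using greedy
  #    breakpoint reduction (near-minimal on compositions of few reversals);
  #    position 1 (anchor / terminal segment) is never moved, and on linear
  #    molecules neither is the last position (telomeres are not loxPsym
  #    sites)
  perm <- match(rank[segs], sort(rank[segs])) * signs
  revs <- .greedySortReversals(perm, circular = circ)
  for (rv in revs) {
    blk <- rv[1L]:rv[2L]
    undo[[length(undo) + 1L]] <- list(op = "reversal", i = rv[1L],
                                      j = rv[2L])
    segs[blk] <- segs[rev(blk)]; signs[blk] <- -signs[rev(blk)]
  }
  if (is.unsorted(rank[segs], strictly = TRUE) || any(signs < 0L))
    stop("unreachable within fallback budget")

  # 3. insert missing runs (undo deletions)
  pos <- rank[segs]
  lo <- if (circ) min(pos) else 1L
  hi <- if (circ) max(pos) else n
  full <- lo:hi
  missing <- setdiff(full, pos)
  if (length(missing)) {
    runs <- split(sort(missing), cumsum(c(1L, diff(sort(missing)) != 1L)))
    for (run in runs) {
      at <- sum(pos < run[1L])          # insert after this many occurrences
      undo[[length(undo) + 1L]] <-
        list(op = "insert", p = at + 1L, len = length(run))
      segs <- append(segs, refIds[run], after = at)
      signs <- append(signs, rep(1L, length(run)), after = at)
      pos <- rank[segs]
    }
  }

  # 4. linearize (undo circularization)
  if (circ) {
    undo[[length(undo) + 1L]] <- list(op = "linearize", a = lo, b = hi)
  }

  if (circ && (lo < 2L || hi > n - 1L))
    stop("unreachable within fallback budget")   # arc would need a telomere

  # convert the undo list (target -> reference) into forward events; a span
  # ending at the stored-word boundary of a circular molecule is expressed
  # with a wrapping junction pair
  events <- list()
  states <- list()      # bookkeeping-frame word after each forward event
  usedSym <- FALSE
  cur <- reference
  wrapJ <- function(word, j2) {
    m <- length(word@segIds)
    if (word@topology == "circular" && j2 == m + 1L) 1L else j2
  }
  for (u in rev(undo)) {
    if (u$op == "rotate") {           # free symmetry, no event
      cur <- .rotate(cur, -u$k)
      usedSym <- TRUE
      next
    }
    if (u$op == "mirror") {
      cur <- .mirror(cur)
      usedSym <- TRUE
      next
    }
    ev <- switch(u$op,
      linearize = .eventWithPayload(cur, "circularization", u$a, u$b + 1L),
      insert = .eventWithPayload(cur, "deletion", u$p,
                                 wrapJ(cur, u$p + u$len)),
      reversal = .eventWithPayload(cur, "inversion", u$i,
                                   wrapJ(cur, u$j + 1L)),
      collapse = .eventWithPayload(cur, "duplication", u$i,
                                   wrapJ(cur, u$i + u$L)))
    cur <- applyEvent(cur, ev)
    events[[length(events) + 1L]] <- ev
    states[[length(states) + 1L]] <- cur
  }
  if (!sameStructure(cur, target, map))
    stop("unreachable within fallback budget")
  if (usedSym)
    events <- .regroundEvents(reference, events, states, map)
  events
}

# Re-express a bookkeeping-frame event list in the pure replay frame.  When
# the constructive pass used free rotation/mirror symmetries of a circular
# molecule, its junction coordinates refer to re-rotated words; this pass
# replays from the reference and, for each event, finds junctions whose
# product is canonically identical to the recorded intermediate state.
.regroundEvents <- function(reference, events, states, map) {
  rank <- .mapRank(map)
  out <- list()
  p <- reference
  for (i in seq_along(events)) {
    ev <- events[[i]]
    wantKey <- .structKey(states[[i]], rank)
    spanLen <- length(ev@payload)
    n <- length(p@segIds)
    circ <- p@topology == "circular"
    cands <- if (circ) {
      if (spanLen > n - 1L) matrix(integer(0), ncol = 2L)
      else {
        j1 <- seq_len(n)
        cbind(j1, ((j1 + spanLen - 1L) %% n) + 1L)
      }
    } else {
      # linear word (events and circularization): interior boundaries only
      if (n - spanLen < 2L) matrix(integer(0), ncol = 2L)
      else {
        j1 <- 2:(n - spanLen)
        cbind(j1, j1 + spanLen)
      }
    }
    found <- FALSE
    for (r in seq_len(nrow(cands))) {
      if (cands[r, 1L] == cands[r, 2L]) next
      ev2 <- tryCatch(.eventWithPayload(p, ev@kind, cands[r, 1L],
                                        cands[r, 2L]),
                      error = function(e) NULL)
      if (is.null(ev2)) next
      q <- tryCatch(applyEvent(p, ev2), error = function(e) NULL)
      if (is.null(q)) next
      if (.structKey(q, rank) == wantKey) {
        out[[length(out) + 1L]] <- ev2
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) stop("unreachable within fallback budget")
  }
  out
}

#' Classify a set of event decompositions at the population level
#'
#' Pools deletion/inversion/duplication events across strains (the
#' circularization event is reported separately as the circular fraction,
#' matching how the screen counts its events) and summarizes per-strain
#' counts and per-topology subgroups.
#'
#' @param decompositions list of \linkS4class{EventDecomposition}.
#' @return list with \code{typeFractions} (named: deletion, inversion,
#'   duplication), \code{counts} (pooled event counts by type),
#'   \code{perStrainEvents} (non-circularization events per strain),
#'   \code{meanEvents}, \code{circularFraction}, and \code{byTopology}
#'   (type fractions within circular / linear subgroups).
#' @export
classifyPopulation <- function(decompositions) {
  stopifnot(length(decompositions) >= 1L)
  kinds <- lapply(decompositions, function(d) eventKinds(d@events))
  isCirc <- vapply(kinds, function(k) "circularization" %in% k, logical(1))
  core <- lapply(kinds, function(k) k[k != "circularization"])
  pool <- unlist(core)
  types <- c("deletion", "inversion", "duplication")
  counts <- vapply(types, function(tp) sum(pool == tp), numeric(1))
  frac <- if (sum(counts) > 0) counts / sum(counts) else counts * 0
  perStrain <- vapply(core, length, integer(1))
  sub <- function(sel) {
    p <- unlist(core[sel])
    cts <- vapply(types, function(tp) sum(p == tp), numeric(1))
    if (sum(cts) > 0) cts / sum(cts) else cts * 0
  }
  list(typeFractions = frac,
       counts = counts,
       perStrainEvents = perStrain,
       meanEvents = mean(perStrain),
       circularFraction = mean(isCirc),
       byTopology = list(circular = sub(isCirc), linear = sub(!isCirc)))
}
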