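#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a ChromosomeStructure
#'
#' @param word signed segment ids, e.g. \code{c("A", "-C", "-B")}; a leading
#'   \code{"-"} marks an inverted occurrence.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @return a \linkS4class{ChromosomeStructure}.
#' @export
ChromosomeStructure <- function(word, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  word <- as.character(word)
  if (length(word) == 0L) stop("structure word must be nonempty")
  neg <- startsWith(word, "-")
  new("ChromosomeStructure", topology = topology,
      segIds = ifelse(neg, substring(word, 2L), word),
      signs = ifelse(neg, -1L, 1L))
}

#' Reference structure of a map: the full-length linear word
#'
#' @param map a \linkS4class{SegmentMap}.
#' @return linear \linkS4class{ChromosomeStructure} listing every segment
#'   once, forward.
#' @export
referenceStructure <- function(map)
  new("ChromosomeStructure", topology = "linear",
      segIds = segIds(map), signs = rep(1L, nSegments(map)))

#' @describeIn ChromosomeStructure topology flag
#' @param x a ChromosomeStructure
#' @export
setMethod("topology", "ChromosomeStructure", function(x) x@topology)

#' @describeIn ChromosomeStructure the signed word as characters
#'   (\code{"-B"} style)
#' @export
setMethod("structureWord", "ChromosomeStructure", function(x)
  paste0(ifelse(x@signs < 0L, "-", ""), x@segIds))

setMethod("show", "ChromosomeStructure", function(object) {
  cat(sprintf("ChromosomeStructure (%s, %d segments): %s\n",
              object@topology, length(object@segIds),
              paste(structureWord(object), collapse = ",")))
})

#' @describeIn ChromosomeStructure word length (number of occurrences)
#' @export
setMethod("length", "ChromosomeStructure", function(x) length(x@segIds))

# mirror: reverse order and flip signs (reading the molecule from the other
# end)
.mirror <- function(x)
  new("ChromosomeStructure", topology = x@topology,
      segIds = rev(x@segIds), signs = rev(-x@signs))

.rotate <- function(x, k) {
  n <- length(x@segIds)
  i <- ((seq_len(n) - 1L + k) %% n) + 1L
  new("ChromosomeStructure", topology = x@topology,
      segIds = x@segIds[i], signs = x@signs[i])
}

# integer encoding of a signed word: 2 * segment rank + (sign < 0), so
# lower ranks sort first and + sorts before - within a rank
.encodeWord <- function(segIds, signs, rank) {
  r <- rank[segIds]
  if (anyNA(r))
    r[is.na(r)] <- length(rank) +
      match(segIds[is.na(r)], sort(unique(segIds[is.na(r)])))
  as.integer(2L * r + (signs < 0L))
}

.lexLess <- function(a, b) {
  i <- which(a != b)[1L]
  !is.na(i) && a[i] < b[i]
}

# lexicographically minimal rotation (words are short; only rotations
# starting at a minimal element can win)
.minRotation <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v = v, k = 0L))
  best <- v; bestK <- 0L
  for (k in which(v == min(v)) - 1L) {
    if (k == 0L) next
    r <- v[((seq_len(n) - 1L + k) %% n) + 1L]
    if (.lexLess(r, best)) { best <- r; bestK <- k }
  }
  list(v = best, k = bestK)
}

# canonical encoded word plus how to realize it: list(v, mirror, k)
.canonInfo <- function(topology, segIds, signs, rank) {
  v <- .encodeWord(segIds, signs, rank)
  vm <- rev(.encodeWord(segIds, -signs, rank))
  if (topology == "linear") {
    if (.lexLess(vm, v)) list(v = vm, mirror = TRUE, k = 0L)
    else list(v = v, mirror = FALSE, k = 0L)
  } else {
    a <- .minRotation(v); b <- .minRotation(vm)
    if (.lexLess(b$v, a$v)) list(v = b$v, mirror = TRUE, k = b$k)
    else list(v = a$v, mirror = FALSE, k = a$k)
  }
}

#' Canonical form of a structure
#'
#' Linear words are equivalent to their mirror (the molecule read from the
#' other end); circular words are additionally equivalent under rotation.
#' The canonical form is the lexicographically smallest representative, with
#' occurrences ordered by segment rank (map order when a map is supplied,
#' otherwise sorted id order) and \code{+} before \code{-}.  Idempotent.
#'
#' @param x a \linkS4class{ChromosomeStructure}.
#' @param map optional \linkS4class{SegmentMap} fixing the segment ordering.
#' @return the canonical \linkS4class{ChromosomeStructure}.
#' @export
setMethod("canonicalForm", "ChromosomeStructure", function(x, map = NULL) {
  ids <- if (is.null(map)) sort(unique(x@segIds)) else segIds(map)
  rank <- stats::setNames(seq_along(ids), ids)
  info <- .canonInfo(x@topology, x@segIds, x@signs, rank)
  y <- if (info$mirror) .mirror(x) else x
  if (info$k > 0L) y <- .rotate(y, info$k)
  y
})

# fast canonical key for hashing/deduplication (no S4 allocation)
.canonKey <- function(topology, segIds, signs, rank)
  paste(topology,
        paste(.canonInfo(topology, segIds, signs, rank)$v, collapse = ","),
        sep = ":")

#' Structure equality up to canonical form
#'
#' @param a,b structures over the same map.
#' @param map optional map fixing segment order.
#' @return logical.
#' @export
sameStructure <- function(a, b, map = NULL) {
  if (a@topology != b@topology || length(a) != length(b)) return(FALSE)
  ca <- canonicalForm(a, map); cb <- canonicalForm(b, map)
  identical(ca@segIds, cb@segIds) && identical(ca@signs, cb@signs)
}

#' Fraction of the reference chromosome retained by a structure
#'
#' A reference segment counts as retained when it occurs at least once in the
#' word, in either orientation; extra copies do not raise the fraction above
#' one.  The default weighting is by bp, matching "percent of chromosome
#' content retained"; \code{"segments"} counts segments instead.
#'
#' @param x a \linkS4class{ChromosomeStructure}.
#' @param map the reference \linkS4class{SegmentMap}.
#' @param weighting \code{"bp"} (default) or \code{"segments"}.
#' @return a fraction in [0, 1].
#' @export
setMethod("retainedFraction", "ChromosomeStructure",
          function(x, map, weighting = c("bp", "segments")) {
  weighting <- match.arg(weighting)
  ids <- segIds(map)
  unknown <- setdiff(x@segIds, ids)
  if (length(unknown))
    stop("structure references unknown segment ids: ",
         paste(unknown, collapse = ", "))
  present <- ids %in% x@segIds
  if (weighting == "bp") sum(segLengths(map)[present]) / totalLength(map)
  else mean(present)
})

#' Per-segment preservation frequency across a population
#'
#' For every reference segment, the fraction of strains whose structure
#' retains it at one or more copies (the per-segment chromosome retention
#' rate of the screen).
#'
#' @param population a \linkS4class{ScramblePopulation} or list of
#'   \linkS4class{StrainRecord}.
#' @param map the reference \linkS4class{SegmentMap}.
#' @return named numeric in map order, values in [0, 1].
#' @export
preservationProfile <- function(population, map) {
  recs <- if (is(population, "ScramblePopulation")) population@strains
  else population
  if (length(recs) == 0L) stop("empty population")
  ids <- segIds(map)
  counts <- rowSums(vapply(recs, function(r)
    ids %in% r@structure@segIds, logical(length(ids))))
  stats::setNames(counts / length(recs), ids)
}

# ---- plain-text / JSON serialization ---------------------------------------

#' Format / parse the one-line structure word representation
#'
#' The plain-text form is \code{topology:linear<TAB>A,-C,-B,D}.
#'
#' @param x a \linkS4class{ChromosomeStructure}.
#' @return \code{formatStructure}: a single string.
#' @export
formatStructure <- function(x)
  paste0("topology:", x@topology, "\t",
         paste(structureWord(x), collapse = ","))

#' @rdname formatStructure
#' @param line a string produced by \code{formatStructure}.
#' @return \code{parseStructure}: a \linkS4class{ChromosomeStructure}.
#' @export
parseStructure <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !startsWith(parts[1L], "topology:"))
    stop("malformed structure line: ", line)
  ChromosomeStructure(strsplit(parts[2L], ",", fixed = TRUE)[[1L]],
                      topology = sub("^topology:", "", parts[1L]))
}

#' Write / read structure words, one strain per line
#'
#' @param structures named list of \linkS4class{ChromosomeStructure}.
#' @param path output TSV path (columns: strain, structure line fields).
#' @export
writeStructures <- function(structures, path) {
  if (is.null(names(structures)))
    names(structures) <- sprintf("strain%03d", seq_along(structures))
  lines <- vapply(structures, formatStructure, character(1))
  writeLines(paste(names(structures), lines, sep = "\t"), path)
  invisible(path)
}

#' @rdname writeStructures
#' @export
readStructures <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parseStructure(paste(parts[-1L], collapse = "\t"))
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
  out
}

#' JSON form of a structure
#'
#' @param x a \linkS4class{ChromosomeStructure}.
#' @return \code{structureToJson}: a JSON string.
#' @export
structureToJson <- function(x)
  as.character(jsonlite::toJSON(list(topology = x@topology,
                                     word = structureWord(x)),
                                auto_unbox = TRUE))

#' @rdname structureToJson
#' @param json a JSON string from \code{structureToJson}.
#' @export
structureFromJson <- function(json) {
  obj <- jsonlite::fromJSON(json)
  ChromosomeStructure(obj$word, topology = obj$topology)
}
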