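# small maps and structures used across tests

map3 <- function() SegmentMap(c(100L, 150L, 150L), ids = c("A", "CEN", "B"),
                              centromere = 2, marker = 2)

# 6 equal segments, centromere C, marker D
map6 <- function() SegmentMap(rep(10000L, 6), ids = LETTERS[1:6],
                              centromere = 3, marker = 4)

word <- function(x, topology = "linear") ChromosomeStructure(x, topology)

# independent brute-force oracle: enumerate every event sequence of length
# <= kMax applied to `reference` (over the same junction model) and return
# the length of the shortest one reaching `target` up to rotation/mirror
# equivalence.  Implemented on plain signed-string words, separately from
# the package's search/constructive machinery.
oracleDistance <- function(reference, target, map, kMax = 3L) {
  normalize <- function(w, circ) {
    cands <- list()
    mirror <- function(v) {
      neg <- startsWith(v, "-")
      rev(ifelse(neg, substring(v, 2), paste0("-", v)))
    }
    if (circ) {
      n <- length(w)
      for (k in seq_len(n) - 1L) {
        r <- w[((seq_len(n) - 1L + k) %% n) + 1L]
        cands[[length(cands) + 1L]] <- r
        cands[[length(cands) + 1L]] <- mirror(r)
      }
    } else {
      cands <- list(w, mirror(w))
    }
    keys <- vapply(cands, paste, character(1), collapse = ",")
    paste(if (circ) "c" else "l", min(keys))
  }
  applyOp <- function(w, circ, kind, j1, j2) {
    n <- length(w)
    spanOf <- function() {
      if (j1 < j2) j1:(j2 - 1L)
      else if (circ) c(j1:n, if (j2 > 1L) 1:(j2 - 1L)) else NULL
    }
    valid <- if (circ) seq_len(n) else if (n >= 2L) 2:n else integer(0)
    if (!(j1 %in% valid) || !(j2 %in% valid)) return(NULL)
    if (kind == "circ") {
      if (circ || j1 >= j2) return(NULL)
      return(list(w = w[j1:(j2 - 1L)], circ = TRUE))
    }
    if (!circ && j1 >= j2) return(NULL)
    span <- spanOf()
    if (is.null(span) || length(span) >= n) return(NULL)
    mirrorSeg <- function(v) {
      neg <- startsWith(v, "-")
      rev(ifelse(neg, substring(v, 2), paste0("-", v)))
    }
    if (kind == "del") list(w = w[-span], circ = circ)
    else if (kind == "inv") {
      w[span] <- mirrorSeg(w[span]); list(w = w, circ = circ)
    } else list(w = append(w, w[span], after = span[length(span)]),
                circ = circ)
  }
  w0 <- structureWord(reference)
  c0 <- topology(reference) == "circular"
  targetKey <- normalize(structureWord(target),
                         topology(target) == "circular")
  if (normalize(w0, c0) == targetKey) return(0L)
  frontier <- list(list(w = w0, circ = c0))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(normalize(w0, c0), TRUE, envir = seen)
  for (depth in seq_len(kMax)) {
    nxt <- list()
    for (node in frontier) {
      n <- length(node$w)
      for (kind in c("del", "inv", "dup", "circ")) {
        for (j1 in seq_len(n)) for (j2 in seq_len(n + 1L)) {
          if (j1 == j2) next
          res <- applyOp(node$w, node$circ, kind, j1, j2)
          if (is.null(res)) next
          key <- normalize(res$w, res$circ)
          if (key == targetKey) return(depth)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- res
          }
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  NA_integer_
}

# exact hypergeometric upper tail by combinatorial enumeration (oracle for
# the enrichment test)
hyperTailManual <- function(hits, setSize, universe, drawn) {
  ks <- hits:min(setSize, drawn)
  sum(choose(setSize, ks) * choose(universe - setSize, drawn - ks)) /
    choose(universe, drawn)
}
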