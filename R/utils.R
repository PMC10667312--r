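#' @include AllClasses.R
NULL

.saveRngState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRngState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# run `expr` under `seed` (if non-NULL) without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  state <- .saveRngState()
  on.exit(.restoreRngState(state))
  set.seed(seed)
  expr
}

# underlying negative-binomial mean whose zero-truncated law has mean `m`
.ztnbMu <- function(m, size) {
  stopifnot(m > 1)
  f <- function(mu) mu / (1 - stats::dnbinom(0, size = size, mu = mu)) - m
  stats::uniroot(f, c(1e-9, m), tol = 1e-10)$root
}

# draw n variates from the zero-truncated negative binomial with truncated
# mean `m` and dispersion `size` (rejection sampling; truncation keeps the
# long right tail intact)
.rztnb <- function(n, m, size) {
  mu <- .ztnbMu(m, size)
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnbinom(length(todo), size = size, mu = mu)
    ok <- draw > 0L
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# md5 of a serializable object via its canonical JSON (tools::md5sum needs a
# file)
.configHash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(tmp))
}
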