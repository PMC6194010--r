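#' @keywords internal
"_PACKAGE"

## Random draws are made inside a local RNG scope so that generators are
## reproducible for a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive child seeds from a single master seed
#'
#' All randomness in a pipeline run flows from one user-supplied integer
#' seed. Stage seeds are derived deterministically as
#' \code{(seed + i * 10007) mod (2^31 - 1)} for stage index \code{i}, which
#' keeps them valid 32-bit integers and decorrelates the per-stage streams.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  as.integer((as.numeric(seed) + seq_len(n) * 10007) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## 32-bit FNV-1a over a deparsed object; used to stamp outputs with a
## configuration fingerprint.
fnv1a_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
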