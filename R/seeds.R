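#' Derive a named seed stream from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed from one global
#' integer through a named stream, so a stage can be regenerated on its own
#' without replaying the stages before it.
#'
#' @param seed integer global seed.
#' @param name character stream name, e.g. `"geometry"` or `"subject_3"`.
#' @return an integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double range
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# run code under a temporary RNG state seeded from (seed, name)
with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  force(code)
}
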