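# internal helpers shared across modules

#' Derive a named RNG substream seed from a master seed
#'
#' All stochastic stages consume a seed derived deterministically from the
#' single user-facing seed plus the stage name, so stages are reproducible
#' independently of execution order.
#'
#' @param seed master integer seed.
#' @param name character stage name.
#' @return an integer seed in [0, 2^31 - 1].
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

# evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a classed condition so pipeline stages can tag errors
igene_abort <- function(message, class = "igenes_error", ...) {
  rlang::abort(message, class = c(class, "igenes_error"), ...)
}
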