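## internal helpers: deterministic RNG substreams and small assertions

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic substream seed
#'
#' Combines a master seed with a character tag (e.g. scheme name, replicate
#' index) into a reproducible 31-bit seed, so that independent operations draw
#' from non-overlapping, order-insensitive random streams.
#'
#' @param seed Integer master seed.
#' @param ... Tag components (coerced to character) identifying the substream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 31 + h) %% 2147483629)
}

## evaluate `code` under `seed` without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_prob <- function(x, field, open_upper = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    (if (open_upper) all(x < 1) else all(x <= 1))
  if (!ok) stop_config(field, "must lie in [0,1]")
  invisible(x)
}
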