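## Internal helpers: seeded evaluation, named substreams, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent substream seed from a master seed and a stream name.
#'
#' A small string hash keeps substreams (variant design, expression,
#' fragmentation, ...) decoupled, so enlarging one simulation stage does not
#' perturb another. Result is always a valid 32-bit seed.
#' @noRd
seed_stream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

tb_log <- function(..., verbose = getOption("txbench.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[txbench] ", ...)
}

## round-half-up (base round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

stop_txbench <- function(..., class = "txbench_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
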