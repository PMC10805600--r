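# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores whatever stream was active before, so that seeded package
#' functions never perturb the caller's RNG state. A `NULL` seed means
#' "use the current stream".
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

#' Derive a sub-seed from a master seed and a counter
#'
#' Counter-based seed splitting: replicate `i` (or clade `i`) always gets the
#' same sub-seed for a given master seed, independent of the order in which
#' units are simulated. Values stay below 2^31 - 1 so they are valid R
#' integer seeds.
#'
#' @param seed integer master seed.
#' @param index non-negative integer counter.
#' @return integer sub-seed.
#' @export
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647
  s <- ((abs(seed) %% m) * 48271 + (index %% m) * 16807 + 12345) %% m
  as.integer(s + 1)
}

# stop() with a message assembled via sprintf
stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
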