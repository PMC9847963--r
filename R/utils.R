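# Internal helpers: classed conditions, seeded evaluation, logging.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "iadct_validation_error", ...)
}

abort_identifiability <- function(msg, ...) {
  rlang::abort(msg, class = "iadct_identifiability_error", ...)
}

warn_iadct <- function(msg, class) {
  rlang::warn(msg, class = class)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions do not perturb user-level random streams.
#' @noRd
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# One reproducible substream per (participant, stream) pair, derived from the
# master seed. Kept below 2^31 - 1 so set.seed() accepts it; arithmetic stays
# exact in doubles (< 2^53).
derive_seed <- function(seed, participant_index, stream) {
  ((as.numeric(seed) %% 1e6) * 1000003 +
     as.numeric(participant_index) * 1009 +
     as.numeric(stream)) %% 2147483647
}

iad_log <- function(msg, level = c("info", "warn")) {
  level <- match.arg(level)
  if (isTRUE(getOption("iadct.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  toupper(level), msg))
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}
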