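#' Derive a child seed from a master seed and a key
#'
#' Deterministically maps a master seed plus an arbitrary character key to an
#' integer seed in `[1, 2^31 - 2]`. Used so that every stochastic stage of the
#' pipeline (epoch synthesis, ratings, hyperparameter search) draws from its
#' own reproducible stream while the user supplies a single master seed.
#'
#' @param seed Integer master seed.
#' @param ... Components of the key (coerced to character and concatenated).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(c(format(seed), vapply(list(...), as.character, character(1))),
               collapse = "/")
  # FNV-1a style rolling hash in double precision (exact below 2^53)
  m <- 2147483647
  h <- 2166136261
  for (cc in utf8ToInt(key)) {
    h <- (bitwXor(as.integer(h %% 2^31), cc) * 16777619) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

#' Evaluate an expression with a local RNG seed
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Stop with a configuration error naming the offending field
#' @keywords internal
#' @noRd
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' Simple stage logger
#'
#' Writes a timestamped message to `con` (default `stderr()`); used by
#' [run_pipeline()] for structured per-stage logging.
#' @keywords internal
#' @noRd
log_stage <- function(fmt, ..., con = NULL) {
  msg <- sprintf(fmt, ...)
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  if (is.null(con)) message(line) else writeLines(line, con)
  invisible(line)
}
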