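# Small shared helpers: logging and seeded evaluation.

.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"

#' Set the logging verbosity
#' @param level One of "quiet", "info", "debug".
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "quiet", "debug")) {
  level <- match.arg(level)
  old <- .log_env$level
  .log_env$level <- level
  invisible(old)
}

ds_log <- function(fmt, ..., level = "info") {
  if (.log_env$level == "quiet") return(invisible(NULL))
  if (level == "debug" && .log_env$level != "debug") return(invisible(NULL))
  message(sprintf(paste0("[delscan] ", fmt), ...))
  invisible(NULL)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Used so every stochastic entry point takes an explicit `seed` argument and
# a run is reproducible without touching the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-stream child seed from a master seed, stably (stream-split so
# per-gene results do not depend on gene order). Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 69069 + 12345 * as.double(stream)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
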