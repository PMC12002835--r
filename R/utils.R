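# Internal helpers shared across modules: seed management, validation,
# and stage-tagged logging.

#' Derive a reproducible child seed for a named random stream
#'
#' A single user-facing seed is expanded into independent per-stream seeds
#' (expression, noise, sex, dropout, ...) so that adding a stream to a
#' generator never perturbs the draws of existing streams. The derivation is
#' a small multiplicative hash kept strictly below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stream Character stream label.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 12345) %% 2147483563)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Stage-tagged message to stderr; suppressible via options(vascage.quiet = TRUE).
vg_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("vascage.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stop_named <- function(name, fmt, ...) {
  cond <- structure(
    class = c(name, "vascage_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  )
  stop(cond)
}

# Smallest reportable p-value; p-values are never reported as exactly 0.
.p_floor <- .Machine$double.xmin

floor_p <- function(p) {
  flagged <- is.finite(p) & p <= 0
  p[flagged] <- .p_floor
  p[is.finite(p) & p > 1] <- 1   # guard rounding overshoot from backends
  list(p = p, floored = flagged)
}
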