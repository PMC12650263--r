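#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c("createlab_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_validation("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# Deterministic child seed for a (base seed, stream label) pair; keeps every
# derived seed inside the 32-bit integer range R requires.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  raw <- utf8ToInt(parts)
  h <- 0
  for (v in raw) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Run an expression with a locally derived RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
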