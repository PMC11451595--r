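# Internal helpers: classed conditions and seeded evaluation.

stop_classed <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "kvperm_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_input    <- function(msg) stop_classed("kvperm_input_error", msg)
stop_geometry <- function(msg) stop_classed("kvperm_geometry_error", msg)
stop_value    <- function(msg) stop_classed("kvperm_value_error", msg)
stop_config   <- function(msg) stop_classed("kvperm_config_error", msg)
stop_internal <- function(msg) stop_classed("kvperm_internal_error", msg)

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_value("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
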