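# Classed conditions so callers (and the CLI) can map failures to exit codes.

stop_pargwas <- function(msg, class) {
  stop(structure(
    class = c(class, "pargwas_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format    <- function(msg) stop_pargwas(msg, "pargwas_format_error")
stop_parameter <- function(msg) stop_pargwas(msg, "pargwas_parameter_error")
stop_io        <- function(msg) stop_pargwas(msg, "pargwas_io_error")
stop_empty     <- function(msg) stop_pargwas(msg, "pargwas_empty_error")
stop_merge     <- function(msg) stop_pargwas(msg, "pargwas_merge_error")
stop_consistency <- function(msg) stop_pargwas(msg, "pargwas_consistency_error")
stop_usage     <- function(msg) stop_pargwas(msg, "pargwas_usage_error")

# Run `code` under a fixed RNG state without disturbing the caller's stream.
# All stochastic operations in the package funnel through this helper so a
# single integer seed reproduces a whole run.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_parameter("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= min
}
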