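# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make unit counts depend on the parity of density * volume.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL means "use the ambient stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("'seed' must be a single finite number or NULL")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a per-stage seed from a master seed by a fixed documented offset,
# keeping the result inside 32-bit integer range (2147483629 is prime).
derive_seed <- function(master, offset) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) * 48271 + offset) %% 2147483629)
}

stop_with <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "spikebench_error")))
}

stop_validation    <- function(msg, ...) stop_with("spikebench_validation_error", msg, ...)
stop_configuration <- function(msg, ...) stop_with("spikebench_configuration_error", msg, ...)
stop_scheduling    <- function(msg, ...) stop_with("spikebench_scheduling_error", msg, ...)
stop_export        <- function(msg, ...) stop_with("spikebench_export_error", msg, ...)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name) {
  if (!is_scalar_num(x) || x < 0 || x > 1) {
    stop_validation(sprintf("'%s' must be a proportion in [0, 1]", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
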