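#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme used everywhere the package needs an
#' independent random stream for a sub-task (one fly, one threshold, one
#' subsampling partition, ...). Each component of the task label is folded
#' into a linear-congruential hash, so the derived seed depends only on the
#' master seed and the label -- never on the order in which tasks are
#' evaluated. Character components are folded character by character.
#'
#' All arithmetic stays below 2^53 so the hash is exact in double precision;
#' the result lies in `[1, 2147483628]` and is always a valid R seed.
#'
#' @param master integer master seed.
#' @param ... integer or character label components identifying the sub-task.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "fly", 3)
#' derive_seed(1, "fly", 3) == derive_seed(1, "fly", 3)
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629 # prime below 2^31
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(paste(part, collapse = "/")) else as.numeric(part)
    for (x in codes) {
      h <- (h * 69069 + x + 1) %% m
    }
  }
  as.integer(h %% 2147483628 + 1)
}

# Run code under a local, seeded RNG without touching the caller's stream.
# seed = NULL evaluates code against the current stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stop_invalid <- function(msg) {
  abort(msg, class = "flymi_error_invalid_parameter")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < lower) {
    stop_invalid(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}
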