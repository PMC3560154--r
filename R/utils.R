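# internal helpers: argument checks and reproducible RNG scoping

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_boundary = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (allow_boundary) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    stop_input(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

check_count_vector <- function(x, name = "counts") {
  if (!is.numeric(x) || length(x) == 0L) {
    stop_input(sprintf("`%s` must be a non-empty numeric vector", name))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_input(sprintf("`%s` contains missing or non-finite values", name))
  }
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop_input(sprintf("`%s` must contain non-negative integers", name))
  }
  invisible(round(x))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a reproducible child seed
#'
#' Mixes a root seed with a sequence of integer indices (repetition, stage,
#' replicate count, ...) into a new seed, so that nested simulation stages
#' draw from independent, individually reproducible streams. The map is a
#' fixed congruential hash; all arithmetic stays below 2^53 so results are
#' exact, and the output lies in `[1, 2^31 - 2]`.
#'
#' @param seed Integer root seed.
#' @param ... Integer indices identifying the child stream.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, 3, 7)
child_seed <- function(seed, ...) {
  check_scalar_number(seed, "seed")
  idx <- c(...)
  x <- abs(as.double(seed)) %% 2147483647
  for (k in idx) {
    check_scalar_number(k, "index")
    x <- (x * 69069 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(x %% 2147483645 + 1)
}
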