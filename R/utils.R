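#' Derive a reproducible child seed from a base seed and string tags
#'
#' Every stochastic stage of the pipeline draws its random numbers from a
#' stream seeded by the single user-supplied seed plus a small set of string
#' tags naming the stage (and, where relevant, the gene, group and dose).
#' This keeps stages reproducible in isolation: re-running one stage with the
#' same base seed gives identical output regardless of what ran before it.
#'
#' @param seed Integer base seed.
#' @param ... Character or numeric tags identifying the consumer.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1L, "ev", "N0", "0")
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (c in utf8ToInt(tags)) {
    # 31-based rolling hash modulo the Mersenne prime 2^31 - 1
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so library internals do not perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
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
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_field(field, sprintf("must be > %g", lower))
  }
  if (!strict_lower && x < lower) {
    stop_field(field, sprintf("must be >= %g", lower))
  }
  if (x > upper) stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}
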