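# internal helpers

.asun <- new.env(parent = emptyenv())

asun_stop <- function(subclass, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(subclass, "asunpbpk_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a fixed RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    asun_stop("validation_error", "seed must be a single number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# linear interpolation of a table column over tabulated ages (constant
# extrapolation at the ends, though ages are validated to lie inside)
interp_age <- function(tab_ages, values, age) {
  stats::approx(tab_ages, values, xout = age, rule = 2)$y
}

# lognormal multiplier with arithmetic CV `cv` and mean 1
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

check_positive <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0)
    asun_stop("validation_error", "%s must be a positive number", name)
  invisible(x)
}
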