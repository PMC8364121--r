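#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov chisq.test coef complete.cases cor lm pt quantile
#'   rnorm rbinom runif sd setNames anova as.formula model.matrix pf
#' @importFrom utils write.table read.table head
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# All seeded operations in the package route through this so that a
# user-level seed never perturbs (and is never perturbed by) the global RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar checks used across constructors
stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower) {
    if (x <= lower) stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("'%s' must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("'%s' must be <= %s", name, upper), call. = FALSE)
  invisible(x)
}
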