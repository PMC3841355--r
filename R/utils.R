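#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never disturb an enclosing simulation.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
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

#' Percentage with fixed rounding
#'
#' Adherence/accounting helper: `100 * k / n` rounded to `digits` decimals,
#' the convention used for CONSORT-style percentages (e.g. 109/114 -> 95.6).
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
#' @examples
#' adherence_pct(104, 114)  # 91.2
adherence_pct <- function(k, n, digits = 1) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  round(100 * k / n, digits)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# TRUE when a vector is constant to numerical precision (its spread is
# negligible relative to its magnitude), in which case t statistics are
# undefined
near_constant <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(TRUE)
  r <- range(x)
  (r[2] - r[1]) <= 1e-10 * max(abs(r), 1e-300)
}

# stop unless all named conditions hold; messages name the violated rule
check_that <- function(...) {
  conds <- list(...)
  nm <- names(conds)
  for (i in seq_along(conds))
    if (!isTRUE(all(conds[[i]]))) stop(nm[i], call. = FALSE)
  invisible(TRUE)
}
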