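# Internal helpers shared across modules.

# mmHg -> Pa conversion factor.
MMHG_TO_PA <- 133.322

#' Convert a pressure value to pascals
#'
#' @param x numeric vector of pressures.
#' @param unit one of `"Pa"`, `"mmHg"`.
#' @return numeric vector in Pa.
#' @keywords internal
#' @noRd
to_pascal <- function(x, unit) {
  switch(unit,
    Pa = x,
    mmHg = x * MMHG_TO_PA,
    stop("unknown pressure unit: ", unit, call. = FALSE)
  )
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a named 32-bit substream seed from a top-level seed so independent
# generators do not share streams.
substream_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65521L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  if (!allow_inf && !is.finite(x)) stopf("`%s` must be finite", name)
  if (x < lower || x > upper) {
    stopf("`%s` = %g outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}
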