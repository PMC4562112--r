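# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring .Random.seed after.
# seed = NULL means "use the current RNG stream unchanged".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Report-level rounding: the field's tables print distances to 0.1 mm and
# percentages to 0.1 %.  Machine-readable outputs keep full precision.
round_report <- function(x, digits = 1) round(x, digits = digits)

deg2rad <- function(deg) deg * pi / 180

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
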