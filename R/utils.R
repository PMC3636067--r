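#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), unlike [round()]'s
#' round-half-to-even.  Used for ordinal score arithmetic and CID scaling.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Days per year used for all calendar conversions.
DAYS_PER_YEAR <- 365.25

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, then restores the caller's RNG state so that
#' seeded package functions do not perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Counter-based fan-out: each pipeline stage gets an independent,
#' reproducible seed so inserting a stage never perturbs earlier streams.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 1).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(stage), length(stage) == 1L)
  s <- (abs(master) * 48271 + stage * 100003) %% 2147483629
  as.integer(s + 1)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop_field(field, "must be a single positive finite number")
  value
}

check_nonneg <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 0)
    stop_field(field, "must be a single nonnegative finite number")
  value
}

check_count <- function(value, field, min = 1) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < min || value != floor(value))
    stop_field(field, sprintf("must be an integer >= %s", min))
  as.integer(value)
}
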