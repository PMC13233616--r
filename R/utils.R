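#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in
#' conservation reports conventionally round half up. Used everywhere a
#' percentage is formatted.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## argument checks ----------------------------------------------------------

stop_invalid <- function(...) {
  stop(structure(class = c("divprior_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop_invalid(name, " must be a single integer >= ", min, " (got ", deparse(x), ")")
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < lo || x > hi || (lo_open && x == lo) || (hi_open && x == hi))
    stop_invalid(name, " must lie in ", if (lo_open) "(" else "[", lo, ", ", hi,
                 if (hi_open) ")" else "]", " (got ", deparse(x), ")")
  as.numeric(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("seed must be a single integer")
  as.integer(seed)
}

## seeded evaluation without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(check_seed(seed))
  expr
}

## derive a stream of sub-seeds from a master seed, kept below 2^31
derive_seeds <- function(seed, n, salt = 0L) {
  (as.double(check_seed(seed)) * 48271 + salt * 16807 + seq_len(n) * 69621) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample() without the scalar-x gotcha: x is always treated as a set
safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
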