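## Internal helpers shared across modules.

#' Convert dates to decimal years
#'
#' Accepts numeric decimal years (returned unchanged), `Date` objects, or
#' ISO-8601 date strings. Conversion is `year + (day_of_year - 1) / 365.25`.
#'
#' @param x numeric, `Date`, or character vector.
#' @return numeric vector of decimal years.
#' @export
decimal_year <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x)) {
    num <- suppressWarnings(as.numeric(x))
    if (!anyNA(num)) return(num)
    x <- as.Date(x)
  }
  if (!inherits(x, "Date")) stop("cannot convert to decimal years: ", class(x)[1])
  yr <- as.integer(format(x, "%Y"))
  doy <- as.integer(format(x, "%j"))
  yr + (doy - 1) / 365.25
}

## Evaluate expr with a temporary RNG state seeded from `seed`,
## restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

## Derive a stream-specific child seed from a master seed. Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Manhattan (L1) distances between rows of x and rows of y -> |x| x |y| matrix.
manhattan_dist <- function(x, y = x) {
  x <- as.matrix(x); y <- as.matrix(y)
  out <- matrix(0, nrow(x), nrow(y))
  for (j in seq_len(nrow(y)))
    out[, j] <- rowSums(abs(sweep(x, 2, y[j, ], "-")))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
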