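## Small shared helpers: unit parsing, deterministic sub-seeds, RNG streams,
## and bilinear field sampling.

#' Parse a duration into seconds
#'
#' Accepts a bare number (seconds) or a string with an `h`, `min`, `s` or
#' `ms` suffix, e.g. `"16h"`, `"5min"`, `"30s"`, `"500ms"`, `"1.5h"`.
#'
#' @param x A single number or string.
#' @return Duration in seconds (numeric scalar).
#' @examples
#' parse_duration("5min")   # 300
#' parse_duration("16h")    # 57600
#' @export
parse_duration <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1L || is.na(x)) stop("duration must be a single number")
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) stop("duration must be a number or string")
  m <- regmatches(x, regexec("^\\s*([0-9]*\\.?[0-9]+)\\s*(ms|s|min|m|h)?\\s*$", x))[[1]]
  if (length(m) == 0L) stop(sprintf("cannot parse duration '%s'", x))
  val <- as.numeric(m[2])
  unit <- if (m[3] == "") "s" else m[3]
  val * switch(unit, ms = 1e-3, s = 1, m = 60, min = 60, h = 3600)
}

#' Derive a deterministic sub-seed from a master seed and a string key
#'
#' Used to give every stage position (and every assay stage) its own
#' independent, reproducible random stream. The result is always a
#' non-negative integer below 2^31.
#'
#' @param seed Master integer seed.
#' @param key Character key (e.g. a position name).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## A resumable RNG stream: an environment holding a .Random.seed snapshot.
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  env
}

## Evaluate expr with the stream's RNG state active; save the advanced state.
with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

## Bilinear sampling of a matrix field at physical coordinates (um).
## field is [row, col] = [y, x]; pixel centres at (i - 0.5) * pixel_size.
## Outside coordinates are clamped ("reflect"/default) or wrapped ("wrap").
sample_field <- function(field, x_um, y_um, pixel_size, boundary = "reflect") {
  nr <- nrow(field); nc <- ncol(field)
  cx <- x_um / pixel_size - 0.5  # 0-based continuous pixel coords
  cy <- y_um / pixel_size - 0.5
  if (boundary == "wrap") {
    idx <- function(i, n) (i %% n) + 1L
    x0 <- floor(cx); y0 <- floor(cy)
    fx <- cx - x0; fy <- cy - y0
    r0 <- idx(y0, nr); r1 <- idx(y0 + 1, nr)
    c0 <- idx(x0, nc); c1 <- idx(x0 + 1, nc)
  } else {
    cx <- clamp(cx, 0, nc - 1); cy <- clamp(cy, 0, nr - 1)
    x0 <- floor(cx); y0 <- floor(cy)
    fx <- cx - x0; fy <- cy - y0
    r0 <- y0 + 1L; r1 <- pmin(y0 + 2L, nr)
    c0 <- x0 + 1L; c1 <- pmin(x0 + 2L, nc)
  }
  f00 <- field[cbind(r0, c0)]; f01 <- field[cbind(r0, c1)]
  f10 <- field[cbind(r1, c0)]; f11 <- field[cbind(r1, c1)]
  (1 - fy) * ((1 - fx) * f00 + fx * f01) + fy * ((1 - fx) * f10 + fx * f11)
}

## Central-difference gradient of a field, per micrometre.
## Returns list(gx, gy) matrices. Wrap or replicate boundary.
field_gradient <- function(field, pixel_size, boundary = "reflect") {
  nr <- nrow(field); nc <- ncol(field)
  if (boundary == "wrap") {
    up <- field[c(nr, 1:(nr - 1)), , drop = FALSE]
    dn <- field[c(2:nr, 1), , drop = FALSE]
    lf <- field[, c(nc, 1:(nc - 1)), drop = FALSE]
    rt <- field[, c(2:nc, 1), drop = FALSE]
  } else {
    up <- field[c(1, 1:(nr - 1)), , drop = FALSE]
    dn <- field[c(2:nr, nr), , drop = FALSE]
    lf <- field[, c(1, 1:(nc - 1)), drop = FALSE]
    rt <- field[, c(2:nc, nc), drop = FALSE]
  }
  list(gx = (rt - lf) / (2 * pixel_size), gy = (dn - up) / (2 * pixel_size))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
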