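## Internal helpers shared across the package.

## Round half away from zero (R's round() is round-half-even); schedules must
## be bit-reproducible across platforms, so the tie rule is fixed here.
roundHalfUp <- function(x) floor(x + 0.5)

## Derive a child seed from a parent seed and an integer offset. A fixed-point
## multiplicative hash keeps results inside the 32-bit integer range so that
## set.seed() accepts them on every platform.
deriveSeed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) + 1
  o <- as.double(offset) %% 2147483647
  as.integer((s * 48271 + o * 1299721 + 12345) %% 2147483647)
}

## Stable hash used to give each view its own noise stream.
viewOffset <- function(view) {
  sum(utf8ToInt(view) * seq_along(utf8ToInt(view)) * 131)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isSquareNumericMatrix <- function(m) {
  is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)
}
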