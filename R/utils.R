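# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring caller RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a sub-seed from a run seed, kept inside 32-bit integer range.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483629L)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# H x W x 3 [0,255] array  <->  EBImage Image (x = width major, [0,1])
toEB <- function(pixels) {
  EBImage::Image(aperm(pixels, c(2L, 1L, 3L)) / 255,
                 colormode = "Color")
}
fromEB <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  clip255(aperm(a, c(2L, 1L, 3L)) * 255)
}

#' Round a reported metric the way the reference tables do
#'
#' Rounds to `digits` decimals with exact halves resolved to the even
#' neighbour (so 0.625 -> 0.62 and 0.675 -> 0.68 at 2 decimals). Ratios of
#' small integer counts land exactly on decimal halves often enough that the
#' tie rule is visible in reported confusion-matrix metrics.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' reportRound(50 / 80, 2)  # 0.62
#' reportRound(0.675, 2)    # 0.68
reportRound <- function(x, digits = 2) {
  p <- 10^digits
  r <- x * p
  f <- r - floor(r)
  half <- abs(f - 0.5) < 1e-9
  out <- ifelse(half,
                ifelse(floor(r) %% 2 == 0, floor(r), floor(r) + 1),
                round(r))
  out / p
}
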